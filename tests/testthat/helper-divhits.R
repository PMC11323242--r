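# Shared fixtures. Parsed libraries are cached for the session so that the
# OpenBabel work is paid once per (n, seed) across test files.

.divhits_test_cache <- new.env(parent = emptyenv())

cached_library <- function(n, seed) {
  key <- sprintf("lib_%d_%d", n, seed)
  if (is.null(.divhits_test_cache[[key]]))
    .divhits_test_cache[[key]] <- make_library(n, seed = seed)
  .divhits_test_cache[[key]]
}

# A fresh task (fresh diversity-filter state!) over a cached library.
cached_task <- function(n, seed, n_actives = 6L, ...) {
  make_benchmark_task(cached_library(n, seed), n_actives = n_actives, ...)
}

# Hand-built molecule record for filter-semantics tests; fields mirror the
# documented public structure.
mock_record <- function(mw = 400, logp = 2, fp = c(1L, 2L, 3L), keys = fp,
                        valid = TRUE, smiles = "mock") {
  structure(list(input_smiles = smiles, canonical_smiles = smiles,
                 valid = valid, fingerprint = fp, substructure_keys = keys,
                 mw = mw, logp = logp),
            class = "molecule_record")
}

random_fp_set <- function(n, space = 0:63, min_on = 3L, max_on = 14L) {
  lapply(seq_len(n), function(i) sort(sample(space, sample(min_on:max_on, 1L))))
}

# Independent oracle for #Circles: exhaustive enumeration over all 2^n
# subsets via bitmasks (n <= 14).
brute_force_circles <- function(items, dist, D) {
  n <- length(items)
  stopifnot(n >= 1L, n <= 14L)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    conflict[i, j] <- conflict[j, i] <- dist(items[[i]], items[[j]]) <= D
  }
  pows <- 2^(0:(n - 1L))
  adj <- vapply(seq_len(n), function(i) sum(pows[conflict[i, ]]), 0)
  M <- 0:(2^n - 1)
  B <- outer(M, pows, function(m, p) bitwAnd(m, p) != 0)
  ok <- rep(TRUE, length(M))
  for (i in seq_len(n)) ok <- ok & (!B[, i] | bitwAnd(M, adj[i]) == 0)
  max(rowSums(B)[ok])
}

# Distance oracle backed by an explicit symmetric matrix over indices.
matrix_dist <- function(dm) function(i, j) dm[i, j]

# A log data frame with the canonical columns.
make_log <- function(smiles, raw, pp = TRUE, dfp = TRUE, final = raw,
                     elapsed = 0) {
  k <- length(smiles)
  data.frame(call_index = seq_len(k) - 1L,
             elapsed_seconds = rep_len(elapsed, k),
             canonical_smiles = smiles,
             raw_oracle = rep_len(raw, k),
             property_pass = rep_len(pp, k),
             df_pass = rep_len(dfp, k),
             final_score = rep_len(final, k),
             stringsAsFactors = FALSE)
}

fake_run <- function(log, generator, task, seed = 1L) {
  structure(list(log = log, seed = as.integer(seed), generator_name = generator,
                 task_name = task, constraint_mode = "sample_limit",
                 calls_consumed = nrow(log), aborted = FALSE),
            class = "run_result")
}
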