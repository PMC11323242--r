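# Deterministic synthetic molecule libraries, toy bioactivity oracles, and
# abstract metric-space generators, so that every module is testable offline.
# The fixture chemistry is enumerated (ring scaffolds decorated with common
# substituents), not sampled from external collections, which keeps the
# package download-free; it stands in for a public screening library in all
# tests and examples.

FIXTURE_BASES <- c(
  "c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "C1CCCCC1", "c1ccsc1",
  "c1ccoc1", "C1CCNCC1", "c1cncnc1", "c1ccc2[nH]ccc2c1", "c1ccc(-c2ccccc2)cc1")

FIXTURE_TEMPLATES_1 <- c(
  "c1ccc(%s)cc1",            # benzene
  "c1ccnc(%s)c1",            # pyridine
  "c1ccc2cc(%s)ccc2c1",      # naphthalene
  "C1CCC(%s)CC1",            # cyclohexane
  "c1cc(%s)cs1",             # thiophene
  "c1cc(%s)co1",             # furan
  "C1CCN(%s)CC1",            # piperidine (N-subst)
  "c1cnc(%s)nc1",            # pyrimidine
  "c1ccc2[nH]c(%s)cc2c1",    # indole
  "c1ccc(-c2ccc(%s)cc2)cc1") # biphenyl

FIXTURE_TEMPLATES_2 <- c(
  "c1cc(%s)ccc1%s",          # para-disubstituted benzene
  "c1cc(%s)cc(%s)c1",        # meta-disubstituted benzene
  "c1nc(%s)ccc1%s",          # disubstituted pyridine
  "C1CC(%s)CCC1%s",          # disubstituted cyclohexane
  "c1ccc2cc(%s)c(%s)cc2c1")  # disubstituted naphthalene

FIXTURE_SUBSTITUENTS <- c(
  "C", "CC", "CCC", "CCCC", "CCCCCC", "CCCCCCCCCC", "O", "OC", "N", "NC",
  "F", "Cl", "Br", "C(F)(F)F", "C(=O)O", "C(=O)OC", "C(=O)N", "S(=O)(=O)N",
  "[N+](=O)[O-]", "CCO", "c2ccccc2", "Cc2ccccc2")

fixture_enumeration <- function() {
  s <- FIXTURE_SUBSTITUENTS
  one <- expand.grid(t = FIXTURE_TEMPLATES_1, s1 = s,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  two <- expand.grid(t = FIXTURE_TEMPLATES_2, s1 = s, s2 = s,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  c(FIXTURE_BASES,
    sprintf(one$t, one$s1),
    sprintf(two$t, two$s1, two$s2))
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Deterministic synthetic screening library
#'
#' Enumerates valid molecules by decorating a fixed list of ring scaffolds
#' (benzene, pyridine, naphthalene, cyclohexane, thiophene, furan,
#' piperidine, pyrimidine, indole, biphenyl) with common substituents
#' (halogens, alkyl chains, hydroxy/amino, carboxy/ester/amide, sulfonamide,
#' nitro, phenyl) at one or two positions. The enumeration order is shuffled
#' by `seed` and the first `n` unique, parseable molecules are returned, so
#' the same `(n, seed)` always yields the identical library. Molecular
#' weights span roughly 90-600 Da, so the default property filter rejects
#' some members (small fragments below 157 Da, greasy long-chain members
#' above logP 8.3).
#'
#' @param n Number of molecules (at least 1).
#' @param seed Integer seed for the enumeration order.
#' @param config A [fingerprint_config()].
#' @return A [screening_library()] with `n` records named `lib_0001`, ...
#' @export
make_library <- function(n, seed = 1L, config = fingerprint_config()) {
  stopifnot(n >= 1L)
  pool <- fixture_enumeration()
  if (n > length(pool))
    stop("n = ", n, " exceeds the enumerable fixture space (maximum ",
         length(pool), " candidate molecules)")
  pool <- with_local_seed(derive_seed(seed, "fixture-library"),
                          sample(pool, length(pool)))
  records <- list()
  seen <- character(0)
  i <- 1L
  while (length(records) < n && i <= length(pool)) {
    j <- min(i + 63L, length(pool))
    recs <- parse_molecules(pool[i:j], config)
    for (r in recs) {
      if (!isTRUE(r$valid) || r$canonical_smiles %in% seen) next
      records[[length(records) + 1L]] <- r
      seen <- c(seen, r$canonical_smiles)
      if (length(records) == n) break
    }
    i <- j + 1L
  }
  if (length(records) < n)
    stop("n = ", n, " exceeds the enumerable fixture space (only ",
         length(records), " unique valid molecules available)")
  names(records) <- sprintf("lib_%04d", seq_along(records))
  screening_library(records, name = sprintf("fixture-%d-seed%d", n, seed))
}

#' Toy oracle configuration
#'
#' @param active_seeds Character vector of SMILES for the "active" reference
#'   molecules; must be nonempty and valid.
#' @param steepness Positive exponent applied to the similarity (larger
#'   values make the activity landscape sharper around the seeds).
#' @param rng_seed Integer, reserved for stochastic oracle variants; the
#'   default oracle is fully deterministic.
#' @return An object of class `toy_oracle_config`.
#' @export
toy_oracle_config <- function(active_seeds, steepness = 1, rng_seed = 1L) {
  stopifnot(is.character(active_seeds), length(active_seeds) >= 1L,
            steepness > 0)
  structure(list(active_seeds = active_seeds, steepness = steepness,
                 rng_seed = as.integer(rng_seed)),
            class = "toy_oracle_config")
}

#' Similarity-based toy bioactivity oracle
#'
#' Emulates the contract of a probabilistic bioactivity classifier: a
#' deterministic map from a molecule to \[0, 1\], here
#' `max_tanimoto_similarity_to_seeds ^ steepness`. An active seed itself
#' scores 1; a molecule sharing no fingerprint bits with any seed scores 0.
#' Because the oracle is similarity-based, the diversity filter demonstrably
#' forces exploration: near-duplicates of a found hit are zeroed during
#' scoring yet remain hits in post-hoc evaluation.
#'
#' @param config A [toy_oracle_config()].
#' @param fp_config Fingerprint settings (must match the scoring context's).
#' @return A function mapping a `molecule_record` to a score in \[0, 1\]
#'   (invalid records score 0).
#' @export
make_toy_oracle <- function(config, fp_config = fingerprint_config()) {
  stopifnot(inherits(config, "toy_oracle_config"))
  seeds <- parse_molecules(config$active_seeds, fp_config)
  ok <- vapply(seeds, function(r) isTRUE(r$valid), TRUE)
  if (!all(ok))
    stop("invalid active seed(s): ",
         paste(config$active_seeds[!ok], collapse = ", "))
  seed_fps <- lapply(seeds, `[[`, "fingerprint")
  k <- config$steepness
  function(record) {
    if (inherits(record, "molecule_record")) {
      if (!isTRUE(record$valid)) return(0)
      fp <- record$fingerprint
    } else {
      fp <- record  # raw fingerprint also accepted
    }
    sim <- 1 - min(tanimoto_to_many(fp, seed_fps))
    sim^k
  }
}

#' Abstract clustered metric space
#'
#' The pathological configuration that cluster-blind diversity metrics get
#' wrong: `k_clusters` groups of `per_cluster` points each, with all
#' within-cluster distances equal to `intra_d` and all between-cluster
#' distances equal to `inter_d`. Any `0 < intra_d < inter_d` yields a valid
#' metric (the two-level ultrametric construction satisfies the triangle
#' inequality), which is verified at construction.
#'
#' @param k_clusters,per_cluster Positive integers.
#' @param intra_d,inter_d Within/between-cluster distances.
#' @return List with `points` (indices 1..n usable as metric items),
#'   `labels` (cluster assignment), and `dist` (vectorized distance oracle
#'   over point indices).
#' @export
make_clustered_points <- function(k_clusters, per_cluster, intra_d, inter_d) {
  stopifnot(k_clusters >= 1L, per_cluster >= 1L)
  if (!(intra_d > 0 && intra_d < inter_d))
    stop("need 0 < intra_d < inter_d for a valid clustered metric")
  # two-level construction: every triangle is (intra,intra,intra),
  # (intra,inter,inter) or (inter,inter,inter); all satisfy the triangle
  # inequality whenever 0 < intra_d < inter_d, so no further check is needed
  n <- k_clusters * per_cluster
  labels <- rep(seq_len(k_clusters), each = per_cluster)
  d <- function(i, j) {
    if (i == j) 0 else if (labels[i] == labels[j]) intra_d else inter_d
  }
  list(points = as.list(seq_len(n)), labels = labels, dist = d,
       k_clusters = k_clusters, per_cluster = per_cluster,
       intra_d = intra_d, inter_d = inter_d)
}

#' Assemble a complete benchmark task from a library
#'
#' Convenience wiring used by tests, examples and the acceptance script:
#' chooses `n_actives` mutually distant active seeds among the library
#' members that pass the default property filter (MaxMin picking, so the
#' actives cover several scaffold families), builds the similarity oracle
#' around them, and bundles everything into a scoring context whose
#' idiosyncrasy vocabulary is derived from the library itself. Deterministic
#' given the library.
#'
#' @param library A [screening_library()].
#' @param n_actives Number of active seed molecules.
#' @param steepness Oracle steepness, see [make_toy_oracle()].
#' @param S Hit threshold.
#' @param D_df Diversity-filter distance threshold (`NULL` disables the DF).
#' @param fp_config A [fingerprint_config()].
#' @return List with `library`, `oracle`, `context` (a [scoring_context()]),
#'   and `active_smiles`.
#' @export
make_benchmark_task <- function(library, n_actives = 8L, steepness = 1,
                                S = 0.5, D_df = 0.7,
                                fp_config = fingerprint_config()) {
  stopifnot(inherits(library, "screening_library"),
            n_actives >= 1L, n_actives <= length(library))
  vocab <- vocabulary_from_records(library)
  filters <- property_filter_config(reference_vocabulary = vocab)
  eligible <- which(vapply(library$records, property_filter, TRUE, cfg = filters))
  if (length(eligible) < n_actives)
    stop("library has only ", length(eligible),
         " members passing the property filter; need ", n_actives)
  fps <- lapply(library$records[eligible], `[[`, "fingerprint")
  ord <- maxmin_order(fps, start = 1L)
  active_idx <- eligible[ord[seq_len(n_actives)]]
  active_smiles <- vapply(library$records[active_idx], `[[`, "",
                          "canonical_smiles")
  oracle <- make_toy_oracle(toy_oracle_config(active_smiles,
                                              steepness = steepness),
                            fp_config)
  df <- if (is.null(D_df)) NULL else
    diversity_filter(distance_threshold = D_df, hit_score_threshold = S)
  list(library = library, oracle = oracle,
       context = scoring_context(oracle, filters = filters, df = df, S = S,
                                 fp_config = fp_config),
       active_smiles = unname(active_smiles))
}
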