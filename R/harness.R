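# Budget-constrained run loop around any generator, full per-call logging,
# and post-hoc conversion of logs into diverse-hit counts, budget curves and
# average-rank reports.

#' Computational budget
#'
#' The two constraint regimes of the benchmark: a sample limit (maximum
#' number of scoring-function evaluations, reference value 10000) and a time
#' limit (maximum wall seconds, reference value 600). At least the limit of
#' the active regime must be finite.
#'
#' @param max_calls Positive integer or `Inf`.
#' @param max_seconds Positive real or `Inf`.
#' @param mode `"sample_limit"` or `"time_limit"`. Under the sample limit the
#'   run is deterministic and log timestamps come from a virtual clock pinned
#'   at 0, so identical runs produce byte-identical logs; under the time
#'   limit the wall clock is used.
#' @return An object of class `budget_config`.
#' @export
budget_config <- function(max_calls = 10000, max_seconds = 600,
                          mode = c("sample_limit", "time_limit")) {
  mode <- match.arg(mode)
  stopifnot(max_calls > 0, max_seconds > 0)
  if (mode == "sample_limit" && !is.finite(max_calls))
    stop("sample_limit mode requires a finite max_calls")
  if (mode == "time_limit" && !is.finite(max_seconds))
    stop("time_limit mode requires a finite max_seconds")
  structure(list(max_calls = max_calls, max_seconds = max_seconds, mode = mode),
            class = "budget_config")
}

# Deterministic sub-seed derivation: one master seed fans out to named
# streams (generator, library shuffling, ...). Kept below 2^31.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

budget_exhausted_condition <- function() {
  structure(class = c("divhits_budget_exhausted", "condition"),
            list(message = "budget exhausted", call = NULL))
}

#' Signal/stop helper for generators
#'
#' Generators should call this when the budget view reports exhaustion; it
#' raises the condition that [run_generator()] interprets as a normal end of
#' run.
#' @keywords internal
#' @export
signal_budget_exhausted <- function() stop(budget_exhausted_condition())

#' Run a generator under a computational budget
#'
#' Wraps a molecule generator in the benchmark's run loop: every proposal is
#' parsed, scored with the composite scoring function, and logged with its
#' call index and elapsed time. Distinct canonical SMILES consume one unit of
#' the call budget each; repeated proposals are answered from a cache without
#' consuming budget (re-scoring a known molecule is free in any sane
#' deployment) but are still logged. The loop stops when the active budget is
#' exhausted or the generator returns.
#'
#' @param generator A function `function(score, budget_view, seed)`. `score`
#'   takes a character vector of SMILES and returns their final scores (it
#'   raises an internal condition when the budget runs out mid-batch);
#'   `budget_view()` returns a list with `calls_used`, `calls_remaining`,
#'   `elapsed_seconds` and `exhausted` so the generator can stop early.
#' @param context A [scoring_context()].
#' @param budget A [budget_config()].
#' @param seed Integer master seed; fans out to the generator stream. The
#'   run is deterministic under the sample limit.
#' @param generator_name,task_name Labels stored in the result (the generator
#'   may carry a `name` attribute used as default).
#' @param strict_counting If `TRUE`, duplicate proposals also consume budget
#'   (sensitivity analysis); default `FALSE`.
#' @return A `run_result`: list with `log` (data frame with columns
#'   `call_index`, `elapsed_seconds`, `canonical_smiles`, `raw_oracle`,
#'   `property_pass`, `df_pass`, `final_score`), `seed`, `generator_name`,
#'   `task_name`, `constraint_mode`, `calls_consumed`, `aborted`.
#' @export
run_generator <- function(generator, context, budget = budget_config(),
                          seed = 1L,
                          generator_name = attr(generator, "name"),
                          task_name = "task", strict_counting = FALSE) {
  stopifnot(is.function(generator), inherits(context, "scoring_context"),
            inherits(budget, "budget_config"))
  if (is.null(generator_name)) generator_name <- "generator"
  t0 <- proc.time()[["elapsed"]]
  clock <- if (budget$mode == "time_limit") {
    function() proc.time()[["elapsed"]] - t0
  } else {
    function() 0  # virtual clock: sample-limited runs are fully reproducible
  }

  env <- new.env(parent = emptyenv())
  env$rows <- vector("list", 1024L)
  env$n_rows <- 0L
  env$calls_used <- 0L
  env$answers <- new.env(parent = emptyenv())  # canonical smiles -> answer
  env$parse_cache <- new.env(parent = emptyenv())
  env$aborted <- FALSE

  exhausted <- function() {
    (is.finite(budget$max_calls) && env$calls_used >= budget$max_calls) ||
      (is.finite(budget$max_seconds) && clock() >= budget$max_seconds)
  }
  budget_view <- function() {
    list(calls_used = env$calls_used,
         calls_remaining = budget$max_calls - env$calls_used,
         elapsed_seconds = clock(),
         max_calls = budget$max_calls, max_seconds = budget$max_seconds,
         exhausted = exhausted())
  }
  log_row <- function(can, raw, pp, dfp, final) {
    env$n_rows <- env$n_rows + 1L
    if (env$n_rows > length(env$rows))
      env$rows <- c(env$rows, vector("list", length(env$rows)))
    env$rows[[env$n_rows]] <- list(call_index = env$n_rows - 1L,
                                   elapsed_seconds = clock(),
                                   canonical_smiles = can, raw_oracle = raw,
                                   property_pass = pp, df_pass = dfp,
                                   final_score = final)
  }
  score <- function(smiles) {
    stopifnot(is.character(smiles))
    out <- numeric(length(smiles))
    for (i in seq_along(smiles)) {
      if (exhausted()) signal_budget_exhausted()  # scored prefix stays logged
      smi <- smiles[i]
      key <- paste0("s:", smi)
      rec <- env$parse_cache[[key]]
      if (is.null(rec)) {
        rec <- parse_molecules(smi, context$fp_config)[[1L]]
        env$parse_cache[[key]] <- rec
      }
      can <- if (isTRUE(rec$valid)) rec$canonical_smiles else ""
      ans <- if (isTRUE(rec$valid) && !strict_counting)
        env$answers[[paste0("c:", can)]] else NULL
      if (is.null(ans)) {
        env$calls_used <- env$calls_used + 1L
        sc <- composite_score(rec, context)
        ans <- list(raw = sc$raw, pp = sc$property_pass, dfp = sc$df_pass,
                    final = sc$final)
        if (isTRUE(rec$valid)) env$answers[[paste0("c:", can)]] <- ans
      }
      log_row(can, ans$raw, ans$pp, ans$dfp, ans$final)
      out[i] <- ans$final
    }
    out
  }

  gseed <- derive_seed(seed, paste0("generator/", generator_name))
  set.seed(gseed)
  tryCatch(
    generator(score, budget_view, gseed),
    divhits_budget_exhausted = function(c) NULL,
    error = function(e) {
      warning("generator '", generator_name, "' raised: ", conditionMessage(e),
              "; partial log preserved", call. = FALSE)
      env$aborted <- TRUE
    })

  rows <- env$rows[seq_len(env$n_rows)]
  log <- if (length(rows) == 0L) {
    data.frame(call_index = integer(0), elapsed_seconds = numeric(0),
               canonical_smiles = character(0), raw_oracle = numeric(0),
               property_pass = logical(0), df_pass = logical(0),
               final_score = numeric(0), stringsAsFactors = FALSE)
  } else {
    data.frame(
      call_index = vapply(rows, `[[`, 0L, "call_index"),
      elapsed_seconds = vapply(rows, `[[`, 0, "elapsed_seconds"),
      canonical_smiles = vapply(rows, `[[`, "", "canonical_smiles"),
      raw_oracle = vapply(rows, `[[`, 0, "raw_oracle"),
      property_pass = vapply(rows, `[[`, TRUE, "property_pass"),
      df_pass = vapply(rows, `[[`, TRUE, "df_pass"),
      final_score = vapply(rows, `[[`, 0, "final_score"),
      stringsAsFactors = FALSE)
  }
  structure(list(log = log, seed = seed, generator_name = generator_name,
                 task_name = task_name, constraint_mode = budget$mode,
                 calls_consumed = env$calls_used, aborted = env$aborted),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run> %s on %s (seed %d, %s): %d proposals, %d budget calls%s\n",
              x$generator_name, x$task_name, x$seed, x$constraint_mode,
              nrow(x$log), x$calls_consumed,
              if (x$aborted) " [ABORTED]" else ""))
  invisible(x)
}

#' Number of budget-consuming oracle calls recorded in a log
#'
#' Recomputable from the log alone: every invalid proposal plus the first
#' occurrence of each distinct canonical SMILES.
#'
#' @param log A log data frame or `run_result`.
#' @return Integer count.
#' @export
budget_consumed <- function(log) {
  log <- as_evaluation_log(log)
  invalid <- !nzchar(log$canonical_smiles)
  sum(invalid) + length(unique(log$canonical_smiles[!invalid]))
}

#' Diverse hits in an evaluation log
#'
#' The post-hoc evaluation of a run: filters the log to hits (property filter
#' passed and raw oracle score >= `S`; the diversity filter is ignored so
#' that hits it suppressed still count), optionally truncates to
#' `elapsed_seconds <= time_cutoff`, deduplicates by canonical SMILES
#' (keeping first occurrences, i.e. discovery order), and counts diverse hits
#' with the #Circles metric at threshold `D_eval`.
#'
#' @param log A log data frame (e.g. from [read_log_csv()]) or `run_result`.
#' @param S Hit threshold; default 0.5.
#' @param D_eval Evaluation distance threshold; default 0.7, mirroring the
#'   diversity-filter threshold.
#' @param time_cutoff Optional wall-second cutoff applied to
#'   `elapsed_seconds` before evaluation (e.g. 600 for the time regime).
#' @param method `"auto"` (exact when at most `exact_limit` unique hits,
#'   greedy otherwise), `"greedy"` (scan in log order) or `"exact"`.
#' @param exact_limit Size bound for the exact solver under `"auto"`.
#' @param fp_config Fingerprint settings used to re-parse the hit SMILES.
#' @param dist Distance oracle over fingerprints.
#' @return A `diverse_hit_result`; attribute `n_hits` carries the number of
#'   unique hits before sphere exclusion, attribute `hit_smiles` the selected
#'   representatives.
#' @export
evaluate_log <- function(log, S = 0.5, D_eval = 0.7, time_cutoff = NULL,
                         method = c("auto", "greedy", "exact"),
                         exact_limit = 25L,
                         fp_config = fingerprint_config(),
                         dist = tanimoto_distance) {
  method <- match.arg(method)
  log <- as_evaluation_log(log)
  stopifnot(D_eval >= 0, D_eval <= 1)
  if (!is.null(time_cutoff)) log <- log[log$elapsed_seconds <= time_cutoff, ]
  hit <- is_hit(log$raw_oracle, log$property_pass, S) & nzchar(log$canonical_smiles)
  smi <- unique(log$canonical_smiles[hit])
  if (length(smi) == 0L) {
    res <- new_diverse_hit_result(integer(0), D_eval,
                                  if (method == "exact") "exact" else "greedy", 0L)
    attr(res, "n_hits") <- 0L
    attr(res, "hit_smiles") <- character(0)
    return(res)
  }
  recs <- parse_molecules(smi, fp_config)
  fps <- lapply(recs, `[[`, "fingerprint")
  if (method == "auto")
    method <- if (length(fps) <= exact_limit) "exact" else "greedy"
  res <- if (method == "exact") {
    n_circles_exact(fps, dist, D_eval, max_n = max(exact_limit, length(fps)))
  } else {
    n_circles_greedy(fps, dist, D_eval)
  }
  attr(res, "n_hits") <- length(smi)
  attr(res, "hit_smiles") <- smi[res$selected]
  res
}

#' Diverse-hit counts along a budget sweep
#'
#' Evaluates the log at increasing prefixes -- by number of proposals or by
#' elapsed time -- using greedy sphere exclusion in log order, which makes
#' the counts non-decreasing along the sweep.
#'
#' @inheritParams evaluate_log
#' @param checkpoints Ascending numeric vector of call counts (`by =
#'   "calls"`, a prefix of the log rows) or elapsed seconds (`by = "time"`).
#' @param by Checkpoint unit.
#' @return Data frame with columns `checkpoint` and `count`.
#' @export
diverse_hits_curve <- function(log, S = 0.5, D_eval = 0.7, checkpoints,
                               by = c("calls", "time"),
                               fp_config = fingerprint_config(),
                               dist = tanimoto_distance) {
  by <- match.arg(by)
  log <- as_evaluation_log(log)
  stopifnot(!is.unsorted(checkpoints))
  hit <- is_hit(log$raw_oracle, log$property_pass, S) & nzchar(log$canonical_smiles)
  hit_rows <- which(hit)
  hit_smi <- log$canonical_smiles[hit_rows]
  first <- !duplicated(hit_smi)
  hit_rows <- hit_rows[first]
  hit_smi <- hit_smi[first]
  fps <- if (length(hit_smi) > 0L)
    lapply(parse_molecules(hit_smi, fp_config), `[[`, "fingerprint") else list()
  pos <- if (by == "calls") seq_len(nrow(log)) else log$elapsed_seconds
  hit_pos <- pos[hit_rows]

  selected <- list()
  counts <- integer(length(checkpoints))
  k <- 1L
  for (ci in seq_along(checkpoints)) {
    while (k <= length(fps) && hit_pos[k] <= checkpoints[ci]) {
      fp <- fps[[k]]
      ok <- TRUE
      for (s in selected) if (dist(fp, s) <= D_eval) { ok <- FALSE; break }
      if (ok) selected[[length(selected) + 1L]] <- fp
      k <- k + 1L
    }
    counts[ci] <- length(selected)
  }
  data.frame(checkpoint = checkpoints, count = counts)
}

#' Aggregate runs into a ranking report
#'
#' For every (generator, task) cell: the minimum, median and maximum
#' diverse-hit count over seeds. Generators are then ranked within each task
#' by median count (rank 1 = highest; ties share the mean of the tied ranks)
#' and sorted by the arithmetic mean of their ranks across tasks. Cells
#' missing from `results` are excluded from the rank average with a warning.
#'
#' @param results List of `run_result` objects covering one or more
#'   generators, tasks and seeds.
#' @inheritParams evaluate_log
#' @return An object of class `divhits_report`: list with `cells` (per
#'   generator x task statistics) and `ranking` (per generator average rank),
#'   both data frames sorted by average rank.
#' @export
aggregate_runs <- function(results, S = 0.5, D_eval = 0.7, ...) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "run_result")))
  counts <- data.frame(
    generator = vapply(results, `[[`, "", "generator_name"),
    task = vapply(results, `[[`, "", "task_name"),
    seed = vapply(results, function(r) as.integer(r$seed), 1L),
    count = vapply(results, function(r)
      evaluate_log(r, S = S, D_eval = D_eval, ...)$count, 1L),
    stringsAsFactors = FALSE)
  cells <- do.call(rbind, lapply(split(counts, counts[c("generator", "task")],
                                       drop = TRUE), function(d)
    data.frame(generator = d$generator[1L], task = d$task[1L],
               n_seeds = nrow(d), min = min(d$count),
               median = stats::median(d$count), max = max(d$count),
               stringsAsFactors = FALSE)))
  rownames(cells) <- NULL
  gens <- unique(cells$generator)
  tasks <- unique(cells$task)
  if (nrow(cells) < length(gens) * length(tasks))
    warning("missing generator x task cells; they are excluded from rank averaging")
  ranks <- do.call(rbind, lapply(tasks, function(tk) {
    d <- cells[cells$task == tk, ]
    d$rank <- rank(-d$median, ties.method = "average")
    d[c("generator", "task", "rank")]
  }))
  ranking <- do.call(rbind, lapply(split(ranks, ranks$generator), function(d)
    data.frame(generator = d$generator[1L], n_tasks = nrow(d),
               avg_rank = mean(d$rank), stringsAsFactors = FALSE)))
  ranking <- ranking[order(ranking$avg_rank, ranking$generator), ]
  rownames(ranking) <- NULL
  cells <- cells[order(match(cells$generator, ranking$generator), cells$task), ]
  rownames(cells) <- NULL
  structure(list(cells = cells, ranking = ranking), class = "divhits_report")
}

#' @export
print.divhits_report <- function(x, ...) {
  cat("Diverse-hit ranking (rank 1 = most diverse hits, median over seeds)\n")
  print(x$ranking, row.names = FALSE)
  cat("\nPer-task counts:\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}
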