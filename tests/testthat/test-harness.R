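test_that("the call budget is conserved and duplicates are answered from cache", {
  task <- cached_task(150, 1)
  bud <- budget_config(max_calls = 10, mode = "sample_limit")

  # a generator streaming unique molecules in one oversized batch: the 11th
  # proposal goes unanswered
  smiles <- vapply(task$library$records[1:11], `[[`, "", "canonical_smiles")
  gen <- function(score, budget_view, seed) score(smiles)
  r <- run_generator(gen, task$context, bud, seed = 1)
  expect_identical(nrow(r$log), 10L)
  expect_identical(r$calls_consumed, 10L)
  expect_identical(budget_consumed(r$log), 10L)
  expect_false(r$aborted)

  # the same molecule proposed 100 times consumes one budget unit
  task2 <- cached_task(150, 1)
  gen2 <- function(score, budget_view, seed)
    for (i in 1:10) score(rep("c1ccccc1", 10))
  r2 <- run_generator(gen2, task2$context, bud, seed = 1)
  expect_identical(nrow(r2$log), 100L)
  expect_identical(r2$calls_consumed, 1L)
  expect_identical(budget_consumed(r2$log), 1L)

  # strict counting is available for sensitivity analysis
  task3 <- cached_task(150, 1)
  r3 <- run_generator(gen2, task3$context, bud, seed = 1, strict_counting = TRUE)
  expect_identical(r3$calls_consumed, 10L)
  expect_identical(nrow(r3$log), 10L)
})

test_that("sample-limited runs are reproducible to the byte", {
  bud <- budget_config(max_calls = 60, mode = "sample_limit")
  r1 <- run_generator(vs_random(cached_library(150, 1)),
                      cached_task(150, 1)$context, bud, seed = 5)
  r2 <- run_generator(vs_random(cached_library(150, 1)),
                      cached_task(150, 1)$context, bud, seed = 5)
  expect_identical(r1$log, r2$log)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_log_csv(r1, f1); write_log_csv(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # different seed, different permutation
  r3 <- run_generator(vs_random(cached_library(150, 1)),
                      cached_task(150, 1)$context, bud, seed = 6)
  expect_false(identical(r1$log$canonical_smiles, r3$log$canonical_smiles))
})

test_that("log invariants hold: indices strictly increasing, time non-decreasing", {
  task <- cached_task(150, 1)
  r <- run_generator(mutation_ga(task$library), task$context,
                     budget_config(max_calls = 50), seed = 3)
  expect_identical(r$log$call_index, seq_len(nrow(r$log)) - 1L)
  expect_true(all(diff(r$log$elapsed_seconds) >= 0))
  expect_true(all(r$log$final_score >= 0 & r$log$final_score <= 1))
  expect_true(all(r$log$raw_oracle >= 0 & r$log$raw_oracle <= 1))
})

test_that("a crashing generator yields a flagged partial log", {
  task <- cached_task(150, 1)
  gen <- function(score, budget_view, seed) {
    score(c("CCO", "c1ccccc1"))
    stop("generator exploded")
  }
  expect_warning(
    r <- run_generator(gen, task$context, budget_config(max_calls = 10), seed = 1),
    "generator exploded")
  expect_true(r$aborted)
  expect_identical(nrow(r$log), 2L)
})

test_that("time-limited runs stop at the wall clock and record elapsed times", {
  task <- cached_task(150, 1)
  slow_oracle <- function(record) { Sys.sleep(0.02); task$oracle(record) }
  ctx <- scoring_context(slow_oracle, filters = task$context$filters,
                         df = diversity_filter(), S = 0.5)
  bud <- budget_config(max_calls = Inf, max_seconds = 0.4, mode = "time_limit")
  r <- run_generator(vs_random(task$library, batch_size = 8), ctx, seed = 1,
                     budget = bud)
  expect_lt(nrow(r$log), length(task$library))
  expect_gt(nrow(r$log), 0L)
  expect_true(any(r$log$elapsed_seconds > 0))
  expect_identical(r$constraint_mode, "time_limit")
})

test_that("evaluate_log counts diverse hits from the audit trail alone", {
  empty <- make_log(character(0), numeric(0))
  expect_identical(evaluate_log(empty)$count, 0L)

  none <- make_log(c("CCO", "CCN"), raw = 0.2)
  expect_identical(evaluate_log(none)$count, 0L)

  # three structurally unrelated hits, pairwise distance > 0.7
  three <- make_log(c("c1ccccc1", "C1CCNCC1", "CC(=O)OCC(F)(F)F"), raw = 0.9)
  ev <- evaluate_log(three)
  expect_identical(ev$count, 3L)
  expect_identical(attr(ev, "n_hits"), 3L)

  # near-duplicates collapse to one circle; DF outcome is ignored
  dup <- make_log(c("CCCCCCCC", "CCCCCCCCC", "CCCCCCCC"), raw = 0.9, dfp = FALSE)
  expect_identical(evaluate_log(dup)$count, 1L)
  expect_identical(attr(evaluate_log(dup), "n_hits"), 2L)

  # time cutoff: a late hit is excluded from the 600-second evaluation
  lg <- make_log(c("c1ccccc1", "C1CCNCC1"), raw = 0.9)
  lg$elapsed_seconds <- c(100, 700)
  expect_identical(evaluate_log(lg, time_cutoff = 600)$count, 1L)
  expect_identical(evaluate_log(lg)$count, 2L)
})

test_that("evaluation is a pure function of the log CSV", {
  task <- cached_task(150, 1)
  r <- run_generator(vs_random(task$library), task$context,
                     budget_config(max_calls = 120), seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_log_csv(r, f)
  expect_identical(evaluate_log(read_log_csv(f))$count, evaluate_log(r)$count)
  # count <= unique hits <= records
  ev <- evaluate_log(r)
  expect_lte(ev$count, attr(ev, "n_hits"))
  expect_lte(attr(ev, "n_hits"), nrow(r$log))
})

test_that("removing the diversity filter never changes hit outcomes", {
  with_df <- cached_task(150, 1)
  without_df <- cached_task(150, 1, D_df = NULL)
  bud <- budget_config(max_calls = 80)
  r1 <- run_generator(vs_random(cached_library(150, 1)), with_df$context,
                      bud, seed = 4)
  r2 <- run_generator(vs_random(cached_library(150, 1)), without_df$context,
                      bud, seed = 4)
  expect_identical(r1$log$canonical_smiles, r2$log$canonical_smiles)
  expect_identical(is_hit(r1$log$raw_oracle, r1$log$property_pass),
                   is_hit(r2$log$raw_oracle, r2$log$property_pass))
  # the DF only zeroes final scores of near-duplicates
  expect_true(all(r2$log$df_pass))
  expect_true(all(r1$log$final_score <= r2$log$final_score + 1e-12))
})

test_that("diverse-hit curves are monotone along prefixes", {
  task <- cached_task(150, 1)
  r <- run_generator(vs_random(task$library), task$context,
                     budget_config(max_calls = 100), seed = 9)
  cps <- c(0, 10, 25, 50, 100, 500, 1000)
  curve <- diverse_hits_curve(r$log, checkpoints = cps)
  expect_identical(curve$checkpoint, cps)
  expect_identical(curve$count[1], 0L)
  expect_true(all(diff(curve$count) >= 0))
  # checkpoints beyond the log's end repeat the final count
  expect_identical(curve$count[6], curve$count[7])
  expect_identical(curve$count[6],
                   evaluate_log(r, method = "greedy")$count)

  # property sweep over random synthetic logs
  pool <- vapply(cached_library(150, 1)$records, `[[`, "", "canonical_smiles")
  set.seed(21)
  for (rep in 1:6) {
    lg <- make_log(sample(pool, 40, replace = TRUE), raw = runif(40))
    cv <- diverse_hits_curve(lg, checkpoints = seq(0, 40, by = 5))
    expect_true(all(diff(cv$count) >= 0))
  }
})

test_that("aggregation ranks generators by median count with mean-rank ties", {
  # representatives that are pairwise > 0.7 apart, so a log with k of them
  # scores exactly k diverse hits
  lib <- cached_library(150, 1)
  sel <- n_circles_greedy(lib$records, D = 0.75)$selected
  reps <- vapply(lib$records[sel], `[[`, "", "canonical_smiles")
  stopifnot(length(reps) >= 10)
  runs_for <- function(gen, task, counts)
    lapply(seq_along(counts), function(i)
      fake_run(make_log(reps[seq_len(counts[i])], raw = 0.9), gen, task, seed = i))

  one <- runs_for("g1", "t1", c(5, 7, 6))
  rep1 <- aggregate_runs(one)
  expect_identical(rep1$cells$min, 5L)
  expect_equal(rep1$cells$median, 6)
  expect_identical(rep1$cells$max, 7L)
  expect_identical(rep1$ranking$avg_rank, 1)

  # dominant generator on both tasks -> average ranks 1 and 2
  two <- c(runs_for("strong", "t1", 10), runs_for("weak", "t1", 2),
           runs_for("strong", "t2", 10), runs_for("weak", "t2", 2))
  rep2 <- aggregate_runs(two)
  expect_identical(rep2$ranking$generator, c("strong", "weak"))
  expect_identical(rep2$ranking$avg_rank, c(1, 2))

  # a tie on one of two tasks contributes rank 1.5 to each
  tie <- c(runs_for("g1", "t1", 4), runs_for("g2", "t1", 4),
           runs_for("g1", "t2", 6), runs_for("g2", "t2", 3))
  rep3 <- aggregate_runs(tie)
  r_g1 <- rep3$ranking$avg_rank[rep3$ranking$generator == "g1"]
  r_g2 <- rep3$ranking$avg_rank[rep3$ranking$generator == "g2"]
  expect_identical(r_g1, (1.5 + 1) / 2)
  expect_identical(r_g2, (1.5 + 2) / 2)

  # missing cells are excluded from rank averaging with a warning
  miss <- c(runs_for("g1", "t1", 4), runs_for("g2", "t1", 5),
            runs_for("g1", "t2", 6))
  expect_warning(rep4 <- aggregate_runs(miss), "missing")
  expect_identical(rep4$ranking$n_tasks[rep4$ranking$generator == "g2"], 1L)
})
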