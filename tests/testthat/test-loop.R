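test_that("area scoring follows the normalized-area convention", {
  expect_equal(score_from_areas(c(reactant = 0, mono = 1, di = 0), "mono"), 100)
  expect_equal(score_from_areas(c(reactant = 1, mono = 1, di = 0), "mono"), 50)
  expect_equal(score_from_areas(c(reactant = 0.2, mono = 0.3, di = 0.5), "di"), 50)
  expect_error(score_from_areas(c(reactant = 0, mono = 0, di = 0)), "zero")
  expect_error(score_from_areas(c(reactant = -1, mono = 2, di = 0)), "non-negative")
})

test_that("best-so-far traces are running maxima", {
  expect_equal(best_so_far(c(0, 10, 5, 20)), c(0, 10, 10, 20))
  expect_equal(best_so_far(rep(0, 5)), rep(0, 5))
  set.seed(40)
  for (i in 1:1000) {
    v <- runif(sample(3:30, 1), 0, 100)
    tr <- best_so_far(v)
    expect_true(all(diff(tr) >= 0))
    expect_equal(tr[length(tr)], max(v))
  }
})

test_that("convergence detection flags plateaus and only plateaus", {
  expect_true(is.na(detect_convergence(seq(0, 100, length.out = 30),
                                       window = 5, tol = 1)))
  expect_identical(detect_convergence(c(1:10, rep(10, 15)), window = 5, tol = 0.5),
                   10L)
  # paper-shaped trace: slow start, steep rise, long plateau
  trace <- c(rep(0, 10), seq(5, 60, by = 5), rep(60.5, 20))
  # hand enumeration: the incumbent stops improving by >= 1 point after the
  # rise ends at position 22
  expect_identical(detect_convergence(trace, window = 10, tol = 1), 22L)
})

test_that("a budgeted loop produces the configured phase structure", {
  sp <- toy_space()
  h <- run_closed_loop(loop_config(sp, toy_oracle(1), budget = 14,
                                   schedule = xi_schedule(1, 0.05, 9, 4),
                                   seed = 6))
  expect_equal(nrow(h), 14)
  expect_equal(as.vector(table(factor(h$phase, c("lhs", "bo_high", "bo_low")))),
               c(4L, 5L, 5L))
  expect_equal(h$index, 1:14)
  expect_true(all(check_candidates(h[names(sp$params)], sp)$ok))
})

test_that("zero budget with priors returns the priors untouched", {
  sp <- toy_space()
  asp <- augment_with_task(sp, "t", "t")
  pri <- suppressMessages(ingest_prior(
    dplyr::mutate(sample_candidates(5, sp, seed = 7), sugar = "t",
                  score = runif(5, 0, 90)), asp))
  h <- run_closed_loop(loop_config(asp, toy_oracle(1), budget = 0,
                                   schedule = xi_schedule(1, 0.05, 9, 0),
                                   priors = pri, seed = 8))
  expect_equal(nrow(h), 5)
  expect_true(all(h$phase == "prior"))
})

test_that("priors replace the opening design entirely", {
  sp <- toy_space()
  asp <- augment_with_task(sp, "t", "t")
  pri <- suppressMessages(ingest_prior(
    dplyr::mutate(sample_candidates(6, sp, seed = 9), sugar = "t",
                  score = runif(6, 0, 50)), asp))
  h <- run_closed_loop(loop_config(asp, toy_oracle(1), budget = 5,
                                   schedule = xi_schedule(1, 0.05, 3, 2),
                                   priors = pri, seed = 10))
  expect_false("lhs" %in% h$phase)
  expect_equal(sum(h$phase != "prior"), 5)
})

test_that("interrupted runs resume bit-identically", {
  sp <- toy_space()
  dir_full <- withr::local_tempdir()
  dir_part <- withr::local_tempdir()
  mk_cfg <- function(dir) loop_config(sp, toy_oracle(2), budget = 12,
    schedule = xi_schedule(1, 0.05, 8, 4), seed = 77, out_dir = dir)
  h_full <- run_closed_loop(mk_cfg(dir_full))
  # simulate a crash after experiment 7
  write_history(h_full[1:7, ], dir_part)
  h_res <- run_closed_loop(mk_cfg(dir_part))
  expect_equal(as.data.frame(h_res), as.data.frame(h_full))
  expect_identical(readLines(file.path(dir_part, "history.tsv")),
                   readLines(file.path(dir_full, "history.tsv")))
})

test_that("identical configurations give byte-identical history files", {
  sp <- toy_space()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    run_closed_loop(loop_config(sp, toy_oracle(2), budget = 10,
      schedule = xi_schedule(1, 0.05, 7, 3), seed = 123, out_dir = d))
  }
  expect_identical(readLines(file.path(d1, "history.tsv")),
                   readLines(file.path(d2, "history.tsv")))
})

test_that("every suggestion in a run is unique", {
  sp <- toy_space()
  h <- run_closed_loop(loop_config(sp, toy_oracle(2), budget = 15,
                                   schedule = xi_schedule(1, 0.05, 10, 5),
                                   seed = 55))
  X <- normalize_candidates(h[names(sp$params)], sp)
  expect_gt(min(dist(X)), 1e-6)
})

test_that("oracle failures are recorded, excluded, and do not stop the loop", {
  sp <- toy_space()
  flaky <- function(candidates, seed = NULL) {
    if (!is.null(seed) && seed %% 2 == 0) stop("instrument offline")
    toy_oracle(1)(candidates, seed)
  }
  h <- run_closed_loop(loop_config(sp, flaky, budget = 10,
                                   schedule = xi_schedule(1, 0.05, 7, 4),
                                   seed = 14))
  expect_equal(nrow(h), 10)
  expect_true(any(is.na(h$score)))
  expect_true(all(is.na(h$score) | (h$score >= 0 & h$score <= 100)))
  tr <- best_so_far(h)
  expect_equal(tr$incumbent[10], max(h$score, na.rm = TRUE))
})

test_that("prior records surface as an old-max baseline, not as incumbents", {
  sp <- toy_space()
  asp <- augment_with_task(sp, "t", "t")
  pri <- suppressMessages(ingest_prior(
    dplyr::mutate(sample_candidates(4, sp, seed = 16), sugar = "t",
                  score = c(95, 10, 20, 30)), asp))
  h <- run_closed_loop(loop_config(asp, toy_oracle(0), budget = 4,
                                   schedule = xi_schedule(1, 0.05, 2, 0),
                                   priors = pri, seed = 17))
  tr <- best_so_far(h)
  expect_equal(attr(tr, "old_max"), 95)
  expect_equal(nrow(tr), 4)
  expect_true(all(tr$incumbent <= 95))
})

test_that("loop histories expose tidy plots", {
  sp <- toy_space()
  h <- run_closed_loop(loop_config(sp, toy_oracle(1), budget = 8,
                                   schedule = xi_schedule(1, 0.05, 6, 3),
                                   seed = 18))
  p <- ggplot2::autoplot(h)
  expect_s3_class(p, "ggplot")
})
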