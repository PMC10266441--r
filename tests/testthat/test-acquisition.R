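test_that("the dual-xi schedule switches strictly at the changeover", {
  sch <- xi_schedule(1.0, 0.01, 48, 12)
  expect_equal(current_xi(sch, 47), 1.0)
  expect_equal(current_xi(sch, 48), 0.01)
  sch3 <- xi_schedule(1.0, 0.02, 24, 0)
  expect_equal(current_xi(sch3, 24), 0.02)
  const <- xi_schedule(0.5, 0.5, 10, 5)
  expect_equal(current_xi(const, 0), current_xi(const, 100))
  expect_error(xi_schedule(0.01, 1, 48, 12), "high_xi")
  expect_error(xi_schedule(1, 0.01, 5, 12), "changeover")
})

test_that("expected improvement honors its closed-form limits", {
  expect_equal(expected_improvement(10, 0, 12, 1), 0)
  expect_equal(expected_improvement(15, 0, 12, 1), 2)
  # symmetric-at-threshold: mean = f* + xi gives sigma * phi(0)
  expect_equal(expected_improvement(13, 2, 12, 1), 2 * dnorm(0),
               tolerance = 1e-12)
  expect_error(expected_improvement(1, -1, 0, 0), "non-negative")
})

test_that("EI is monotone in xi and, below threshold, in sd", {
  set.seed(8)
  for (i in 1:50) {
    mu <- runif(1, -10, 10); s <- runif(1, 0, 5); fb <- runif(1, -10, 10)
    xis <- sort(runif(3, 0, 3))
    eis <- expected_improvement(mu, s, fb, xis)
    expect_true(all(diff(eis) <= 1e-12))
    if (mu - fb - xis[1] <= 0) {
      sds <- sort(runif(3, 0, 5))
      eis2 <- expected_improvement(mu, sds, fb, xis[1])
      expect_true(all(diff(eis2) >= -1e-12))
    }
  }
})

test_that("Latin hypercube designs stratify every numeric dimension", {
  sp <- cl1_space()
  for (n in c(5, 12, 48)) {
    d <- suppressMessages(lhs_candidates(n, sp, seed = n))
    expect_true(all(check_candidates(d, sp)$ok))
    for (pn in c("eq_bz", "eq_base", "conc")) {
      p <- sp$params[[pn]]
      u <- (d[[pn]] - p$lower) / (p$upper - p$lower)
      expect_identical(sort(unique(floor(u * n))), as.numeric(0:(n - 1)))
    }
  }
  d1 <- suppressMessages(lhs_candidates(12, sp, seed = 1))
  d2 <- suppressMessages(lhs_candidates(12, sp, seed = 1))
  expect_identical(d1, d2)
  expect_equal(nrow(suppressMessages(lhs_candidates(1, sp, seed = 1))), 1)
  expect_message(lhs_candidates(3, sp, seed = 1), "cycled")
})

test_that("categorical levels are stratified by shuffling", {
  sp <- toy_space()
  d <- lhs_candidates(9, sp, seed = 2)
  expect_equal(as.vector(table(d$solvent)), rep(3L, 3))
})

test_that("suggestions always lie inside the space (fuzz over random spaces)", {
  set.seed(9)
  for (i in 1:5) {
    sp <- reaction_space(list(
      param_spec("a", "continuous", lower = runif(1, -5, 0), upper = runif(1, 1, 5)),
      param_spec("b", "ordinal", levels = seq_len(sample(2:6, 1))),
      param_spec("c", "categorical", levels = LETTERS[1:sample(2:5, 1)])
    ), name = paste0("fuzz", i))
    cand <- sample_candidates(8, sp, seed = i)
    X <- normalize_candidates(cand, sp)
    y <- runif(8, 0, 100)
    m <- gp_fit(X, y, groups = attr(X, "groups"), seed = i)
    s <- suggest_next(m, sp, xi = 0.5, f_best = max(y), history = cand, seed = i)
    expect_true(all(check_candidates(s, sp)$ok))
  }
})

test_that("with an unreachable incumbent the suggestion maximizes uncertainty", {
  sp <- toy_space()
  cand <- sample_candidates(15, sp, seed = 10)
  X <- normalize_candidates(cand, sp)
  y <- runif(15, 0, 50)
  m <- gp_fit(X, y, groups = attr(X, "groups"), seed = 10)
  s <- suggest_next(m, sp, xi = 50, f_best = 1000, history = cand, seed = 10)
  sd_s <- predict(m, normalize_candidates(s, sp))$sd
  rc <- sample_candidates(1000, sp, seed = 11)
  sd_rc <- predict(m, normalize_candidates(rc, sp))$sd
  # pure exploration limit: suggested point at least as uncertain as the
  # bulk of the space
  expect_gte(sd_s, quantile(sd_rc, 0.99))
})

test_that("1-D suggestion matches a dense-grid EI argmax", {
  sp <- reaction_space(list(param_spec("x", "continuous", 0, 1)), name = "oned")
  xs <- matrix(c(0.1, 0.45, 0.9), ncol = 1)
  y <- bumpy_1d(xs[, 1])
  m <- gp_fit(xs, y, seed = 3)
  fb <- max(y)
  s <- suggest_next(m, sp, xi = 0.1, f_best = fb, seed = 3)
  grid <- matrix(seq(0, 1, length.out = 2001), ncol = 1)
  pr <- predict(m, grid)
  ei <- expected_improvement(pr$mean, pr$sd, fb, 0.1)
  expect_lt(abs(s$x - grid[which.max(ei), 1]), 2e-3)
})

test_that("duplicate suggestions are suppressed in favour of distinct optima", {
  sp <- reaction_space(list(param_spec("x", "continuous", 0, 1)), name = "oned")
  xs <- matrix(c(0.2, 0.5, 0.8), ncol = 1)
  y <- c(10, 60, 20)
  m <- gp_fit(xs, y, noise_var = 1e-8, seed = 4)
  hist <- tibble::tibble(x = xs[, 1], score = y)
  s <- suggest_next(m, sp, xi = 0.001, f_best = 60, history = hist, seed = 4)
  expect_gt(min(abs(s$x - xs[, 1])), 1e-6)
})

test_that("high xi disperses suggestions more than low xi on a frozen model", {
  sp <- toy_space()
  cand <- sample_candidates(20, sp, seed = 20)
  X <- normalize_candidates(cand, sp)
  y <- toy_oracle()(cand)$score
  m <- gp_fit(X, y, groups = attr(X, "groups"), seed = 20)
  disp <- function(xi) {
    sug <- purrr::map_dfr(1:20, function(s) {
      suggest_next(m, sp, xi = xi, f_best = max(y), history = cand, seed = s)
    })
    Xs <- normalize_candidates(sug, sp)
    mean(dist(Xs))
  }
  expect_gt(disp(20), disp(0.01))
})
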