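prof3 <- make_profiles()
tsp <- transfer_space()

test_that("no-reaction and complete-conversion limits hold", {
  p <- prof3$glucoside
  dead <- tibble::tibble(eq_bz = 3, eq_base = 2, conc = 0.1, bz_reagent = 2L,
                         base = 9L, t1 = 0L, solvent = "DMF")
  fr <- species_fractions(dead, p)
  expect_gt(fr$reactant, 0.999)

  # k1 huge, k2 = 0: everything converts to the mono product
  fast <- p
  fast$k1ref <- 1e6
  fast$k2ref <- 0
  hot <- tibble::tibble(eq_bz = 2, eq_base = 16, conc = 0.115,
                        bz_reagent = 2L, base = 1L, t1 = 0L,
                        solvent = "MeCN/THF")
  fr2 <- species_fractions(hot, fast)
  expect_equal(fr2$mono, 1, tolerance = 1e-6)
  expect_equal(fr2$reactant, 0, tolerance = 1e-6)
})

test_that("closed-form fractions match a numerical ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(12)
  cand <- sample_candidates(20, tsp, seed = 12)
  for (p in prof3) {
    k <- rxnbo:::rate_constants(cand, p)
    fr <- species_fractions(cand, p)
    for (i in seq_len(5)) {
      sol <- deSolve::ode(
        y = c(A = 1, B = 0, C = 0), times = c(0, 1),
        func = function(t, y, parms) {
          list(c(-parms[1] * y[1],
                 parms[1] * y[1] - parms[2] * y[2],
                 parms[2] * y[2]))
        }, parms = c(k$k1[i], k$k2[i]), rtol = 1e-10, atol = 1e-12)
      expect_equal(unname(sol[2, c("A", "B", "C")]),
                   unlist(fr[i, ], use.names = FALSE), tolerance = 1e-6)
    }
  }
})

test_that("mass is conserved and conversion is monotone in reagent equivalents", {
  cand <- sample_candidates(300, tsp, seed = 13)
  for (p in prof3) {
    fr <- species_fractions(cand, p)
    expect_lt(max(abs(fr$reactant + fr$mono + fr$di - 1)), 1e-12)
  }
  base_cand <- sample_candidates(50, tsp, seed = 14)
  for (e in list(c(1, 2), c(2, 5), c(5, 10))) {
    lo <- hi <- base_cand
    lo$eq_bz <- e[1]; hi$eq_bz <- e[2]
    expect_true(all(species_fractions(hi, prof3$glucoside)$reactant <=
                    species_fractions(lo, prof3$glucoside)$reactant + 1e-12))
  }
})

test_that("measurement is exact without noise and zero-mean on dead zones", {
  fr <- tibble::tibble(reactant = 0.2, mono = 0.5, di = 0.3)
  expect_equal(measure_yield(fr, "mono", sigma = 0), 50)
  expect_equal(measure_yield(fr, "di", sigma = 0), 30)
  # objective switch reweights the same species distribution
  expect_false(measure_yield(fr, "mono", 0) == measure_yield(fr, "di", 0))

  # clipping/detection-aware sampling oracle for the dead-zone mean
  dead <- tibble::tibble(reactant = rep(1, 4000), mono = 0, di = 0)
  obs <- measure_yield(dead, "mono", sigma = 2, seed = 15)
  set.seed(16)
  ref <- pmin(pmax(rnorm(2e5, 0, 2), 0), 100)
  ref[ref < 0.5] <- 0
  se <- sd(ref) / sqrt(4000)
  expect_lt(abs(mean(obs) - mean(ref)), 4 * se)
  expect_equal(measure_yield(fr, "mono", sigma = 2, seed = 9),
               measure_yield(fr, "mono", sigma = 2, seed = 9))
})

test_that("profiles are deterministic and their optima show the di > mono pattern", {
  p1 <- make_profiles(seed = 1)
  p2 <- make_profiles(seed = 1)
  expect_identical(p1$glucoside$optima$mono$yield,
                   p2$glucoside$optima$mono$yield)
  for (p in p1) {
    expect_gt(p$optima$di$candidate$eq_bz, p$optima$mono$candidate$eq_bz)
    expect_gt(p$optima$mono$yield, 0)
  }
})

test_that("a fresh dense random search recovers the recorded maxima", {
  for (nm in names(prof3)) {
    p <- prof3[[nm]]
    rc <- sample_candidates(1e5, tsp, seed = 1234)
    best <- max(100 * species_fractions(rc, p)$mono)
    expect_lt(abs(best - p$optima$mono$yield), 1)
  }
})

test_that("profile pairs sit in the designed correlation band", {
  rc <- sample_candidates(1000, tsp, seed = 99)
  ys <- sapply(prof3, function(p)
    measure_yield(species_fractions(rc, p), "mono", sigma = 0))
  rho <- cor(ys, method = "spearman")
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_gte(rho[pair[1], pair[2]], 0.3)
    expect_lte(rho[pair[1], pair[2]], 0.8)
  }
})

test_that("a 12-point opening design rarely finds detectable yield", {
  hits <- sapply(1:60, function(s) {
    d <- suppressMessages(lhs_candidates(12, tsp, seed = s))
    sum(measure_yield(species_fractions(d, prof3$glucoside), "mono",
                      sigma = 0) > 5)
  })
  expect_lte(mean(hits), 2.5)
})

test_that("profiles survive a structured-text round trip", {
  p <- prof3$glucoside
  path <- withr::local_tempfile(fileext = ".yaml")
  write_profile(p, path)
  back <- read_profile(path)
  expect_equal(back$conc_opt, p$conc_opt)
  expect_equal(back$solvent_mult, p$solvent_mult)
  cand <- sample_candidates(20, tsp, seed = 50)
  expect_equal(species_fractions(cand, back), species_fractions(cand, p))
})

test_that("the file oracle answers candidate queries over tabular files", {
  req <- withr::local_tempfile(fileext = ".tsv")
  resp <- withr::local_tempfile(fileext = ".tsv")
  cand <- sample_candidates(5, tsp, seed = 60)
  out <- as.data.frame(cand)
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  write.table(out, req, sep = "\t", row.names = FALSE, quote = FALSE)
  serve_oracle(req, resp, prof3$glucoside, "mono", sigma = 0)
  back <- read.table(resp, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(nrow(back), 5)
  expect_equal(back$score,
               measure_yield(species_fractions(cand, prof3$glucoside),
                             "mono", sigma = 0),
               tolerance = 1e-10)
})
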