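tsp <- transfer_space()

test_that("task augmentation appends a pinned, model-carried parameter", {
  asp <- augment_with_task(tsp, c("glucoside", "thiomannoside"), "thiomannoside")
  expect_length(asp$params, 8)
  expect_equal(asp$params$sugar$fixed, "thiomannoside")
  expect_true(asp$params$sugar$in_model)
  expect_identical(space_dim(asp), space_dim(tsp) + 2L)
  expect_error(augment_with_task(tsp, c("a", "b"), "c"), "not among")
})

test_that("suggestions under augmentation always carry the current task", {
  asp <- augment_with_task(tsp, c("glucoside", "thiomannoside"), "thiomannoside")
  cand <- sample_candidates(12, asp, seed = 30)
  X <- normalize_candidates(cand, asp)
  y <- runif(12, 0, 60)
  m <- gp_fit(X, y, groups = attr(X, "groups"), seed = 30)
  sugg <- purrr::map_dfr(1:10, function(s)
    suggest_next(m, asp, xi = 0.5, f_best = max(y), history = cand, seed = s))
  expect_true(all(sugg$sugar == "thiomannoside"))
})

test_that("a single-task augmentation is model-equivalent to no augmentation", {
  asp1 <- augment_with_task(tsp, "onlytask", "onlytask")
  cand <- sample_candidates(10, tsp, seed = 31)
  cand1 <- dplyr::mutate(cand, sugar = "onlytask")
  y <- runif(10, 0, 80)
  hyper <- list(lengthscales = 0.5, signal_var = 1, noise_var = 0.01, seed = 1)
  X0 <- normalize_candidates(cand, tsp)
  X1 <- normalize_candidates(cand1, asp1)
  m0 <- do.call(gp_fit, c(list(X = X0, y = y, groups = attr(X0, "groups")), hyper))
  m1 <- do.call(gp_fit, c(list(X = X1, y = y, groups = attr(X1, "groups")), hyper))
  q <- sample_candidates(5, tsp, seed = 32)
  p0 <- predict(m0, normalize_candidates(q, tsp))
  p1 <- predict(m1, normalize_candidates(dplyr::mutate(q, sugar = "onlytask"), asp1))
  expect_equal(p0$mean, p1$mean, tolerance = 1e-8)
  expect_equal(p0$sd, p1$sd, tolerance = 1e-8)
})

test_that("prior ingestion validates, maps, and reports drops", {
  asp <- augment_with_task(tsp, c("glucoside", "thiomannoside"), "thiomannoside")
  pri <- tibble::tibble(
    eq_bz = c(2, 3, 50), eq_base = c(10, 35, 10), conc = c(0.1, 0.1, 0.1),
    bz_reagent = 2L, base = 1L, t1 = 3L, solvent = "THF",
    sugar = "glucoside", score = c(40, 50, 60))
  rec <- suppressMessages(ingest_prior(pri, asp))
  expect_equal(nrow(rec), 1)         # rows 2 (eq_base) and 3 (eq_bz) dropped
  expect_equal(attr(rec, "report")$dropped, 2)
  expect_true(all(rec$phase == "prior"))
  expect_true(all(rec$task == "glucoside"))
})

test_that("a categorical solvent maps onto the solvent-ratio parameter", {
  cl2 <- build_space(system.file("extdata", "space_cl2.yaml", package = "rxnbo"))
  asp <- augment_with_task(cl2, "glucoside", "glucoside")
  pri <- tibble::tibble(
    eq_bz = 2, eq_base = c(10, 12, 14, 16), conc = 0.1, bz_reagent = 2L,
    base = 1L, t1 = 3L,
    solvent = c("THF", "MeCN", "MeCN/THF", "Dioxane"),
    sugar = "glucoside", score = 40)
  rec <- suppressMessages(ingest_prior(pri, asp))
  expect_equal(nrow(rec), 3)  # underivable Dioxane record dropped
  expect_equal(rec$solvent_ratio, c(1, 0, 0.5))
})

test_that("empty prior libraries reduce to a cold start", {
  sp <- toy_space()
  cfg_cold <- loop_config(sp, toy_oracle(2), budget = 8,
                          schedule = xi_schedule(1, 0.1, 6, 4), seed = 5)
  cfg_empty <- loop_config(sp, toy_oracle(2), budget = 8,
                           schedule = xi_schedule(1, 0.1, 6, 4), seed = 5,
                           priors = ingest_prior(tibble::tibble(), sp))
  h1 <- run_closed_loop(cfg_cold)
  h2 <- run_closed_loop(cfg_empty)
  expect_equal(as.data.frame(h1), as.data.frame(h2))
})

test_that("the task column is a mechanism, not a no-op relabeling", {
  asp <- augment_with_task(tsp, c("glucoside", "thiomannoside"), "thiomannoside")
  prof <- make_profiles()
  gl <- sample_candidates(25, tsp, seed = 33)
  gl$sugar <- "glucoside"
  th <- sample_candidates(10, tsp, seed = 34)
  th$sugar <- "thiomannoside"
  cand <- dplyr::bind_rows(gl, th)
  y <- c(measure_yield(species_fractions(gl, prof$glucoside), "mono", 2, 1),
         measure_yield(species_fractions(th, prof$thiomannoside), "mono", 2, 2))
  hyper <- list(lengthscales = 0.5, signal_var = 1, noise_var = 0.05, seed = 1)
  Xa <- normalize_candidates(cand, asp)
  ma <- do.call(gp_fit, c(list(X = Xa, y = y, groups = attr(Xa, "groups")), hyper))
  Xu <- normalize_candidates(cand[names(tsp$params)], tsp)
  mu <- do.call(gp_fit, c(list(X = Xu, y = y, groups = attr(Xu, "groups")), hyper))
  q <- sample_candidates(20, tsp, seed = 35)
  pa <- predict(ma, normalize_candidates(dplyr::mutate(q, sugar = "thiomannoside"), asp))
  pu <- predict(mu, normalize_candidates(q, tsp))
  expect_gt(max(abs(pa$mean - pu$mean)), 0.1)
})
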