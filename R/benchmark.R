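# Benchmark harness: closed-loop optimizer vs random search, and the
# transfer-learning acceleration / saturation study, all on the synthetic
# substrate profiles.

#' Benchmark the closed loop against random search
#'
#' Runs the full dual-xi campaign and an equal-budget uniform random search
#' on one substrate profile over several seeds and reports the final
#' incumbent of each run, together with the profile's recorded noise-free
#' global maximum.
#'
#' @param profile A [substrate_profile()] (with recorded optima, see
#'   [make_profiles()]).
#' @param space The [reaction_space()] to search.
#' @param objective `"mono"` or `"di"`.
#' @param n_seeds Number of independent campaigns per method.
#' @param budget Experiments per campaign.
#' @param schedule An [xi_schedule()].
#' @param base_seed Offset added to the per-campaign seeds.
#' @return A tibble with columns `seed`, `method` (`bo` / `random`),
#'   `final_incumbent`, and `frac_of_max`; the recorded maximum is attached
#'   as attribute `"global_max"`.
#' @export
benchmark_optimizer <- function(profile, space, objective = c("mono", "di"),
                                n_seeds = 20L, budget = 70L,
                                schedule = xi_schedule(1.0, 0.01, 48L, 12L),
                                base_seed = 0L) {
  objective <- match.arg(objective)
  gmax <- profile$optima[[objective]]$yield
  oracle <- simulator_oracle(profile, objective)
  rows <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    sd <- base_seed + i
    h_bo <- run_closed_loop(loop_config(space, oracle, budget = budget,
                                        schedule = schedule,
                                        objective = objective, seed = sd,
                                        task = profile$name))
    h_rs <- run_random_search(space, oracle, budget = budget, seed = sd,
                              task = profile$name)
    tibble(seed = sd, method = c("bo", "random"),
           final_incumbent = c(max(best_so_far(h_bo)$incumbent),
                               max(h_rs$score, na.rm = TRUE)))
  })
  rows$frac_of_max <- rows$final_incumbent / gmax
  attr(rows, "global_max") <- gmax
  rows
}

#' Transfer-learning acceleration and saturation benchmark
#'
#' Compares three ways of optimizing one substrate: a cold start (LHS +
#' dual-xi loop), a warm start ingesting a prior campaign from a related
#' substrate through the task-categorical mechanism, and a warm start with a
#' second, additional prior substrate.  The outcome per seed is the number
#' of experiments until the incumbent reaches `threshold_frac` of the
#' current substrate's recorded maximum (budget + 1 when never reached).
#'
#' @param profiles Named list from [make_profiles()].
#' @param space The un-augmented [reaction_space()].
#' @param current Name of the profile being optimized.
#' @param prior_task Name of the first prior substrate.
#' @param third_task Name of the additional prior substrate (saturation arm).
#' @param objective `"mono"` or `"di"`.
#' @param n_seeds Campaigns per arm.
#' @param cold_budget,transfer_budget Experiment budgets per arm.
#' @param prior_budget Records generated for the first prior campaign.
#' @param third_budget Records generated for the additional prior campaign.
#' @param threshold_frac Fraction of the recorded maximum defining success.
#' @param cold_schedule,transfer_schedule Schedules for the two arm types;
#'   with informative priors the loop opens without an LHS block and switches
#'   to the low xi earlier.
#' @param base_seed Offset added to the per-campaign seeds.
#' @return A tibble with columns `seed`, `arm` (`cold` / `transfer` /
#'   `transfer3`), `n_to_threshold`, `reached`; the threshold and prior
#'   record counts are attached as attributes.
#' @export
benchmark_transfer <- function(profiles, space, current = "thiomannoside",
                               prior_task = "glucoside",
                               third_task = "galactoside",
                               objective = c("mono", "di"), n_seeds = 20L,
                               cold_budget = 70L, transfer_budget = 40L,
                               prior_budget = 71L, third_budget = 40L,
                               threshold_frac = 0.9,
                               cold_schedule = xi_schedule(1.0, 0.01, 48L, 12L),
                               transfer_schedule = xi_schedule(1.0, 0.02, 12L, 0L),
                               base_seed = 0L) {
  objective <- match.arg(objective)
  threshold <- threshold_frac * profiles[[current]]$optima[[objective]]$yield
  oracle_cur <- simulator_oracle(profiles[[current]], objective)

  prior_campaign <- function(task, budget, seed) {
    h <- run_closed_loop(loop_config(
      space, simulator_oracle(profiles[[task]], objective), budget = budget,
      schedule = cold_schedule, objective = objective, seed = seed,
      task = task))
    h$sugar <- task
    h
  }
  h_prior1 <- prior_campaign(prior_task, prior_budget, 1000L + base_seed)
  h_prior2 <- prior_campaign(third_task, third_budget, 2000L + base_seed)

  sp2 <- augment_with_task(space, c(prior_task, current), current)
  sp3 <- augment_with_task(space, c(prior_task, third_task, current), current)
  pri2 <- ingest_prior(h_prior1, sp2)
  pri3 <- ingest_prior(dplyr::bind_rows(h_prior1, h_prior2), sp3)

  n_to <- function(h, budget) {
    v <- experiments_to_threshold(h, threshold)
    if (is.na(v)) budget + 1L else v
  }
  rows <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    sd <- base_seed + i
    cold <- run_closed_loop(loop_config(space, oracle_cur,
      budget = cold_budget, schedule = cold_schedule, objective = objective,
      seed = sd, task = current))
    warm2 <- run_closed_loop(loop_config(sp2, oracle_cur,
      budget = transfer_budget, schedule = transfer_schedule,
      objective = objective, priors = pri2, seed = sd, task = current))
    warm3 <- run_closed_loop(loop_config(sp3, oracle_cur,
      budget = transfer_budget, schedule = transfer_schedule,
      objective = objective, priors = pri3, seed = sd, task = current))
    tibble(seed = sd, arm = c("cold", "transfer", "transfer3"),
           n_to_threshold = c(n_to(cold, cold_budget),
                              n_to(warm2, transfer_budget),
                              n_to(warm3, transfer_budget)),
           reached = n_to_threshold <= c(cold_budget, transfer_budget,
                                         transfer_budget))
  })
  attr(rows, "threshold") <- threshold
  attr(rows, "n_prior") <- c(two_task = nrow(pri2), three_task = nrow(pri3))
  rows
}
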