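# Closed-loop orchestration: LHS phase -> explorative BO -> exploitative BO,
# with persistent, crash-resumable histories.

history_area_cols <- c("area_reactant", "area_mono", "area_di")

empty_history <- function(space) {
  cols <- lapply(space$params, function(p) {
    switch(p$kind, continuous = numeric(0), ordinal = integer(0),
           categorical = character(0))
  })
  out <- dplyr::bind_cols(tibble(index = integer(0)), as_tibble(cols))
  for (a in history_area_cols) out[[a]] <- numeric(0)
  out$score <- numeric(0)
  out$phase <- character(0)
  out$task <- character(0)
  out$seed <- integer(0)
  out
}

current_records <- function(history) {
  history[history$phase != "prior", , drop = FALSE]
}

#' Configure a closed-loop optimization
#'
#' @param space A [reaction_space()] (augmented with a task parameter when
#'   priors are used).
#' @param oracle Function `(candidates, seed) -> tibble` with columns
#'   `area_reactant`, `area_mono`, `area_di`, `score`; see
#'   [simulator_oracle()] for the built-in simulator backend.
#' @param budget Total number of new experiments to run.
#' @param schedule An [xi_schedule()].
#' @param objective `"mono"` or `"di"` (recorded in the manifest; the oracle
#'   itself is already bound to an objective).
#' @param priors Optional prior-record tibble from [ingest_prior()]; when
#'   supplied the Latin-hypercube phase is skipped entirely and optimization
#'   starts from the prior surrogate.
#' @param seed Master seed; every per-experiment seed is derived from it.
#' @param task Label of the task being optimized (defaults to the space's
#'   fixed task parameter, else `"task"`).
#' @param count_prior_in_schedule Should prior records count toward the xi
#'   changeover? Default `FALSE`: the schedule counts only experiments of
#'   the current campaign.
#' @param out_dir Optional directory; when set, the history is flushed to
#'   `history.tsv` after every experiment together with a `manifest.yaml`,
#'   and an interrupted run restarted with the same configuration resumes
#'   from the persisted records and reproduces the remainder exactly.
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(space, oracle, budget, schedule = xi_schedule(),
                        objective = c("mono", "di"), priors = NULL,
                        seed = 1L, task = NULL,
                        count_prior_in_schedule = FALSE, out_dir = NULL) {
  objective <- match.arg(objective)
  if (budget < 0L) stop_rxn("budget must be >= 0")
  if (is.null(priors) && budget > 0L && budget < schedule$n_initial) {
    stop_rxn("budget (%d) smaller than the LHS phase (%d)",
             budget, schedule$n_initial)
  }
  if (is.null(task)) {
    sugar <- space$params[["sugar"]]
    task <- if (!is.null(sugar) && is_fixed(sugar)) sugar$fixed else "task"
  }
  structure(
    list(space = space, oracle = oracle, budget = as.integer(budget),
         schedule = schedule, objective = objective, priors = priors,
         seed = as.integer(seed), task = task,
         count_prior_in_schedule = isTRUE(count_prior_in_schedule),
         out_dir = out_dir),
    class = "loop_config"
  )
}

loop_phase <- function(schedule, n_completed, n_initial_eff) {
  if (n_completed < n_initial_eff) return("lhs")
  if (n_completed < schedule$changeover) "bo_high" else "bo_low"
}

#' Run a closed-loop optimization campaign
#'
#' Runs `budget` experiments: a Latin-hypercube opening block (skipped when
#' prior records are supplied), then sequential expected-improvement
#' suggestions under the dual-xi schedule, each scored by the oracle.  The
#' incumbent for EI and the xi changeover count are computed over
#' current-campaign records only.  All randomness derives from the master
#' seed, so a run interrupted at any point and restarted with the same
#' configuration reproduces the remaining records exactly.
#'
#' @param config A [loop_config()].
#' @return The history: a tibble (class `rxn_loop_history`) with one row per
#'   record (priors first), columns = parameters, species areas, `score`,
#'   `phase` (`prior`/`lhs`/`bo_high`/`bo_low`), `task`, `seed`, `index`.
#' @export
run_closed_loop <- function(config) {
  stopifnot(inherits(config, "loop_config"))
  space <- config$space
  sched <- config$schedule
  budget <- config$budget

  priors <- config$priors %||% empty_history(space)
  attr(priors, "report") <- NULL
  n_prior <- nrow(priors)
  n_initial_eff <- if (n_prior > 0L) 0L else min(sched$n_initial, budget)

  history <- priors
  if (n_prior > 0L) history$index <- seq_len(n_prior)

  done <- 0L
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hfile <- file.path(config$out_dir, "history.tsv")
    if (file.exists(hfile)) {
      prev <- read_history(hfile, space)
      done <- nrow(current_records(prev))
      if (done > 0L) history <- prev
    }
  }

  oracle_seeds <- derive_seeds(config$seed, max(budget, 1L), stream = 1L)
  sugg_seeds <- derive_seeds(config$seed, max(budget, 1L), stream = 2L)
  lhs_seed <- derive_seeds(config$seed, 1L, stream = 3L)
  lhs_block <- if (n_initial_eff > 0L) {
    lhs_candidates(n_initial_eff, space, seed = lhs_seed)
  } else {
    NULL
  }

  i <- done
  while (i < budget) {
    i <- i + 1L
    n_completed <- i - 1L + if (config$count_prior_in_schedule) n_prior else 0L
    phase <- loop_phase(sched, n_completed, n_initial_eff)
    if (phase == "lhs") {
      cand <- lhs_block[i, , drop = FALSE]
    } else {
      cur <- current_records(history)
      train <- history[!is.na(history$score), , drop = FALSE]
      if (nrow(train) == 0L) {
        # nothing scored yet (every opening experiment failed): fall back to
        # a seeded random draw until the surrogate has data
        cand <- sample_candidates(1L, space, seed = sugg_seeds[i])
        res <- tryCatch(config$oracle(cand, seed = oracle_seeds[i]),
                        error = function(e) NULL)
        rec <- cand
        for (a in history_area_cols) {
          rec[[a]] <- if (!is.null(res) && a %in% names(res)) res[[a]] else NA_real_
        }
        rec$score <- if (!is.null(res)) res$score else NA_real_
        rec$phase <- phase
        rec$task <- config$task
        rec$seed <- oracle_seeds[i]
        rec <- dplyr::bind_cols(tibble(index = n_prior + i), rec)
        history <- dplyr::bind_rows(history, rec)
        if (!is.null(config$out_dir)) write_history(history, config$out_dir, config)
        next
      }
      X <- normalize_candidates(train[names(space$params)], space)
      model <- gp_fit(X, train$score, groups = attr(X, "groups"),
                      seed = sugg_seeds[i])
      scored <- cur$score[!is.na(cur$score)]
      f_best <- if (length(scored)) max(scored) else {
        # no scored current-campaign record yet: fall back to the best prior
        max(train$score)
      }
      xi <- current_xi(sched, n_completed)
      cand <- suggest_next(model, space, xi, f_best,
                           history = history, seed = sugg_seeds[i])
    }
    res <- tryCatch(config$oracle(cand, seed = oracle_seeds[i]),
                    error = function(e) NULL)
    rec <- cand
    for (a in history_area_cols) {
      rec[[a]] <- if (!is.null(res) && a %in% names(res)) res[[a]] else NA_real_
    }
    rec$score <- if (!is.null(res)) res$score else NA_real_
    rec$phase <- phase
    rec$task <- config$task
    rec$seed <- oracle_seeds[i]
    rec <- dplyr::bind_cols(tibble(index = n_prior + i), rec)
    history <- dplyr::bind_rows(history, rec)
    if (!is.null(config$out_dir)) {
      write_history(history, config$out_dir, config)
    }
  }
  class(history) <- c("rxn_loop_history", class(tibble()))
  attr(history, "config_summary") <- list(
    space = space$name, budget = budget, objective = config$objective,
    seed = config$seed, task = config$task,
    schedule = unclass(sched), n_prior = n_prior)
  history
}

#' Persist / load loop histories
#'
#' Histories are flat tab-separated tables with a mandatory header row, one
#' column per space parameter plus the species areas, `score`, `phase`,
#' `task`, `seed`, and `index`.  A `manifest.yaml` beside the table records
#' the configuration (space, schedule, seeds, package version) and
#' wall-clock provenance; the table itself contains no timestamps, so
#' identical (configuration, seed) runs produce byte-identical tables.
#'
#' @param history History tibble.
#' @param dir Output directory.
#' @param config Optional [loop_config()] echoed into the manifest.
#' @return `write_history()` returns the history file path invisibly;
#'   `read_history()` returns the history tibble.
#' @export
write_history <- function(history, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hfile <- file.path(dir, "history.tsv")
  out <- as.data.frame(history)
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, hfile, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "rxnbo",
    version = as.character(utils::packageVersion("rxnbo")),
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_records = nrow(history)
  )
  if (!is.null(config)) {
    manifest$config <- list(
      space = config$space$name, budget = config$budget,
      objective = config$objective, seed = config$seed,
      task = config$task,
      schedule = unclass(config$schedule),
      count_prior_in_schedule = config$count_prior_in_schedule)
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(hfile)
}

#' @rdname write_history
#' @param path History file (or the directory holding `history.tsv`).
#' @param space Space used to restore column types.
#' @export
read_history <- function(path, space) {
  if (dir.exists(path)) path <- file.path(path, "history.tsv")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  out <- as_tibble(df)
  pars <- validate_candidates(out[names(space$params)], space)
  out[names(space$params)] <- pars
  out$phase <- as.character(out$phase)
  out$task <- as.character(out$task)
  out
}

#' Score a yield from chromatogram peak areas
#'
#' Normalized-area scoring over the tracked species (reactant, mono, di),
#' assuming equal detector response factors:
#' `yield = 100 * area(objective) / sum(areas)`.
#'
#' @param areas Named numeric vector or one-row data frame with entries
#'   `reactant`, `mono`, `di` (or the `area_*` column names).
#' @param objective `"mono"` or `"di"`.
#' @return Yield percent.
#' @export
score_from_areas <- function(areas, objective = c("mono", "di")) {
  objective <- match.arg(objective)
  if (is.data.frame(areas)) areas <- unlist(areas[1L, ])
  names(areas) <- sub("^area_", "", names(areas))
  need <- c("reactant", "mono", "di")
  if (!all(need %in% names(areas))) {
    stop_rxn("areas must contain: %s", paste(need, collapse = ", "))
  }
  areas <- areas[need]
  if (any(areas < 0) || !all(is.finite(areas))) {
    stop_rxn("areas must be finite and non-negative")
  }
  tot <- sum(areas)
  if (tot == 0) stop_rxn("all species areas are zero")
  100 * unname(areas[[objective]]) / tot
}

#' Best-so-far (incumbent) trace of a history
#'
#' Running maximum of observed yields over the current-campaign records
#' (failed experiments carried over, never counted).  Prior records are
#' summarized into a single `old_max` baseline attached as an attribute.
#'
#' @param history History tibble from [run_closed_loop()], or a plain
#'   numeric vector of yields.
#' @return A tibble with columns `index` and `incumbent` (attribute
#'   `old_max` when priors are present), or a numeric trace when the input
#'   was a numeric vector.
#' @export
best_so_far <- function(history) {
  if (is.numeric(history)) {
    return(cummax(ifelse(is.na(history), -Inf, history)))
  }
  if (!nrow(history)) stop_rxn("empty history")
  cur <- current_records(history)
  pri <- history[history$phase == "prior", , drop = FALSE]
  trace <- tibble(
    index = cur$index,
    incumbent = cummax(ifelse(is.na(cur$score), -Inf, cur$score))
  )
  attr(trace, "old_max") <- if (nrow(pri)) max(pri$score, na.rm = TRUE) else NA_real_
  trace
}

#' Post-hoc convergence diagnostic
#'
#' Smallest record position `i` such that the incumbent improves by less
#' than `tol` yield points over the following `window` records.  A reporting
#' diagnostic only — loops are stopped by budget, never by this criterion.
#'
#' @param history History tibble or numeric yield vector.
#' @param window Look-ahead window (records).
#' @param tol Improvement threshold (yield points).
#' @return The position within the current-campaign records, or `NA` if the
#'   incumbent keeps improving.
#' @export
detect_convergence <- function(history, window = 10L, tol = 1) {
  stopifnot(window >= 1L)
  trace <- if (is.numeric(history)) best_so_far(history) else
    best_so_far(history)$incumbent
  n <- length(trace)
  if (n <= window) return(NA_integer_)
  for (i in seq_len(n - window)) {
    if (trace[i + window] - trace[i] < tol) return(i)
  }
  NA_integer_
}

#' Experiments needed to reach a yield threshold
#'
#' @param history History tibble (or numeric yields).
#' @param threshold Yield (percent) the incumbent must reach.
#' @return Position of the first current-campaign record whose incumbent
#'   reaches the threshold, or `NA` if never reached.
#' @export
experiments_to_threshold <- function(history, threshold) {
  trace <- if (is.numeric(history)) best_so_far(history) else
    best_so_far(history)$incumbent
  hit <- which(trace >= threshold)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Uniform random candidates (random-search baseline)
#'
#' @param n Number of candidates.
#' @param space A [reaction_space()].
#' @param seed Seed.
#' @return A tibble of `n` valid candidates drawn uniformly (continuous
#'   dimensions uniform in their bounds; discrete dimensions uniform over
#'   levels; fixed parameters held).
#' @export
sample_candidates <- function(n, space, seed = 1L) {
  with_seed(seed, {
    out <- list()
    for (p in space$params) {
      if (is_fixed(p)) { out[[p$name]] <- rep(p$fixed, n); next }
      out[[p$name]] <- switch(p$kind,
        continuous = runif(n, p$lower, p$upper),
        ordinal = sample(p$levels, n, replace = TRUE),
        categorical = sample(p$levels, n, replace = TRUE))
    }
    validate_candidates(as_tibble(out), space)
  })
}

#' Random-search baseline campaign
#'
#' Evaluates `budget` uniformly sampled candidates with the oracle; the
#' equal-budget baseline the closed loop is benchmarked against.
#'
#' @inheritParams loop_config
#' @return A history tibble with `phase = "random"`.
#' @export
run_random_search <- function(space, oracle, budget, seed = 1L,
                              task = "task") {
  cand <- sample_candidates(budget, space, seed = seed)
  seeds <- derive_seeds(seed, budget, stream = 1L)
  res <- oracle(cand, seed = seeds[1L])
  out <- dplyr::bind_cols(tibble(index = seq_len(budget)), cand)
  for (a in history_area_cols) {
    out[[a]] <- if (a %in% names(res)) res[[a]] else NA_real_
  }
  out$score <- res$score
  out$phase <- "random"
  out$task <- task
  out$seed <- seeds[1L]
  out
}
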