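# Expected-improvement acquisition with a dual exploration schedule.
#
# The optimizer runs in two regimes: an explorative regime with a high xi
# (the improvement margin demanded before expected improvement rewards
# exploitation) for the first `changeover` experiments, then an exploitative
# regime with a low xi.  Initial experiments come from a Latin-hypercube
# design.

#' Dual-xi acquisition schedule
#'
#' @param high_xi Xi used while fewer than `changeover` experiments are
#'   completed (explorative regime).
#' @param low_xi Xi used afterwards (exploitative regime).
#' @param changeover Completed-experiment count at which the schedule
#'   switches; the comparison is strict (`n_completed < changeover` keeps the
#'   high xi).
#' @param n_initial Number of Latin-hypercube experiments opening a loop.
#' @return An object of class `xi_schedule`.
#' @export
xi_schedule <- function(high_xi = 1.0, low_xi = 0.01, changeover = 48L,
                        n_initial = 12L) {
  if (!is_number(high_xi) || !is_number(low_xi) || low_xi <= 0 ||
      high_xi < low_xi) {
    stop_rxn("need high_xi >= low_xi > 0")
  }
  if (changeover < n_initial || n_initial < 0L) {
    stop_rxn("need changeover >= n_initial >= 0")
  }
  structure(list(high_xi = high_xi, low_xi = low_xi,
                 changeover = as.integer(changeover),
                 n_initial = as.integer(n_initial)),
            class = "xi_schedule")
}

#' @export
print.xi_schedule <- function(x, ...) {
  cat(sprintf("<xi_schedule> high %g -> low %g at %d experiments (%d LHS)\n",
              x$high_xi, x$low_xi, x$changeover, x$n_initial))
  invisible(x)
}

#' Xi in effect after a given number of completed experiments
#'
#' @param schedule An [xi_schedule()].
#' @param n_completed Number of completed experiments counting toward the
#'   changeover.
#' @return The xi value in effect for the next suggestion.
#' @export
current_xi <- function(schedule, n_completed) {
  stopifnot(n_completed >= 0)
  if (n_completed < schedule$changeover) schedule$high_xi else schedule$low_xi
}

#' Expected improvement
#'
#' Closed-form expected improvement over the incumbent `f_best` with
#' exploration margin `xi` under a Gaussian posterior:
#' `EI = (mu - f* - xi) * Phi(z) + sigma * phi(z)` with
#' `z = (mu - f* - xi) / sigma`, and the limit
#' `EI = max(mu - f* - xi, 0)` when `sigma = 0`.  All arguments are
#' vectorized.
#'
#' @param mean,sd Posterior mean and standard deviation (`sd >= 0`).
#' @param f_best Incumbent (best observed) value.
#' @param xi Exploration margin (>= 0 in normal use).
#' @return Expected improvement, always `>= 0`.
#' @export
expected_improvement <- function(mean, sd, f_best, xi = 0) {
  if (any(sd < 0)) stop_rxn("sd must be non-negative")
  n <- max(length(mean), length(sd), length(f_best), length(xi))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  f_best <- rep_len(f_best, n); xi <- rep_len(xi, n)
  d <- mean - f_best - xi
  out <- pmax(d, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- d[pos] / sd[pos]
    out[pos] <- d[pos] * pnorm(z) + sd[pos] * dnorm(z)
  }
  pmax(out, 0)
}

#' Latin-hypercube initial design over a reaction space
#'
#' Continuous and ordinal dimensions are stratified: the `n` points occupy
#' the `n` equal-probability strata of each continuous dimension exactly
#' once, and ordinal levels are drawn through the same stratified ranks.
#' Categorical dimensions are sampled by stratified shuffling over their
#' levels (each level appears `floor(n / L)` or `ceiling(n / L)` times); when
#' `n` is smaller than the number of levels the shuffled levels are cycled
#' and a note is emitted.  Fixed parameters hold their fixed values.
#'
#' @param n Number of design points (>= 1).
#' @param space A [reaction_space()].
#' @param seed Seed making the design reproducible.
#' @return A tibble of `n` valid candidates.
#' @export
lhs_candidates <- function(n, space, seed = 1L) {
  if (n < 1L) stop_rxn("n must be >= 1")
  free <- free_params(space)
  numish <- free[vapply(free, function(p) p$kind != "categorical", TRUE)]
  cats <- free[vapply(free, function(p) p$kind == "categorical", TRUE)]
  with_seed(seed, {
    U <- if (length(numish)) lhs::randomLHS(n, length(numish)) else
      matrix(0, n, 0)
    out <- list()
    for (i in seq_along(numish)) {
      p <- numish[[i]]
      u <- U[, i]
      if (p$kind == "continuous") {
        out[[p$name]] <- p$lower + u * (p$upper - p$lower)
      } else {
        L <- length(p$levels)
        out[[p$name]] <- p$levels[pmin(floor(u * L) + 1L, L)]
      }
    }
    for (p in cats) {
      L <- length(p$levels)
      if (n < L) {
        inform(sprintf("LHS: n = %d < %d levels of '%s'; levels cycled",
                       n, L, p$name))
      }
      lv <- rep(sample(p$levels), length.out = max(n, L))
      out[[p$name]] <- sample(lv)[seq_len(n)]
    }
    for (p in space$params[vapply(space$params, is_fixed, TRUE)]) {
      out[[p$name]] <- rep(p$fixed, n)
    }
    validate_candidates(as_tibble(out), space)
  })
}

# Normalized coordinates of the free continuous/ordinal columns and of the
# free categorical blocks, given a space layout.
acq_layout <- function(space) {
  lay <- normalized_layout(space)
  fixed_names <- names(space$params)[vapply(space$params, is_fixed, TRUE)]
  lay$fixed <- lay$param %in% fixed_names
  lay
}

#' Propose the next experiment by maximizing expected improvement
#'
#' Maximizes the expected-improvement acquisition over the mixed space:
#' free categorical level combinations are enumerated (up to
#' `max_enumeration`, beyond which a seeded subsample is used), and for each
#' combination the continuous/ordinal block is optimized by seeded random
#' multi-start with local Nelder-Mead refinement; ordinal coordinates are
#' snapped to their nearest admissible level at the end.  Candidates closer
#' than `dup_tol` (normalized distance) to a previously run experiment are
#' suppressed in favour of the next-best distinct optimum, so the loop never
#' re-runs an identical experiment.
#'
#' @param model Fitted [gp_fit()] surrogate on the space's normalized
#'   representation.
#' @param space A [reaction_space()].
#' @param xi Exploration margin for [expected_improvement()].
#' @param f_best Incumbent yield to improve upon.
#' @param history Optional tibble of already-run candidates (parameter
#'   columns) used for duplicate suppression.
#' @param seed Seed controlling start points; suggestions are deterministic
#'   given (model, space, xi, f_best, history, seed).
#' @param n_starts Random starts per categorical combination.
#' @param n_refine Number of top starts polished by local refinement.
#' @param max_enumeration Cap on enumerated categorical combinations.
#' @param dup_tol Normalized-distance tolerance for duplicate suppression.
#' @return A one-row tibble: the proposed candidate.
#' @export
suggest_next <- function(model, space, xi, f_best, history = NULL, seed = 1L,
                         n_starts = 96L, n_refine = 10L,
                         max_enumeration = 5000L, dup_tol = 1e-6) {
  lay <- acq_layout(space)
  if (all(lay$fixed) || nrow(lay) == 0L) {
    # in_model task columns are fixed; need at least one searchable column
  }
  if (length(free_params(space)) == 0L) stop_rxn("space has no free parameters")
  num_idx <- which(!lay$fixed & lay$kind %in% c("continuous", "ordinal"))
  cat_params <- free_params(space)
  cat_params <- cat_params[vapply(cat_params, function(p) p$kind == "categorical", TRUE)]

  # Template normalized row holding every fixed/in-model coordinate.
  template <- rep(0, nrow(lay))
  for (p in model_params(space)) {
    if (!is_fixed(p)) next
    if (p$kind == "categorical") {
      template[match(paste0(p$name, "=", p$fixed), lay$column)] <- 1
    } else if (p$kind == "ordinal") {
      L <- length(p$levels)
      r <- match(p$fixed, p$levels)
      template[match(p$name, lay$column)] <- if (L == 1L) 0.5 else (r - 1) / (L - 1)
    } else {
      template[match(p$name, lay$column)] <-
        (p$fixed - p$lower) / (p$upper - p$lower)
    }
  }

  combos <- if (length(cat_params)) {
    grid <- expand.grid(lapply(cat_params, `[[`, "levels"),
                        stringsAsFactors = FALSE)
    names(grid) <- vapply(cat_params, `[[`, "", "name")
    grid
  } else {
    data.frame(row.names = 1L)
  }
  history_X <- if (!is.null(history) && nrow(history)) {
    normalize_candidates(history[names(space$params)], space)
  } else {
    NULL
  }

  # When the incumbent is unreachably far above every posterior mean, EI
  # underflows to zero everywhere; fall back to posterior-sd maximization,
  # the pure exploration limit of EI.
  explore_mode <- FALSE
  ei_at <- function(Xmat) {
    pr <- gp_mean_sd(model, Xmat)
    if (explore_mode) return(pr$sd)
    expected_improvement(pr$mean, pr$sd, f_best, xi)
  }
  snap_num <- function(x) {
    for (j in num_idx) {
      if (lay$kind[j] == "ordinal") {
        p <- space$params[[lay$param[j]]]
        L <- length(p$levels)
        x[j] <- if (L == 1L) 0.5 else round(x[j] * (L - 1)) / (L - 1)
      }
      x[j] <- min(max(x[j], 0), 1)
    }
    x
  }

  with_seed(seed, {
    nc <- nrow(combos)
    if (nc > max_enumeration) {
      combos <- combos[sample.int(nc, max_enumeration), , drop = FALSE]
      nc <- max_enumeration
    }
    # Seeded random starts: n_starts points per categorical combination.
    reps <- max(nc, 1L)
    starts <- matrix(rep(template, each = n_starts * reps),
                     nrow = n_starts * reps)
    if (length(num_idx)) {
      starts[, num_idx] <- runif(n_starts * reps * length(num_idx))
    }
    if (nc > 0L) {
      rows <- rep(seq_len(nc), each = n_starts)
      for (p in names(combos)) {
        jj <- which(lay$param == p)
        starts[, jj] <- 0
        hit <- match(paste0(p, "=", combos[rows, p]), lay$column)
        starts[cbind(seq_len(nrow(starts)), hit)] <- 1
      }
    }
    # Anchor additional starts at the best-scoring past experiments: EI
    # optima cluster near the incumbent once the loop is exploiting.
    if (xi <= 0.1 && !is.null(history) && "score" %in% names(history) &&
        any(is.finite(history$score))) {
      hb <- history[order(history$score, decreasing = TRUE), , drop = FALSE]
      hb <- hb[seq_len(min(3L, nrow(hb))), , drop = FALSE]
      Xb <- normalize_candidates(hb[names(space$params)], space)
      loc <- Xb[rep(seq_len(nrow(Xb)), each = 8L), , drop = FALSE]
      if (length(num_idx)) {
        pert <- matrix(rnorm(nrow(loc) * length(num_idx), 0, 0.07), nrow(loc))
        loc[, num_idx] <- pmin(pmax(loc[, num_idx, drop = FALSE] + pert, 0), 1)
      }
      starts <- rbind(starts, loc)
    }
    ei0 <- ei_at(starts)
    if (max(ei0) <= 0) {
      explore_mode <- TRUE
      ei0 <- ei_at(starts)
    }
    ord <- order(ei0, decreasing = TRUE)
    top <- ord[seq_len(min(n_refine, length(ord)))]

    # Batched local refinement: shrinking Gaussian perturbations around each
    # kept start, evaluated in one posterior call per round.
    cur <- starts[top, , drop = FALSE]
    cur_ei <- ei0[top]
    if (length(num_idx)) {
      n_pert <- 32L
      nr <- nrow(cur)
      for (radius in c(0.4, 0.15, 0.05, 0.02)) {
        P <- cur[rep(seq_len(nr), each = n_pert), , drop = FALSE]
        noise <- matrix(rnorm(nr * n_pert * length(num_idx), 0, radius),
                        nr * n_pert)
        P[, num_idx] <- pmin(pmax(P[, num_idx, drop = FALSE] + noise, 0), 1)
        ei_p <- ei_at(P)
        for (i in seq_len(nr)) {
          jj <- ((i - 1L) * n_pert + 1L):(i * n_pert)
          j_best <- jj[which.max(ei_p[jj])]
          if (ei_p[j_best] > cur_ei[i]) {
            cur[i, ] <- P[j_best, ]
            cur_ei[i] <- ei_p[j_best]
          }
        }
      }
    }
    refined <- lapply(seq_len(nrow(cur)), function(i) snap_num(cur[i, ]))
    # Also keep the snapped top raw starts as fallback optima.
    fallback <- lapply(ord[seq_len(min(50L, length(ord)))], function(i) {
      snap_num(starts[i, ])
    })
    cand <- unique(do.call(rbind, c(refined, fallback)))
    ei_final <- ei_at(cand)
    cand <- cand[order(ei_final, decreasing = TRUE), , drop = FALSE]

    pick <- NULL
    if (!is.null(history_X)) {
      for (i in seq_len(nrow(cand))) {
        d2 <- colSums((t(history_X) - cand[i, ])^2)
        if (min(d2) > dup_tol^2) { pick <- cand[i, ]; break }
      }
    } else {
      pick <- cand[1L, ]
    }
    if (is.null(pick)) {
      # every optimum coincides with a past experiment: perturb until distinct
      for (try in 1:200) {
        x <- snap_num(template + runif(length(template)))
        x[-num_idx] <- cand[1L, -num_idx]
        d2 <- colSums((t(history_X) - x)^2)
        if (min(d2) > dup_tol^2) { pick <- x; break }
      }
      if (is.null(pick)) pick <- cand[1L, ]
    }
    denormalize_candidates(matrix(pick, 1L), space)
  })
}
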