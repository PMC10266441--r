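# Gaussian-process surrogate over the normalized design space.
#
# Kernel: anisotropic Matern-5/2 with one lengthscale per parameter block
# (continuous and ordinal parameters get their own lengthscale; a categorical
# one-hot block shares one).  One-hot columns are rescaled so that two
# candidates differing only in a categorical level sit at distance 1/2 in
# kernel space, a half-unit move comparable to half the range of a continuous
# parameter.  Outputs are standardized to zero mean / unit variance before
# fitting; predictions are mapped back to yield units.

ONE_HOT_SCALE <- 0.5 / sqrt(2)
GP_JITTER <- 1e-8

matern52 <- function(r2) {
  a <- sqrt(5 * pmax(r2, 0))
  (1 + a + a^2 / 3) * exp(-a)
}

# Per-group squared-distance matrices between rows of X (and optionally X2).
group_sqdist <- function(X, groups, X2 = NULL) {
  if (is.null(X2)) X2 <- X
  lapply(unique(groups), function(g) {
    j <- which(groups == g)
    A <- X[, j, drop = FALSE]
    B <- X2[, j, drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    pmax(d2, 0)
  })
}

kernel_from_sqdist <- function(D, log_ell, signal_var) {
  r2 <- 0
  for (i in seq_along(D)) r2 <- r2 + D[[i]] / exp(2 * log_ell[i])
  signal_var * matern52(r2)
}

as_sqdist_cube <- function(D) {
  n <- nrow(D[[1L]])
  array(unlist(D, use.names = FALSE), dim = c(n, n, length(D)))
}

# Log marginal likelihood and its gradient w.r.t. log-hyperparameters.
# theta = c(log lengthscale per group, log signal_var, log noise_var).
# Thin wrapper around the compiled core; `D` is a list of per-group squared
# distance matrices (or the cube already built from them).
gp_lml_grad <- function(theta, D, y, want_grad = TRUE) {
  if (is.list(D)) D <- as_sqdist_cube(D)
  res <- gp_lml_grad_cpp(D, y, theta, GP_JITTER, want_grad)
  if (want_grad) res$grad <- as.numeric(res$grad)
  res
}

gp_lml_grad_reference <- function(theta, D, y, want_grad = TRUE) {
  ng <- length(D)
  log_ell <- theta[seq_len(ng)]
  sv <- exp(theta[ng + 1L])
  nv <- exp(theta[ng + 2L])
  n <- length(y)
  r2 <- 0
  for (i in seq_len(ng)) r2 <- r2 + D[[i]] / exp(2 * log_ell[i])
  a <- sqrt(5 * r2)
  R <- (1 + a + a^2 / 3) * exp(-a)
  K <- sv * R
  diag(K) <- diag(K) + nv + GP_JITTER
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) {
    return(list(lml = -1e10, grad = rep(0, length(theta))))
  }
  alpha <- backsolve(L, forwardsolve(t(L), y))
  lml <- -0.5 * sum(y * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
  if (!want_grad) return(list(lml = lml, grad = NULL))
  Kinv <- chol2inv(L)
  W <- tcrossprod(alpha) - Kinv
  grad <- numeric(length(theta))
  # d k / d r2 = -(5/6) sv (1 + a) e^{-a};  d r2 / d log ell_g = -2 D_g/ell_g^2
  core <- (5 / 3) * sv * (1 + a) * exp(-a)
  for (i in seq_len(ng)) {
    dK <- core * (D[[i]] / exp(2 * log_ell[i]))
    grad[i] <- 0.5 * sum(W * dK)
  }
  grad[ng + 1L] <- 0.5 * sum(W * (sv * R))
  grad[ng + 2L] <- 0.5 * nv * sum(diag(W))
  list(lml = lml, grad = grad)
}

#' Log marginal likelihood of a GP at fixed hyperparameters
#'
#' Exposed mainly for diagnostics and cross-checking; [gp_fit()] maximizes
#' this quantity over the hyperparameters.
#'
#' @param X Numeric matrix of normalized inputs (rows = observations).
#' @param y Numeric response vector (used as-is; no standardization).
#' @param lengthscales Positive lengthscale per column group.
#' @param signal_var,noise_var Positive kernel signal and noise variances.
#' @param groups Integer grouping of columns sharing a lengthscale
#'   (default: every column its own group).
#' @return The log marginal likelihood (scalar).
#' @export
gp_log_marginal <- function(X, y, lengthscales, signal_var, noise_var,
                            groups = NULL) {
  X <- as.matrix(X)
  groups <- groups %||% seq_len(ncol(X))
  X <- scale_onehot(X, groups)
  D <- group_sqdist(X, groups)
  theta <- c(log(lengthscales), log(signal_var), log(noise_var))
  gp_lml_grad(theta, D, y, want_grad = FALSE)$lml
}

scale_onehot <- function(X, groups) {
  tab <- table(groups)
  multi <- as.integer(names(tab)[tab > 1L])
  if (length(multi)) {
    j <- groups %in% multi
    X[, j] <- X[, j] * ONE_HOT_SCALE
  }
  X
}

#' Fit the Gaussian-process surrogate
#'
#' Fits a Matern-5/2 GP to observed (normalized condition, yield) pairs by
#' maximizing the log marginal likelihood with multi-restart L-BFGS-B using
#' analytic gradients.  Deterministic for a given seed: refitting on the same
#' data reproduces identical hyperparameters.
#'
#' @param X Numeric matrix of normalized inputs, typically from
#'   [normalize_candidates()] (its `groups` attribute is picked up
#'   automatically).
#' @param y Observed yields (percent).
#' @param groups Optional integer vector grouping columns that share a
#'   lengthscale (categorical one-hot blocks).
#' @param seed Seed for the restart draws.
#' @param n_restarts Number of random restarts in addition to the default
#'   start.
#' @param lengthscales,signal_var,noise_var Optional pinned values; any
#'   hyperparameter supplied here is held fixed instead of fitted (e.g.
#'   `noise_var = 1e-8` for noise-free interpolation).
#' @return An object of class `rxn_gp`.
#' @export
gp_fit <- function(X, y, groups = NULL, seed = 1L, n_restarts = 5L,
                   lengthscales = NULL, signal_var = NULL, noise_var = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_rxn("nrow(X) must equal length(y)")
  if (length(y) < 1L) stop_rxn("need at least one observation")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop_rxn("non-finite values in GP training data")
  }
  groups <- groups %||% attr(X, "groups") %||% seq_len(ncol(X))
  groups <- match(groups, unique(groups))
  Xs <- scale_onehot(X, groups)
  ym <- mean(y)
  ys <- if (length(unique(y)) >= 2L) sd(y) else 1
  if (ys == 0) ys <- 1
  yz <- (y - ym) / ys
  ng <- length(unique(groups))
  D <- group_sqdist(Xs, groups)
  Dcube <- as_sqdist_cube(D)

  lb <- c(rep(log(1e-2), ng), log(1e-3), log(1e-6))
  ub <- c(rep(log(1e2), ng), log(1e3), log(1))
  pin <- c(if (is.null(lengthscales)) rep(NA_real_, ng) else log(rep(lengthscales, length.out = ng)),
           if (is.null(signal_var)) NA_real_ else log(signal_var),
           if (is.null(noise_var)) NA_real_ else log(noise_var))
  free <- is.na(pin)

  # optim calls fn and gr at the same point back-to-back; cache one evaluation.
  cache <- new.env(parent = emptyenv())
  obj <- function(th_free) {
    key <- paste(format(th_free, digits = 17), collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    th <- pin
    th[free] <- th_free
    res <- gp_lml_grad(th, Dcube, yz)
    cache$key <- key
    cache$val <- list(value = -res$lml, gradient = -res$grad[free])
    cache$val
  }
  fn <- function(p) obj(p)$value
  gr <- function(p) obj(p)$gradient

  default_start <- c(rep(log(0.5), ng), log(1), log(1e-2))
  starts <- list(default_start[free])
  if (any(free) && n_restarts > 0L) {
    extra <- with_seed(seed, {
      lapply(seq_len(n_restarts), function(i) {
        runif(sum(free), lb[free], ub[free])
      })
    })
    starts <- c(starts, extra)
  }

  # Screen all starts with a short L-BFGS-B run, then polish the best one:
  # same optimum quality as full runs from every start at a fraction of the
  # likelihood evaluations.
  best <- NULL
  if (!any(free)) {
    best <- list(par = numeric(0), value = fn(numeric(0)))
  } else {
    for (st in starts) {
      fit <- tryCatch(
        optim(st, fn, gr, method = "L-BFGS-B", lower = lb[free],
              upper = ub[free], control = list(maxit = 12L, factr = 1e9)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop_rxn("hyperparameter optimization failed")
    polish <- tryCatch(
      optim(best$par, fn, gr, method = "L-BFGS-B", lower = lb[free],
            upper = ub[free], control = list(maxit = 60L, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) best <- polish
  }
  theta <- pin
  theta[free] <- best$par

  log_ell <- theta[seq_len(ng)]
  sv <- exp(theta[ng + 1L])
  nv <- exp(theta[ng + 2L])
  K <- kernel_from_sqdist(D, log_ell, sv)
  diag(K) <- diag(K) + nv + GP_JITTER
  L <- NULL
  jit <- GP_JITTER
  while (is.null(L) && jit <= 1e-4) {
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) {
      jit <- jit * 10
      diag(K) <- diag(K) + jit
    }
  }
  if (is.null(L)) stop_rxn("covariance factorization failed")
  alpha <- backsolve(L, forwardsolve(t(L), yz))
  Llow <- t(L)

  structure(
    list(X = Xs, y = y, yz = yz, ym = ym, ys = ys, groups = groups, Llow = Llow,
         lengthscales = exp(log_ell), signal_var = sv, noise_var = nv,
         L = L, alpha = alpha, lml = -best$value, seed = seed),
    class = "rxn_gp"
  )
}

#' @export
print.rxn_gp <- function(x, ...) {
  cat(sprintf("<rxn_gp> n = %d, d = %d, log marginal likelihood = %.3f\n",
              nrow(x$X), ncol(x$X), x$lml))
  cat(sprintf("  signal sd %.3f, noise sd %.4f (standardized scale)\n",
              sqrt(x$signal_var), sqrt(x$noise_var)))
  cat("  lengthscales:", paste(sprintf("%.3g", x$lengthscales), collapse = " "), "\n")
  invisible(x)
}

# Fast internal predictor: mean/sd in yield units without tibble overhead.
# `Xn_raw` is a matrix in the normalized representation (unscaled one-hot).
gp_mean_sd <- function(object, Xn_raw) {
  Xn <- scale_onehot(Xn_raw, object$groups)
  D <- group_sqdist(object$X, object$groups, Xn)
  theta <- c(log(object$lengthscales), log(object$signal_var), 0)
  post <- gp_post_cpp(unlist(D, use.names = FALSE), nrow(Xn), theta,
                      object$Llow, object$alpha)
  list(mean = object$ym + object$ys * drop(post$mean),
       sd = object$ys * drop(post$sd))
}

#' Posterior prediction from a fitted surrogate
#'
#' Returns the posterior mean and standard deviation of the latent yield
#' surface (measurement noise excluded) at new normalized inputs, in yield
#' units.
#'
#' @param object A fitted [gp_fit()] model.
#' @param newdata Numeric matrix (or single vector) of normalized inputs with
#'   the model's dimensionality.
#' @param ... Unused.
#' @return A tibble with columns `mean` and `sd`, one row per input row.
#' @export
predict.rxn_gp <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X)) {
    stop_rxn("newdata has %d columns; model expects %d",
             ncol(newdata), ncol(object$X))
  }
  pr <- gp_mean_sd(object, newdata)
  tibble(mean = pr$mean, sd = pr$sd)
}

#' @method tidy rxn_gp
#' @export
tidy.rxn_gp <- function(x, ...) {
  tibble(
    term = c(paste0("lengthscale_", seq_along(x$lengthscales)),
             "signal_var", "noise_var"),
    estimate = c(x$lengthscales, x$signal_var, x$noise_var)
  )
}

#' @method glance rxn_gp
#' @export
glance.rxn_gp <- function(x, ...) {
  tibble(n_obs = nrow(x$X), dim = ncol(x$X), log_marginal = x$lml,
         noise_sd_yield = sqrt(x$noise_var) * x$ys)
}

#' Serialize / restore a fitted surrogate as structured text
#'
#' Writes the fitted hyperparameters and the training-data snapshot to YAML;
#' restoring rebuilds the factorized model; predictions from the restored
#' model match the original's to the round-trip precision of the text
#' snapshot.
#'
#' @param model A fitted [gp_fit()] object.
#' @param path Output (input) file path.
#' @return `write_gp()` returns `path` invisibly; `read_gp()` returns an
#'   `rxn_gp` model.
#' @export
write_gp <- function(model, path) {
  yaml::write_yaml(list(
    lengthscales = model$lengthscales, signal_var = model$signal_var,
    noise_var = model$noise_var, groups = model$groups, seed = model$seed,
    X = apply(unclass(model$X), 1L, function(r) paste(sprintf("%.17g", r),
                                                      collapse = " ")),
    y = sprintf("%.17g", model$y)), path)
  invisible(path)
}

#' @rdname write_gp
#' @export
read_gp <- function(path) {
  x <- yaml::read_yaml(path)
  X <- do.call(rbind, lapply(x$X, function(r) as.numeric(strsplit(r, " ")[[1L]])))
  # the snapshot stores the already block-scaled inputs; undo before gp_fit
  groups <- as.integer(unlist(x$groups))
  tab <- table(groups)
  multi <- as.integer(names(tab)[tab > 1L])
  if (length(multi)) {
    j <- groups %in% multi
    X[, j] <- X[, j] / ONE_HOT_SCALE
  }
  gp_fit(X, as.numeric(x$y), groups = groups, seed = x$seed,
         lengthscales = unlist(x$lengthscales), signal_var = x$signal_var,
         noise_var = x$noise_var)
}
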