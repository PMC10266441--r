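#' Describe one searchable reaction parameter
#'
#' A reaction-condition space is built from parameter specifications of three
#' kinds: `continuous` parameters carry physical bounds (equivalents, mol/L,
#' minutes), `ordinal` parameters take labelled integer levels with a
#' meaningful order (for example reagents encoded by descriptor PCA), and
#' `categorical` parameters take unordered labels (solvents and solvent
#' mixtures, substrates).
#'
#' @param name Parameter name (unique within a space).
#' @param kind One of `"continuous"`, `"ordinal"`, `"categorical"`.
#' @param lower,upper Finite bounds, continuous parameters only.
#' @param levels Ordered integer levels (ordinal) or character labels
#'   (categorical).
#' @param labels Optional display labels for ordinal levels, same length as
#'   `levels`.
#' @param fixed Optional value freezing the parameter at one point of its
#'   domain.  Fixed parameters are carried by every candidate but are not
#'   searched, and by default are not part of the surrogate's input space.
#' @param in_model Logical; include this parameter in the surrogate input even
#'   when fixed.  Used by [augment_with_task()] so prior-task records keep
#'   their task coordinate while suggestions stay pinned to the current task.
#'
#' @return An object of class `param_spec`.
#' @seealso [reaction_space()], [build_space()]
#' @export
param_spec <- function(name, kind = c("continuous", "ordinal", "categorical"),
                       lower = NULL, upper = NULL, levels = NULL,
                       labels = NULL, fixed = NULL, in_model = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_rxn("parameter name must be a non-empty string")
  }
  if (kind == "continuous") {
    if (!is_number(lower) || !is_number(upper)) {
      stop_rxn("continuous parameter '%s' needs finite lower and upper bounds", name)
    }
    if (lower >= upper) {
      stop_rxn("continuous parameter '%s' has lower >= upper (%g >= %g)",
               name, lower, upper)
    }
    levels <- NULL
  } else if (kind == "ordinal") {
    if (is.null(levels) || length(levels) < 1L) {
      stop_rxn("ordinal parameter '%s' has an empty level list", name)
    }
    if (any(levels != round(levels)) || anyDuplicated(levels) > 0L) {
      stop_rxn("ordinal parameter '%s' needs distinct integer levels", name)
    }
    levels <- as.integer(levels)
    if (!is.null(labels)) {
      if (length(labels) != length(levels) || anyDuplicated(labels) > 0L) {
        stop_rxn("ordinal parameter '%s': labels must be unique, one per level", name)
      }
    }
    lower <- upper <- NULL
  } else {
    if (is.null(levels) || anyDuplicated(levels) > 0L) {
      stop_rxn("categorical parameter '%s' needs distinct labels", name)
    }
    levels <- as.character(levels)
    if (length(levels) < 2L && is.null(fixed)) {
      stop_rxn("categorical parameter '%s' needs at least 2 labels unless fixed", name)
    }
    lower <- upper <- NULL
  }
  spec <- structure(
    list(name = name, kind = kind, lower = lower, upper = upper,
         levels = levels, labels = labels, fixed = NULL,
         in_model = isTRUE(in_model)),
    class = "param_spec"
  )
  if (!is.null(fixed)) {
    if (!value_in_domain(spec, fixed)) {
      stop_rxn("fixed value for '%s' lies outside its domain", name)
    }
    spec$fixed <- if (kind == "ordinal") as.integer(fixed)
      else if (kind == "categorical") as.character(fixed) else as.numeric(fixed)
  }
  spec
}

value_in_domain <- function(spec, value) {
  if (length(value) != 1L || is.na(value)) return(FALSE)
  switch(spec$kind,
    continuous = is.numeric(value) && is.finite(value) &&
      value >= spec$lower && value <= spec$upper,
    ordinal = !is.na(suppressWarnings(as.integer(value))) &&
      as.integer(value) %in% spec$levels,
    categorical = as.character(value) %in% spec$levels
  )
}

is_fixed <- function(spec) !is.null(spec$fixed)

#' Assemble a reaction-condition space
#'
#' @param params List of [param_spec()] objects.
#' @param metadata Free-text provenance (constants such as a fixed reaction
#'   time belong here, not in the parameter list).
#' @param name Short identifier for the space.
#'
#' @return An object of class `reaction_space`.
#' @export
reaction_space <- function(params, metadata = list(), name = "space") {
  if (!length(params) || !all(vapply(params, inherits, TRUE, "param_spec"))) {
    stop_rxn("params must be a non-empty list of param_spec objects")
  }
  nms <- vapply(params, `[[`, "", "name")
  if (anyDuplicated(nms) > 0L) {
    stop_rxn("duplicate parameter names: %s",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(params) <- nms
  if (all(vapply(params, is_fixed, TRUE))) {
    stop_rxn("space needs at least one non-fixed parameter")
  }
  structure(list(name = name, params = params, metadata = metadata),
            class = "reaction_space")
}

#' @export
print.reaction_space <- function(x, ...) {
  cat(sprintf("<reaction_space '%s'> %d parameters (%d free), model dim %d\n",
              x$name, length(x$params),
              sum(!vapply(x$params, is_fixed, TRUE)), space_dim(x)))
  for (p in x$params) {
    dom <- switch(p$kind,
      continuous = sprintf("[%g, %g]", p$lower, p$upper),
      ordinal = sprintf("{%s}", paste(p$levels, collapse = ",")),
      categorical = sprintf("{%s}", paste(p$levels, collapse = ","))
    )
    tag <- if (is_fixed(p)) sprintf(" (fixed = %s)", p$fixed) else ""
    cat(sprintf("  %-12s %-11s %s%s\n", p$name, p$kind, dom, tag))
  }
  invisible(x)
}

# Parameters that enter the surrogate's normalized input: every free
# parameter, plus fixed parameters explicitly flagged in_model (task tags).
model_params <- function(space) {
  keep <- vapply(space$params, function(p) !is_fixed(p) || isTRUE(p$in_model), TRUE)
  space$params[keep]
}

free_params <- function(space) {
  space$params[!vapply(space$params, is_fixed, TRUE)]
}

#' Normalized dimensionality of a space
#'
#' Continuous and ordinal parameters contribute one coordinate each; each
#' categorical parameter contributes a one-hot block with one coordinate per
#' level.  Fixed parameters are omitted unless flagged `in_model`.
#'
#' @param space A [reaction_space()].
#' @return Integer dimension of the normalized representation.
#' @export
space_dim <- function(space) {
  sum(vapply(model_params(space), function(p) {
    if (p$kind == "categorical") length(p$levels) else 1L
  }, 1L))
}

#' Build a reaction space from a configuration document
#'
#' Reads a YAML document (or an equivalent nested list) that declares each
#' parameter with its kind and domain, validates it, and returns the space.
#' Example configurations for the shipped closed-loop layouts are under
#' `system.file("extdata", package = "rxnbo")`.
#'
#' @param config Path to a YAML file, or a list with elements `name`,
#'   `parameters` (list of parameter blocks), and optional `metadata`.
#' @return A [reaction_space()].
#' @export
#' @examples
#' cfg <- system.file("extdata", "space_cl1.yaml", package = "rxnbo")
#' build_space(cfg)
build_space <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$parameters)) {
    stop_rxn("config must declare a 'parameters' list")
  }
  params <- lapply(config$parameters, function(p) {
    if (is.null(p$name) || is.null(p$kind)) {
      stop_rxn("every parameter block needs 'name' and 'kind'")
    }
    if (!p$kind %in% c("continuous", "ordinal", "categorical")) {
      stop_rxn("malformed kind '%s' for parameter '%s'", p$kind, p$name)
    }
    param_spec(name = p$name, kind = p$kind, lower = p$lower, upper = p$upper,
               levels = unlist(p$levels), labels = unlist(p$labels),
               fixed = p$fixed)
  })
  reaction_space(params,
                 metadata = config$metadata %||% list(),
                 name = config$name %||% "space")
}

#' Validate candidates against a space
#'
#' @param candidates Data frame with one column per space parameter, one row
#'   per candidate.
#' @param space A [reaction_space()].
#' @return `check_candidates()` returns a tibble with columns `ok` and
#'   `reason` (NA when valid); `validate_candidates()` errors on the first
#'   invalid row and otherwise returns the candidates as a tibble, invisibly
#'   coerced to canonical column types.
#' @export
check_candidates <- function(candidates, space) {
  candidates <- as_tibble(candidates)
  n <- nrow(candidates)
  ok <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  flag <- function(bad, msg) {
    new <- bad & ok
    ok[new] <<- FALSE
    reason[new] <<- msg
  }
  for (p in space$params) {
    if (!p$name %in% names(candidates)) {
      flag(rep(TRUE, n), sprintf("missing parameter '%s'", p$name))
      next
    }
    v <- candidates[[p$name]]
    if (p$kind == "continuous") {
      v <- suppressWarnings(as.numeric(v))
      flag(!is.finite(v) | v < p$lower | v > p$upper,
           sprintf("'%s' out of bounds [%g, %g]", p$name, p$lower, p$upper))
    } else if (p$kind == "ordinal") {
      vi <- suppressWarnings(as.integer(v))
      flag(is.na(vi) | !(vi %in% p$levels),
           sprintf("'%s' not an admissible level", p$name))
      v <- vi
    } else {
      flag(!(as.character(v) %in% p$levels),
           sprintf("'%s' not an admissible label", p$name))
    }
    if (is_fixed(p) && !isTRUE(p$in_model)) {
      # model-carried task parameters are pinned for suggestions only;
      # records may legitimately hold other task labels
      flag(!is.na(v) & v != p$fixed,
           sprintf("'%s' must hold its fixed value %s", p$name, p$fixed))
    }
  }
  tibble(ok = ok, reason = reason)
}

#' @rdname check_candidates
#' @export
validate_candidates <- function(candidates, space) {
  chk <- check_candidates(candidates, space)
  if (!all(chk$ok)) {
    i <- which(!chk$ok)[1L]
    stop_rxn("candidate row %d invalid: %s", i, chk$reason[i])
  }
  out <- as_tibble(candidates)
  for (p in space$params) {
    out[[p$name]] <- switch(p$kind,
      continuous = as.numeric(out[[p$name]]),
      ordinal = as.integer(out[[p$name]]),
      categorical = as.character(out[[p$name]]))
  }
  out[names(space$params)]
}

# Column layout of the normalized representation: one block per modelled
# parameter.  Returns a data frame describing each normalized column and an
# integer lengthscale-group id (continuous/ordinal: own group; categorical:
# one shared group per block).
normalized_layout <- function(space) {
  cols <- list()
  g <- 0L
  for (p in model_params(space)) {
    g <- g + 1L
    if (p$kind == "categorical") {
      cols[[length(cols) + 1L]] <- data.frame(
        param = p$name, level = p$levels, kind = p$kind, group = g,
        column = paste0(p$name, "=", p$levels), stringsAsFactors = FALSE)
    } else {
      cols[[length(cols) + 1L]] <- data.frame(
        param = p$name, level = NA_character_, kind = p$kind, group = g,
        column = p$name, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, cols)
}

#' Map candidates to the normalized unit representation
#'
#' Continuous values are affinely rescaled to \[0, 1\]; ordinal levels map to
#' their rank rescaled to \[0, 1\]; categorical labels map to a one-hot block.
#' Fixed parameters are omitted unless they are model-carried task tags.
#' `denormalize_candidates()` inverts the map, snapping ordinal ranks to the
#' nearest admissible level and reading one-hot blocks by arg-max.
#'
#' @param candidates Data frame of candidates, validated against `space`.
#' @param space A [reaction_space()].
#' @return A numeric matrix with `space_dim(space)` columns and attributes
#'   `layout` (column descriptions) and `groups` (lengthscale group per
#'   column).
#' @export
normalize_candidates <- function(candidates, space) {
  candidates <- validate_candidates(candidates, space)
  lay <- normalized_layout(space)
  n <- nrow(candidates)
  X <- matrix(0, n, nrow(lay), dimnames = list(NULL, lay$column))
  for (p in model_params(space)) {
    v <- candidates[[p$name]]
    if (p$kind == "continuous") {
      X[, p$name] <- (v - p$lower) / (p$upper - p$lower)
    } else if (p$kind == "ordinal") {
      L <- length(p$levels)
      r <- match(v, p$levels)
      X[, p$name] <- if (L == 1L) 0.5 else (r - 1) / (L - 1)
    } else {
      idx <- match(v, p$levels)
      X[cbind(seq_len(n), match(paste0(p$name, "=", v), lay$column))] <- 1
    }
  }
  attr(X, "layout") <- lay
  attr(X, "groups") <- lay$group
  X
}

#' @rdname normalize_candidates
#' @param X Numeric matrix in the normalized representation.
#' @export
denormalize_candidates <- function(X, space) {
  lay <- normalized_layout(space)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != nrow(lay)) {
    stop_rxn("normalized matrix has %d columns; space expects %d",
             ncol(X), nrow(lay))
  }
  n <- nrow(X)
  out <- list()
  for (p in space$params) {
    if (is_fixed(p) && !isTRUE(p$in_model)) {
      out[[p$name]] <- rep(p$fixed, n)
      next
    }
    if (p$kind == "continuous") {
      j <- match(p$name, lay$column)
      out[[p$name]] <- p$lower + pmin(pmax(X[, j], 0), 1) * (p$upper - p$lower)
    } else if (p$kind == "ordinal") {
      j <- match(p$name, lay$column)
      L <- length(p$levels)
      r <- if (L == 1L) rep(1L, n) else
        pmin(pmax(round(X[, j] * (L - 1)) + 1, 1), L)
      out[[p$name]] <- p$levels[r]
    } else {
      jj <- which(lay$param == p$name)
      out[[p$name]] <- p$levels[max.col(X[, jj, drop = FALSE], ties.method = "first")]
    }
  }
  validate_candidates(as_tibble(out), space)
}

#' Derive a restricted or augmented space
#'
#' Builds a child space from a parent by freezing parameters, updating
#' continuous bounds, adding new parameters, and optionally dropping
#' parameters (for example replacing a solvent categorical by a continuous
#' mixture-ratio parameter when a binary solvent system is locked in).
#'
#' @param space Parent [reaction_space()].
#' @param fixes Named list: parameter name -> value to freeze it at.
#' @param bound_updates Named list: continuous parameter name ->
#'   `c(lower, upper)` (or a list with `lower`/`upper` elements).
#' @param added_params List of [param_spec()] objects to append.
#' @param dropped_params Character vector of parameter names to remove.
#' @param name Name for the child space.
#' @return A new [reaction_space()].
#' @export
restrict_space <- function(space, fixes = list(), bound_updates = list(),
                           added_params = list(), dropped_params = character(),
                           name = paste0(space$name, "_restricted")) {
  params <- space$params
  bad <- setdiff(c(names(fixes), names(bound_updates), dropped_params),
                 names(params))
  if (length(bad)) {
    stop_rxn("unknown parameter(s): %s", paste(bad, collapse = ", "))
  }
  for (nm in names(bound_updates)) {
    p <- params[[nm]]
    if (p$kind != "continuous") {
      stop_rxn("bound update on non-continuous parameter '%s'", nm)
    }
    b <- unlist(bound_updates[[nm]])
    lo <- if (!is.null(names(b)) && "lower" %in% names(b)) b[["lower"]] else b[1L]
    hi <- if (!is.null(names(b)) && "upper" %in% names(b)) b[["upper"]] else b[2L]
    newp <- param_spec(p$name, "continuous", lower = lo, upper = hi)
    if (is_fixed(p)) {
      if (!value_in_domain(newp, p$fixed)) {
        stop_rxn("new bounds for '%s' exclude its fixed value %g", nm, p$fixed)
      }
      newp$fixed <- p$fixed
    }
    params[[nm]] <- newp
  }
  for (nm in names(fixes)) {
    p <- params[[nm]]
    if (!value_in_domain(p, fixes[[nm]])) {
      stop_rxn("cannot fix '%s' to out-of-domain value '%s'", nm, fixes[[nm]])
    }
    p$fixed <- if (p$kind == "ordinal") as.integer(fixes[[nm]])
      else if (p$kind == "categorical") as.character(fixes[[nm]])
      else as.numeric(fixes[[nm]])
    params[[nm]] <- p
  }
  if (length(dropped_params)) params[dropped_params] <- NULL
  for (p in added_params) {
    if (!inherits(p, "param_spec")) stop_rxn("added_params must be param_spec objects")
    if (p$name %in% names(params)) {
      stop_rxn("added parameter '%s' collides with an existing one", p$name)
    }
    params[[p$name]] <- p
  }
  reaction_space(params, metadata = space$metadata, name = name)
}
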