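#' Read a physicochemical descriptor table
#'
#' Descriptor tables are delimiter-separated text files with the item label
#' in the first column and one numeric descriptor per remaining column
#' (molecular weight, density, refractive index, melting and boiling point,
#' logP, dipole moment, polar topological surface area, pKaH, ...).
#'
#' @param path File path.
#' @param sep Field delimiter (default `","`).
#' @return A tibble; first column `item`, remaining columns numeric.
#' @export
read_descriptor_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df)[1L] <- "item"
  df[-1L] <- lapply(df[-1L], as.numeric)
  as_tibble(df)
}

descriptor_matrix <- function(table) {
  table <- as_tibble(table)
  if (!"item" %in% names(table)) names(table)[1L] <- "item"
  m <- as.matrix(table[setdiff(names(table), "item")])
  if (!is.numeric(m)) stop_rxn("descriptor columns must be numeric")
  if (anyNA(m)) stop_rxn("descriptor table has missing entries")
  if (nrow(m) < 2L) stop_rxn("need at least 2 items")
  rownames(m) <- table$item
  m
}

#' Standardize descriptor columns
#'
#' Centers every descriptor to mean zero and scales it to unit sample
#' standard deviation, so that descriptors with incommensurate units
#' contribute comparably to the principal components.  Zero-variance columns
#' carry no ordering information and are dropped with a warning.
#'
#' @param table Descriptor table (see [read_descriptor_table()]).
#' @return A tibble of the same layout with standardized descriptor columns.
#' @export
standardize_descriptors <- function(table) {
  m <- descriptor_matrix(table)
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping constant descriptor column(s): %s",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) == 0L) stop_rxn("no non-constant descriptors left")
  }
  z <- scale(m)
  out <- as_tibble(as.data.frame(z))
  dplyr::bind_cols(tibble(item = rownames(m)), out)
}

#' Principal component analysis of a descriptor table
#'
#' Correlation-matrix PCA: the table is standardized (see
#' [standardize_descriptors()]) and decomposed into orthogonal components
#' ordered by decreasing explained variance.  Component signs are arbitrary
#' at this stage; [assign_integers()] fixes the orientation of the first
#' component via a user-named reference item.
#'
#' @param table Descriptor table.
#' @return An object of class `descriptor_pca` with elements `items`,
#'   `loadings` (descriptors x components), `scores` (items x components),
#'   and `explained_variance_ratio`.
#' @export
descriptor_pca <- function(table) {
  std <- standardize_descriptors(table)
  z <- descriptor_matrix(std)
  if (nrow(z) < 2L) stop_rxn("PCA needs at least 2 items")
  fit <- prcomp(z, center = FALSE, scale. = FALSE)
  evr <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(items = rownames(z), loadings = fit$rotation, scores = fit$x,
         explained_variance_ratio = evr),
    class = "descriptor_pca"
  )
}

#' @export
print.descriptor_pca <- function(x, ...) {
  cat(sprintf("<descriptor_pca> %d items, %d components\n",
              length(x$items), ncol(x$scores)))
  cat("explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}

#' @method tidy descriptor_pca
#' @export
tidy.descriptor_pca <- function(x, ...) {
  sc <- as.data.frame(x$scores)
  dplyr::bind_cols(tibble(item = x$items), as_tibble(sc))
}

#' @method glance descriptor_pca
#' @export
glance.descriptor_pca <- function(x, ...) {
  tibble(
    n_items = length(x$items),
    n_components = ncol(x$scores),
    pc1_variance_ratio = x$explained_variance_ratio[1L],
    pc2_variance_ratio = if (length(x$explained_variance_ratio) > 1L)
      x$explained_variance_ratio[2L] else NA_real_
  )
}

#' Assign consecutive integers from the first principal component
#'
#' Items are ranked by their score on the first principal component and given
#' consecutive integers 1..n.  The global sign of a principal component is
#' arbitrary, so the component is oriented such that `reference_first`
#' receives rank 1.  Exact score ties are broken lexicographically by item
#' label and reported.
#'
#' @param pca A [descriptor_pca()] fit.
#' @param reference_first Item label that anchors the orientation (rank 1).
#' @return A tibble with columns `item`, `integer`, `pc1_score` ordered by
#'   assigned integer.
#' @export
#' @examples
#' tbl <- tibble::tibble(item = c("a", "b", "c"), d1 = c(1, 2, 3), d2 = c(2, 4, 6))
#' assign_integers(descriptor_pca(tbl), reference_first = "a")
assign_integers <- function(pca, reference_first) {
  if (!reference_first %in% pca$items) {
    stop_rxn("reference item '%s' not in the table", reference_first)
  }
  s <- pca$scores[, 1L]
  ref <- match(reference_first, pca$items)
  # Orient PC1 so the reference item sits at the low end of the axis.
  if (rank(s, ties.method = "min")[ref] > rank(-s, ties.method = "min")[ref]) {
    s <- -s
  }
  if (anyDuplicated(s) > 0L) {
    inform("exact PC1 score ties resolved lexicographically by item label")
  }
  ord <- order(s, pca$items)
  tibble(item = pca$items[ord],
         integer = seq_along(ord),
         pc1_score = unname(s[ord]))
}

#' Encode reagents as ordinal integers in one step
#'
#' Convenience wrapper: standardize, run the descriptor PCA, and assign
#' integers anchored at `reference_first`.
#'
#' @inheritParams descriptor_pca
#' @inheritParams assign_integers
#' @return A tibble as returned by [assign_integers()].
#' @export
encode_items <- function(table, reference_first) {
  assign_integers(descriptor_pca(table), reference_first)
}
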