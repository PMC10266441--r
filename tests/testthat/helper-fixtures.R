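# Shared fixtures, all generated in code.

cl1_space <- function() {
  build_space(system.file("extdata", "space_cl1.yaml", package = "rxnbo"))
}

transfer_space <- function() {
  build_space(system.file("extdata", "space_transfer.yaml", package = "rxnbo"))
}

# A small mixed space that keeps loop tests fast.
toy_space <- function() {
  reaction_space(list(
    param_spec("eq", "continuous", lower = 0, upper = 5),
    param_spec("conc", "continuous", lower = 0.01, upper = 0.2),
    param_spec("base", "ordinal", levels = 1:4),
    param_spec("solvent", "categorical", levels = c("A", "B", "C"))
  ), name = "toy")
}

# Synthetic descriptor table with a planted dominant factor: every
# descriptor is a positive multiple of one latent order plus small noise.
planted_descriptor_table <- function(n_items = 9, n_desc = 6, noise = 0.01,
                                     seed = 42) {
  set.seed(seed)
  latent <- seq_len(n_items)
  m <- sapply(seq_len(n_desc), function(j) {
    runif(1, 0.5, 2) * latent + rnorm(n_items, 0, noise)
  })
  colnames(m) <- paste0("d", seq_len(n_desc))
  dplyr::bind_cols(tibble::tibble(item = sprintf("item%02d", latent)),
                   tibble::as_tibble(as.data.frame(m)))
}

# Deterministic smooth 1-D test function on [0, 1].
bumpy_1d <- function(x) 0.4 + 0.3 * sin(2 * pi * x) + 0.15 * x

# Quick oracle for a toy space: smooth unimodal yield surface.
toy_oracle <- function(sigma = 0) {
  function(candidates, seed = NULL) {
    f <- unname(80 * exp(-((candidates$eq - 3)^2) / 2) *
      exp(-(log(candidates$conc / 0.1))^2 / 0.5) *
      c(1, 0.8, 0.5, 0.2)[candidates$base] *
      c(A = 1, B = 0.7, C = 0.4)[candidates$solvent])
    s <- if (sigma > 0 && !is.null(seed)) {
      rxnbo:::with_seed(seed, rnorm(length(f), 0, sigma))
    } else 0
    tibble::tibble(area_reactant = 1 - f / 100, area_mono = f / 100,
                   area_di = 0, score = pmin(pmax(f + s, 0), 100))
  }
}
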