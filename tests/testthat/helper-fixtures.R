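# Shared fixtures, generated in code.

# Compact 5-group test map: 60 cM per group, markers every 5 cM.
test_map <- function(n_groups = 5, length_cM = 60, spacing = 5) {
  dplyr::bind_rows(lapply(seq_len(n_groups), function(g) {
    pos <- seq(0, length_cM, by = spacing)
    tibble::tibble(
      group = paste0("LG", g),
      marker = paste0("LG", g, "_m", seq_along(pos)),
      position = pos
    )
  }))
}

# One-QTL F2 design at the effect magnitude of the reference cross's
# largest seed-colour QTL (a ~ 20, d ~ -19), residual variance chosen so
# the QTL explains about 40% of the F2 phenotypic variance.
test_qtl_design <- function(n_f2 = 260, r2 = 0.4, a = 20, d = -19,
                            group = "LG2", position = 27) {
  qvar <- a^2 / 2 + d^2 / 4
  cross_design(
    test_map(),
    qtl = tibble::tibble(group = group, position = position, a = a, d = d),
    mean = 60,
    resid_var = qvar * (1 - r2) / r2,
    n_f2 = n_f2,
    f3_progeny = 5
  )
}

# Moderate six-generation sample for fit-based unit tests.
test_generations <- function(seed = 101, n = 150) {
  simulate_generations(
    "E_0", seedcolor_params(),
    sizes = c(P1 = 30, P2 = 30, F1 = 30, BC1 = n, BC2 = n, F2 = n),
    seed = seed
  )
}

# Closed-form mixture mean of a generation under given parameters.
mixture_mean <- function(model, generation, params) {
  spec <- generation_spec(model, generation)
  coeff <- as.matrix(spec[, segqtl:::seg_effect_names()])
  sum(spec$frequency * as.vector(coeff %*% params[segqtl:::seg_effect_names()]))
}
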