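# Six-generation phenotype simulator: draws plant-level values from the
# constrained normal mixture a chosen inheritance model implies.

#' Simulate six-generation phenotype data
#'
#' Each plant's mixture component (major-gene genotype class) is drawn at
#' the generation's Mendelian frequency, then the phenotype is drawn from
#' `Normal(component mean, sigma2_e + c_g * sigma2_pg)`, where `c_g` is the
#' generation's polygenic-variance multiplier (0 for P1/P2/F1, 1/2 for
#' BC1/BC2, 1 for F2).
#'
#' @param model Model code (see [genetic_models()]) or `seg_model` object.
#' @param params A [genetic_params()] vector respecting the model's
#'   constraints.
#' @param sizes Named vector of per-generation plant counts; defaults to the
#'   field design of the reference cross.
#' @param reps Number of replications to simulate (each an independent draw
#'   with the same parameters).
#' @param seed Optional integer seed; fixed seeds give identical output.
#' @param clip_rgb If `TRUE`, clip values to the RGB range \[0, 255\].  Off
#'   by default so that moment checks against the mixture algebra are exact.
#' @return A tibble with columns `generation` (factor), `replication`,
#'   `plant_id`, `genotype` (true component label) and `value`.
#' @examples
#' sim <- simulate_generations("E_0", seedcolor_params(), seed = 1)
#' dplyr::count(sim, generation)
#' @export
simulate_generations <- function(model = "E_0", params = seedcolor_params(),
                                 sizes = seedcolor_sizes(), reps = 1,
                                 seed = NULL, clip_rgb = FALSE) {
  mod <- get_model(model)
  params <- as_genetic_params(params)
  validate_params(mod, params)
  if (is.null(names(sizes)) || !all(names(sizes) %in% seg_generations())) {
    rlang::abort("`sizes` must be named with generation labels")
  }
  if (any(sizes < 1)) {
    rlang::abort("all generation sizes must be >= 1")
  }
  theta <- params[seg_effect_names()]
  blocks <- component_blocks(mod, names(sizes))
  with_seed(seed, {
    out <- lapply(seq_len(reps), function(r) {
      gen_tbls <- lapply(blocks, function(b) {
        v <- params[["sigma2_e"]] + b$c_pg * params[["sigma2_pg"]]
        if (v < 0) rlang::abort("negative within-component variance")
        mu <- as.vector(b$coeff %*% theta)
        n <- as.integer(sizes[[b$generation]])
        j <- sample.int(length(b$frequency), n, replace = TRUE,
                        prob = b$frequency)
        tibble::tibble(
          generation = b$generation,
          replication = r,
          plant_id = seq_len(n),
          genotype = b$genotype[j],
          value = stats::rnorm(n, mean = mu[j], sd = sqrt(v))
        )
      })
      dplyr::bind_rows(gen_tbls)
    })
    out <- dplyr::bind_rows(out)
    if (clip_rgb) {
      out$value <- pmin(pmax(out$value, 0), 255)
    }
    out$generation <- factor(out$generation, levels = seg_generations())
    out
  })
}

#' Bin phenotype values into fixed-width classes
#'
#' Summarises plant-level values into the binned layout used for reporting
#' seed-colour distributions (10-unit RGB classes).
#'
#' @param data Tibble with columns `generation`, `replication`, `value`.
#' @param width Bin width.
#' @param from,to Lower edge of the first bin and upper limit.
#' @return Tibble with `replication`, `generation`, `bin_low`, `count`
#'   (empty bins omitted).
#' @export
bin_phenotypes <- function(data, width = 10, from = 20, to = 160) {
  data <- validate_phenotypes(data, require_replication = FALSE)
  if (!"replication" %in% names(data)) data$replication <- 1L
  breaks <- seq(from, to, by = width)
  data |>
    dplyr::mutate(bin_low = breaks[pmin(
      pmax(findInterval(.data$value, breaks), 1L), length(breaks) - 1L
    )]) |>
    dplyr::count(.data$replication, .data$generation, .data$bin_low,
                 name = "count")
}
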