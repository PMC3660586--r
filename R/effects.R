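# First-order genetic effects (least squares on component means) and
# second-order variance components / heritability decomposition.

#' First-order genetic effects from a fitted model
#'
#' Solves ordinary least squares of the fitted component means against the
#' mean-coefficient design matrix over all distinct components of all
#' generations, and reports the effect estimates together with the
#' dominance ratios `h_a/d_a` and `h_b/d_b` where defined.
#'
#' @param fit A `seg_fit` for the chosen (optimal) model.
#' @param ratio_floor Dominance ratios are reported only when the additive
#'   effect's magnitude exceeds this floor.
#' @return Tibble `term`, `estimate` containing the model's free effect
#'   parameters and the defined dominance ratios.
#' @export
first_order_effects <- function(fit, ratio_floor = 1e-6) {
  stopifnot(inherits(fit, "seg_fit"))
  mod <- get_model(fit$model)
  comps <- fit$components
  blocks <- component_blocks(mod, unique(comps$generation))
  design <- do.call(rbind, lapply(blocks, `[[`, "design"))
  labels <- unlist(lapply(blocks, `[[`, "genotype"), use.names = FALSE)
  keep <- !duplicated(labels)
  X <- design[keep, , drop = FALSE]
  y <- comps$mean[keep]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    rlang::abort(paste0(
      "design matrix is rank deficient; unidentifiable effect columns: ",
      paste(bad, collapse = ", ")
    ))
  }
  phi <- qr.coef(qrX, y)
  theta <- stats::setNames(as.vector(mod$map %*% phi), seg_effect_names())
  out <- tibble::tibble(term = names(phi), estimate = unname(phi))
  ratios <- tibble::tibble(term = character(), estimate = numeric())
  for (gene in c("a", "b")) {
    dname <- paste0("d_", gene)
    hname <- paste0("h_", gene)
    if (abs(theta[[dname]]) > ratio_floor &&
        (hname %in% mod$free || any(mod$map[hname, ] != 0))) {
      ratios <- dplyr::bind_rows(ratios, tibble::tibble(
        term = paste0(hname, "/", dname),
        estimate = theta[[hname]] / theta[[dname]]
      ))
    }
  }
  dplyr::bind_rows(out, ratios)
}

#' Average estimates across replications
#'
#' @param data Tibble with columns `parameter`, `replication`, `value` (one
#'   row per parameter x replication).
#' @return Tibble `parameter`, `average` (arithmetic mean across
#'   replications, full precision; round to 2 decimals for display).
#' @examples
#' average_replicates(tibble::tibble(
#'   parameter = "d_b", replication = 1:3, value = c(25.04, 24.80, 25.42)
#' ))
#' @export
average_replicates <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("parameter", "value") %in% names(data))) {
    rlang::abort("`data` needs columns parameter, replication, value")
  }
  data |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(average = mean(.data$value), .groups = "drop")
}

#' Variance components and heritabilities from phenotypic components
#'
#' Pure decomposition arithmetic: the major-gene variance is what remains
#' of the phenotypic variance after the polygenic and environmental parts,
#' truncated at zero (with the truncated mass reported, never silently
#' dropped), and heritabilities are percentage ratios.
#'
#' @param sigma2_p Phenotypic variance(s) of the segregating generation.
#' @param sigma2_pg Polygenic variance component(s).
#' @param sigma2_e Environmental variance component(s).
#' @return Tibble `sigma2_p`, `sigma2_mg`, `sigma2_pg`, `sigma2_e`,
#'   `h2_mg`, `h2_pg` (percent), `truncated` (mass clipped from a negative
#'   major-gene estimate).
#' @examples
#' variance_components(1170.90, 71.78, 58.85) # h2_mg = 88.84
#' @export
variance_components <- function(sigma2_p, sigma2_pg, sigma2_e) {
  if (any(sigma2_p <= 0)) {
    rlang::abort("phenotypic variance must be positive for heritabilities")
  }
  raw_mg <- sigma2_p - sigma2_pg - sigma2_e
  truncated <- pmax(0, -raw_mg)
  if (any(truncated > 0)) {
    rlang::warn("negative major-gene variance estimate truncated to 0")
  }
  sigma2_mg <- pmax(0, raw_mg)
  tibble::tibble(
    sigma2_p = sigma2_p,
    sigma2_mg = sigma2_mg,
    sigma2_pg = sigma2_pg,
    sigma2_e = sigma2_e,
    h2_mg = 100 * sigma2_mg / sigma2_p,
    h2_pg = 100 * sigma2_pg / sigma2_p,
    truncated = truncated
  )
}

#' Second-order genetic parameters for the segregating generations
#'
#' For each segregating generation present (BC1, BC2, F2): the phenotypic
#' variance is the sample variance of that generation; the environmental
#' variance is the degrees-of-freedom-weighted pooled variance of P1, P2
#' and F1; the polygenic component is `c_g` times the fitted polygenic
#' variance; and the major-gene component is the (truncated-at-zero)
#' remainder.  Heritabilities are percentage ratios of the phenotypic
#' variance.
#'
#' @param data Tibble `generation`, `value` (one replication).
#' @param fit The optimal-model `seg_fit` for the same data.
#' @return Tibble with one row per segregating generation (columns as in
#'   [variance_components()], plus `generation`).
#' @export
second_order_components <- function(data, fit) {
  stopifnot(inherits(fit, "seg_fit"))
  data <- validate_phenotypes(data, require_replication = FALSE)
  gens <- as.character(data$generation)
  nonseg <- intersect(c("P1", "P2", "F1"), unique(gens))
  if (length(nonseg) == 0) {
    rlang::abort("need at least one of P1, P2, F1 to pool environmental variance")
  }
  vs <- vapply(nonseg, function(g) stats::var(data$value[gens == g]), 0)
  ns <- vapply(nonseg, function(g) sum(gens == g), 0L)
  s2e <- sum((ns - 1) * vs) / sum(ns - 1)
  seg <- intersect(c("BC1", "BC2", "F2"), unique(gens))
  out <- lapply(seg, function(g) {
    x <- data$value[gens == g]
    s2p <- stats::var(x)
    if (!is.finite(s2p) || s2p == 0) {
      rlang::abort(paste0("zero phenotypic variance in ", g,
                          "; heritabilities undefined"))
    }
    s2pg <- unname(polygene_variance_coeff(g)) * fit$params[["sigma2_pg"]]
    vc <- variance_components(s2p, s2pg, s2e)
    dplyr::bind_cols(tibble::tibble(generation = g), vc)
  })
  dplyr::bind_rows(out)
}
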