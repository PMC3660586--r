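# Published reference tables for the white x black sesame seed-coat colour
# cross, usable as inputs (the raw plant-level data were never released).

#' Reference first-order genetic parameter estimates
#'
#' Per-replication least-squares estimates of the first-order genetic
#' parameters of the seed-coat colour trait (E_0 model; RGB units), as
#' published for the white x black sesame cross.
#'
#' @return Tibble `parameter`, `replication`, `value`.
#' @export
seedcolor_first_order <- function() {
  pars <- c("d_a", "d_b", "h_a", "h_b", "i", "j_ab", "j_ba", "l")
  vals <- rbind(
    d_a  = c(20.13, 20.16, 20.60),
    d_b  = c(25.04, 24.80, 25.42),
    h_a  = c(-34.66, -38.00, -35.17),
    h_b  = c(-8.62, -9.77, -9.65),
    i    = c(3.61, 3.51, 1.79),
    j_ab = c(7.58, 6.93, 8.78),
    j_ba = c(-18.45, -20.98, -16.74),
    l    = c(15.96, 22.80, 14.86)
  )
  tibble::tibble(
    parameter = rep(pars, each = 3),
    replication = rep(1:3, times = length(pars)),
    value = as.vector(t(vals))
  )
}

#' Reference second-order genetic parameter estimates
#'
#' Per-replication variance components and heritabilities of the seed-coat
#' colour trait for the segregating generations of the reference cross:
#' phenotypic (`sigma2_p`), major-gene (`sigma2_mg`), polygene
#' (`sigma2_pg`) and environmental (`sigma2_e`) variances, and the
#' major-gene / polygene heritabilities in percent.
#'
#' @return Tibble `generation`, `replication`, `sigma2_p`, `sigma2_mg`,
#'   `sigma2_pg`, `sigma2_e`, `h2_mg`, `h2_pg`.
#' @export
seedcolor_second_order <- function() {
  rows <- rbind(
    c(1, 1170.90, 1040.27, 71.78, 58.85, 88.84, 6.13),
    c(2, 1236.68, 1108.23, 70.83, 57.62, 89.61, 5.73),
    c(3, 1060.72,  948.62, 47.09, 65.01, 89.43, 4.44),
    c(1,   75.74,   16.89,  0.00, 58.85, 22.30, 0.00),
    c(2,   80.59,   22.97,  0.00, 57.62, 28.50, 0.00),
    c(3,   82.49,   17.48,  0.00, 65.01, 21.19, 0.00),
    c(1,  744.35,  668.52, 16.98, 58.85, 89.81, 2.28),
    c(2,  721.61,  663.99,  0.00, 57.62, 92.02, 0.00),
    c(3,  799.51,  731.47,  3.02, 65.01, 91.49, 0.38)
  )
  tibble::tibble(
    generation = rep(c("BC1", "BC2", "F2"), each = 3),
    replication = as.integer(rows[, 1]),
    sigma2_p = rows[, 2],
    sigma2_mg = rows[, 3],
    sigma2_pg = rows[, 4],
    sigma2_e = rows[, 5],
    h2_mg = rows[, 6],
    h2_pg = rows[, 7]
  )
}

#' Reference binned seed-colour distributions
#'
#' Binned RGB-value distributions (10-unit classes) of the six generations
#' of the reference cross, three field replications, as published.  The
#' row sums per generation x replication are the plant numbers.
#'
#' @return Tibble `replication`, `generation`, `bin_low`, `count`.
#' @export
seedcolor_bins <- function() {
  path <- system.file("extdata", "seedcolor_bins.csv", package = "segqtl")
  out <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  out$generation <- factor(out$generation, levels = seg_generations())
  out
}

#' Reference linkage-map facts
#'
#' Published summary numbers of the high-density sesame linkage map used
#' with the reference cross: 653 loci in 14 groups spanning 1216.00 cM, an
#' externally estimated genome length of 1380.938 cM, and 79 of 724 tested
#' markers showing segregation distortion at P < 0.05.
#'
#' @return Named list of the reference values.
#' @export
seedcolor_map_facts <- function() {
  list(
    n_groups = 14L,
    n_loci = 653L,
    total_length = 1216.00,
    expected_genome_length = 1380.938,
    distorted_count = 79L,
    markers_tested = 724L,
    largest_group = list(loci = 345L, length = 166.57),
    smallest_group = list(loci = 6L, length = 47.54)
  )
}

#' Synthetic linkage map with the reference map's summary geometry
#'
#' Builds a 14-group, 653-locus map whose total length (1216.00 cM),
#' largest group (345 loci, 166.57 cM) and smallest group (6 loci,
#' 47.54 cM) match the published summary numbers; the remaining loci and
#' length are spread evenly, with equidistant markers within groups.  This
#' is a synthetic stand-in (per-group marker spacings were never
#' published); it reproduces the summary arithmetic, not the real marker
#' order.
#'
#' @return Map tibble `group`, `marker`, `position`.
#' @export
synthetic_sesame_map <- function() {
  facts <- seedcolor_map_facts()
  n_mid <- facts$n_loci - facts$largest_group$loci - facts$smallest_group$loci
  loci <- c(facts$largest_group$loci,
            rep(n_mid %/% 12 + 1L, n_mid %% 12),
            rep(n_mid %/% 12, 12L - n_mid %% 12),
            facts$smallest_group$loci)
  len_mid <- (facts$total_length - facts$largest_group$length -
                facts$smallest_group$length) / 12
  lens <- c(facts$largest_group$length, rep(len_mid, 12), facts$smallest_group$length)
  dplyr::bind_rows(lapply(1:14, function(g) {
    tibble::tibble(
      group = paste0("LG", g),
      marker = paste0("LG", g, "_m", seq_len(loci[g])),
      position = seq(0, lens[g], length.out = loci[g])
    )
  }))
}
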