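# F2 / F3 marker-QTL cross simulator: gametes formed by sequential
# recombination along each linkage group, QTL effects added to phenotypes,
# F3 families produced by selfing.

#' Map functions: genetic distance to recombination fraction
#'
#' Haldane assumes no crossover interference; Kosambi partial interference.
#'
#' @param d_cM Genetic distance in centiMorgans (vectorised).
#' @param map_function `"haldane"` or `"kosambi"`.
#' @return Recombination fraction(s) in \[0, 0.5\].
#' @examples
#' rec_frac(50) # (1 - exp(-1))/2 = 0.3161
#' @export
rec_frac <- function(d_cM, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(d_cM < 0)) rlang::abort("distances must be >= 0")
  switch(map_function,
    haldane = 0.5 * (1 - exp(-2 * d_cM / 100)),
    kosambi = 0.5 * tanh(2 * d_cM / 100)
  )
}

#' Specify an F2/F3 cross design
#'
#' @param map Linkage map tibble with columns `group`, `marker`,
#'   `position` (cM, non-decreasing within group, group-local).
#' @param qtl Tibble of QTL with columns `group`, `position`, `a` (additive
#'   effect), `d` (dominance effect); may be `NULL` for a null cross.
#' @param mean Phenotype baseline.
#' @param resid_var Residual (environmental) phenotype variance, > 0.
#' @param map_function Map function used both to simulate recombination and
#'   later to analyse the cross.
#' @param n_f2 Number of F2 individuals.
#' @param f3_progeny Number of selfed progeny scored per F3 family; the
#'   family phenotype is their mean.
#' @return A `cross_design` list.
#' @export
cross_design <- function(map, qtl = NULL, mean = 0, resid_var = 1,
                         map_function = c("haldane", "kosambi"),
                         n_f2 = 260, f3_progeny = 5) {
  map_function <- match.arg(map_function)
  map <- validate_map(map)
  if (resid_var <= 0) rlang::abort("`resid_var` must be > 0")
  if (n_f2 < 1 || f3_progeny < 1) {
    rlang::abort("`n_f2` and `f3_progeny` must be >= 1")
  }
  if (!is.null(qtl)) {
    qtl <- tibble::as_tibble(qtl)
    req <- c("group", "position", "a", "d")
    if (!all(req %in% names(qtl))) {
      rlang::abort("`qtl` needs columns group, position, a, d")
    }
    for (k in seq_len(nrow(qtl))) {
      gmap <- map[map$group == qtl$group[k], ]
      if (nrow(gmap) == 0) {
        rlang::abort(paste0("QTL group '", qtl$group[k], "' not on the map"))
      }
      if (qtl$position[k] < min(gmap$position) ||
          qtl$position[k] > max(gmap$position)) {
        rlang::abort(paste0(
          "QTL at ", qtl$position[k], " cM lies outside group '",
          qtl$group[k], "' (", min(gmap$position), "-", max(gmap$position),
          " cM)"
        ))
      }
    }
  }
  structure(list(map = map, qtl = qtl, mean = mean, resid_var = resid_var,
                 map_function = map_function, n_f2 = as.integer(n_f2),
                 f3_progeny = as.integer(f3_progeny)),
            class = "cross_design")
}

# Simulate n gametes along a set of loci with inter-locus recombination
# fractions r (length = n_loci - 1).  Returns an n x n_loci 0/1 matrix of
# parental-origin indicators (1 = P1 homolog).
.sim_gametes <- function(n, r) {
  n_loci <- length(r) + 1L
  H <- matrix(0L, n, n_loci)
  H[, 1L] <- stats::rbinom(n, 1L, 0.5)
  if (n_loci > 1L) {
    for (l in 2L:n_loci) {
      sw <- stats::rbinom(n, 1L, r[l - 1L])
      H[, l] <- ifelse(sw == 1L, 1L - H[, l - 1L], H[, l - 1L])
    }
  }
  H
}

# Gametes produced by a (possibly recombinant) parent: homolog indicators
# from .sim_gametes index into the parent's two haplotype rows.
.self_gametes <- function(h1, h2, n, r) {
  pick <- .sim_gametes(n, r)  # which parental homolog at each locus
  out <- matrix(0L, n, length(h1))
  for (l in seq_len(length(h1))) {
    out[, l] <- ifelse(pick[, l] == 1L, h1[l], h2[l])
  }
  out
}

#' Simulate an F2 population with F3 families
#'
#' F1 gametes are formed by sequential recombination along each linkage
#' group under the design's map function (no interference under Haldane);
#' two independent gametes make an F2 plant.  Each QTL contributes
#' `+a`, `d`, `-a` to the phenotype for genotypes QQ, Qq, qq.  F3 families
#' are produced by selfing each F2 plant; the family phenotype is the mean
#' of `f3_progeny` progeny values.
#'
#' @param design A [cross_design()].
#' @param seed Optional integer seed.
#' @return A `cross_sim` list: `genotypes` (tibble, `id` + one 0/1/2 column
#'   per marker), `phenotypes` (tibble `id`, `f2_value`, `f3_value`),
#'   `qtl_genotypes` (true QTL genotype codes), `haplotypes` (per-group
#'   phased marker+QTL indicator matrices, for diagnostics), `map`,
#'   `design`.
#' @examples
#' map <- tibble::tibble(group = "1", marker = c("m1", "m2", "m3"),
#'                       position = c(0, 25, 50))
#' des <- cross_design(map, qtl = tibble::tibble(group = "1", position = 25,
#'                                               a = 20, d = -19),
#'                     resid_var = 400, n_f2 = 100)
#' sim <- simulate_cross(des, seed = 1)
#' @export
simulate_cross <- function(design, seed = NULL) {
  stopifnot(inherits(design, "cross_design"))
  map <- design$map
  qtl <- design$qtl
  n <- design$n_f2
  with_seed(seed, {
    groups <- unique(map$group)
    geno_cols <- list()
    hap_store <- list()
    qtl_geno <- NULL
    qtl_info <- list()
    for (g in groups) {
      gmap <- map[map$group == g, ]
      gq <- if (is.null(qtl)) {
        tibble::tibble(group = character(), position = numeric(),
                       a = numeric(), d = numeric())
      } else {
        qtl[qtl$group == g, , drop = FALSE]
      }
      loci <- tibble::tibble(
        name = c(gmap$marker, if (nrow(gq)) paste0("QTL_", g, "_", gq$position)),
        position = c(gmap$position, gq$position),
        is_qtl = c(rep(FALSE, nrow(gmap)), rep(TRUE, nrow(gq)))
      )
      loci <- loci[order(loci$position, loci$is_qtl), ]
      r <- rec_frac(diff(loci$position), design$map_function)
      h1 <- .sim_gametes(n, r)
      h2 <- .sim_gametes(n, r)
      geno <- h1 + h2
      colnames(geno) <- loci$name
      geno_cols[[g]] <- geno[, !loci$is_qtl, drop = FALSE]
      hap_store[[g]] <- list(h1 = h1, h2 = h2, loci = loci)
      if (any(loci$is_qtl)) {
        qg <- geno[, loci$is_qtl, drop = FALSE]
        qtl_geno <- cbind(qtl_geno, qg)
        qtl_info[[g]] <- list(
          idx = which(loci$is_qtl),
          a = gq$a[order(gq$position)],
          d = gq$d[order(gq$position)],
          r = r
        )
      }
    }
    qtl_effect <- function(codes, a, d) {
      # codes: matrix n x q of 0/1/2 QTL genotypes
      eff <- numeric(nrow(codes))
      for (k in seq_len(ncol(codes))) {
        eff <- eff + c(-a[k], d[k], a[k])[codes[, k] + 1L]
      }
      eff
    }
    gvalue <- numeric(n)
    for (g in names(qtl_info)) {
      qi <- qtl_info[[g]]
      codes <- (hap_store[[g]]$h1 + hap_store[[g]]$h2)[, qi$idx, drop = FALSE]
      gvalue <- gvalue + qtl_effect(codes, qi$a, qi$d)
    }
    f2_value <- design$mean + gvalue + stats::rnorm(n, 0, sqrt(design$resid_var))
    # F3 families: k selfed progeny per F2 plant, scored at the QTL loci only
    k <- design$f3_progeny
    fam_sum <- numeric(n)
    prog_g <- matrix(0, n, k)  # genetic values of progeny
    for (g in names(qtl_info)) {
      qi <- qtl_info[[g]]
      hs <- hap_store[[g]]
      qpos <- hs$loci$position[qi$idx]
      rq <- rec_frac(diff(qpos), design$map_function)
      for (i in seq_len(n)) {
        g1 <- .self_gametes(hs$h1[i, qi$idx], hs$h2[i, qi$idx], k, rq)
        g2 <- .self_gametes(hs$h1[i, qi$idx], hs$h2[i, qi$idx], k, rq)
        prog_g[i, ] <- prog_g[i, ] + qtl_effect(g1 + g2, qi$a, qi$d)
      }
    }
    prog_value <- design$mean + prog_g +
      matrix(stats::rnorm(n * k, 0, sqrt(design$resid_var)), n, k)
    f3_value <- rowMeans(prog_value)
    geno_mat <- do.call(cbind, unname(geno_cols))
    genotypes <- dplyr::bind_cols(
      tibble::tibble(id = seq_len(n)),
      tibble::as_tibble(geno_mat)
    )
    structure(list(
      genotypes = genotypes,
      phenotypes = tibble::tibble(id = seq_len(n), f2_value = f2_value,
                                  f3_value = f3_value),
      qtl_genotypes = qtl_geno,
      haplotypes = hap_store,
      map = map,
      design = design
    ), class = "cross_sim")
  })
}

#' F3 family phenotype from progeny values
#'
#' @param x Numeric vector of progeny phenotype values for one family.
#' @return Their arithmetic mean.
#' @export
f3_phenotype <- function(x) {
  if (length(x) == 0) rlang::abort("empty F3 family")
  if (!is.numeric(x) || any(!is.finite(x))) {
    rlang::abort("progeny values must be finite numbers")
  }
  mean(x)
}
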