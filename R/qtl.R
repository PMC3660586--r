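# Composite interval mapping for F2/F3 designs: conditional QTL genotype
# probabilities from flanking markers, stepwise cofactor selection,
# Haley-Knott-style regression scan, permutation thresholds and
# single-marker ANOVA.

# Conditional distribution of the F2 genotype at a test position given the
# genotypes at two flanking markers, assuming no crossover interference:
# both gametes are independent Markov chains along the chromosome, so the
# three-locus genotype distribution is the convolution of the gamete
# haplotype distribution with itself.  Returns a 3 x 3 x 3 array
# cond[gl, gr, gq] over genotype codes 0/1/2 (count of P1 alleles).
.cond_table2 <- function(r1, r2) {
  h <- array(0, c(2, 2, 2))
  for (aL in 0:1) for (aQ in 0:1) for (aR in 0:1) {
    t1 <- if (aL == aQ) 1 - r1 else r1
    t2 <- if (aQ == aR) 1 - r2 else r2
    h[aL + 1, aQ + 1, aR + 1] <- 0.5 * t1 * t2
  }
  joint <- array(0, c(3, 3, 3)) # [gl, gq, gr]
  for (i in 1:8) for (j in 1:8) {
    a1 <- arrayInd(i, c(2, 2, 2)) - 1L
    a2 <- arrayInd(j, c(2, 2, 2)) - 1L
    gl <- a1[1] + a2[1]; gq <- a1[2] + a2[2]; gr <- a1[3] + a2[3]
    joint[gl + 1, gq + 1, gr + 1] <- joint[gl + 1, gq + 1, gr + 1] +
      h[i] * h[j]
  }
  cond <- array(0, c(3, 3, 3)) # [gl, gr, gq]
  prior <- c(0.25, 0.5, 0.25)
  for (gl in 1:3) for (gr in 1:3) {
    tot <- sum(joint[gl, , gr])
    cond[gl, gr, ] <- if (tot > 0) joint[gl, , gr] / tot else prior
  }
  cond
}

# Single-flank version: cond[gl, gq] given only one marker at recombination
# fraction r from the test position.
.cond_table1 <- function(r) {
  h <- matrix(0, 2, 2)
  for (aL in 0:1) for (aQ in 0:1) {
    h[aL + 1, aQ + 1] <- 0.5 * (if (aL == aQ) 1 - r else r)
  }
  joint <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    a1 <- arrayInd(i, c(2, 2)) - 1L
    a2 <- arrayInd(j, c(2, 2)) - 1L
    joint[a1[1] + a2[1] + 1, a1[2] + a2[2] + 1] <-
      joint[a1[1] + a2[1] + 1, a1[2] + a2[2] + 1] + h[i] * h[j]
  }
  sweep(joint, 1, rowSums(joint), "/")
}

#' Conditional QTL genotype probabilities at a test position
#'
#' Probability of each QTL genotype (QQ, Qq, qq) for F2 individuals given
#' the genotypes of the nearest informative flanking markers, assuming no
#' crossover interference.  A missing flank falls back to the single
#' informative marker; if both flanks are missing the Mendelian 1:2:1 prior
#' is returned.
#'
#' @param left,right Integer genotype codes at the flanking markers
#'   (2 = AA, 1 = Aa, 0 = aa, NA = missing), vectorised over individuals.
#' @param d_left,d_right Distances (cM) from the test position to the left
#'   and right markers.
#' @param map_function Map function converting distance to recombination
#'   fraction.
#' @return An n x 3 matrix with columns `QQ`, `Qq`, `qq`.
#' @examples
#' qtl_genotype_probs(1, 1, 0, 10) # on a marker typed Aa: (0, 1, 0)
#' @export
qtl_genotype_probs <- function(left, right, d_left, d_right,
                               map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  n <- max(length(left), length(right))
  left <- rep_len(left, n)
  right <- rep_len(right, n)
  r1 <- rec_frac(d_left, map_function)
  r2 <- rec_frac(d_right, map_function)
  out <- matrix(NA_real_, n, 3)
  both <- !is.na(left) & !is.na(right)
  lonly <- !is.na(left) & is.na(right)
  ronly <- is.na(left) & !is.na(right)
  none <- is.na(left) & is.na(right)
  if (any(both)) {
    tab <- .cond_table2(r1, r2)
    out[both, ] <- t(vapply(which(both), function(k) {
      tab[left[k] + 1, right[k] + 1, ]
    }, numeric(3)))
  }
  if (any(lonly)) {
    tab <- .cond_table1(r1)
    out[lonly, ] <- tab[left[lonly] + 1, , drop = FALSE]
  }
  if (any(ronly)) {
    tab <- .cond_table1(r2)
    out[ronly, ] <- tab[right[ronly] + 1, , drop = FALSE]
  }
  if (any(none)) {
    out[none, ] <- matrix(c(0.25, 0.5, 0.25), sum(none), 3, byrow = TRUE)
  }
  # columns ordered by code 0,1,2 -> report as QQ, Qq, qq
  colnames(out) <- c("qq", "Qq", "QQ")
  out[, c("QQ", "Qq", "qq"), drop = FALSE]
}

# Align phenotype and genotype tables, returning y (numeric), genotype
# matrix (individual x marker, codes 0/1/2/NA) and the validated map.
.align_scan_inputs <- function(phenotypes, genotypes, map) {
  map <- validate_map(map)
  if (is.numeric(phenotypes)) {
    pheno <- tibble::tibble(id = seq_along(phenotypes), value = phenotypes)
  } else {
    pheno <- tibble::as_tibble(phenotypes)
    vcol <- intersect(c("value", "f2_value", "f3_value"), names(pheno))
    if (length(vcol) == 0) rlang::abort("no phenotype value column found")
    pheno <- tibble::tibble(id = pheno$id %||% seq_len(nrow(pheno)),
                            value = pheno[[vcol[1L]]])
  }
  if (is.matrix(genotypes)) {
    G <- genotypes
    ids <- seq_len(nrow(G))
  } else {
    gt <- tibble::as_tibble(genotypes)
    ids <- gt$id %||% seq_len(nrow(gt))
    G <- as.matrix(gt[, setdiff(names(gt), "id"), drop = FALSE])
  }
  if (nrow(G) == 0 || ncol(G) == 0) rlang::abort("empty genotype table")
  missing_markers <- setdiff(colnames(G), map$marker)
  if (length(missing_markers) > 0) {
    rlang::abort(paste0("markers absent from the map: ",
                        paste(missing_markers, collapse = ", ")))
  }
  idx <- match(pheno$id, ids)
  if (any(is.na(idx))) {
    rlang::abort("phenotype individuals missing from the genotype table")
  }
  G <- G[idx, , drop = FALSE]
  bad <- !(G %in% c(0, 1, 2) | is.na(G))
  if (any(bad)) rlang::abort("genotype codes must be 0, 1, 2 or NA")
  map <- map[map$marker %in% colnames(G), , drop = FALSE]
  list(y = pheno$value, G = G, map = map)
}

# Precompute everything that does not depend on the phenotype: per-position
# additive/dominance expected scores and the per-position cofactor
# exclusion windows.  Reused across permutations.
.cim_prep <- function(G, map, step, window, map_function) {
  n <- nrow(G)
  groups <- unique(map$group)
  pos_list <- list(); grp_list <- list()
  Xa <- NULL; Zd <- NULL
  excl <- list()
  marker_group <- map$group[match(colnames(G), map$marker)]
  marker_pos <- map$position[match(colnames(G), map$marker)]
  for (g in groups) {
    gmap <- map[map$group == g, ]
    Gg <- G[, gmap$marker, drop = FALSE]
    M <- ncol(Gg)
    pos <- gmap$position
    obs <- !is.na(Gg)
    # index of nearest informative marker at or left/right of each marker
    Lidx <- matrix(0L, n, M)
    Lidx[, 1] <- ifelse(obs[, 1], 1L, 0L)
    if (M > 1) for (k in 2:M) Lidx[, k] <- ifelse(obs[, k], k, Lidx[, k - 1])
    Ridx <- matrix(0L, n, M)
    Ridx[, M] <- ifelse(obs[, M], M, 0L)
    if (M > 1) for (k in (M - 1):1) Ridx[, k] <- ifelse(obs[, k], k, Ridx[, k + 1])
    grid <- seq(min(pos), max(pos), by = step)
    if (max(pos) - grid[length(grid)] > 1e-9) grid <- c(grid, max(pos))
    for (p in grid) {
      li <- findInterval(p, pos)
      ri <- if (li < M && pos[li] < p || li == 0L) li + 1L else li
      # individuals' informative flanks for this interval
      le <- Lidx[, max(li, 1L)]
      if (li == 0L) le <- rep(0L, n)
      re <- Ridx[, min(ri, M)]
      if (ri > M) re <- rep(0L, n)
      key <- paste(le, re)
      probs <- matrix(NA_real_, n, 3,
                      dimnames = list(NULL, c("QQ", "Qq", "qq")))
      for (k in unique(key)) {
        sel <- key == k
        i1 <- le[sel][1L]; i2 <- re[sel][1L]
        lg <- if (i1 > 0L) Gg[sel, i1] else rep(NA_integer_, sum(sel))
        rg <- if (i2 > 0L) Gg[sel, i2] else rep(NA_integer_, sum(sel))
        d1 <- if (i1 > 0L) p - pos[i1] else 0
        d2 <- if (i2 > 0L) pos[i2] - p else 0
        probs[sel, ] <- qtl_genotype_probs(lg, rg, d1, d2, map_function)
      }
      Xa <- cbind(Xa, probs[, "QQ"] - probs[, "qq"])
      Zd <- cbind(Zd, probs[, "Qq"])
      pos_list[[length(pos_list) + 1L]] <- p
      grp_list[[length(grp_list) + 1L]] <- g
      excl[[length(excl) + 1L]] <- which(
        marker_group == g & abs(marker_pos - p) <= window
      )
    }
  }
  # additive cofactor coding with mean imputation of missing genotypes
  A <- G - 1
  for (k in seq_len(ncol(A))) {
    nas <- is.na(A[, k])
    if (any(nas)) A[nas, k] <- mean(A[, k], na.rm = TRUE)
  }
  list(n = n, group = unlist(grp_list), position = unlist(pos_list),
       Xa = Xa, Zd = Zd, excl = excl, A = A, markers = colnames(G))
}

# Forward-backward stepwise selection of cofactor markers (additive
# coding), entry/stay p-value thresholds, capped at max_k cofactors.
.stepwise_cofactors <- function(y, A, max_k = 5, p_enter = 0.05,
                                p_remove = 0.05) {
  n <- length(y)
  sel <- integer(0)
  for (sweep_i in 1:25) {
    changed <- FALSE
    X <- cbind(1, A[, sel, drop = FALSE])
    qx <- qr(X)
    Q <- qr.Q(qx)
    r <- y - Q %*% crossprod(Q, y)
    rss0 <- sum(r^2)
    if (length(sel) < max_k && rss0 > 0) {
      cand <- setdiff(seq_len(ncol(A)), sel)
      if (length(cand) > 0) {
        Z <- A[, cand, drop = FALSE]
        Zr <- Z - Q %*% crossprod(Q, Z)
        ss <- colSums(Zr^2)
        red <- ifelse(ss > 1e-10 * n, colSums(Zr * as.vector(r))^2 / ss, 0)
        df2 <- n - ncol(X) - 1
        Fv <- red / pmax(rss0 - red, 1e-300) * df2
        pv <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
        pv[ss <= 1e-10 * n] <- 1
        b <- which.min(pv)
        if (pv[b] < p_enter) {
          sel <- c(sel, cand[b])
          changed <- TRUE
        }
      }
    }
    if (length(sel) > 0) {
      X <- cbind(1, A[, sel, drop = FALSE])
      rss_full <- sum(stats::.lm.fit(X, y)$residuals^2)
      df2 <- n - ncol(X)
      pv <- vapply(seq_along(sel), function(j) {
        rss_j <- sum(stats::.lm.fit(X[, -(j + 1L), drop = FALSE], y)$residuals^2)
        Fv <- (rss_j - rss_full) / pmax(rss_full, 1e-300) * df2
        stats::pf(Fv, 1, df2, lower.tail = FALSE)
      }, 0)
      w <- which.max(pv)
      if (pv[w] > p_remove) {
        sel <- sel[-w]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sel
}

# Scan the prepared grid for one phenotype vector.
.cim_core <- function(y, prep, cofactors) {
  n <- prep$n
  tss <- sum((y - mean(y))^2)
  P <- length(prep$position)
  lod <- numeric(P); add <- numeric(P); dom <- numeric(P); r2 <- numeric(P)
  excl_key <- vapply(prep$excl, function(e) {
    paste(intersect(cofactors, e), collapse = ",")
  }, "")
  for (k in unique(excl_key)) {
    sel_pos <- which(excl_key == k)
    keep <- setdiff(cofactors, prep$excl[[sel_pos[1L]]])
    B <- cbind(1, prep$A[, keep, drop = FALSE])
    rss_red <- sum(stats::.lm.fit(B, y)$residuals^2)
    for (p in sel_pos) {
      X <- cbind(B, prep$Xa[, p], prep$Zd[, p])
      fit <- stats::lm.fit(X, y) # lm.fit restores coefficient order under pivoting
      rss_full <- sum(fit$residuals^2)
      cf <- fit$coefficients
      nc <- length(cf)
      a <- cf[nc - 1L]; d <- cf[nc]
      lod[p] <- (n / 2) * log10(rss_red / max(rss_full, 1e-300))
      # degenerate positions (e.g. monomorphic scores) drop to rank
      # deficiency: no QTL information there
      add[p] <- ifelse(is.na(a), 0, a)
      dom[p] <- ifelse(is.na(d), 0, d)
      r2[p] <- if (tss > 0) (rss_red - rss_full) / tss else 0
    }
  }
  tibble::tibble(group = prep$group, position = prep$position,
                 lod = pmax(lod, 0), additive = add, dominance = dom,
                 r2 = pmin(pmax(r2, 0), 1))
}

#' Composite interval mapping scan
#'
#' Scans a fixed-step grid along every linkage group.  Background markers
#' are first chosen as cofactors by forward-backward stepwise regression
#' (entry/stay p = 0.05, at most `n_cofactors`).  At each grid point the
#' phenotype is regressed on the expected additive score
#' `x = P(QQ) - P(qq)` and dominance score `z = P(Qq)` given the flanking
#' markers, plus the cofactors lying outside a `window`-cM exclusion window
#' around the test position; `LOD = (n/2) log10(RSS_reduced/RSS_full)`,
#' the additive and dominance effects are the regression coefficients, and
#' `r2` is the fraction of the total sum of squares explained by the QTL
#' term.
#'
#' @param phenotypes Numeric vector, or tibble with `id` and a value column
#'   (`value`, `f2_value` or `f3_value`).
#' @param genotypes Tibble (`id` + one column per marker) or matrix of
#'   genotype codes 2/1/0/NA for AA/Aa/aa/missing.
#' @param map Linkage map tibble (`group`, `marker`, `position`).
#' @param step Scan step (cM).
#' @param window Cofactor exclusion window around the test position (cM).
#' @param n_cofactors Maximum number of stepwise cofactors.
#' @param map_function Map function for distance-to-recombination
#'   conversion.
#' @return A `qtl_scan` tibble: `group`, `position`, `lod`, `additive`,
#'   `dominance`, `r2`, with the selected cofactor markers, sample size and
#'   scan settings as attributes.
#' @export
cim_scan <- function(phenotypes, genotypes, map, step = 1, window = 10,
                     n_cofactors = 5,
                     map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  inp <- .align_scan_inputs(phenotypes, genotypes, map)
  if (length(inp$y) <= n_cofactors + 3L) {
    rlang::abort("fewer individuals than regression parameters")
  }
  prep <- .cim_prep(inp$G, inp$map, step, window, map_function)
  cof <- .stepwise_cofactors(inp$y, prep$A, max_k = n_cofactors)
  out <- .cim_core(inp$y, prep, cof)
  structure(out,
            cofactors = prep$markers[cof],
            n = prep$n,
            settings = list(step = step, window = window,
                            n_cofactors = n_cofactors,
                            map_function = map_function),
            class = c("qtl_scan", class(out)))
}

#' Genome-wide LOD threshold by phenotype permutation
#'
#' Re-runs the full scan (including cofactor re-selection) on permuted
#' phenotypes and returns the `1 - alpha` quantile of the genome-wide
#' maximum LOD.
#'
#' @inheritParams cim_scan
#' @param n_perm Number of permutations (>= 100 recommended; the reference
#'   analysis used 1000).
#' @param alpha Genome-wide type-I error rate.
#' @param seed Optional integer seed; fixed seeds give identical
#'   thresholds.
#' @return The threshold (scalar), with the permutation maxima as attribute
#'   `max_lods`.
#' @export
permutation_threshold <- function(phenotypes, genotypes, map, n_perm = 1000,
                                  alpha = 0.05, seed = NULL, step = 1,
                                  window = 10, n_cofactors = 5,
                                  map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (n_perm < 2) rlang::abort("`n_perm` must be at least 2")
  inp <- .align_scan_inputs(phenotypes, genotypes, map)
  prep <- .cim_prep(inp$G, inp$map, step, window, map_function)
  maxs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yb <- sample(inp$y)
      cof <- .stepwise_cofactors(yb, prep$A, max_k = n_cofactors)
      max(.cim_core(yb, prep, cof)$lod)
    }, 0)
  })
  structure(unname(stats::quantile(maxs, 1 - alpha, type = 7)),
            max_lods = maxs)
}

#' Declare QTL from a scan profile
#'
#' Contiguous runs of the profile above the threshold yield one QTL each,
#' at the run's LOD maximum; the support interval is the contiguous region
#' around the peak within `drop` LOD of the peak.
#'
#' @param scan A `qtl_scan`.
#' @param threshold Genome-wide LOD threshold (e.g. from
#'   [permutation_threshold()]).
#' @param drop LOD drop defining the support interval (default 1).
#' @return Tibble `group`, `qtl`, `position`, `interval_lo`, `interval_hi`,
#'   `lod`, `r2`, `additive`, `dominance`; zero rows when nothing exceeds
#'   the threshold.
#' @export
declare_qtl <- function(scan, threshold, drop = 1) {
  stopifnot(inherits(scan, "qtl_scan"))
  out <- list()
  for (g in unique(scan$group)) {
    s <- scan[scan$group == g, ]
    above <- s$lod > threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      idx <- starts[k]:ends[k]
      peak <- idx[which.max(s$lod[idx])]
      lo <- peak
      while (lo > 1L && s$lod[lo - 1L] >= s$lod[peak] - drop) lo <- lo - 1L
      hi <- peak
      while (hi < nrow(s) && s$lod[hi + 1L] >= s$lod[peak] - drop) hi <- hi + 1L
      out[[length(out) + 1L]] <- tibble::tibble(
        group = g,
        position = s$position[peak],
        interval_lo = s$position[lo],
        interval_hi = s$position[hi],
        lod = s$lod[peak],
        r2 = s$r2[peak],
        additive = s$additive[peak],
        dominance = s$dominance[peak]
      )
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    group = character(), position = numeric(), interval_lo = numeric(),
    interval_hi = numeric(), lod = numeric(), r2 = numeric(),
    additive = numeric(), dominance = numeric()
  )
  dplyr::bind_cols(
    res[, "group", drop = FALSE],
    tibble::tibble(qtl = if (nrow(res)) paste0(res$group, "-",
      stats::ave(seq_len(nrow(res)), res$group, FUN = seq_along)) else character()),
    res[, setdiff(names(res), "group"), drop = FALSE]
  )
}

#' Single-marker one-way ANOVA
#'
#' Fixed-effects one-way analysis of variance of the phenotype across the
#' genotype classes of a single marker, as used to corroborate QTL in F3
#' families.
#'
#' @param values Numeric phenotype vector.
#' @param genotypes Genotype codes (0/1/2 or factor levels), same length.
#' @return One-row tibble `f_value`, `df_between`, `df_within`, `p_value`,
#'   `r2` (between-class share of the total sum of squares).
#' @export
single_marker_anova <- function(values, genotypes) {
  keep <- !is.na(values) & !is.na(genotypes)
  values <- values[keep]
  g <- factor(genotypes[keep])
  if (nlevels(g) < 2) {
    rlang::abort("need at least two genotype classes for ANOVA")
  }
  cls_mean <- tapply(values, g, mean)
  cls_n <- tapply(values, g, length)
  gm <- mean(values)
  ssb <- sum(cls_n * (cls_mean - gm)^2)
  ssw <- sum((values - cls_mean[g])^2)
  sst <- ssb + ssw
  df1 <- nlevels(g) - 1L
  df2 <- length(values) - nlevels(g)
  f <- if (ssw > 0) (ssb / df1) / (ssw / df2) else Inf
  tibble::tibble(
    f_value = f,
    df_between = df1,
    df_within = df2,
    p_value = if (is.finite(f)) stats::pf(f, df1, df2, lower.tail = FALSE)
              else 0,
    r2 = if (sst > 0) ssb / sst else 0
  )
}
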