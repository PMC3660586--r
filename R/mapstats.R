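# Linkage-map summary arithmetic, expected genome length and
# segregation-distortion testing.

#' Expected genome length from a linkage map
#'
#' Two standard estimators: `"fishman"` extends each group by twice its
#' average inter-marker spacing; `"postlethwait"` scales each group length
#' by `(m + 1)/(m - 1)` for `m` markers.  Groups with fewer than two
#' markers cannot be extended and are carried at their observed length with
#' a warning.
#'
#' @param map Linkage map tibble (`group`, `marker`, `position`).
#' @param method `"fishman"` or `"postlethwait"`.
#' @return Estimated genome length (cM).
#' @export
expected_genome_length <- function(map, method = c("fishman", "postlethwait")) {
  method <- match.arg(method)
  map <- validate_map(map)
  per_group <- vapply(unique(map$group), function(g) {
    pos <- map$position[map$group == g]
    m <- length(pos)
    len <- max(pos) - min(pos)
    if (m < 2) {
      rlang::warn(paste0("group '", g, "' has fewer than 2 markers; ",
                         "carried at observed length"))
      return(len)
    }
    switch(method,
      fishman = len + 2 * len / (m - 1),
      postlethwait = len * (m + 1) / (m - 1)
    )
  }, 0)
  sum(per_group)
}

#' Summarise a linkage map
#'
#' Totals and ratios: group and locus counts, total and mean group length,
#' mean loci per group, marker density (cM per marker), expected genome
#' length (user-supplied, or estimated from the map), genome coverage and
#' optionally the segregation-distortion fraction.
#'
#' @param map Linkage map tibble (`group`, `marker`, `position`).
#' @param expected_length Optional externally estimated genome length (cM);
#'   when `NULL` it is computed with [expected_genome_length()].
#' @param method Estimator used when `expected_length` is `NULL`.
#' @param distorted_count,markers_tested Optional counts of
#'   significantly distorted markers and of all markers tested, for the
#'   distortion fraction.
#' @return One-row tibble: `n_groups`, `n_loci`, `total_length`,
#'   `mean_group_length`, `mean_loci_per_group`, `density`,
#'   `expected_genome_length`, `coverage_pct`, and when supplied
#'   `distorted_count`, `distorted_pct`.  Values are full precision; round
#'   to 2 decimals for display.
#' @export
map_summary <- function(map, expected_length = NULL,
                        method = c("fishman", "postlethwait"),
                        distorted_count = NULL, markers_tested = NULL) {
  method <- match.arg(method)
  map <- validate_map(map)
  groups <- unique(map$group)
  lens <- vapply(groups, function(g) {
    pos <- map$position[map$group == g]
    max(pos) - min(pos)
  }, 0)
  n_loci <- nrow(map)
  total <- sum(lens)
  exp_len <- expected_length %||% expected_genome_length(map, method)
  out <- tibble::tibble(
    n_groups = length(groups),
    n_loci = n_loci,
    total_length = total,
    mean_group_length = total / length(groups),
    mean_loci_per_group = n_loci / length(groups),
    density = total / n_loci,
    expected_genome_length = exp_len,
    coverage_pct = 100 * total / exp_len
  )
  if (!is.null(distorted_count)) {
    tested <- markers_tested %||% n_loci
    out$distorted_count <- distorted_count
    out$distorted_pct <- 100 * distorted_count / tested
  }
  out
}

#' Chi-square test for segregation distortion
#'
#' Goodness of fit of observed marker genotype counts against the Mendelian
#' expectation: 1:2:1 (codominant marker, counts ordered AA, Aa, aa; 2 df)
#' or 3:1 (dominant marker, counts ordered band-present, band-absent;
#' 1 df).
#'
#' @param counts Integer vector of genotype-class counts (length 3 for
#'   codominant, 2 for dominant markers).
#' @param type Marker type.
#' @return One-row tibble `chisq`, `df`, `p_value`.
#' @examples
#' distortion_test(c(65, 130, 65)) # perfect 1:2:1 -> chisq 0
#' @export
distortion_test <- function(counts, type = c("codominant", "dominant")) {
  type <- match.arg(type)
  expected_ratio <- switch(type,
    codominant = c(1, 2, 1) / 4,
    dominant = c(3, 1) / 4
  )
  if (length(counts) != length(expected_ratio)) {
    rlang::abort(paste0("`counts` must have length ", length(expected_ratio),
                        " for ", type, " markers"))
  }
  if (any(counts < 0) || sum(counts) == 0) {
    rlang::abort("`counts` must be non-negative with a positive total")
  }
  expected <- sum(counts) * expected_ratio
  chisq <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  tibble::tibble(
    chisq = chisq,
    df = df,
    p_value = stats::pchisq(chisq, df, lower.tail = FALSE)
  )
}

#' Segregation-distortion scan over a genotype table
#'
#' Applies [distortion_test()] to every marker column of an F2 genotype
#' table (codes 2/1/0/NA).
#'
#' @param genotypes Tibble (`id` + marker columns) or matrix of codes.
#' @param alpha Significance level for the distortion flag.
#' @return Tibble `marker`, `n`, `chisq`, `df`, `p_value`, `distorted`.
#' @export
distortion_scan <- function(genotypes, alpha = 0.05) {
  G <- if (is.matrix(genotypes)) genotypes else {
    gt <- tibble::as_tibble(genotypes)
    as.matrix(gt[, setdiff(names(gt), "id"), drop = FALSE])
  }
  out <- lapply(colnames(G), function(mk) {
    g <- G[, mk]
    g <- g[!is.na(g)]
    counts <- c(sum(g == 2), sum(g == 1), sum(g == 0))
    dt <- distortion_test(counts, "codominant")
    dplyr::bind_cols(tibble::tibble(marker = mk, n = length(g)), dt)
  })
  out <- dplyr::bind_rows(out)
  out$distorted <- out$p_value < alpha
  out
}
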