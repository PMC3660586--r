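# Goodness-of-fit battery for a fitted mixture: probability-integral
# transform, Neyman-smooth uniformity components (U1^2..U3^2),
# Cramer-von Mises and Kolmogorov tests.

#' Probability-integral transform under a fitted mixture
#'
#' Evaluates the fitted per-generation mixture CDF at each observation;
#' under a correct model the transformed values are Uniform(0, 1).
#'
#' @param fit A `seg_fit`.
#' @param data Tibble with `generation`, `value`; defaults to the data the
#'   model was fitted to.
#' @return Tibble `generation`, `value`, `pit`.
#' @export
pit_transform <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "seg_fit"))
  data <- validate_phenotypes(data %||% fit$data, require_replication = FALSE)
  comps <- fit$components
  out <- lapply(intersect(seg_generations(), unique(as.character(data$generation))),
                function(g) {
    cg <- comps[comps$generation == g, ]
    if (nrow(cg) == 0) {
      rlang::abort(paste0("fit has no components for generation ", g))
    }
    x <- data$value[data$generation == g]
    y <- rowSums(matrix(vapply(seq_len(nrow(cg)), function(j) {
      cg$frequency[j] * stats::pnorm(x, cg$mean[j], sqrt(cg$variance[j]))
    }, numeric(length(x))), nrow = length(x)))
    tibble::tibble(generation = g, value = x, pit = y)
  })
  dplyr::bind_rows(out)
}

# Legendre polynomials P1..P3 on [-1, 1].
.legendre <- function(k, x) {
  switch(k,
    `1` = x,
    `2` = (3 * x^2 - 1) / 2,
    `3` = (5 * x^3 - 3 * x) / 2
  )
}

#' Neyman-smooth uniformity components U1^2, U2^2, U3^2
#'
#' The k-th component is `U_k = sqrt(n) * mean(sqrt(2k+1) * P_k(2y - 1))`
#' with `P_k` the k-th Legendre polynomial; under uniformity each `U_k^2`
#' is asymptotically chi-squared with 1 degree of freedom.  U1 picks up
#' location (mean) misfit, U2 dispersion and U3 skewness of the transformed
#' sample.
#'
#' @param y Numeric vector of probability-integral-transform values.
#' @return Tibble with rows `U1sq`, `U2sq`, `U3sq`: `statistic`, `value`,
#'   `p_value`.
#' @export
u_tests <- function(y) {
  if (length(y) == 0) rlang::abort("empty sample")
  if (any(!is.finite(y))) rlang::abort("PIT values must be finite")
  n <- length(y)
  z <- 2 * y - 1
  vals <- vapply(1:3, function(k) {
    u <- sqrt(n) * sqrt(2 * k + 1) * mean(.legendre(k, z))
    u^2
  }, 0)
  tibble::tibble(
    statistic = c("U1sq", "U2sq", "U3sq"),
    value = vals,
    p_value = stats::pchisq(vals, df = 1, lower.tail = FALSE)
  )
}

# Asymptotic CDF of the Cramer-von Mises statistic (Bessel-K series of
# Anderson-Darling 1952 / Csorgo-Faraway 1996).
pcvm_asymptotic <- function(x) {
  vapply(x, function(q) {
    if (q <= 0) return(0)
    if (q > 10) return(1)
    j <- 0:12
    coef <- exp(lgamma(j + 0.5) - lgamma(0.5) - lgamma(j + 1))
    a <- (4 * j + 1)^2 / (16 * q)
    terms <- coef * sqrt(4 * j + 1) * exp(-a) * besselK(a, 0.25)
    min(1, max(0, sum(terms) / (pi * sqrt(q))))
  }, 0)
}

#' Cramer-von Mises and Kolmogorov tests of uniformity
#'
#' `W2 = 1/(12n) + sum(y_(i) - (2i-1)/(2n))^2` with an asymptotic p-value
#' from the classical limiting distribution; the Kolmogorov statistic and
#' p-value are delegated to [stats::ks.test()] against Uniform(0, 1).
#'
#' @param y Numeric vector of probability-integral-transform values in
#'   \[0, 1\].
#' @return Tibble with rows `W2` and `Dn`: `statistic`, `value`, `p_value`.
#' @export
cvm_ks <- function(y) {
  if (length(y) == 0) rlang::abort("empty sample")
  if (any(!is.finite(y)) || any(y < 0 | y > 1)) {
    rlang::abort("PIT values must lie in [0, 1]")
  }
  n <- length(y)
  ys <- sort(y)
  w2 <- 1 / (12 * n) + sum((ys - (2 * seq_len(n) - 1) / (2 * n))^2)
  p_w2 <- 1 - pcvm_asymptotic(w2)
  ks <- suppressWarnings(stats::ks.test(y, "punif"))
  tibble::tibble(
    statistic = c("W2", "Dn"),
    value = c(w2, unname(ks$statistic)),
    p_value = c(p_w2, ks$p.value)
  )
}

#' Goodness-of-fit battery for a fitted segregation model
#'
#' Applies the probability-integral transform per generation, then the five
#' uniformity statistics (U1^2, U2^2, U3^2, Cramer-von Mises W2,
#' Kolmogorov Dn).
#'
#' @param fit A `seg_fit`.
#' @param data Optional data (defaults to the fitted data).
#' @param alpha Significance level for flagging statistics.
#' @return Tibble `generation`, `statistic`, `value`, `p_value`,
#'   `significant`; the total number of significant statistics is attached
#'   as attribute `significant_count`.
#' @export
gof_tests <- function(fit, data = NULL, alpha = 0.05) {
  pit <- pit_transform(fit, data)
  out <- pit |>
    dplyr::group_by(.data$generation) |>
    dplyr::group_modify(function(d, key) {
      dplyr::bind_rows(u_tests(d$pit), cvm_ks(d$pit))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_value < alpha)
  attr(out, "significant_count") <- sum(out$significant)
  out
}
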