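# broom-style tidy()/glance() methods for fitted objects.

#' Tidy a segregation fit
#'
#' @param x A `seg_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` over the model's free effect
#'   parameters and variance components.
#' @method tidy seg_fit
#' @export
tidy.seg_fit <- function(x, ...) {
  mod <- get_model(x$model)
  terms <- c(mod$free, "sigma2_e", if (mod$polygene_variance) "sigma2_pg")
  tibble::tibble(
    term = terms,
    estimate = unname(c(x$free[mod$free], x$params[["sigma2_e"]],
                        if (mod$polygene_variance) x$params[["sigma2_pg"]]))
  )
}

#' One-row summary of a segregation fit
#'
#' @param x A `seg_fit`.
#' @param ... Unused.
#' @return Tibble `model`, `class`, `n`, `n_par`, `logLik`, `AIC`,
#'   `iterations`, `converged`.
#' @method glance seg_fit
#' @export
glance.seg_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    class = x$class,
    n = x$n,
    n_par = x$n_par,
    logLik = x$logLik,
    AIC = x$AIC,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Tidy a model-comparison set
#'
#' @param x A `seg_model_set` from [fit_all_models()].
#' @param ... Unused.
#' @return The comparison tibble (model, class, n_par, logLik, AIC,
#'   delta_AIC, converged).
#' @method tidy seg_model_set
#' @export
tidy.seg_model_set <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a QTL scan
#'
#' @param x A `qtl_scan`.
#' @param ... Unused.
#' @return The scan profile tibble.
#' @method tidy qtl_scan
#' @export
tidy.qtl_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a QTL scan
#'
#' @param x A `qtl_scan`.
#' @param ... Unused.
#' @return Tibble `n`, `n_positions`, `n_cofactors`, `max_lod`,
#'   `max_lod_group`, `max_lod_position`.
#' @method glance qtl_scan
#' @export
glance.qtl_scan <- function(x, ...) {
  i <- which.max(x$lod)
  tibble::tibble(
    n = attr(x, "n"),
    n_positions = nrow(x),
    n_cofactors = length(attr(x, "cofactors")),
    max_lod = x$lod[i],
    max_lod_group = x$group[i],
    max_lod_position = x$position[i]
  )
}
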