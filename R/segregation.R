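# Joint segregation analysis: constrained normal-mixture likelihood,
# iterated expectation-conditional-maximisation (IECM) fitting, AIC model
# comparison and optimal-model selection.
#
# Mixture structure per generation g: components j with Mendelian (fixed)
# frequencies pi_gj, means mu_gj linear in the effect parameters, and a
# common within-component variance sigma2_e + c_g * sigma2_pg.

#' Mixture log-likelihood of six-generation data under a model
#'
#' Computes `sum_g sum_i log sum_j pi_gj Normal(x_gi; mu_gj, sigma2_g)`
#' where the component means are determined by the effect parameters and the
#' within-component variance is `sigma2_e + c_g * sigma2_pg`.
#'
#' @param data Tibble with columns `generation` and `value` (any subset of
#'   the six generations).
#' @param model Model code or `seg_model`.
#' @param params A [genetic_params()] vector respecting the model.
#' @return The log-likelihood (scalar).
#' @export
seg_loglik <- function(data, model = "E_0", params) {
  mod <- get_model(model)
  params <- as_genetic_params(params)
  data <- validate_phenotypes(data, require_replication = FALSE)
  gens <- intersect(seg_generations(), unique(as.character(data$generation)))
  theta <- params[seg_effect_names()]
  total <- 0
  for (g in gens) {
    b <- component_blocks(mod, g)[[1L]]
    v <- params[["sigma2_e"]] + b$c_pg * params[["sigma2_pg"]]
    if (v <= 0) rlang::abort("non-positive within-component variance")
    x <- data$value[data$generation == g]
    mu <- as.vector(b$coeff %*% theta)
    lw <- vapply(seq_along(mu), function(j) {
      log(b$frequency[j]) + stats::dnorm(x, mu[j], sqrt(v), log = TRUE)
    }, numeric(length(x)))
    lw <- matrix(lw, nrow = length(x))
    total <- total + sum(row_log_sum_exp(lw))
  }
  total
}

# Method-of-moments starting values for the free effect vector and the
# variance components, derived from generation means.
.moment_init <- function(data, mod) {
  gm <- tapply(data$value, as.character(data$generation), mean)
  gv <- tapply(data$value, as.character(data$generation), stats::var)
  gn <- tapply(data$value, as.character(data$generation), length)
  have <- function(g) g %in% names(gm)
  m0 <- if (have("P1") && have("P2")) (gm[["P1"]] + gm[["P2"]]) / 2 else mean(data$value)
  spread <- if (have("P1") && have("P2")) (gm[["P1"]] - gm[["P2"]]) / 2 else stats::sd(data$value)
  dev <- if (have("F1")) gm[["F1"]] - m0 else 0
  full <- stats::setNames(numeric(length(seg_effect_names())), seg_effect_names())
  full["m"] <- m0
  if (mod$n_major == 2L) {
    full["d_a"] <- full["d_b"] <- spread / 2
    full["h_a"] <- full["h_b"] <- dev / 2
  } else if (mod$n_major == 1L) {
    full["d_a"] <- spread
    full["h_a"] <- dev
  }
  if (any(c("d_pg", "h_pg") %in% mod$free)) {
    scl <- if (mod$n_major > 0L) 0.25 else 1
    full["d_pg"] <- spread * scl
    full["h_pg"] <- dev * scl
  }
  phi <- qr.coef(qr(mod$map), full)
  phi[is.na(phi)] <- 0
  nonseg <- intersect(c("P1", "P2", "F1"), names(gv))
  nonseg <- nonseg[gn[nonseg] > 1]
  s2e <- if (length(nonseg)) {
    sum((gn[nonseg] - 1) * gv[nonseg]) / sum(gn[nonseg] - 1)
  } else {
    stats::var(data$value) / 4
  }
  s2pg <- if (mod$polygene_variance) max(0.1 * stats::var(data$value), s2e / 10) else 0
  list(phi = phi, sigma2_e = s2e, sigma2_pg = s2pg)
}

# One EM run from a given start.  Returns params, trace, convergence info.
# Each loop iteration evaluates the mixture densities once, serving both as
# the E-step of the current iteration and the log-likelihood of the
# parameters produced by the previous one.
.em_run <- function(x_list, blocks, mod, start, tol, max_iter, floor) {
  phi <- start$phi
  s2e <- max(start$sigma2_e, floor)
  s2pg <- if (mod$polygene_variance) max(start$sigma2_pg, 0) else 0
  gens <- names(blocks)
  c_pg <- vapply(blocks, `[[`, 0, "c_pg")
  n_g <- vapply(x_list, length, 0L)
  log_freq <- lapply(blocks, function(b) log(b$frequency))

  # densities + posteriors + loglik at given parameters
  estep <- function(phi, s2e, s2pg, want_weights = TRUE) {
    total <- 0
    w_list <- if (want_weights) vector("list", length(gens)) else NULL
    for (gi in seq_along(gens)) {
      b <- blocks[[gi]]
      v <- s2e + b$c_pg * s2pg
      mu <- as.vector(b$design %*% phi)
      D <- outer(x_list[[gi]], mu, "-")
      lw <- -0.5 * D * D / v + rep(log_freq[[gi]] - 0.5 * log(2 * pi * v),
                                   each = n_g[[gi]])
      lse <- row_log_sum_exp(lw)
      total <- total + sum(lse)
      if (want_weights) w_list[[gi]] <- exp(lw - lse)
    }
    list(logLik = total, w = w_list)
  }

  es <- estep(phi, s2e, s2pg, want_weights = !is.infinite(tol))
  ll_prev <- es$logLik
  trace <- ll_prev
  converged <- FALSE
  iterations <- 0L
  if (!is.finite(tol)) {
    # no-op limit: the initialisation is returned unchanged
    return(list(phi = phi, sigma2_e = s2e, sigma2_pg = s2pg,
                logLik = ll_prev, trace = trace, iterations = 1L,
                converged = FALSE))
  }
  design_all <- do.call(rbind, lapply(blocks, `[[`, "design"))
  for (it in seq_len(max_iter)) {
    iterations <- it
    # CM-step (a): weighted least squares for the effect parameters,
    # using the posterior memberships of the E-step
    Wj_list <- lapply(es$w, colSums)
    ybar_list <- lapply(seq_along(gens), function(gi) {
      Wj <- Wj_list[[gi]]
      ifelse(Wj > 0, colSums(es$w[[gi]] * x_list[[gi]]) / pmax(Wj, 1e-300), 0)
    })
    v_cur <- s2e + c_pg * s2pg
    wv <- unlist(lapply(seq_along(gens), function(gi) {
      Wj_list[[gi]] / v_cur[[gi]]
    }), use.names = FALSE)
    yv <- unlist(ybar_list, use.names = FALSE)
    fit_w <- stats::lm.wfit(design_all, yv, wv)
    phi_new <- fit_w$coefficients
    phi_new[is.na(phi_new)] <- phi[is.na(phi_new)]
    # CM-step (b): variance components given the updated means
    S_g <- vapply(seq_along(gens), function(gi) {
      mu <- as.vector(blocks[[gi]]$design %*% phi_new)
      D <- outer(x_list[[gi]], mu, "-")
      sum(es$w[[gi]] * D * D)
    }, 0)
    if (!mod$polygene_variance) {
      s2e_new <- max(sum(S_g) / sum(n_g), floor)
      s2pg_new <- 0
    } else {
      cc <- c_pg
      obj <- function(p) {
        v <- p[1] + cc * p[2]
        if (any(v <= 0)) return(1e300)
        sum(n_g * log(v) + S_g / v)
      }
      grd <- function(p) {
        v <- p[1] + cc * p[2]
        dv <- n_g / v - S_g / v^2
        c(sum(dv), sum(cc * dv))
      }
      cur <- c(s2e, s2pg)
      opt <- tryCatch(
        stats::optim(cur, obj, grd, method = "L-BFGS-B",
                     lower = c(floor, 0)),
        error = function(e) list(par = cur, value = obj(cur))
      )
      if (opt$value <= obj(cur)) {
        s2e_new <- opt$par[1]
        s2pg_new <- opt$par[2]
      } else {
        s2e_new <- s2e
        s2pg_new <- s2pg
      }
    }
    es_new <- estep(phi_new, s2e_new, s2pg_new)
    ll_new <- es_new$logLik
    if (!is.finite(ll_new) ||
        ll_new < ll_prev - 1e-8 * (1 + abs(ll_prev))) {
      # numerical safeguard: never accept a decrease
      converged <- TRUE
      break
    }
    phi <- phi_new; s2e <- s2e_new; s2pg <- s2pg_new
    es <- es_new
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll_prev) < tol) {
      ll_prev <- ll_new
      converged <- TRUE
      break
    }
    ll_prev <- ll_new
  }
  list(phi = phi, sigma2_e = s2e, sigma2_pg = s2pg, logLik = ll_prev,
       trace = trace, iterations = iterations, converged = converged)
}

# Two-major-gene mixtures are exactly invariant under exchanging the gene
# labels ((d_a, h_a, j_ab) <-> (d_b, h_b, j_ba)): every generation's
# component set maps onto itself.  Fits are therefore reported in a
# canonical labelling: gene a is the one with the smaller additive effect
# (d_a <= d_b); on the near-equal-additive ridge, where the pairing is
# identified only through dominance, the smaller dominance effect breaks
# the tie (h_a <= h_b).
.canonicalize_genes <- function(mod, phi) {
  free <- names(phi)
  if (!all(c("d_a", "d_b") %in% free)) {
    return(phi)
  }
  scale <- abs(phi[["d_a"]]) + abs(phi[["d_b"]])
  near_equal <- abs(phi[["d_a"]] - phi[["d_b"]]) <= 1e-3 * (scale + 1e-12)
  swap <- if (near_equal && all(c("h_a", "h_b") %in% free)) {
    phi[["h_a"]] > phi[["h_b"]]
  } else {
    phi[["d_a"]] > phi[["d_b"]]
  }
  if (swap) {
    for (pair in list(c("d_a", "d_b"), c("h_a", "h_b"), c("j_ab", "j_ba"))) {
      if (all(pair %in% free)) {
        phi[pair] <- phi[rev(pair)]
      }
    }
  }
  phi
}

#' Fit one inheritance model by IECM
#'
#' The E-step computes posterior component memberships; the CM-steps update
#' (a) the genetic-effect parameters by weighted least squares of the
#' posterior component means against the model's mean-coefficient design and
#' (b) the variance components under the `sigma2_e + c_g * sigma2_pg`
#' structure, holding component frequencies fixed at their Mendelian values.
#' The log-likelihood is non-decreasing across iterations; the best of
#' several starts (method-of-moments plus seeded jitters) is returned.
#'
#' @param data Tibble with columns `generation` and `value`; one
#'   replication's data.
#' @param model Model code (see [genetic_models()]).
#' @param inits Optional list of [genetic_params()]-like starting values
#'   (each a named vector); when supplied these replace the moment starts.
#' @param tol Absolute log-likelihood increase below which the fit is
#'   declared converged.
#' @param max_iter Maximum IECM iterations per start.
#' @param n_starts Number of starts (first is the moment start).
#' @param seed Optional seed controlling the start jitter.
#' @return A `seg_fit` object with the fitted [genetic_params()], component
#'   table (means, frequencies, variances per generation), log-likelihood,
#'   AIC, iteration count, convergence flag and the per-iteration
#'   log-likelihood trace.
#' @examples
#' sim <- simulate_generations("A_1", genetic_params(m = 80, d_a = 30,
#'   h_a = -10, sigma2_e = 50), seed = 1)
#' fit <- fit_segregation(sim, "A_1", seed = 1)
#' glance(fit)
#' @export
fit_segregation <- function(data, model = "E_0", inits = NULL, tol = 1e-6,
                            max_iter = 2000, n_starts = 5, seed = NULL) {
  mod <- get_model(model)
  data <- validate_phenotypes(data, require_replication = FALSE)
  gens <- intersect(seg_generations(), unique(as.character(data$generation)))
  if (length(gens) == 0) rlang::abort("no recognised generations in `data`")
  x_list <- lapply(stats::setNames(gens, gens), function(g) {
    x <- data$value[data$generation == g]
    if (length(x) == 0) rlang::abort(paste0("generation ", g, " is empty"))
    x
  })
  blocks <- component_blocks(mod, gens)
  # identifiability: the stacked design over all components must have full
  # column rank for this model to be estimable from these generations
  X_all <- do.call(rbind, lapply(blocks, `[[`, "design"))
  qr_all <- qr(X_all)
  if (qr_all$rank < ncol(X_all)) {
    bad <- colnames(X_all)[qr_all$pivot[seq.int(qr_all$rank + 1L, ncol(X_all))]]
    rlang::abort(paste0(
      "design matrix is rank deficient for model ", mod$code,
      "; unidentifiable parameters: ", paste(bad, collapse = ", ")
    ))
  }
  all_x <- unlist(x_list, use.names = FALSE)
  vfloor <- max(1e-8 * stats::var(all_x), 1e-12)
  if (!is.finite(vfloor)) vfloor <- 1e-12

  starts <- if (!is.null(inits)) {
    if (!is.list(inits) || is.numeric(inits)) inits <- list(inits)
    lapply(inits, function(p) {
      p <- as_genetic_params(p)
      phi <- qr.coef(qr(mod$map), p[seg_effect_names()])
      phi[is.na(phi)] <- 0
      list(phi = phi, sigma2_e = p[["sigma2_e"]], sigma2_pg = p[["sigma2_pg"]])
    })
  } else {
    base <- .moment_init(data, mod)
    with_seed(seed, {
      c(list(base), lapply(seq_len(max(0L, n_starts - 1L)), function(s) {
        jig <- base
        jig$phi <- base$phi * stats::runif(length(base$phi), 0.7, 1.3)
        jig$sigma2_e <- base$sigma2_e * stats::runif(1, 0.5, 2)
        jig$sigma2_pg <- base$sigma2_pg * stats::runif(1, 0.5, 2)
        jig
      }))
    })
  }

  runs <- lapply(starts, function(s) {
    .em_run(x_list, blocks, mod, s, tol = tol, max_iter = max_iter,
            floor = vfloor)
  })
  best <- runs[[which.max(vapply(runs, `[[`, 0, "logLik"))]]
  if (is.finite(tol)) best$phi <- .canonicalize_genes(mod, best$phi)

  theta <- as.vector(mod$map %*% best$phi)
  names(theta) <- seg_effect_names()
  params <- do.call(genetic_params, c(as.list(theta),
                                      list(sigma2_pg = best$sigma2_pg,
                                           sigma2_e = best$sigma2_e)))
  comps <- dplyr::bind_rows(lapply(blocks, function(b) {
    tibble::tibble(
      generation = b$generation,
      genotype = b$genotype,
      frequency = b$frequency,
      mean = as.vector(b$design %*% best$phi),
      variance = best$sigma2_e + b$c_pg * best$sigma2_pg
    )
  }))
  n <- length(all_x)
  ll <- best$logLik
  k <- mod$n_par
  structure(list(
    model = mod$code,
    class = mod$class,
    params = params,
    free = stats::setNames(best$phi, colnames(mod$map)),
    components = comps,
    logLik = ll,
    AIC = -2 * ll + 2 * k,
    n_par = k,
    n = n,
    iterations = best$iterations,
    converged = best$converged,
    boundary = best$sigma2_e <= vfloor * (1 + 1e-6),
    trace = best$trace,
    data = data[, c("generation", "value")]
  ), class = "seg_fit")
}

#' @export
print.seg_fit <- function(x, ...) {
  cat("Segregation-analysis fit, model ", x$model, " (class ", x$class,
      ")\n", sep = "")
  cat("  n = ", x$n, ", logLik = ", format(x$logLik, digits = 8),
      ", AIC = ", format(x$AIC, digits = 8), "\n", sep = "")
  cat("  ", x$iterations, " IECM iterations; converged: ", x$converged,
      "\n", sep = "")
  print(round(unclass(x$params), 3))
  invisible(x)
}

#' Fit all (or a subset of) catalogue models
#'
#' @inheritParams fit_segregation
#' @param models Character vector of model codes; default the whole
#'   24-model catalogue.
#' @param n_starts Starts per model; model screening uses fewer starts than
#'   a single-model fit because the moment start is deterministic and the
#'   catalogue is refit widely.
#' @param ... Passed to [fit_segregation()].
#' @return A `seg_model_set`: a tibble with one row per model (`model`,
#'   `class`, `n_par`, `logLik`, `AIC`, `delta_AIC`, `converged`), sorted by
#'   AIC, carrying the individual `seg_fit` objects in the `fits` attribute.
#' @export
fit_all_models <- function(data, models = NULL, n_starts = 2, seed = NULL,
                           ...) {
  codes <- models %||% names(seg_registry())
  if (anyDuplicated(codes)) rlang::abort("duplicate model codes requested")
  fits <- lapply(stats::setNames(codes, codes), function(code) {
    fit_segregation(data, code, n_starts = n_starts, seed = seed, ...)
  })
  tab <- tibble::tibble(
    model = unname(codes),
    class = unname(vapply(fits, `[[`, "", "class")),
    n_par = unname(vapply(fits, `[[`, 0L, "n_par")),
    logLik = unname(vapply(fits, `[[`, 0, "logLik")),
    AIC = unname(vapply(fits, `[[`, 0, "AIC")),
    converged = unname(vapply(fits, `[[`, NA, "converged"))
  )
  tab <- tab[order(tab$AIC), ]
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  structure(tab, fits = fits, class = c("seg_model_set", class(tab)))
}

#' Candidate models by AIC
#'
#' @param model_set A [fit_all_models()] result.
#' @param n Number of smallest-AIC models to keep (default 5).
#' @param window Optional AIC window: keep all models with
#'   `AIC <= min(AIC) + window` instead of a fixed count.
#' @return Character vector of candidate model codes.
#' @export
candidate_models <- function(model_set, n = 5, window = NULL) {
  stopifnot(inherits(model_set, "seg_model_set"))
  if (!is.null(window)) {
    model_set$model[model_set$delta_AIC <= window]
  } else {
    utils::head(model_set$model, n)
  }
}

#' Select the optimal model among candidates
#'
#' Among the candidate models, returns the one with the fewest significant
#' goodness-of-fit statistics; ties are broken by smaller AIC.
#'
#' @param model_set A [fit_all_models()] result.
#' @param candidates Character vector of candidate codes (default: the five
#'   smallest-AIC models).
#' @param counts Optional named vector of significant-statistic counts per
#'   candidate; when omitted they are computed by running [gof_tests()] on
#'   each candidate's fit.
#' @param alpha Significance level used when computing counts.
#' @return The selected model code (with the counts as attribute).
#' @export
select_optimal_model <- function(model_set, candidates = NULL, counts = NULL,
                                 alpha = 0.05) {
  stopifnot(inherits(model_set, "seg_model_set"))
  candidates <- candidates %||% candidate_models(model_set)
  if (length(candidates) == 0) rlang::abort("empty candidate set")
  fits <- attr(model_set, "fits")
  if (is.null(counts)) {
    counts <- vapply(candidates, function(code) {
      gof <- gof_tests(fits[[code]], alpha = alpha)
      sum(gof$significant)
    }, 0)
  }
  if (is.null(names(counts))) names(counts) <- candidates
  counts <- counts[candidates]
  aics <- model_set$AIC[match(candidates, model_set$model)]
  ord <- order(counts, aics)
  structure(candidates[ord[1L]], counts = counts)
}
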