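test_that("single-component log-likelihood has the Gaussian closed form", {
  # two P1 points exactly at the component mean
  p <- genetic_params(m = 10, d_a = 0, d_b = 0, i = 0, sigma2_e = 4)
  data <- tibble::tibble(generation = c("P1", "P1"), value = c(10, 10))
  expect_equal(seg_loglik(data, "E_0", p), 2 * log(1 / sqrt(2 * pi * 4)))
})

test_that("log-likelihood equals a brute-force mixture-density summation", {
  p <- genetic_params(m = 70, d_a = 18, d_b = 22, h_a = -30, h_b = -8,
                      i = 3, j_ab = 7, j_ba = -15, l = 12,
                      sigma2_pg = 25, sigma2_e = 55)
  data <- tibble::tibble(
    generation = c("F2", "F2", "BC1", "P1", "F1"),
    value = c(55.2, 101.7, 88.1, 112.4, 47.9)
  )
  # independent high-precision oracle: explicit sum over components
  oracle <- 0
  for (r in seq_len(nrow(data))) {
    g <- as.character(data$generation[r])
    spec <- generation_spec("E_0", g)
    mu <- as.vector(as.matrix(spec[, segqtl:::seg_effect_names()]) %*%
                      p[segqtl:::seg_effect_names()])
    v <- p[["sigma2_e"]] + spec$c_pg[1] * p[["sigma2_pg"]]
    oracle <- oracle +
      log(sum(spec$frequency * stats::dnorm(data$value[r], mu, sqrt(v))))
  }
  expect_equal(seg_loglik(data, "E_0", p), oracle, tolerance = 1e-10)
})

test_that("scaling data and parameters shifts the log-likelihood by -n log c", {
  p <- genetic_params(m = 70, d_a = 18, d_b = 22, h_a = -30, h_b = -8,
                      i = 3, j_ab = 7, j_ba = -15, l = 12,
                      sigma2_pg = 25, sigma2_e = 55)
  data <- tibble::tibble(
    generation = c("F2", "F2", "BC2", "P2", "F1", "BC1"),
    value = c(55.2, 101.7, 48.1, 42.4, 47.9, 90.3)
  )
  cc <- 2.5
  ps <- as.list(p)
  for (nm in segqtl:::seg_effect_names()) ps[[nm]] <- ps[[nm]] * cc
  ps$sigma2_pg <- ps$sigma2_pg * cc^2
  ps$sigma2_e <- ps$sigma2_e * cc^2
  scaled <- dplyr::mutate(data, value = value * cc)
  expect_equal(
    seg_loglik(scaled, "E_0", do.call(genetic_params, ps)),
    seg_loglik(data, "E_0", p) - nrow(data) * log(cc),
    tolerance = 1e-10
  )
})

test_that("non-positive variance is rejected in the likelihood", {
  data <- tibble::tibble(generation = "P1", value = 1)
  expect_error(
    seg_loglik(data, "E_0", genetic_params(sigma2_e = 0)),
    "non-positive"
  )
})

test_that("IECM log-likelihood trace is monotone non-decreasing", {
  sim <- test_generations(seed = 5)
  for (code in c("A_1", "B_1", "C_0", "D_0", "E_0")) {
    fit <- fit_segregation(sim, code, seed = 1, n_starts = 2)
    tr <- fit$trace
    expect_true(all(diff(tr) >= -1e-8 * (1 + abs(tr[-length(tr)]))),
                label = paste("monotone trace for", code))
    # AIC identity, recomputed independently
    expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$n_par)
    # reported logLik agrees with the standalone likelihood
    expect_equal(seg_loglik(sim, code, fit$params), fit$logLik,
                 tolerance = 1e-6)
  }
})

test_that("saturated one-component fit reduces to sample means and pooled ML variance", {
  data <- tibble::tibble(
    generation = rep(c("P1", "P2"), c(20, 30)),
    value = c(rnorm_fixed <- local({
      set.seed(9)
      c(stats::rnorm(20, 100, 5), stats::rnorm(30, 40, 5))
    }))
  )
  # C_1 over P1 and P2 alone is a saturated two-mean Gaussian model
  fit <- fit_segregation(data, "C_1", seed = 1, n_starts = 1, tol = 1e-10)
  m1 <- mean(data$value[data$generation == "P1"])
  m2 <- mean(data$value[data$generation == "P2"])
  comp <- fit$components
  expect_equal(comp$mean[comp$generation == "P1"], m1, tolerance = 1e-6)
  expect_equal(comp$mean[comp$generation == "P2"], m2, tolerance = 1e-6)
  sse <- sum((data$value - ifelse(data$generation == "P1", m1, m2))^2)
  expect_equal(fit$params[["sigma2_e"]], sse / nrow(data), tolerance = 1e-6)
})

test_that("infinite tolerance returns the initialisation unchanged", {
  sim <- test_generations(seed = 6)
  init <- genetic_params(m = 85, d_a = 15, d_b = 20, h_a = -25, h_b = -5,
                         i = 1, j_ab = 2, j_ba = -3, l = 4,
                         sigma2_pg = 20, sigma2_e = 50)
  fit <- fit_segregation(sim, "E_0", inits = list(init), tol = Inf)
  expect_false(fit$converged)
  expect_equal(fit$iterations, 1L)
  expect_equal(unclass(fit$params), unclass(init), tolerance = 1e-12)
})

test_that("parameters of a single-gene model are recovered from simulation", {
  true_d <- 30
  hits <- vapply(1:20, function(s) {
    sim <- simulate_generations(
      "A_1", genetic_params(m = 80, d_a = true_d, h_a = -10, sigma2_e = 60),
      sizes = c(P1 = 300, P2 = 300, F1 = 300, BC1 = 300, BC2 = 300, F2 = 300),
      seed = 1000 + s
    )
    fit <- fit_segregation(sim, "A_1", seed = s, n_starts = 2)
    abs(fit$params[["d_a"]] - true_d) < 0.15 * true_d
  }, NA)
  expect_gte(mean(hits), 0.8)
})

test_that("nested models cannot beat their parent's likelihood", {
  sim <- test_generations(seed = 12)
  fit_small <- fit_segregation(sim, "C_1", seed = 1, n_starts = 2)
  # refit the larger model starting from the nested solution (EM ascent
  # then guarantees at least the nested likelihood)
  fit_large <- fit_segregation(sim, "C_0",
                               inits = list(fit_small$params, NULL)[1])
  expect_gte(fit_large$logLik, fit_small$logLik - 1e-6)
})

test_that("fit_all_models returns an AIC-sorted table and candidates", {
  sim <- test_generations(seed = 31)
  codes <- c("A_1", "B_1", "C_0", "E_0", "E_2")
  ms <- fit_all_models(sim, models = codes, seed = 1)
  expect_equal(nrow(ms), length(codes))
  expect_false(is.unsorted(ms$AIC))
  expect_equal(ms$delta_AIC[1], 0)
  expect_equal(candidate_models(ms, n = 2), ms$model[1:2])
  expect_error(fit_all_models(sim, models = c("E_0", "E_0")), "duplicate")
})

test_that("optimal-model selection minimises significant counts with AIC ties", {
  sim <- test_generations(seed = 31)
  ms <- fit_all_models(sim, models = c("B_1", "E_0", "E_2"), seed = 1)
  pick <- select_optimal_model(ms, candidates = c("E_0", "B_1", "E_2"),
                               counts = c(E_0 = 0, B_1 = 3, E_2 = 5))
  expect_equal(as.character(pick), "E_0")
  # all counts equal -> smallest AIC among candidates
  pick2 <- select_optimal_model(ms, candidates = c("E_0", "B_1", "E_2"),
                                counts = c(E_0 = 2, B_1 = 2, E_2 = 2))
  best_aic <- ms$model[ms$model %in% c("E_0", "B_1", "E_2")][1]
  expect_equal(as.character(pick2), best_aic)
  # single candidate -> itself
  pick3 <- select_optimal_model(ms, candidates = "E_2", counts = c(E_2 = 9))
  expect_equal(as.character(pick3), "E_2")
  expect_error(select_optimal_model(ms, candidates = character(0)), "empty")
})

test_that("unidentifiable model/generation combinations raise a rank error", {
  data <- tibble::tibble(generation = rep("P1", 10), value = rnorm(10))
  expect_error(fit_segregation(data, "E_0"), "rank deficient")
})

test_that("two-gene fits use the canonical gene labelling without changing fit", {
  sim <- test_generations(seed = 77)
  fit <- fit_segregation(sim, "E_0", seed = 2, n_starts = 2)
  # canonical order: gene a carries the smaller additive effect
  expect_lte(fit$params[["d_a"]],
             fit$params[["d_b"]] + 1e-3 * (abs(fit$params[["d_b"]]) + 1))
  # the exchanged labelling is likelihood-equivalent (exact symmetry)
  p <- as.list(fit$params)
  swapped <- p
  swapped[c("d_a", "d_b")] <- p[c("d_b", "d_a")]
  swapped[c("h_a", "h_b")] <- p[c("h_b", "h_a")]
  swapped[c("j_ab", "j_ba")] <- p[c("j_ba", "j_ab")]
  expect_equal(seg_loglik(sim, "E_0", do.call(genetic_params, swapped)),
               fit$logLik, tolerance = 1e-8)
})
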