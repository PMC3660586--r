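test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_generations("E_0", seedcolor_params(), seed = 7)
  b <- simulate_generations("E_0", seedcolor_params(), seed = 7)
  expect_identical(a, b)
  c <- simulate_generations("E_0", seedcolor_params(), seed = 8)
  expect_false(identical(a$value, c$value))
})

test_that("degenerate simulation returns the baseline exactly", {
  p <- genetic_params(m = 50, sigma2_e = 0)
  sim <- simulate_generations("E_0", p, sizes = c(P1 = 5, F2 = 10), seed = 1)
  expect_true(all(sim$value == 50))
})

test_that("F2 sample mean matches the closed-form mixture mean at large n", {
  p <- seedcolor_params()
  sim <- simulate_generations("E_0", p, sizes = c(F2 = 1e5), seed = 42)
  mu <- p[["m"]] + p[["h_a"]] / 2 + p[["h_b"]] / 2 + p[["l"]] / 4
  # within 3 standard errors of the closed-form mixture mean
  se <- stats::sd(sim$value) / sqrt(length(sim$value))
  expect_lt(abs(mean(sim$value) - mu), 3 * se)
})

test_that("negative variance is rejected; invalid sizes are rejected", {
  expect_error(genetic_params(sigma2_e = -1), "non-negative")
  expect_error(
    simulate_generations("E_0", seedcolor_params(), sizes = c(F2 = 0)),
    ">= 1"
  )
  expect_error(
    simulate_generations("E_0", seedcolor_params(), sizes = c(X1 = 10)),
    "named"
  )
})

test_that("binned summaries reproduce the published distribution shapes", {
  sim <- simulate_generations("E_0", seedcolor_params(), seed = 3)
  gm <- tapply(sim$value, sim$generation, mean)
  gs <- tapply(sim$value, sim$generation, sd)
  # non-segregating generations are tight; BC1/F2 wide
  expect_lt(max(gs[c("P1", "P2", "F1")]), 15)
  expect_gt(min(gs[c("BC1", "F2")]), 20)
  # BC2 concentrated near the recurrent low-value parent P2
  expect_lt(abs(gm[["BC2"]] - gm[["P2"]]), abs(gm[["BC2"]] - gm[["P1"]]))
  bins <- bin_phenotypes(sim)
  expect_true(all(c("replication", "generation", "bin_low", "count")
                  %in% names(bins)))
  expect_equal(sum(bins$count), nrow(sim))
})

test_that("F2 marker genotypes segregate 1:2:1 under simulation", {
  map <- tibble::tibble(group = "1", marker = c("a", "b"),
                        position = c(0, 20))
  sim <- simulate_cross(cross_design(map, NULL, n_f2 = 10000), seed = 21)
  counts <- table(factor(sim$genotypes$a, levels = 0:2))
  p <- distortion_test(as.integer(counts[c("2", "1", "0")]))$p_value
  expect_gt(p, 0.01)
})

test_that("zero map distance gives identical genotype columns", {
  map <- tibble::tibble(group = "1", marker = c("a", "b"),
                        position = c(5, 5))
  sim <- simulate_cross(cross_design(map, NULL, n_f2 = 500), seed = 2)
  expect_identical(sim$genotypes$a, sim$genotypes$b)
})

test_that("recombination fraction matches the Haldane map function", {
  map <- tibble::tibble(group = "1", marker = c("a", "b"),
                        position = c(0, 50))
  sim <- simulate_cross(cross_design(map, NULL, n_f2 = 10000), seed = 3)
  h <- sim$haplotypes[["1"]]
  rf <- mean(c(h$h1[, 1] != h$h1[, 2], h$h2[, 1] != h$h2[, 2]))
  truth <- rec_frac(50) # (1 - exp(-1))/2
  expect_equal(truth, (1 - exp(-1)) / 2, tolerance = 1e-12)
  se <- sqrt(truth * (1 - truth) / 20000)
  expect_lt(abs(rf - truth), 3 * se)
})

test_that("F3 family means for Qq parents approach m + d/2 under selfing", {
  # selfing a Qq plant gives QQ:Qq:qq = 1/4:1/2:1/4, so the expected family
  # value is m + a*0 + d/2
  map <- tibble::tibble(group = "1", marker = c("a", "b"),
                        position = c(0, 30))
  des <- cross_design(map,
                      qtl = tibble::tibble(group = "1", position = 15,
                                           a = 10, d = -6),
                      mean = 50, resid_var = 4, n_f2 = 400, f3_progeny = 200)
  sim <- simulate_cross(des, seed = 11)
  qq <- sim$qtl_genotypes[, 1]
  fam <- sim$phenotypes$f3_value[qq == 1]
  expect_gt(length(fam), 100)
  expect_lt(abs(mean(fam) - (50 - 6 / 2)), 3 * stats::sd(fam) / sqrt(length(fam)))
})

test_that("QTL positions off the map are rejected", {
  map <- tibble::tibble(group = "1", marker = c("a", "b"),
                        position = c(0, 30))
  expect_error(
    cross_design(map, tibble::tibble(group = "1", position = 45,
                                     a = 1, d = 0)),
    "outside"
  )
  expect_error(
    cross_design(map, tibble::tibble(group = "2", position = 10,
                                     a = 1, d = 0)),
    "not on the map"
  )
})
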