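test_that("registry holds the 24 catalogue models with unique codes", {
  reg <- genetic_models()
  expect_equal(nrow(reg), 24L)
  expect_false(anyDuplicated(reg$model) > 0)
  expect_setequal(unique(reg$class), c("A", "B", "C", "D", "E"))
  # class sizes of the catalogue
  expect_equal(unname(table(reg$class)[c("A", "B", "C", "D", "E")]),
               c(4L, 6L, 2L, 5L, 7L), ignore_attr = TRUE)
})

test_that("E_0 frees every effect and variance; C_0 has no major-gene effect", {
  reg <- genetic_models()
  e0 <- reg$free_params[[which(reg$model == "E_0")]]
  expect_true(all(c("m", "d_a", "d_b", "h_a", "h_b", "i", "j_ab", "j_ba",
                    "l", "sigma2_pg", "sigma2_e") %in% e0))
  c0 <- reg$free_params[[which(reg$model == "C_0")]]
  expect_false(any(c("d_a", "d_b", "h_a", "h_b", "i", "j_ab", "j_ba", "l")
                   %in% c0))
  expect_true("sigma2_pg" %in% c0)
})

test_that("generation mixture structure follows Mendelian expectations", {
  f2 <- generation_spec("E_0", "F2")
  expect_equal(nrow(f2), 9L)
  expect_equal(sort(f2$frequency * 16), c(1, 1, 1, 1, 2, 2, 2, 2, 4))
  bc1 <- generation_spec("E_0", "BC1")
  expect_equal(nrow(bc1), 4L)
  expect_setequal(bc1$genotype, c("AABB", "AABb", "AaBB", "AaBb"))
  bc2 <- generation_spec("E_0", "BC2")
  expect_setequal(bc2$genotype, c("AaBb", "Aabb", "aaBb", "aabb"))
  for (g in c("P1", "P2", "F1")) {
    expect_equal(nrow(generation_spec("E_0", g)), 1L)
  }
  expect_error(generation_spec("E_0", "F4"), "unknown generation")
})

test_that("component frequencies sum to one for every model and generation", {
  for (code in genetic_models()$model) {
    for (g in c("P1", "P2", "F1", "BC1", "BC2", "F2")) {
      expect_equal(sum(generation_spec(code, g)$frequency), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("single-component means match the parental/F1 expectations", {
  p <- genetic_params(m = 10, d_a = 3, d_b = 5, h_a = -2, h_b = 1,
                      i = 0.5, j_ab = 0.25, j_ba = -0.25, l = 2,
                      sigma2_pg = 1, sigma2_e = 1)
  eff <- p[segqtl:::seg_effect_names()]
  mean_of <- function(gen) {
    spec <- generation_spec("E_0", gen)
    as.vector(as.matrix(spec[, segqtl:::seg_effect_names()]) %*% eff)
  }
  expect_equal(mean_of("P1"), 10 + 3 + 5 + 0.5)       # AABB: m+d_a+d_b+i
  expect_equal(mean_of("P2"), 10 - 3 - 5 + 0.5)       # aabb: m-d_a-d_b+i
  expect_equal(mean_of("F1"), 10 - 2 + 1 + 2)         # AaBb: m+h_a+h_b+l
})

test_that("zero-effect degeneracy collapses all F2 component means to m", {
  p <- genetic_params(m = 42, sigma2_e = 1)
  spec <- generation_spec("E_0", "F2")
  mu <- as.vector(as.matrix(spec[, segqtl:::seg_effect_names()]) %*%
                    p[segqtl:::seg_effect_names()])
  expect_equal(mu, rep(42, 9))
})

test_that("BC1 and F2 mixture means match brute-force component averages", {
  p <- genetic_params(m = 7, d_a = 1.5, d_b = -2.5, h_a = 4, h_b = 0.5,
                      i = -1, j_ab = 2, j_ba = -3, l = 1.25,
                      sigma2_pg = 1, sigma2_e = 1)
  # brute-force oracle = frequency-weighted average in mixture_mean()
  bc1 <- mixture_mean("E_0", "BC1", p)
  expect_equal(
    bc1,
    7 + (1.5 + 4) / 2 + (-2.5 + 0.5) / 2 + (-1 + 2 + (-3) + 1.25) / 4
  )
  f2 <- mixture_mean("E_0", "F2", p)
  expect_equal(f2, 7 + 4 / 2 + 0.5 / 2 + 1.25 / 4)
})

test_that("without dominance or epistasis the F1 mean is the midparent value", {
  p <- genetic_params(m = 12, d_a = 4, d_b = 2, sigma2_e = 1)
  expect_equal(mixture_mean("E_0", "F1", p), 12)
  expect_equal(
    (mixture_mean("E_0", "P1", p) + mixture_mean("E_0", "P2", p)) / 2, 12
  )
})

test_that("model constraints are enforced on parameter vectors", {
  expect_silent(segqtl:::validate_params("A_2", genetic_params(
    m = 5, d_a = 2, sigma2_e = 1)))
  # A_2 is additive-only: a dominance effect violates it
  expect_error(segqtl:::validate_params("A_2", genetic_params(
    m = 5, d_a = 2, h_a = 1, sigma2_e = 1)), "constraints")
  # A_3 ties h_a = d_a
  expect_silent(segqtl:::validate_params("A_3", genetic_params(
    m = 5, d_a = 2, h_a = 2, sigma2_e = 1)))
  expect_error(segqtl:::validate_params("A_3", genetic_params(
    m = 5, d_a = 2, h_a = 1, sigma2_e = 1)), "constraints")
  expect_error(segqtl:::validate_params("B_1", genetic_params(
    m = 5, d_a = 2, sigma2_pg = 3, sigma2_e = 1)), "sigma2_pg")
})
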