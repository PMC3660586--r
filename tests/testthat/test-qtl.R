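test_that("QTL genotype probabilities handle markers, priors and enumeration", {
  # on a marker typed Aa: certainty
  expect_equal(unname(qtl_genotype_probs(1, 1, 0, 10)[1, ]), c(0, 1, 0))
  expect_equal(unname(qtl_genotype_probs(2, 2, 0, 10)[1, ]), c(1, 0, 0))
  # both flanks missing: Mendelian prior
  expect_equal(unname(qtl_genotype_probs(NA, NA, 5, 5)[1, ]),
               c(0.25, 0.5, 0.25))
  # midpoint of a 20 cM interval with AA/AA flanks: brute-force enumeration
  # over gamete haplotypes (two independent gametes, no interference)
  r1 <- rec_frac(10); r2 <- rec_frac(10); r12 <- r1 + r2 - 2 * r1 * r2
  pQ_gamete <- (1 - r1) * (1 - r2) / (1 - r12) # P(gamete Q | A...A flanks)
  oracle <- c(pQ_gamete^2, 2 * pQ_gamete * (1 - pQ_gamete),
              (1 - pQ_gamete)^2)
  expect_equal(unname(qtl_genotype_probs(2, 2, 10, 10)[1, ]), oracle,
               tolerance = 1e-12)
  # rows always sum to one
  for (l in c(0:2, NA)) for (r in c(0:2, NA)) {
    expect_equal(sum(qtl_genotype_probs(l, r, 7, 13)), 1, tolerance = 1e-12)
  }
})

test_that("a strong simulated QTL is localised with correct effect signs", {
  des <- test_qtl_design()
  sim <- simulate_cross(des, seed = 5)
  sc <- cim_scan(sim$phenotypes$f2_value, sim$genotypes, des$map)
  pk <- sc[which.max(sc$lod), ]
  expect_equal(pk$group, "LG2")
  expect_lt(abs(pk$position - 27), 5)
  expect_gt(pk$additive, 0)
  expect_lt(pk$dominance, 0)
  expect_true(all(sc$lod >= 0))
  expect_true(all(sc$r2 >= 0 & sc$r2 <= 1))
})

test_that("LOD profile is invariant to affine rescaling of the phenotype", {
  des <- test_qtl_design(n_f2 = 150)
  sim <- simulate_cross(des, seed = 8)
  y <- sim$phenotypes$f2_value
  sc1 <- cim_scan(y, sim$genotypes, des$map, step = 5)
  sc2 <- cim_scan(3.2 * y - 40, sim$genotypes, des$map, step = 5)
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-8)
  expect_equal(sc1$r2, sc2$r2, tolerance = 1e-8)
})

test_that("without cofactors the scan at markers equals direct regression", {
  des <- test_qtl_design(n_f2 = 200)
  sim <- simulate_cross(des, seed = 13)
  y <- sim$phenotypes$f2_value
  sc <- cim_scan(y, sim$genotypes, des$map, step = 5, n_cofactors = 0)
  # oracle: plain interval-mapping regression on the marker's own scores
  G <- as.matrix(sim$genotypes[, -1])
  for (mk in c("LG2_m6", "LG3_m1")) {
    gmk <- G[, mk]
    x <- gmk - 1
    z <- as.numeric(gmk == 1)
    full <- stats::lm(y ~ x + z)
    red <- stats::lm(y ~ 1)
    lod_oracle <- (length(y) / 2) *
      log10(sum(red$residuals^2) / sum(full$residuals^2))
    info <- des$map[des$map$marker == mk, ]
    row <- sc[sc$group == info$group & abs(sc$position - info$position) < 1e-9, ]
    expect_equal(row$lod, lod_oracle, tolerance = 1e-8)
    expect_equal(row$additive, unname(stats::coef(full)["x"]),
                 tolerance = 1e-8)
  }
})

test_that("monomorphic genotype columns give zero LOD at their position", {
  map <- tibble::tibble(group = "1", marker = c("a", "b"),
                        position = c(0, 10))
  geno <- tibble::tibble(id = 1:50, a = rep(1L, 50),
                         b = rep(c(0L, 1L, 2L), length.out = 50))
  set.seed(4)
  y <- stats::rnorm(50)
  sc <- cim_scan(y, geno, map, step = 10, n_cofactors = 0)
  expect_equal(sc$lod[sc$position == 0], 0, tolerance = 1e-9)
})

test_that("permutation thresholds are deterministic and edge quantiles work", {
  des <- test_qtl_design(n_f2 = 120)
  sim <- simulate_cross(des, seed = 17)
  y <- sim$phenotypes$f2_value
  t1 <- permutation_threshold(y, sim$genotypes, des$map, n_perm = 30,
                              seed = 3, step = 10)
  t2 <- permutation_threshold(y, sim$genotypes, des$map, n_perm = 30,
                              seed = 3, step = 10)
  expect_identical(t1, t2)
  tmin <- permutation_threshold(y, sim$genotypes, des$map, n_perm = 30,
                                alpha = 1, seed = 3, step = 10)
  expect_equal(as.numeric(tmin), min(attr(tmin, "max_lods")))
  expect_error(permutation_threshold(y, sim$genotypes, des$map, n_perm = 1),
               "at least")
})

test_that("declared QTL respect the threshold and support intervals", {
  des <- test_qtl_design()
  sim <- simulate_cross(des, seed = 23)
  sc <- cim_scan(sim$phenotypes$f2_value, sim$genotypes, des$map)
  q <- declare_qtl(sc, threshold = 5)
  expect_gte(nrow(q), 1)
  expect_true(all(q$lod > 5))
  expect_true(all(q$interval_lo <= q$position & q$position <= q$interval_hi))
  none <- declare_qtl(sc, threshold = max(sc$lod) + 1)
  expect_equal(nrow(none), 0)
})

test_that("single-marker ANOVA matches a hand-computed decomposition", {
  # 9 values 1..9 in three classes of three
  vals <- 1:9
  cls <- rep(c(0, 1, 2), each = 3)
  res <- single_marker_anova(vals, cls)
  # brute-force sums of squares
  gm <- mean(vals)
  ssb <- sum(3 * (tapply(vals, cls, mean) - gm)^2)
  ssw <- sum((vals - rep(tapply(vals, cls, mean), each = 3))^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$f_value, f_oracle, tolerance = 1e-12)
  expect_equal(res$r2, ssb / (ssb + ssw), tolerance = 1e-12)
  expect_equal(res$p_value,
               stats::pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # agreement with the stats::anova oracle on a regular sample
  set.seed(8)
  yv <- stats::rnorm(30)
  gv <- sample(0:2, 30, TRUE)
  mine <- single_marker_anova(yv, gv)
  ref <- stats::anova(stats::lm(yv ~ factor(gv)))
  expect_equal(mine$f_value, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)
  # perfect separation
  sep <- single_marker_anova(c(0, 0, 1, 1), c(0, 0, 2, 2))
  expect_equal(sep$r2, 1)
  # equal class means with within-class spread
  eq <- single_marker_anova(c(1, 9, 1, 9), c(0, 0, 2, 2))
  expect_equal(eq$r2, 0)
  expect_gte(eq$p_value, 0.99)
  expect_error(single_marker_anova(1:5, rep(1, 5)), "two genotype classes")
})

test_that("f3_phenotype is the family mean with edge handling", {
  expect_equal(f3_phenotype(c(10, 20, 30)), 20)
  expect_equal(f3_phenotype(7), 7)
  expect_error(f3_phenotype(numeric(0)), "empty")
})

test_that("markers missing from the map are reported by name", {
  des <- test_qtl_design(n_f2 = 60)
  sim <- simulate_cross(des, seed = 2)
  geno <- sim$genotypes
  names(geno)[2] <- "rogue_marker"
  expect_error(cim_scan(sim$phenotypes$f2_value, geno, des$map),
               "rogue_marker")
})
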