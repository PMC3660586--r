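# Catalogue of major-gene + polygene mixed inheritance models and the
# constrained normal-mixture structure each model implies for the six
# classical generations of a biparental cross.

# Effect parameters, in the fixed order used by every coefficient matrix:
#   m     population-mean baseline
#   d_a   additive effect of major gene a        h_a  dominance effect of a
#   d_b   additive effect of major gene b        h_b  dominance effect of b
#   i     additive x additive epistasis
#   j_ab  additive(a) x dominance(b)             j_ba dominance(a) x additive(b)
#   l     dominance x dominance
#   d_pg  collective polygene additive mean effect (C-class and D_4 only)
#   h_pg  collective polygene dominance mean effect
seg_effect_names <- function() {
  c("m", "d_a", "d_b", "h_a", "h_b", "i", "j_ab", "j_ba", "l", "d_pg", "h_pg")
}

seg_generations <- function() c("P1", "P2", "F1", "BC1", "BC2", "F2")

# Two-locus genotype mean coefficients with P1 = AABB carrying the
# increasing alleles.  Additive codes: AA = +1, Aa = 0, aa = -1; dominance
# codes: Aa = 1, homozygote = 0; epistatic coefficients are products.
.geno2_coeffs <- function() {
  g <- expand.grid(a = c("AA", "Aa", "aa"), b = c("BB", "Bb", "bb"),
                   stringsAsFactors = FALSE)
  add <- c(AA = 1, Aa = 0, aa = -1, BB = 1, Bb = 0, bb = -1)
  dom <- c(AA = 0, Aa = 1, aa = 0, BB = 0, Bb = 1, bb = 0)
  out <- matrix(0, nrow(g), length(seg_effect_names()),
                dimnames = list(paste0(g$a, g$b), seg_effect_names()))
  out[, "m"] <- 1
  out[, "d_a"] <- add[g$a]
  out[, "h_a"] <- dom[g$a]
  out[, "d_b"] <- add[g$b]
  out[, "h_b"] <- dom[g$b]
  out[, "i"] <- add[g$a] * add[g$b]
  out[, "j_ab"] <- add[g$a] * dom[g$b]
  out[, "j_ba"] <- dom[g$a] * add[g$b]
  out[, "l"] <- dom[g$a] * dom[g$b]
  out
}

.geno1_coeffs <- function() {
  out <- matrix(0, 3, length(seg_effect_names()),
                dimnames = list(c("AA", "Aa", "aa"), seg_effect_names()))
  out[, "m"] <- 1
  out[, "d_a"] <- c(1, 0, -1)
  out[, "h_a"] <- c(0, 1, 0)
  out
}

# Collective polygene mean contribution of each generation under the
# additive-dominance polygene expectation (selfing/backcross algebra).
.polygene_mean_coeffs <- function() {
  rbind(
    P1  = c(d_pg = 1,    h_pg = 0),
    P2  = c(d_pg = -1,   h_pg = 0),
    F1  = c(d_pg = 0,    h_pg = 1),
    BC1 = c(d_pg = 0.5,  h_pg = 0.5),
    BC2 = c(d_pg = -0.5, h_pg = 0.5),
    F2  = c(d_pg = 0,    h_pg = 0.5)
  )
}

# Polygenic-variance multiplier per generation: non-segregating generations
# carry none, first backcrosses half, F2 the full additive polygene variance.
polygene_variance_coeff <- function(generation) {
  c(P1 = 0, P2 = 0, F1 = 0, BC1 = 0.5, BC2 = 0.5, F2 = 1)[generation]
}

# Mendelian mixture composition (genotype labels + frequencies) per
# generation for two, one, or zero segregating major genes.
.generation_components <- function(n_major, generation) {
  if (n_major == 2L) {
    switch(generation,
      P1 = list(g = "AABB", f = 1),
      P2 = list(g = "aabb", f = 1),
      F1 = list(g = "AaBb", f = 1),
      BC1 = list(g = c("AABB", "AABb", "AaBB", "AaBb"), f = rep(1 / 4, 4)),
      BC2 = list(g = c("AaBb", "Aabb", "aaBb", "aabb"), f = rep(1 / 4, 4)),
      F2 = {
        a <- c(AA = 1 / 4, Aa = 1 / 2, aa = 1 / 4)
        b <- c(BB = 1 / 4, Bb = 1 / 2, bb = 1 / 4)
        g <- as.vector(outer(names(a), names(b), paste0))
        list(g = g, f = as.vector(outer(a, b)))
      }
    )
  } else if (n_major == 1L) {
    switch(generation,
      P1 = list(g = "AA", f = 1),
      P2 = list(g = "aa", f = 1),
      F1 = list(g = "Aa", f = 1),
      BC1 = list(g = c("AA", "Aa"), f = c(1 / 2, 1 / 2)),
      BC2 = list(g = c("Aa", "aa"), f = c(1 / 2, 1 / 2)),
      F2 = list(g = c("AA", "Aa", "aa"), f = c(1 / 4, 1 / 2, 1 / 4))
    )
  } else {
    list(g = "poly", f = 1)
  }
}

.new_model <- function(code, class, n_major, free, ties = NULL, description) {
  eff <- seg_effect_names()
  map <- matrix(0, length(eff), length(free), dimnames = list(eff, free))
  for (f in free) map[f, f] <- 1
  for (target in names(ties)) {
    src <- ties[[target]]
    sgn <- 1
    if (startsWith(src, "-")) {
      sgn <- -1
      src <- substring(src, 2L)
    }
    map[target, src] <- sgn
  }
  polygene <- class %in% c("C", "D", "E")
  structure(list(
    code = code, class = class, n_major = n_major, free = free,
    ties = ties, map = map, polygene_variance = polygene,
    n_par = length(free) + 1L + as.integer(polygene),
    description = description
  ), class = "seg_model")
}

# The 24-model registry.  Only the full two-major-gene
# additive-dominant-epistatic + polygene model (E_0) is pinned down by the
# analysis this catalogue supports; the remaining constraint sets follow the
# standard joint segregation-analysis catalogue (additive-dominance AD,
# additive-only A, equal-additive EA, complete dominance CD h = d, negative
# complete dominance NCD h = -d) and are an editable, documented
# interpretation rather than a canonical definition.
.build_registry <- function() {
  two_free <- c("m", "d_a", "d_b", "h_a", "h_b")
  full_free <- c(two_free, "i", "j_ab", "j_ba", "l")
  models <- list(
    .new_model("A_1", "A", 1L, c("m", "d_a", "h_a"),
               description = "one major gene, additive-dominance"),
    .new_model("A_2", "A", 1L, c("m", "d_a"),
               description = "one major gene, additive"),
    .new_model("A_3", "A", 1L, c("m", "d_a"), ties = c(h_a = "d_a"),
               description = "one major gene, complete dominance"),
    .new_model("A_4", "A", 1L, c("m", "d_a"), ties = c(h_a = "-d_a"),
               description = "one major gene, negative complete dominance"),
    .new_model("B_1", "B", 2L, full_free,
               description = "two major genes, additive-dominance-epistasis"),
    .new_model("B_2", "B", 2L, two_free,
               description = "two major genes, additive-dominance"),
    .new_model("B_3", "B", 2L, c("m", "d_a", "d_b"),
               description = "two major genes, additive"),
    .new_model("B_4", "B", 2L, c("m", "d_a"), ties = c(d_b = "d_a"),
               description = "two major genes, equal additive"),
    .new_model("B_5", "B", 2L, c("m", "d_a", "d_b"),
               ties = c(h_a = "d_a", h_b = "d_b"),
               description = "two major genes, complete dominance"),
    .new_model("B_6", "B", 2L, c("m", "d_a", "d_b"),
               ties = c(h_a = "-d_a", h_b = "-d_b"),
               description = "two major genes, negative complete dominance"),
    .new_model("C_0", "C", 0L, c("m", "d_pg", "h_pg"),
               description = "polygenes, additive-dominance"),
    .new_model("C_1", "C", 0L, c("m", "d_pg"),
               description = "polygenes, additive"),
    .new_model("D_0", "D", 1L, c("m", "d_a", "h_a"),
               description = "one major gene (AD) + polygenes"),
    .new_model("D_1", "D", 1L, c("m", "d_a"),
               description = "one major gene (additive) + polygenes"),
    .new_model("D_2", "D", 1L, c("m", "d_a"), ties = c(h_a = "d_a"),
               description = "one major gene (complete dominance) + polygenes"),
    .new_model("D_3", "D", 1L, c("m", "d_a"), ties = c(h_a = "-d_a"),
               description = "one major gene (negative CD) + polygenes"),
    .new_model("D_4", "D", 1L, c("m", "d_a", "h_a", "d_pg", "h_pg"),
               description = "one major gene (AD) + polygenes with mean effects"),
    .new_model("E_0", "E", 2L, full_free,
               description = "two major genes (ADI) + polygenes"),
    .new_model("E_1", "E", 2L, two_free,
               description = "two major genes (AD) + polygenes"),
    .new_model("E_2", "E", 2L, c("m", "d_a", "d_b"),
               description = "two major genes (additive) + polygenes"),
    .new_model("E_3", "E", 2L, c("m", "d_a"), ties = c(d_b = "d_a"),
               description = "two major genes (equal additive) + polygenes"),
    .new_model("E_4", "E", 2L, c("m", "d_a", "d_b"),
               ties = c(h_a = "d_a", h_b = "d_b"),
               description = "two major genes (complete dominance) + polygenes"),
    .new_model("E_5", "E", 2L, c("m", "d_a", "d_b"),
               ties = c(h_a = "-d_a", h_b = "-d_b"),
               description = "two major genes (negative CD) + polygenes"),
    .new_model("E_6", "E", 2L, c("m", "d_a", "h_a"),
               ties = c(d_b = "d_a", h_b = "h_a"),
               description = "two major genes (equal AD) + polygenes")
  )
  names(models) <- vapply(models, `[[`, "", "code")
  if (anyDuplicated(names(models))) {
    rlang::abort("duplicate model codes in registry")
  }
  models
}

.registry_env <- new.env(parent = emptyenv())

seg_registry <- function() {
  if (is.null(.registry_env$models)) {
    .registry_env$models <- .build_registry()
  }
  .registry_env$models
}

#' Retrieve one inheritance model from the registry
#'
#' @param model A model code such as `"E_0"`, or a `seg_model` object
#'   (returned unchanged).
#' @return A `seg_model` object: code, class, number of major genes, free
#'   effect parameters, equality constraints, and the linear map from free
#'   parameters to the full effect vector.
#' @export
get_model <- function(model) {
  if (inherits(model, "seg_model")) {
    return(model)
  }
  reg <- seg_registry()
  if (!is.character(model) || length(model) != 1L || !model %in% names(reg)) {
    rlang::abort(paste0(
      "unknown model code; available codes: ",
      paste(names(reg), collapse = ", ")
    ))
  }
  reg[[model]]
}

#' List the catalogue of major-gene + polygene inheritance models
#'
#' The catalogue holds 24 models in five classes: one major gene (A), two
#' major genes (B), polygenes only (C), one major gene plus polygenes (D) and
#' two major genes plus polygenes (E).  Within a class, variants constrain
#' the effect set (additive-dominance, additive-only, equal-additive,
#' complete or negative-complete dominance, with or without epistasis).
#' `E_0`, the full two-major-gene additive-dominant-epistatic + polygene
#' model, is the least constrained member.
#'
#' @return A tibble with one row per model: `model`, `class`, `n_major`,
#'   `polygene_variance`, `n_par` (free parameters counted for AIC, i.e.
#'   free genetic effects + baseline + free variances), `free_params`
#'   (list-column of free effect names) and `description`.
#' @examples
#' genetic_models()
#' @export
genetic_models <- function() {
  reg <- seg_registry()
  tibble::tibble(
    model = vapply(reg, `[[`, "", "code"),
    class = vapply(reg, `[[`, "", "class"),
    n_major = vapply(reg, `[[`, 0L, "n_major"),
    polygene_variance = vapply(reg, `[[`, NA, "polygene_variance"),
    n_par = vapply(reg, `[[`, 0L, "n_par"),
    free_params = lapply(reg, function(m) {
      c(m$free, "sigma2_e", if (m$polygene_variance) "sigma2_pg")
    }),
    description = vapply(reg, `[[`, "", "description")
  )
}

#' Mixture structure implied by a model for one generation
#'
#' For a two-major-gene model the F2 segregates into the nine two-locus
#' genotype classes at Mendelian (1:2:1) x (1:2:1) frequencies, the first
#' backcrosses into four classes at 1/4 each, and P1/P2/F1 are single
#' components (AABB, aabb, AaBb).  One-major-gene models use the analogous
#' three-class table; polygene-only models have a single component per
#' generation whose mean carries the collective polygene effects.
#'
#' @param model Model code or `seg_model` object.
#' @param generation One of `"P1","P2","F1","BC1","BC2","F2"`.
#' @return A tibble with one row per mixture component: `generation`,
#'   `genotype`, `frequency`, `c_pg` (multiplier of the polygenic variance in
#'   the within-component variance) and one coefficient column per effect
#'   parameter, so that the component mean is the inner product of the
#'   coefficients with the effect vector.
#' @examples
#' generation_spec("E_0", "F2")
#' @export
generation_spec <- function(model, generation) {
  mod <- get_model(model)
  if (!is.character(generation) || length(generation) != 1L ||
      !generation %in% seg_generations()) {
    rlang::abort(paste0(
      "unknown generation label '", paste(generation, collapse = ","),
      "'; expected one of ", paste(seg_generations(), collapse = ", ")
    ))
  }
  comp <- .generation_components(mod$n_major, generation)
  base <- switch(as.character(mod$n_major),
    "2" = .geno2_coeffs(),
    "1" = .geno1_coeffs(),
    "0" = {
      z <- matrix(0, 1, length(seg_effect_names()),
                  dimnames = list("poly", seg_effect_names()))
      z[, "m"] <- 1
      z
    }
  )
  coeffs <- base[comp$g, , drop = FALSE]
  pg <- .polygene_mean_coeffs()[generation, ]
  coeffs[, "d_pg"] <- pg[["d_pg"]]
  coeffs[, "h_pg"] <- pg[["h_pg"]]
  out <- tibble::tibble(
    generation = generation,
    genotype = comp$g,
    frequency = comp$f,
    c_pg = unname(polygene_variance_coeff(generation))
  )
  dplyr::bind_cols(out, tibble::as_tibble(coeffs))
}

# All components of all (requested) generations, as a list with the pieces
# the EM machinery needs: frequencies, raw 11-column coefficient matrix and
# the model-reduced design (coefficients %*% map).
component_blocks <- function(model, generations = seg_generations()) {
  mod <- get_model(model)
  lapply(stats::setNames(generations, generations), function(g) {
    spec <- generation_spec(mod, g)
    coeff <- as.matrix(spec[, seg_effect_names()])
    list(
      generation = g,
      genotype = spec$genotype,
      frequency = spec$frequency,
      c_pg = spec$c_pg[1L],
      coeff = coeff,
      design = coeff %*% mod$map
    )
  })
}

#' Component table for a model across generations
#'
#' @inheritParams generation_spec
#' @param generations Character vector of generation labels.
#' @return A tibble binding [generation_spec()] rows for the requested
#'   generations.
#' @export
component_table <- function(model, generations = seg_generations()) {
  dplyr::bind_rows(lapply(generations, function(g) generation_spec(model, g)))
}
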