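---
title: "Joint segregation analysis and QTL mapping of a quantitative seed-colour trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint segregation analysis and QTL mapping of a quantitative seed-colour trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segqtl)
```

## The model

Seed-coat colour in sesame, measured as an RGB intensity, behaves as a
quantitative trait: continuous within generations, transgressive and
multimodal in segregating ones. `segqtl` implements the classical joint
(multi-generation) segregation-analysis framework for such traits: the
phenotype of a plant in generation $g$ is

$$x \sim \sum_j \pi_{gj}\, N\!\left(\mu_{gj},\; \sigma^2_e + c_g \sigma^2_{pg}\right),$$

where the mixture components $j$ are the major-gene genotype classes of
that generation, $\pi_{gj}$ their Mendelian frequencies (fixed, not
estimated), and every component mean is linear in the genetic effects.
For two major genes with P1 = AABB carrying the increasing alleles, the
nine F2 genotype means follow the standard two-locus table — e.g.
$\mu_{AABB} = m + d_a + d_b + i$, $\mu_{AaBb} = m + h_a + h_b + l$,
$\mu_{aabb} = m - d_a - d_b + i$ — with additive effects $d_a, d_b$,
dominance effects $h_a, h_b$ and epistatic effects $i$ (add×add),
$j_{ab}$, $j_{ba}$ (add×dom) and $l$ (dom×dom). Polygenes contribute a
Gaussian variance component $\sigma^2_{pg}$ whose generation multiplier
$c_g$ is 0 for P1/P2/F1, 1/2 for the first backcrosses and 1 for the F2
(the additive expectation for selfed/backcrossed polygenes; the framework
literature does not print these values, so they are fixed here once and
documented).

### The 24-model catalogue

Models fall into five classes: one major gene (A), two major genes (B),
polygenes only (C), one major gene + polygenes (D), two major genes +
polygenes (E). Within a class, variants constrain the effect set:
additive–dominance, additive-only, equal-additive, complete dominance
($h = d$), negative complete dominance ($h = -d$), with or without
epistasis. Only the full model E_0 — two major genes with
additive–dominant–epistatic effects plus polygenes — is pinned down
unambiguously by the analysis this catalogue supports; the constraint
sets of the other 23 variants follow the standard catalogue of the joint
segregation-analysis literature and are encoded in `genetic_models()` as
a documented, editable interpretation rather than a canonical definition.
For the polygene-only class C the collective polygene mean effects
$[d_{pg}], [h_{pg}]$ parameterise the generation means
(P1: $m + d_{pg}$, F1: $m + h_{pg}$, F2: $m + h_{pg}/2$, …); for the D/E
classes the polygene contribution to generation means is absorbed into
$m$ and the polygenes act through the variance only (D_4, which frees the
polygene mean effects alongside a single major gene, is the one
exception).

## Fitting: IECM

Each model is fitted by an iterated expectation–conditional-maximisation
algorithm:

* **E-step** — posterior component memberships
  $w_{gij} \propto \pi_{gj}\,\phi(x_{gi}; \mu_{gj}, \sigma^2_g)$.
* **CM-step (a)** — the free effect vector solves a weighted least-squares
  problem: posterior component means regressed on the model's
  mean-coefficient design (equality constraints such as $h_a = d_a$ are a
  linear reparameterisation, so the step stays exact).
* **CM-step (b)** — $(\sigma^2_e, \sigma^2_{pg})$ maximise the expected
  complete-data likelihood under the $\sigma^2_e + c_g \sigma^2_{pg}$
  structure; with no polygenic component this is a closed form, otherwise
  a bounded quasi-Newton step that is only accepted when it improves the
  objective, so the EM ascent property is preserved either way.

Frequencies stay fixed at their Mendelian values throughout — they are
not free parameters in this framework. The log-likelihood is therefore
non-decreasing across iterations (asserted in the tests for every fit).

Numerical choices, each made once:

* convergence when the absolute log-likelihood increase falls below
  `tol = 1e-6`, capped at 2000 iterations;
* a variance floor of $10^{-8}\times$ the overall phenotype variance
  guards against component collapse; hitting it flags the fit as a
  boundary solution rather than an error;
* starts: a deterministic method-of-moments initialisation ($m$ from the
  midparent, additive effects from the parental spread, dominance from
  the F1 deviation) plus seeded multiplicative jitters. `fit_segregation()`
  uses 5 starts; `fit_all_models()` screens the catalogue with 2, because
  the moment start is deterministic and the structured means leave little
  room for label-switching;
* AIC counts free genetic effects + baseline + free variances; because
  the catalogue's exact per-variant parameter counts are an
  interpretation (above), absolute AIC values are comparable within this
  package but not across implementations.

Two-major-gene mixtures are exactly invariant under exchanging the gene
labels ($d_a, h_a, j_{ab} \leftrightarrow d_b, h_b, j_{ba}$): every
generation's component set maps onto itself, so both labellings have
identical likelihood. Fits are therefore reported in a canonical
labelling — gene *a* is the gene with the smaller additive effect, and on
the near-equal-additive ridge (where the pairing is identified only
through dominance) the smaller dominance effect breaks the tie. A related
practical caveat: the *sums* $d_a + d_b$ and $h_a + h_b + l$ are
estimated much more precisely than the individual effects, so individual
two-gene effects at moderate sample sizes should be read with care.

Model choice follows the published workflow: candidate models are the
five smallest by AIC (`candidate_models()`), and among candidates the
optimal model minimises the number of significant goodness-of-fit
statistics, with AIC breaking ties (`select_optimal_model()`).

## Goodness of fit

Each generation's fitted mixture CDF maps its observations to $[0,1]$
(probability-integral transform); under a correct model these are
uniform. Five statistics per generation: the first three Neyman-smooth
components $U_k^2$, $U_k = \sqrt{n}\,\overline{\sqrt{2k+1}\,P_k(2y-1)}$
with Legendre polynomials $P_k$ (location, dispersion and skewness
departures; asymptotically $\chi^2_1$), the Cramér–von Mises statistic
$W^2$ with its classical asymptotic distribution (implemented in-package
as the Bessel-K series), and the Kolmogorov statistic via
`stats::ks.test()`. The battery names U₁²–U₃² as the uniformity-moment
construction; the literature that names these statistics does not define
them, so this realisation is documented as an interpretation. All five
are calibrated to a type-I error near $\alpha = 0.05$ at $n = 200$
(checked by simulation in the tests).

## Genetic effects and heritability

First-order effects solve ordinary least squares of the fitted component
means against the mean-coefficient design over all distinct components
(exact recovery when the means are consistent; rank deficiencies are
reported by column). Second-order components per segregating generation:
$\sigma^2_p$ is the sample variance, $\sigma^2$ the df-weighted pooled
variance of P1/P2/F1 (the published tables show one shared environmental
variance per replication but not its formula — pooling is this package's
choice), $\sigma^2_{pg} = c_g \hat\sigma^2_{pg}$ from the fit (the
alternative — variance differencing — is not used), and
$\sigma^2_{mg} = \sigma^2_p - \sigma^2_{pg} - \sigma^2$ truncated at zero
with the truncated mass reported. Heritabilities are percentage ratios;
additivity $\sigma^2_p = \sigma^2_{mg} + \sigma^2_{pg} + \sigma^2$ holds
by construction modulo the reported truncation.

## Composite interval mapping

The scan is a Haley–Knott-style regression approximation of CIM: full
mixture maximum likelihood at every grid point is replaced by regression
on the expected additive score $x = P(QQ) - P(qq)$ and dominance score
$z = P(Qq)$, conditional on the nearest informative flanking markers
under no interference (the conditional probabilities are exact gamete
enumerations; missing flanks fall back to the next informative marker or
the 1:2:1 prior — never row deletion, so $n$ is constant along the
genome). This diverges from the reference software's internal Model-6
likelihood machinery, which is not published; at the effect sizes of
interest the two are materially equivalent. Settings mirror the
published analysis: 1-cM step, 10-cM cofactor exclusion window, up to 5
cofactors chosen by forward–backward stepwise regression (entry/stay
p = 0.05 — the "four parameters" of the original stepwise configuration
are not itemised in print, so the conventional thresholds are used).
LOD $= (n/2)\log_{10}(\mathrm{RSS}_{red}/\mathrm{RSS}_{full})$; $r^2$ is
the share of the total sum of squares explained by the QTL term; support
intervals are 1-LOD drops (the published tables print marker intervals
without defining them). Genome-wide thresholds come from phenotype
permutations with full cofactor re-selection per permutation. The
mixed-model joint-environment machinery of the complementary MCIM
analysis (epistatic networks, G×E) is out of scope; per-environment scans
substitute.

## The simulators

`simulate_generations()` draws each plant's genotype class at its
Mendelian frequency and its phenotype from the implied normal component —
exactly the structure the analysis assumes. Defaults are the study
conditions of the reference cross: effect magnitudes are the published
across-replication averages ($d_a = 20.30$, $d_b = 25.09$,
$h_a = -35.94$, $h_b = -9.35$, $i = 2.97$, $j_{ab} = 7.76$,
$j_{ba} = -18.72$, $l = 17.87$ RGB units), $\sigma^2_e = 60.49$ (the
published shared estimate), and per-generation sizes matching the field
design (≈28 parental/F1 plants, ≈185–306 per segregating generation).
Two quantities the published tables do not pin down consistently are
fixed once: the baseline $m = 88$ (placing the parents near RGB 136/43,
inside their observed 120–150 / 20–50 ranges) and $\sigma^2_{pg} = 30$
(between the values implied by the BC1 and F2 decompositions, keeping
polygene heritability in the published few-percent range). Values are
raw Gaussians by default — clipping to the RGB range [0, 255] is opt-in —
so moment checks against the mixture algebra are exact.

`simulate_cross()` builds F2 gametes by sequential recombination along
each linkage group (Haldane by default — no interference, matching the
scan's assumptions; Kosambi optional, applied interval-wise), inserts
QTL as extra loci with effects $+a, d, -a$ for QQ/Qq/qq, and produces F3
families by selfing with 5 scored progeny per family, mirroring the
field protocol. Phased haplotypes are retained for diagnostics.

What the simulators deliberately do **not** emulate: dominant/partially
scored AFLP bands, genotyping error, segregation-distortion mechanisms,
clustering of markers, non-Gaussian phenotype error, and G×E. Passing
tests therefore demonstrate correctness of the algorithms under the
model's own assumptions — not robustness to the artefacts of real marker
data.

## Problem sizes and experiment design

The statistical property checks use 20-seed batteries: six-generation
fits at $n = 200$ per generation (the field design's order of magnitude),
a 5-group × 60-cM map with 5-cM marker spacing, $n = 260$ F2 individuals
(the mapping-population size), one QTL with $a = 20$, $d = -19$ and
residual variance set so the QTL explains $r^2 \approx 0.4$ — the
magnitude of the largest published seed-colour QTL — and 200-permutation
thresholds. These sizes give stable pass/fail behaviour for peak
localisation within 5 cM, sign recovery, and null calibration while
keeping the whole battery comfortably inside a routine test run.

## Known limitations

* The constraint sets of 23 of the 24 catalogue models are an
  interpretation (only E_0 is fixed by the analysis the catalogue
  supports); absolute AIC values are therefore not comparable to other
  implementations.
* The a/b split of two-gene effects is weakly identified at moderate
  sample sizes — the sums $d_a + d_b$ and $h_a + h_b$ are estimated much
  more precisely than the individual effects; signs and magnitudes of the
  dominant gene are stable.
* The regression approximation understates LOD slightly relative to full
  mixture ML when residuals are strongly non-normal.
* Kosambi recombination is applied per interval, which (as in standard
  practice) is not exactly consistent with a single chiasma process
  across intervals.
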