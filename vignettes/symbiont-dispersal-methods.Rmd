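---
title: "Methods: quantifying fish-mediated dispersal of coral symbionts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying fish-mediated dispersal of coral symbionts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`symdisp` estimates how many live Symbiodiniaceae cells corallivorous fishes
disperse across a reef, and whether the symbiont communities they disperse
resemble those of nearby corals. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not demonstrate.

## 1. Hemocytometer density model

A preserved sample (feces, sediment or seawater) is a suspension of the
original material in fixative and stain. Each of the (by design, eight)
technical replicates counts the cells in a grid region representing a known
suspension volume $v$ (default $10^{-4}$ ml, one Neubauer large square:
1 mm × 1 mm × 0.1 mm). The chain is:

$$\text{conc} = \overline{\text{count}/v}, \qquad
  D_\text{source} = \text{conc} \cdot
  \frac{V_s + V_f + V_\text{st}}{V_s}, \qquad
  D_{\text{per g}} = D_\text{source}\frac{V_s\,[\text{ml}]}{m\,[\text{g}]}$$

with $V_s$ the sample volume, $V_f$ the fixative volume (750 µl in the
emulated protocol), $V_\text{st}$ the stain volume, and $m$ the fecal mass.
Replicates are averaged, never summed. All volumes are explicit fields in
declared units, so no bare unit-conversion constants appear in the
arithmetic. The stain volume is rarely recorded at the bench and defaults to
0; the counted grid volume is configurable because chamber use varies
between operators. Non-detections enter downstream summaries as 0 cells
ml⁻¹ — excluding them would inflate group means. Detection fractions are
reported both raw and rounded to integer percent.

Two structural identities are worth noting (and are tested): the whole chain
is linear in the replicate counts, and densities depend on the
fixative/stain split only through their total.

## 2. Genus-level community analysis

Genus count tables (five genera: *Symbiodinium*, *Breviolum*, *Cladocopium*,
*Durusdinium*, *Fugacium*) are filtered at a minimum library size of 1000
reads (strict: a 999-read library is discarded), converted to row
percentages, and compared with Bray–Curtis dissimilarity on the
untransformed percentage rows (raw counts are supported via
`use_percent = FALSE`; percent is the default because compositions, not
library sizes, are the quantity of interest).

PERMANOVA uses the distance-based one-way formulation:
$SS_T = \sum_{i<j} d_{ij}^2 / N$, $SS_W = \sum_g \sum_{i<j \in g}
d_{ij}^2/n_g$, pseudo-$F = \frac{(SS_T-SS_W)/(k-1)}{SS_W/(N-k)}$, $R^2 =
1 - SS_W/SS_T$. The permutation p-value uses the add-one estimator
$p = (1 + \#\{F^\pi \ge F\})/(1 + B)$ with $B = 999$ by default, so $p$ is
never 0 and never below $1/(B+1)$; ties count as exceedances
(conservative). The implementation is verified against a brute-force
$O(N^2)$ recomputation, exhaustive enumeration at $N \le 8$, a simulated
type-I error study, and `vegan::adonis2`.

Because PERMANOVA confounds location and dispersion effects under unbalanced
designs, the pipeline subsamples a balanced design (default 12 samples per
category, either seeded-random or a fixed ID list) and reports a
homogeneity-of-dispersion test: principal-coordinates embedding (axes with
negative eigenvalues kept under the imaginary-distance convention;
eigenvalues below $10^{-8}$ of the largest magnitude dropped as noise),
per-sample distance to the group *centroid*
($d = \sqrt{\max(0, d^2_\text{real} - d^2_\text{imag})}$), then an F-test on
those distances with an optional permutation p. Centroids, not spatial
medians, are used; the cross-check against `vegan::betadisper(type =
"centroid")` agrees to machine precision.

Pairwise PERMANOVAs are Benjamini–Hochberg corrected; significance letters
are derived heuristically as connected components of the
"not-significantly-different" graph — a display convenience, not an
inferential procedure. Rarefaction uses the closed-form hypergeometric
expectation $E[S(n)] = \sum_g \left(1 - \binom{N-N_g}{n}/\binom{N}{n}\right)$
computed with log-binomials, cross-checked by resampling.

## 3. The bootstrap dispersal estimator T = gSWCF

The reef-scale flux of live symbiont cells is
$T = g\,S\,W\,C\,F$ in cells per 100 m² per day, with $g$ the species'
egestions per day (pooled event count over pooled observation time, scaled
by an assumed 8-h activity window), $S$ pellet length (cm), $W$ fecal
linear density (g cm⁻¹), $C$ live cells per g feces, and $F$ fish per
100 m² (belt-transect counts over 250 m², converted ×0.4).

The default bootstrap (1000 iterations) resamples each of $S, W, C, F$ with
replacement at its original size, takes each vector's mean, and multiplies:
the natural bootstrap of a product of independent sample means. $g$ is a
fixed species constant and is never resampled. A `single-draw` scheme (one
value per variable per iteration) is available behind a flag for users who
prefer to propagate per-observation variability; the resample-means scheme
is the default and the one used throughout the tests, because the estimand
is the product of the population means. The reported interval is the
percentile interval of the draws (a normal-theory mean ± z·sd interval is
also computed for comparison); the symmetric "±" summary is the percentile
interval's half-width, since a percentile interval of a product is generally
asymmetric. Inputs are validated with unit labels carried from the column
names of the input files, so a mismatched unit fails at the boundary rather
than corrupting the product.

## 4. Univariate field statistics

Group differences in cell densities use Kruskal–Wallis (tie-corrected, χ²
reference) with Dunn's post-hoc z tests,
$z_{ij} = (\bar R_i - \bar R_j)\big/\sqrt{\left(\tfrac{N(N+1)}{12} -
\tfrac{\sum_t (t^3-t)}{12(N-1)}\right)\left(\tfrac1{n_i}+\tfrac1{n_j}\right)}$,
Bonferroni-adjusted over all pairs by default (the full pair family is the
conservative choice when the intended family is unstated). Kruskal–Wallis
and ANOVA go through base R (`kruskal.test`, `aov`); Dunn's test is
implemented in-package since no standard implementation ships with the
environment's R. Coral-cover differences between reef zones use one-way
ANOVA reported together with Shapiro–Wilk on residuals (residuals, not raw
values, are the primary normality check) and Levene's test
(median-centred by default) via `car`. The outlier screen flags values
outside Q1 − 1.5·IQR, Q3 + 1.5·IQR with type-7 (linear-interpolation)
quartiles and never removes anything.

## 5. The synthetic reef

The generator produces every input with known ground truth, one global seed
fanning out to per-generator child streams (`child_seeds()`: the children
are `sample.int` draws under the global seed, so the fan-out is itself
reproducible byte-for-byte).

Guild density laws are lognormal — the minimal positive heavy-tailed choice
for quantities reported as means ± SE spanning orders of magnitude — with
log₁₀ means calibrated to the observed structure: obligate corallivores 6.4,
facultative 5.0 (and the largest spread, σ = 0.9), grazer/detritivores 2.5,
sediment 1.4, water −0.6. Guilds where live cells are genuinely absent from
some samples carry zero-inflation probabilities (facultative 0.18, grazer
0.64, sediment 0.58, water 0.92) chosen to match the observed detection
fractions. Replicate counts are Poisson at mean = true density × dilution
fraction × counted volume: pure counting statistics, since replicate
overdispersion is not separately characterized. Sample volumes and masses
are uniform over the observed ranges (42–234 µl; 22–170 mg). A consequence
worth stating plainly: at the realistic counted volume of $10^{-4}$ ml,
densities below ~10³ cells ml⁻¹ are below the detection limit of the
counting design, so synthetic grazer/sediment/water samples are mostly
recorded as non-detections — exactly as in the field. Parameter-recovery
tests that need the faint guilds quantified therefore use a larger counted
volume (0.05 ml), which is a property of the experiment design, not of the
estimator.

Genus compositions are Dirichlet-multinomial per guild: obligate feces and
corals Cladocopium-dominated (obligate mean relative abundance ≈ 0.88,
within the observed 72–98% band), facultative mixed
Cladocopium/Durusdinium, grazers carrying *Fugacium*, sediment/water diffuse
with *Breviolum*. Read depths are log-uniform over 600–20 000 (per-sample
depths are not published; the lower end deliberately produces occasional
sub-1000-read libraries so the filter is exercised). Egestion events are
Poisson in follow duration; pellet lengths and linear densities are
truncated normal above zero; transect counts are Poisson; coral-cover
points are Bernoulli at zone cover probabilities (defaults 0.448 fore,
0.1533 back, with the study's 5/12 transect design).

What the synthetic reef does *not* emulate: spatial or temporal structure in
fish behaviour, diel variation in egestion, replicate overdispersion beyond
Poisson, sequencing artefacts below the genus level, or correlations between
a sample's density and its composition. Passing tests therefore demonstrate
the correctness and calibration of the estimators under the stated
statistical structure, not the field accuracy of the study's numbers.

## 6. Problem sizes and determinism

Default analysis conditions mirror the study design: 8 technical replicates,
1000-read filter, 12 samples per category in the balanced subsample, 999
permutations (the smallest count at which a reported p of 0.001 is
attainable with the add-one estimator), 1000 bootstrap iterations, 8-h
activity window, ×0.4 transect conversion. Simulation-based tests use 100
replicate simulations for power/separation claims, 1000 for type-I error
rates, and 10 000 draws where a Monte-Carlo mean is compared with a
closed-form expectation. Every stochastic step takes an explicit seed;
identical seeds give byte-identical outputs, and pipeline runs log the seed,
config hash and package version needed to replay them.

## 7. Known limitations

- The dispersal estimator treats the five factors as independent; any
  field covariance between, say, fish density and per-gram cell density is
  not propagated.
- The percentile CI is reported as a symmetric half-width for comparability,
  which understates asymmetry when the draw distribution is skewed (the raw
  bounds and the draws themselves are always available).
- The dispersion test permutes centroid distances, which is slightly more
  liberal than permuting least-squares residuals; its parametric F is also
  reported.
- Significance letters compress the pairwise table and can mask
  intransitivity; consult the adjusted p table for inference.
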