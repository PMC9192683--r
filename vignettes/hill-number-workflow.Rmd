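---
title: "Incidence-based Hill-number diversity estimation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incidence-based Hill-number diversity estimation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incidiv)
```

## The estimation problem

Benthic habitats such as fleshy red-algae mats, seagrass leaf canopies and
rhizome layers are surveyed with very different effort: a handful of frame
samples here, a few dozen single leaves there. Raw phenotype richness is
then incomparable across habitats, because richness climbs with the number
of sampling units and rare, patchily detected phenotypes keep appearing in
every additional sample. `incidiv` implements the standard remedy from
community ecology: work on *incidence* (presence/absence per sampling unit)
rather than abundance, summarise each habitat by its incidence frequencies,
and compare habitats either asymptotically (estimated complete-sampling
diversity) or non-asymptotically at a common sample coverage.

The sufficient statistics are the number of sampling units $T$, the
incidence frequencies $Q_i$ (number of units containing phenotype $i$), the
singleton and doubleton counts $Q_1, Q_2$, the total incidence count
$U = \sum_i Q_i$ and the observed richness $S_{obs}$. Every estimator in the
package consumes only these (`incidence_frequencies()`).

Diversity is expressed as Hill numbers: with relative incidences
$p_i = Q_i / U$,
$$ {}^qD = \Big(\sum_i p_i^q\Big)^{1/(1-q)}, \qquad
   {}^1D = \exp\Big(-\sum_i p_i \log p_i\Big), $$
so $q = 0$ counts phenotypes equally (richness), $q = 1$ weights them by
frequency (exponential Shannon) and $q = 2$ emphasises the dominant ones
(inverse Simpson). ${}^qD$ is non-increasing and continuous in $q$; both
properties are exercised in the test suite.

## The four steps

1. **Sample-completeness profiles.** The detected share of order-$q$
   diversity as a function of $q$. Two orders have canonical estimators:
   completeness at $q=0$ is $S_{obs}/\hat S_{Chao2}$ and completeness at
   $q=1$ is the sample coverage
   $\hat C = 1 - \frac{Q_1}{U}\frac{(T-1)Q_1}{(T-1)Q_1 + 2Q_2}$. For
   intermediate orders no closed-form estimator is forced by those anchors;
   `completeness_profile()` evaluates the detected share of
   $\sum_i \lambda_i^q$ under the estimated full assemblage described below,
   a construction that reproduces both anchors exactly (tested to machine
   precision). A profile that rises with $q$ signals undetected rare
   diversity.

2. **Asymptotic estimation and size-based R/E curves.** Chao2
   (`chao2_richness()`) estimates richness from the singleton/doubleton
   ratio, with the bias-corrected branch when $Q_2 = 0$. The asymptotic
   Shannon estimator is the incidence analogue of the Chao–Wang–Jost
   entropy estimator (incidence frequencies and sampling units substituted
   for abundances and individuals, then rescaled from detection rates to
   relative incidences); the asymptotic Simpson estimator is the unbiased
   $U^2(T-1) / (T \sum_i Q_i(Q_i-1))$. On synthetic assemblages with known
   detection probabilities the two land within a few percent of the truth at
   realistic effort (a 5% bound at $T=200$ is part of the acceptance suite).
   Rarefaction of richness is exact
   ($S(t) = S_{obs} - \sum_i \binom{T-Q_i}{t}/\binom{T}{t}$, verified
   against exhaustive subset enumeration for $T \le 8$); extrapolation
   follows the Chao2-anchored exponential form and is cut off at $2T$,
   beyond which richness extrapolation is not trustworthy.

3. **Coverage standardization at $C_{max}$.** Expected coverage of a
   $t$-unit sample uses $\binom{T-Q_i}{t}/\binom{T-1}{t}$ when rarefying
   (this denominator, not $\binom{T}{t}$, makes the curve continuous and
   non-decreasing through the reference point) and the geometric decay
   $1 - (Q_1/U) A^{t-T+1}$ when extrapolating. $C_{max}$ is the smallest
   doubled-size coverage across the habitats being compared and is always
   *computed* from the data at hand; it is never accepted as a constant,
   since printed coverage levels for one survey can disagree in the third
   digit depending on rounding and plotting conventions.
   `estimate_at_coverage()` inverts the coverage curve (linear interpolation
   between the bracketing integer sizes) and reads the diversity curve
   there; standardizing at the reference coverage returns the empirical
   Hill number exactly.

4. **Evenness.** The normalised slope of the diversity profile,
   $E(q) = ({}^qD - 1)/({}^0D - 1)$ for $q > 0$, evaluated at
   $C_{max}$-standardized Hill numbers, plus Pielou's
   $J = \log {}^1D / \log {}^0D$.

### Size-based curves for q > 0

For $t \le T$ the subsampled incidence of phenotype $i$ is hypergeometric,
and the package evaluates the plug-in Hill number of the *expected frequency
counts* $E[S_k(t)]$ with expected incidence total $U_t = tU/T$. At $t = T$
this reproduces the empirical value exactly — the continuity anchor all
curves are tested against. For $q = 2$ the same expectation collapses to a
closed form valid at every $t$, including extrapolation, whose
$t \to \infty$ limit is the asymptotic Simpson estimator.

For extrapolated orders other than 2 no closed form is available from the
sample alone. The package computes the expected plug-in diversity of the
*estimated full assemblage* under independent Bernoulli sampling of $t$
units and shifts the resulting curve by a constant so that it passes through
the empirical value at $t = T$. This is a modelling choice, made once: its
defence is behavioural (correct anchor, monotone growth towards an
asymptote, agreement with simulation truth on synthetic assemblages) rather
than formula transcription, and the acceptance suite tests exactly those
behaviours.

### The estimated full assemblage and the bootstrap

Several pieces above need a working model of the unseen part of the
community. Following the standard incidence-bootstrap construction, the
observed phenotypes get adjusted detection rates
$\hat\lambda_i = \frac{Q_i}{T}\big[1 - \tau (1 - Q_i/T)^T\big]$, with $\tau$
chosen so the adjustments sum to the coverage deficit, and
$\hat Q_0 = \hat S_{Chao2} - S_{obs}$ undetected phenotypes share the
residual rate mass equally. `incidence_bootstrap()` then draws replicate
frequencies $Q_i^* \sim \mathrm{Binomial}(T, \hat\lambda_i)$ — units are
independent, so the full matrix never needs to be materialised — and
re-evaluates any statistic.

Intervals are *point estimate $\pm\ z_{0.975}$ bootstrap SD* (the
normal-approximation form, which yields the narrow bands typical of
coverage-standardized estimates), not percentile intervals. Centering on the
point estimate rather than the bootstrap mean is deliberate: the bootstrap
world is biased towards the sample, and recentering on its mean would
double-count that bias. Calibration is checked empirically: across 200
synthetic worlds the 95% interval for asymptotic Shannon diversity covers
the generating truth at a rate inside [0.90, 0.99] (acceptance suite,
$B = 200$; the workflow default is $B = 500$).

## Classical indices

For comparisons with older surveys that only publish index tables, the
package also provides the classical per-taxon indices: Shannon
$H' = -\sum_i p_i \log_2 p_i$ over the proportions $p_i = n_i/N$ of
phenotypes per higher taxon ($N = \sum_i n_i$), Simpson *concentration*
$D = \sum_i n_i(n_i-1) / (N(N-1))$ (small = diverse), and evenness
$J = (-\sum_i p_i \ln p_i)/\ln k$ with $k$ the number of taxa present. The
printed definitions of such indices are sometimes ambiguous about what "N"
denotes; this reading — proportions over the phenotype total, evenness
denominator over the taxon count — is the unique one under which published
(H', evenness, taxa) triples we use as references are mutually consistent,
and `evenness_from_shannon()` ($J = H'\ln 2 / \ln k$) encodes the
deterministic link between the two formulas that the tests exploit row by
row.

## Community composition

Counts (per habitat m²) are square-root transformed before Bray–Curtis
dissimilarity (`vegan::vegdist`); on presences the same coefficient is the
Sørensen dissimilarity, which the incidence ordination uses. The one-way
PERMANOVA partitions squared dissimilarities (Anderson's pseudo-F) with
unrestricted permutation of sample labels and
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$; with a single factor, Type III
sums of squares reduce to this one-way partition, so no general linear-model
machinery is involved. Tiny designs that admit fewer distinct label
arrangements than requested are enumerated exactly (with a warning) instead
of sampled. Monte-Carlo-style asymptotic p-values offered by some commercial
packages are intentionally not reproduced; the permutation p is the
statistic of record. Dispersion homogeneity uses principal-coordinate
embedding with imaginary-part correction (`vegan::betadisper` +
`permutest`), and ordination uses Kruskal stress-1 nMDS
(`vegan::metaMDS`, classical-scaling start plus random restarts, best
configuration kept, deterministic under a seed).

## Surface-area normalization

Abundances are normalised per sample — density on the habitat's 3D surface
(count / sample 3D area), then per seafloor m² by multiplying with the
habitat's enlargement factor (EF) — and only then averaged (mean ± SE over
samples). Computing per sample first matters: the ratio-of-totals estimate
differs in the fourth digit and does not reproduce per-sample-averaged
published summaries.

EF formulas per substrate: algal mats scale an imaged, two-sided subsample
thallus area by wet weight; seagrass models rhizomes as lateral cylinder
surfaces (end caps are buried) and leaves as two-sided rectangles — the
two-sided choice mirrors the thallus convention, since a one-sided reading
is equally defensible from the geometry alone; hard bottom drapes ball
chains (whole 2.4 mm links) along a frame's edges and diagonals and averages
the two diagonal-based Heron triangulations. A flat substrate gives EF = 1
under all three; chains can only add length, so EF ≥ 1 always.

## The synthetic generator

`generate_assemblage()` emulates the sampling design the workflow targets:
three habitats with $T = 16/29/20$ sampling units, species pools built from
a 90-phenotype core shared by all habitats plus 133/21/18 habitat-unique
phenotypes (pools of 223/111/108), heavy-tailed lognormal detection
probabilities, and zero-truncated negative-binomial counts attached to
detected cells (counts exist only to exercise normalization and
Bray–Curtis; diversity truth is defined on incidence). The detection
parameters (meanlog $-2$, sdlog $1.2$) were fixed once, before any estimator
testing, by solving for the regime in which expected detected richness at
those $T$ falls in the 73–86% band typical of real surveys of this kind —
the regime in which completeness profiles rise with $q$, singletons are
plentiful, and estimator bias is actually at stake. Ground truth (pool
size, expected coverage at $T$, true Hill numbers of the normalised
detection rates) is computed analytically from the generating
probabilities, never from a large simulation.

What the generator does *not* emulate: spatial autocorrelation between
neighbouring sampling units, site-to-site heterogeneity within a habitat,
misassignment of phenotypes, or any coupling between a phenotype's
detection probability and its local abundance. Tests passing on these
synthetic assemblages therefore validate the estimators under independent,
exchangeable sampling units — the assumption the estimators themselves
make — and say nothing about robustness to violations of it.

## Numerical choices and degenerate inputs

- $q$-grid default 0–2 in steps of 0.05; size-based curves on integer unit
  counts in $[1, 2T]$, $T$ and $2T$ always included.
- Hill evaluation switches to the entropy limit only within $10^{-10}$ of
  $q = 1$; elsewhere the generic power form is used (continuity at $q=1$ is
  tested at $10^{-4}$).
- Phenotypes present in every unit carry no correction terms anywhere
  ($(1 - Q_i/T)^T = 0$); complete assemblages yield coverage 1, completeness
  identically 1, and zero-width bootstrap intervals.
- All-zero phenotype rows are retained but logged; they contribute to no
  estimator.
- Bootstrap replicates whose statistic fails are dropped and logged; more
  than 10% failures aborts.
- Coverage inversion interpolates linearly between bracketing integer
  sizes; requests beyond the $2T$ coverage are refused rather than
  extrapolated.
- All stochastic stages draw from one root seed split deterministically per
  stage and habitat; reruns are byte-identical.

## Problem sizes in the shipped analyses and tests

The `analysis/` drivers run the full pipeline on the default synthetic
design with $B = 200$ bootstrap replicates and 999 permutations (about half
a minute in total); the package default of $B = 500$ matches the workflow's
convention. The simulation-based test suites use 200 synthetic worlds for
bootstrap calibration ($B = 200$), 1000 null datasets for the PERMANOVA
type-I check ($n_{perm} = 199$), and 200 replicates per effort level for
Chao2 consistency — sizes chosen to keep Monte-Carlo error well inside the
asserted bands.

## Known limitations

- Abundance-based Hill estimation is deliberately out of scope; the
  workflow is incidence-only.
- Size-based extrapolation for $q \notin \{0, 2\}$ rests on the estimated
  assemblage (see above); different but equally defensible constructions
  would shift extrapolated segments slightly while agreeing at the anchors.
- The completeness profile between its two anchor orders is
  model-dependent in the same way.
- PERMANOVA is one-way only; nested or multi-factor designs are not
  supported.
- `derive_holobiont()` concatenates leaf and rhizome units as independent
  samples. If the original survey paired them, $T$-dependent statistics
  (everything in this package) would differ; concatenation is the choice
  that preserves the additive unit counts reported for such surveys.
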