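# incidiv

Incidence-based Hill-number diversity estimation and comparison for benthic
assemblages surveyed with unequal effort.

## The problem

Surveys of sessile invertebrates in structurally complex habitats — fleshy
red-algae mats, seagrass leaf canopies, rhizome layers, bare hard bottom —
rarely sample each habitat with the same number of units (frames, leaves,
specimens). Observed phenotype richness is then an artefact of effort, and
abundance counts normalised to surface area lose the singleton structure
that richness estimators feed on. The established solution is to analyse
phenotype *incidence* across sampling units and to compare habitats either
asymptotically or at a common sample coverage. `incidiv` implements that
workflow end to end for anyone comparing alpha and beta diversity across
habitats sampled with unequal effort.

## What it computes

With `T` sampling units, incidence frequencies `Q_i`, singletons/doubletons
`Q1, Q2`, total incidences `U` and observed richness `S_obs`:

- **Hill numbers** `^qD = (Σ p_i^q)^(1/(1−q))`, `p_i = Q_i/U` — richness
  (q=0), exponential Shannon (q=1), inverse Simpson (q=2);
- **Chao2** richness `S_obs + ((T−1)/T)·Q1²/(2Q2)` (bias-corrected branch
  when `Q2 = 0`), and incidence analogues of the asymptotic Shannon/Simpson
  estimators;
- **sample coverage** `Ĉ = 1 − (Q1/U)·(T−1)Q1/((T−1)Q1+2Q2)`, completeness
  profiles over `q`, and size-based rarefaction/extrapolation curves to
  `2T`;
- **coverage standardization at C_max** (the lowest doubled-size coverage
  across habitats) with incidence-bootstrap confidence bands;
- **evenness profiles** `E(q) = (^qD − 1)/(^0D − 1)` and Pielou's
  `J = ln(^1D)/ln(^0D)` at C_max;
- **classical indices** for cross-study tables (Shannon in log2, Simpson
  concentration, evenness over higher taxa);
- **community composition**: square-root Bray–Curtis, one-way PERMANOVA
  with permutation p and pairwise tests, multivariate-dispersion check,
  nMDS, Venn partitions of phenotype sets;
- **surface-area enlargement factors** for algal mats (wet-weight-scaled
  image areas), seagrass (cylinder rhizomes + two-sided leaves) and hard
  bottom (ball-chain Heron triangulation), plus per-habitat-m² and
  per-seafloor-m² abundance normalization, clod-card dissolution rates and
  daily logger summaries;
- a **synthetic assemblage generator** with analytic ground truth for all
  of the above.

## Worked example

```r
library(incidiv)

# four sampling units, four phenotypes occurring in (4, 2, 1, 1) units
f <- incfreq(c(4, 2, 1, 1), T = 4)

empirical_hill(f, c(0, 1, 2))
#> [1] 4.000000 3.363586 2.909091
chao2_richness(f)       # 4 + (3/4) * 2^2 / (2*1)
#> [1] 5.5
sample_coverage(f)
#> [1] 0.8125
completeness_profile(f, c(0, 1))$completeness   # S_obs/Chao2, coverage
#> [1] 0.7272727 0.8125000
```

So ~73% of phenotypes but ~81% of incidence mass are estimated detected:
the sample is less complete for rare phenotypes than frequent ones.

On the bundled synthetic field design (three habitats, `T = 16/29/20`,
heavy-tailed detection), the full four-step workflow:

```r
g <- generate_assemblage(assemblage_spec(seed = 20190527))
res <- run_four_steps(lapply(g, `[[`, "incidence"), tempdir(), B = 200,
                      seed = 20190527)
round(res$cmax, 4)
#> [1] 0.9842
res$pielou[, c("habitat", "d0_cmax", "d1_cmax", "pielou_j")]
#>       habitat   d0_cmax   d1_cmax  pielou_j
#> 1      PC_mat 190.40482 127.65294 0.9238282
#> 2   PO_leaves 102.83507  57.76979 0.8755354
#> 3 PO_rhizomes  92.62898  60.94788 0.9075691
```

Here all habitats are standardized at coverage C_max = 98.4% before
comparison; the mat habitat carries both the highest standardized richness
(~190 phenotypes) and the most even community (J = 0.92). The asymptotic
Shannon estimates land within ~2% of the generator's analytic truth
(`results/data/ground_truth.csv` after running the analysis scripts).

## Analysis scripts

Numbered drivers under `analysis/` reproduce the whole sequence on the
synthetic design and write tidy CSVs under `results/`:

```sh
Rscript analysis/01_simulate.R      # assemblages + ground truth
Rscript analysis/02_diversity.R     # four-step Hill workflow
Rscript analysis/03_composition.R   # PERMANOVA, dispersion, nMDS, Venn
Rscript analysis/04_surface_env.R   # enlargement factors, clod cards, loggers
```

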