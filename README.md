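# lipidmrm

Tools for building and validating extensive targeted lipidomics methods
on triple-quadrupole instruments, written for grape (*Vitis vinifera*)
ripening studies but applicable to any matrix profiled with
class-based multiple reaction monitoring (MRM).

Targeted lipid profiling at this scale starts from combinatorics, not
from a compound catalogue: every fatty-acyl chain with an even carbon
number from 14 to 22 and 0–6 double bonds (35 chains) is attached to a
class scaffold, so a two-chain glycerophospholipid class contributes
C(36, 2) = 630 species and triacylglycerols C(37, 3) = 7770. For each
species the package derives the MRM transition — precursor m/z (Q1)
from elemental-composition arithmetic with the class adduct
([M+H]⁺, [M−H]⁻, [M+Na]⁺, [M+HCOO]⁻, [M+H−18]⁺) and product m/z (Q2)
from the class fragmentation rule (sn-chain carboxylate, neutral loss
of the leaving fatty acid, glycerol loss, head-group constants such as
the 184.1 phosphocholine fragment) — attaches per-class source
voltages, merges Q1/Q2 collisions, and exports vendor-neutral
positive- and negative-mode transition lists with the 21 internal
standards flagged.

Around the library sit the statistics of the workflow:

* **Kendrick mass defect validation** (`kendrick()`, `grid_check()`):
  with KM = m/z · 14/14.01565, CH₂ homologs share their mass defect,
  so equal-double-bond series are horizontal and equal-carbon series
  diagonal on a KMD-vs-retention-time plot; points breaking the grid
  are flagged as annotation outliers.
* **Internal-standard semi-quantification** (`semi_quantify()`,
  `impute_missing()`): conc = area ratio × IS µg / sample g, in µg/g
  fresh weight; missing values imputed uniformly on (0, min/2).
* **Method validation** (`recovery()`, `linearity_lod()`,
  `cv_percent()`, `validation_filter()`): spike recovery over
  0.1/0.5/1 mg/L, linear-range search with LOQ/LOD, precision CVs and
  the combined CV ≤ 20% + KMD retention filter.
* **Ripening trends** (`pareto_pca()`, `fit_pls()`,
  `q2_resampling()`, `permutation_null()`,
  `quartile_class_summary()`): PCA on log/Pareto-scaled data and a
  SIMPLS °Brix regression validated by 1000 random 2/3–1/3 splits
  (median Q² = 1 − PRESS/TSS) and a 1000-fold label-permutation null,
  summarised per class by coefficient-quartile fractions.
* **Synthetic studies** (`simulate_maturation()`,
  `simulate_spike_design()`): a 13-point maturation design (5
  replicates, 3 at the last two points) with planted class trends and
  known ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(lipidmrm)

m <- build_method()
m
#> <mrm_method> 4230 positive + 4002 negative transitions (21 IS)
m$summary[m$summary$class %in% c("PE", "SM", "TG"), ]
#>   class compounds_in_method
#>   PE                    630
#>   SM                     35
#>   TG                   1981

sp <- species("PC", "16:0_18:1")
species_mass(sp); precursor_mz(sp); product_mz(sp)
#> [1] 759.5778     # neutral monoisotopic mass
#> [1] 804.576      # [M+HCOO]- precursor
#> [1] 281.2486     # sn-chain carboxylate (18:1)
```

The PE row reproduces the two-chain count of the published method; TG
is 1981 rather than the printed 1834 because no stated deduplication
rule reproduces that figure (see the methods vignette). For the
analysis layer, on a simulated maturation study:

```r
sim  <- simulate_maturation(seed = 7)
conc <- impute_missing(semi_quantify(sim$areas, sim$samples,
          compounds = sim$truth$compounds[, c("transition_id", "class")]),
          seed = 7)
am  <- analysis_matrix(conc, sim$samples)
fit <- fit_pls(am$x, am$brix, seed = 7)
fit
#> <pls_fit> 1 component(s), 120 compounds, R2 = 0.989
q2_resampling(am$x, am$brix, n = 200, ncomp = fit$ncomp, seed = 7)$median
#> [1] 0.966
permutation_null(am$x, am$brix, n = 200, seed = 7)$median
#> [1] -0.211
head(dplyr::arrange(quartile_class_summary(fit$coefficients, am$classes),
                    dplyr::desc(frac_q1)), 3)
#>   class     n  n_q1  n_q4 frac_q1 frac_q4
#>   MGDG      8     8     0   1       0
#>   LPG       8     7     0   0.875   0
#>   MG        8     7     0   0.875   0
```

The planted falling classes (MGDG, LPG, MG, CER, DGDG) dominate the
lower coefficient quartile and the rising classes (PG, PE, LPE, LPC,
PI) the upper one, while the permutation null sits at a negative
median Q² — the behaviour the validation strategy is designed to show.

A thin command-line front end wraps the same functions
(`inst/exec/lipidmrm`, subcommands `build-library`, `kmd-check`,
`quantify`, `simulate`, `analyze`).

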