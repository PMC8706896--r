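---
title: "Targeted lipid MRM libraries and ripening-trend analysis: methods"
author: "lipidmrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted lipid MRM libraries and ripening-trend analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmrm)
```

# Scope

`lipidmrm` implements the computational core of an extensive targeted
lipidomics workflow for a triple-quadrupole instrument, as applied to
grape (*Vitis vinifera*) ripening studies: it enumerates a fatty-acyl
chain space into class-specific lipid species, derives every multiple
reaction monitoring (MRM) transition from elemental-composition
arithmetic, validates compound annotations with Kendrick-mass-defect
(KMD) grid checks, semi-quantifies peak areas against class internal
standards, computes the bioanalytical validation statistics (recovery,
linearity, LOD/LOQ, repeatability CVs), and analyses lipid trends
against ripeness (°Brix) with PCA and a resampling- and
permutation-validated PLS regression. A synthetic-data module simulates
maturation studies and spike designs with known ground truth, so that
every downstream step is testable end to end without instrument data.

Chromatography, peak integration and instrument control are outside the
package: peak areas are inputs.

# Chain space and species combinatorics

The default chain space covers even-numbered acyl chains from 14 to 22
carbons with 0–6 double bonds — the plant-lipid convention — giving
`r nrow(enumerate_chains(chain_space()))` chains. Species are
*multisets* of chains on a class scaffold: the sn positions of a
glycerophospholipid or glycerolipid are not resolved by an MRM method
built on nominal chain totals, so `PE 16:0_18:1` and `PE 18:1_16:0` are
one species. Over $n$ chains a $k$-chain class therefore enumerates
$\binom{n+k-1}{k}$ species: 630 for the two-chain classes and 7770 for
triacylglycerols over the 35-chain space. Sphingolipid classes carry a
fixed sphingoid base (d18:1 for CER/glcCER/lacCER and SM, d18:0 for the
dihydro forms, distinguished by their 264.1 vs 266.1 base fragments)
plus one variable N-acyl chain, so they enumerate like single-chain
classes (35 each; 210 for the six-class ceramide family).

Two counts printed in the source method differ from what the
combinatorics can produce, and both are asserted in the test suite as
known differences so they cannot drift silently:

* the acylcarnitine class is printed with 48 species, but no chain
  space described anywhere in the method yields 48; the shipped default
  keeps the 35-chain space;
* the triacylglycerol list is printed with 1834 unique Q1/Q2 pairs out
  of "7700" (the multiset count is 7770). Exact-collision
  deduplication of the built TG set gives 1981 unique pairs — at every
  rounding precision from 0 to 4 decimals — and the all-candidate audit
  mode gives 4095, so no plain rounding rule reproduces 1834. The
  package reports 1981.

# Mass model

Every species mass is assembled as

$$M = M_\text{scaffold} + \sum_i M_\text{FA}(C_i, D_i) - n_\text{link}\,M_{\mathrm{H_2O}},$$

where the free fatty acid has composition $\mathrm{C}_n\mathrm{H}_{2n-2d}\mathrm{O}_2$
and $n_\text{link}$ is the number of ester/amide linkages (zero for
free fatty acids). Scaffold compositions — glycerol,
glycerophospho-head groups, mono-/di-galactosylglycerol, sphingoid
bases with their sugar extensions, sphingosylphosphorylcholine,
carnitine — are stored as verified elemental-composition constants; a
release-gate test compares one species per class against frozen
reference monoisotopic masses computed through an independent
atomic-mass route, at a tolerance of 0.001 Da.

Adducts ([M+H]$^+$, [M−H]$^-$, [M+Na]$^+$, [M+HCOO]$^-$,
[M+H−18]$^+$) are applied as composition deltas with the electron-mass
correction, so the positive and negative protonated forms bracket the
neutral mass to within two electron masses. "[M+H−18]$^+$" is read as
dehydration, i.e. loss of one real water (18.0106 u), not a nominal 18.

Product ions follow the class rule: the sn-chain carboxylate for
negative-mode glycerophospholipids, neutral loss of the leaving fatty
acid for the sodiated glycerolipids and galactolipids, glycerol loss
for monoacylglycerols (yielding the acylium ion; the literal
C$_3$H$_7$O$_3$ radical loss is available via `mg_loss = "radical"`),
the intact deprotonated ion for free fatty acids, and printed constants
(184.1, 264.1, 266.1, 85.1) for the head-group fragments. The printed
constants are exported verbatim because the artifact reproduces the
published method; `recompute_fragments = TRUE` exposes the exact
composition-derived values (the phosphocholine head computes to
184.0733, which rounds to the printed 184.1, while the d18:1 base
fragment computes to 264.27 — one of the reasons the printed constants
are kept as the export default).

# Transition assembly and deduplication

For a multiset species the "sn2" (or "sn3") leaving chain is not
positionally known. The builder therefore designates the largest chain
of the sorted multiset as the leaving group and emits **one transition
per species**, which is the only convention consistent with the
published per-class counts (630 two-chain transitions, not 1225). An
audit mode (`leaving = "all"`) emits one candidate per distinct chain
of the multiset for users who want the full fragment fan.

`dedup_transitions()` merges transitions whose (Q1, Q2, polarity)
collide after rounding to a configurable precision (default 1 decimal,
the acquisition-resolution scale), keeps a `;`-joined audit trail of
all contributing species, and is idempotent. Every exported Q1/Q2 pair
is reproducible from its species identifier, which the tests verify by
recomputation.

The full method build appends the 21 internal-standard transitions
(deuterium label masses added to Q1; carboxylate fragments carry the
label of the labelled chain, fixed head-group fragments do not) and
splits the list into one positive- and one negative-mode method.

# Kendrick mass defect validation

With the CH$_2$ Kendrick base, $KM = m/z \cdot 14/14.01565$ and
$KMD = \mathrm{round}(KM) - KM$, so CH$_2$ homologs share their KMD
exactly. On a KMD-versus-retention-time plot of one class, species with
equal double-bond count form a horizontal series (constant KMD, RT
increasing with carbons) and species with equal carbon count form a
diagonal (RT decreasing as double bonds are added).

`grid_check()` flags

* `horizontal_violation` when a point's KMD deviates from its equal-DB
  series median by more than `kmd_tolerance`, and
* `diagonal_violation` when retention time breaks the expected ordering.

Because a single misordered pair cannot tell which member is the
culprit, RT violations are corroborated across the two grid directions
when both are checkable (series of at least 3 members): a point is
flagged only when it collects violation votes from
$\min(2, \text{checkable series})$ directions. A planted RT swap is
then attributed to exactly the swapped pair instead of smearing flags
over innocent neighbours; singleton series are passed with an explicit
note.

The default `kmd_tolerance` of 0.003 sits above instrument mass-jitter
but below the KMD shift of a double-bond annotation error (~0.013). A
$^{13}$C isotope mis-pick (+1.00335 u) shifts the KMD by only 0.00223,
so screens targeting that failure mode should tighten the tolerance
(the test suite uses 0.001 for its isotope fixture); the default is
kept at the annotation-error scale.

# Semi-quantification and validation statistics

Concentrations are internal-standard ratios scaled to sample mass:

$$c = \frac{A_\text{compound}}{A_\text{IS(class)}} \cdot
      \frac{m_\text{IS}\ (\mu g)}{w\ (g)} \quad [\mu g/g],$$

with one internal standard per class and a default
$m_\text{IS} = 150\ \mu$g (15 µL of a 10 mg/mL mix) on ~100 mg of
powder — both configurable. Missing values are replaced by uniform
draws on $(0, \min_\text{observed}/2)$ per compound, under a caller
seed.

Recovery is the mean over replicates of measured/expected per spike
level (0.1, 0.5, 1 mg/L; five replicates), averaged over the three
levels per class. The simulated spike design uses mean-one log-normal
noise so the estimator is unbiased; a 1000-repeat calibration in the
test suite confirms planted recoveries (including a 68% class) are
recovered within ±2% at 5% noise.

Linearity is the longest contiguous calibration run with
$R^2 \ge 0.99$ and back-calculated accuracy within ±20% — acceptance
norms aligned with standard bioanalytical validation guidance, since
the source text does not state its own. The LOQ is the lowest point of
that run. "LOD = 3.3 × (S/N)" is dimensionally a ratio, not a
concentration; it is implemented as the concentration at which the
predicted signal-to-noise reaches 3.3, i.e.
$LOD = 3.3\,\sigma_\text{noise}/\text{slope}$.

Repeatability, intra-day and inter-day precision are plain CV%
(100·sd/mean; thresholds 20/15/20). The compound filter retains
species with repeatability CV ≤ 20% (inclusive) **and** a passing KMD
flag; intra-/inter-day thresholds can be applied as exclusions or
carried descriptively, as both readings of the source protocol are
defensible.

# PCA and PLS trend analysis

Exploratory PCA runs on natural-log, Pareto-scaled data (centre, then
divide by $\sqrt{sd}$) through `stats::prcomp`; zero-variance compounds
are dropped with a warning because Pareto and unit-variance scaling are
undefined for them.

The PLS regression of °Brix on the log-transformed, centred, scaled
compound matrix uses a SIMPLS core written for a single response. Two
closed-form identities anchor its correctness in the tests: with as
many components as the predictor rank it reproduces ordinary least
squares, and its first weight vector is proportional to $X^\top y$.
Unit-variance scaling is the default ("scaled and centred" in the
source protocol; Pareto is selectable). The component count minimises
10-fold cross-validated RMSEP with a one-standard-error tie-break
toward fewer components.

Predictive performance is the median $Q^2 = 1 - PRESS/TSS$ over 1000
random 2/3–1/3 splits, with TSS centred on the training mean; splits
with a constant training response are skipped and counted. The
permutation null repeats the same procedure with the response permuted
independently per iteration, and re-selects the component count per
permutation so the null reflects the entire selection procedure.

Class-level trends are summarised by the first/last quartile of the
coefficient distribution (type-7 percentiles, strict tail membership —
so an all-equal coefficient vector puts nothing in either tail): per
class, the fraction of members below the Q1 threshold (falling with
ripeness) and above the Q4 threshold (rising).

# Synthetic maturation studies

`simulate_maturation()` emulates the sampling scheme of a
véraison-to-harvest study: 13 time points, five biological replicates
each except three at the last two points (61 study samples), pooled QC
injections, °Brix rising linearly from 14 to 22 with 0.15 °Brix
replicate jitter. Per-compound baselines are log-normal around 5 µg/g;
trend classes (rising: LPC, LPE, PE, PG, PI; falling: CER, MG, LPG,
DGDG, MGDG) get linear-in-°Brix log-concentration slopes of
0.15 × Unif(0.5, 1.5) per degree with the planted sign — about a
three-fold change across the study, a magnitude a field lipidomics
study would call a clear trend. Noise is mean-one log-normal at 10% CV
(the published repeatability CVs span roughly 2–21%), and 5% of areas
are dropped as missing. Areas are generated by inverting the
quantification formula, so with noise and missingness switched off,
`semi_quantify()` returns the planted concentrations at machine
precision — the round-trip identity the tests rely on.

The generator emulates *design structure*, not instrument physics: no
retention-time drift, no censoring-at-LOD missingness mechanism (holes
are missing completely at random), no between-class correlation beyond
the planted trends, and noise that is honestly multiplicative.
Passing tests on these fixtures demonstrate that the estimators invert
their own forward models and detect planted structure at realistic
noise — not that any particular real-world dataset would reproduce the
published real-data statistics, which depend on raw data that is not
deposited.

# Problem sizes and determinism

The test suite works at the sizes the methods are designed for where
that is cheap (full 7770-species TG builds, 1000-repeat recovery
calibrations, 1000-split $Q^2$ and 1000-permutation nulls on the
61 × 120 synthetic study) and at reduced sizes for auxiliary
properties (e.g. 150-iteration null-vs-null distribution comparisons),
chosen as the smallest sizes at which the checked property is stable
across seeds. Every stochastic routine takes an explicit seed and is
reproducible; transition-list export is byte-stable.

# Known limitations

* Odd-chain, ether-linked, hydroxylated and oxidised species, sterols
  and prenols are out of scope (absent from the class registry).
* The printed CAR = 48 and TG = 1834 counts are not derivable from the
  stated rules; the package ships 35 and 1981 with the discrepancy
  documented and asserted.
* Scheduled-MRM retention windows and vendor-binary method files are
  not produced; the export is a vendor-neutral delimited list.
* The KMD check requires at least three members per series; sparse
  classes pass by default with a `singleton` note rather than being
  silently excluded.
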