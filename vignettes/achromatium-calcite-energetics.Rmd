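---
title: "Modeling calcite-driven energetics and habitat chemistry of Achromatium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling calcite-driven energetics and habitat chemistry of Achromatium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(achrotools)
```

## The scientific setting

*Achromatium* are giant (10–100 µm) sulfur-oxidizing bacteria whose cells
are packed with intracellular calcite (CaCO~3~) inclusions — a feature
almost unique among prokaryotes, and one whose function is unresolved. A
long-standing hypothesis set includes pH buffering, ballast, and proton
generation for dissolving sedimentary iron sulfides. Single-cell genomes
of *Achromatium* from a warm, brackish, sulfidic spring added a further
candidate: the drafts encode vacuolar (V-type) ATPases and
pyrophosphatases, membrane proton pumps that are rare in bacteria. If
those pumps sit in the membranes of the calcite inclusions, the protons
released by calcite precipitation,

$$\mathrm{Ca^{2+} + HCO_3^- \rightarrow CaCO_3 + H^+},$$

could drive ATP synthesis chemiosmotically — energy generation by mineral
precipitation.

This package implements the quantitative models needed to examine that
hypothesis and the surrounding habitat chemistry: carbonate speciation of
the spring water, the proton/ATP budget of a cell's calcite inventory,
the sediment budget of dissolved versus mineral-bound sulfide, and the
genome-quality and 16S phylotyping metrics used on the single-cell
drafts. A seeded synthetic-data module generates ground-truthed inputs
for every stage.

## Carbonate speciation (`speciate`)

Speciation is anchored on the measured pair (pH, HCO~3~^−^), which is what
field campaigns actually report:

$$[\mathrm{CO_2(aq)}] = \frac{[\mathrm{HCO_3^-}]\,[\mathrm{H^+}]}{K_1},
\qquad
[\mathrm{CO_3^{2-}}] = \frac{[\mathrm{HCO_3^-}]\,K_2}{[\mathrm{H^+}]},$$

with DIC the sum of the three species (conserved to 1e−12 relative by
construction). Alkalinity- or DIC-anchored solving, borate/phosphate
contributions, and pressure corrections are deliberately out of scope.

**Constants.** `compute_constants()` uses the Millero (2006) K~1~/K~2~
fits, chosen because their validity range (S 0–50, T 0–50 °C) spans the
fresh-to-brackish conditions of interest in one continuous formulation,
and the Mucci (1983) calcite solubility product. Below S = 5 the Mucci
fit is an extrapolation; Ω values there should be read qualitatively.
The `formulation_id` is recorded in the `constant_set` so results are
reproducible bit for bit. Constants are on the mol/kg-solution scale and
are treated as interchangeable with mol/L; the ~1–3% density difference
is far below the precision of field bicarbonate data.

**pH scales.** Field meters report the NBS (activity) scale while the
constants are defined on the seawater (concentration) scale. Rather than
mixing scales, `speciate(ph_scale = "nbs")` (the default) converts the
measured hydrogen-ion activity to a seawater-scale concentration with
the Takahashi activity factor $f_H(T, S)$, exactly as the CO2SYS family
of speciation programs does for NBS-scale input. At the basin reference
conditions (pH 7.03, HCO~3~^−^ 2 mM, 29.6 °C, S ≈ 17.5) this yields
CO~2~(aq) ≈ 215 µM; skipping the conversion (`ph_scale = "sws"`) gives
≈ 145 µM. Both sit inside the "about 200 µM" envelope the field estimate
carries, but the converted value is the defensible one and is the
package default.

**Salinity from conductivity.** `conductivity_to_salinity()` is a
deliberately simple ratio-to-seawater conversion (2%/°C temperature
correction, anchor 53 mS/cm = salinity 35). It is documented as
approximate and is good to about one salinity unit in the brackish
range — sufficient, since a full PSS-78 treatment would change the
derived salinity by far less than the K~1~ sensitivity to it.

**Saturation state.** Ω = [Ca^2+^][CO~3~^2−^]/K~sp~. Note an instructive
subtlety in the reference data: dissolved calcium (11.1 mM) was measured
on the October sampling date (pH 7.32), where the model gives Ω ≈ 1.5
(supersaturated); pairing that calcium with the June column (pH 7.03)
gives Ω ≈ 0.7. The package therefore exposes both sampling dates in the
reproduction configuration and the tests pin Ω > 1 to the October
column only. The wider observation motivating the energetics model —
that *Achromatium* precipitates calcite even in undersaturated waters —
does not depend on which column is used.

## Calcite-driven chemiosmotic energetics

`calcite_proton_yield()` encodes the 1:1 proton stoichiometry of the
precipitation reaction. `atp_from_calcite()` converts a cell's calcite
inventory (default 0.05 nmol, an average cell) through
`h_per_calcite / h_per_atp`; with the aerobic ~3 H^+^/ATP this gives
16.67 pmol ATP, truncated to 16 pmol by the reporting convention
(`atp_integer_pmol()`; full precision is kept internally). The
anaerobic H^+^/ATP stoichiometry is not well constrained, so
`h_per_atp` is an explicit parameter rather than a hidden constant.

**Division accounting.** `division_capacity()` asks how many complete
doubling cycles an ATP budget funds when each *new* cell costs
`atp_per_division` (0.1–0.2 pmol, an *E. coli*-scale construction cost):
$n$ cycles create $2^n - 1$ new cells, so the capacity is the largest
$n$ with $(2^n - 1)\,c \le B$. At 16 pmol this gives 6 cycles
(population 64) at 0.2 pmol/cell and 7 cycles (population 128) at
0.1 pmol/cell. The non-compounding alternative — simply $B/c$ new
cells, 80–160 here — is exposed as `affordable_new_cells()` but is not
the default, because it ignores that later cycles must fund
exponentially many daughters. A cell-by-cell simulation oracle in the
test suite confirms the closed form on a budget/cost grid.

**The nitrate comparison.** `nitrate_vacuole_atp()` models the
alternative storage strategy of other giant sulfur bacteria: vacuoles
occupying 80% of cell volume at 250 mM nitrate and ~16 ATP per mole of
nitrate. The cell volumes behind the literature's 0.08–375 µmol ATP
range are not printed anywhere, so volume is an explicit input and the
package does not assert that range as ground truth; the tests instead
check that the formula inverts consistently at both endpoints.
`compare_strategies()` reports the yield ratio and its raw log~10~
(no flooring), which at the lower endpoint is ~3.7 orders of magnitude
in favour of nitrate.

## Sediment sulfide reservoirs

For a bulk sediment volume with porosity $\phi$:

* dissolved: $V \phi \cdot c_{\mathrm{H_2S}}$ (µM → µmol via the
  cm³–L factor), giving 0.027 ≈ 0.03 µmol/cm³ at $\phi = 0.9$ and 30 µM;
* mineral-bound: $V (1-\phi)\, \rho_s \cdot \mathrm{AVS}$, giving
  0.050–0.100 µmol/cm³ at 0.3–0.6 µmol/g solid.

The solid grain density is not reported for the littoral peat/sand
mixture. The default $\rho_s = 1.67$ g/cm³ is a back-calibration: it is
the unique density that reproduces *both* reported inventory endpoints
(0.05 and 0.10 µmol) from the measured AVS endpoints at $\phi = 0.9$,
and it is physically sensible for an organic-rich peat–quartz mixture
(between ~1.4 for peat solids and 2.65 for quartz). It is a configurable
parameter, not a constant. Headline numbers are displayed at two
decimals, rounded half away from zero, matching how the field numbers
are quoted.

The ratio of the two reservoirs (`reservoir_ratio()`, 1.9–3.7 at the
reference conditions) is the quantitative content of the claim that
mineral-bound sulfide is the larger electron-donor pool — the pool a
calcite-precipitating, proton-exporting cell could uniquely tap.

## Single-cell genome QC

* `filter_contigs()`: drops contigs < 500 bp (threshold kept, "less
  than" removed), the usual post-assembly cleanup.
* `n50()`: largest length $L$ such that contigs ≥ $L$ cover at least
  half the assembly — the common convention, stated explicitly because
  alternatives differ on ties. A brute-force oracle over random length
  sets confirms it.
* `gc_unimodality()`: Gaussian-kernel density of per-contig GC on a
  fixed 512-point grid over [0, 1], bandwidth 0.02 GC-fraction units
  (about the spread of a clean single-genome draft); modes are strict
  local maxima above 1% of the peak density, the floor suppressing
  numerical ripples in near-flat tails. One mode is consistent with an
  uncontaminated draft; two or more flag a mixture.
* `completeness()`: detected fraction of a conserved single-copy marker
  set. The canonical marker list is an input, not a constant — the
  package ships only a clearly-labelled synthetic placeholder list
  (`inst/extdata/marker_set_synthetic.csv`), and marker *detection*
  (homology search) is out of scope.
* `estimate_genome_size()`: assembly size / completeness, rounded to one
  decimal **half away from zero** — the convention is load-bearing,
  since 1.3/0.40 = 3.25 must report as 3.3 (banker's rounding would give
  3.2). Scaled values are snapped to nine decimals first so binary
  representation error (3.8/0.8 = 4.74999…) cannot drop an exact half.

The extrapolation assumes markers sample the genome uniformly;
amplification bias in single-cell libraries violates this to an unknown
degree, which is why estimated sizes are reported to one decimal only.

## 16S phylotyping

`pairwise_identity()` uses the pairwise-deletion convention: the
denominator counts columns where **both** sequences are non-gap, and a
match requires identical unambiguous bases (N never matches, including
against N; U is normalized to T on load). The all-columns denominator is
available as an option since the convention behind published identity
figures is rarely stated. `identity_matrix()` is symmetric with 100 on
the diagonal by construction.

Cluster A/B assignment follows the classical diagnostic: phylotypes with
a deletion in helix 38 of the V6 region form Cluster A, intact-helix
phylotypes Cluster B. `detect_helix38_deletion()` calls a deletion when
the gap fraction inside an annotated region reaches 0.5; the region is
supplied as an annotation (0-based, half-open columns) because helix
coordinates are alignment-specific and hard-coding reference numbering
would silently break on re-aligned data.

## Synthetic data: what it does and does not emulate

All generators are seed-deterministic (identical seed and parameters
give identical output, without disturbing the caller's RNG stream) and
attach a schema-tagged truth sidecar consumed by the tests.

* Water and sediment generators reproduce the basin reference columns
  verbatim in their "paper"/"paper-basin" scenarios and jitter around
  them otherwise (porosity truncated to [0, 1]).
* `gen_marker_survey()` drops markers independently at a fixed rate —
  uniform dropout, deliberately ignoring the *correlated* dropout that
  amplification bias produces in real single-cell data.
* `gen_contig_set()` draws lognormal lengths and mixture-of-normals GC.
* `gen_alignment()` places substitutions by **exact count**, not
  Bernoulli draws: one block of substituted columns shared by all
  non-root sequences plus disjoint private blocks, so every pair differs
  at $k = \mathrm{round}((1-t)L)$ columns ($k$ or $k+1$ between non-root
  pairs when $k$ is odd). Identity targets are therefore exact by
  construction, which is what lets the identity-matrix tests assert
  equality rather than tolerance. Deletions are implanted as literal gap
  runs with recorded coordinates.

Passing tests on these inputs demonstrate the *algorithms* are correct
under known truth; they do not demonstrate robustness to real-data
pathologies (chimeras, correlated MDA dropout, alignment error), which
are upstream of this package's scope.

## Problem sizes and numerical choices

The test suite runs the property checks at sizes chosen to give tight
oracle coverage while completing in seconds on one core: 1000 random
contig sets for the N50 oracle, a 10 × 6 budget/cost grid for division
accounting, 200 replicate surveys of 1000 markers for completeness
recovery, 20 seeded alignments for cluster-call truth, and a
4 × 4 × 5 T/S/pH grid for the speciation cross-check against independent
published constant fits (Harned & Davis / Harned & Scholes fresh water;
Lueker 2000 seawater), with a 5% agreement band that comfortably covers
the small scale offsets between formulations.

Known limitations: no alkalinity-based speciation; Ω extrapolated below
S = 5; the energetics model ignores the cost of pumping Ca^2+^ into the
inclusion vacuole (which would reduce the net yield, as would any
ΔΨ/ΔpH partitioning of the proton-motive force); and the genome-size
estimator inherits the uniform-marker assumption discussed above.
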