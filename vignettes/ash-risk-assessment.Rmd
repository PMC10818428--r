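---
title: "Assessing ecological and health risks of REYs and heavy metals in coal ash"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing ecological and health risks of REYs and heavy metals in coal ash}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reyrisk)
```

Coal fly ash concentrates both potentially recoverable rare earth elements
plus yttrium (REYs) and genuinely hazardous heavy metal(loid)s. This package
implements the chain of indices used to judge an ash from both sides:
is it worth mining for REYs, and how dangerous is it to ecosystems and to
people living near the stacks and landfills? This vignette explains each
model, its assumptions, the defaults, and what the package's synthetic data
can and cannot tell you about real ash.

## Element sets and reference compositions

All analyses work on the 15-element REY family (the lanthanides minus
radioactive promethium, plus yttrium, which geochemically tracks the heavy
lanthanides) and 13 heavy metal(loid)s. `element_set()` fixes the
partitions: light REYs La–Gd, heavy REYs Tb–Lu plus Y, and the demand-based
split into *critical* (Eu, Tb, Nd, Dy, Y, Er — supply-constrained, high
demand) and *excessive* (Ce, Yb, Ho, Tm, Lu — oversupplied) groups.

Two reference compositions are shipped as CSV under `inst/extdata/`:

* **UCC** — the Upper Continental Crust average of Rudnick & Gao (2003),
  the background for the enrichment factor, geoaccumulation index and
  ecological risk. This compilation was chosen over alternatives (e.g.
  Taylor & McLennan 1985) because its values (Lu 0.31, Gd 4.0 mg/kg)
  are consistent with the downstream index values the package is
  validated against.
* **NASC** — the North American Shale Composite of Gromet et al. (1984),
  used only to normalize patterns for Ce/Eu anomaly calculation. A few
  elements not reported by Gromet et al. carry commonly adopted
  interpolated values, marked in the file's `source` column. Published
  anomaly tables are sensitive to exactly which NASC compilation a study
  used, which is rarely stated; anomaly outputs here are therefore
  validated by structural properties (flat pattern gives exactly 1,
  scale invariance) rather than against any published per-sample table.

Both load through `load_reference_set()`, and users can substitute their
own CSV (`element,value` columns) to change the background.

## Geochemical characterization

`normalize_rey()` divides each sample by the reference composition
element-wise. `rey_anomalies()` computes

$$Ce/Ce^{*} = \frac{Ce_N}{\sqrt{La_N \cdot Pr_N}}, \qquad
  Eu/Eu^{*} = \frac{Eu_N}{\sqrt{Sm_N \cdot Gd_N}},$$

the ratio of the measured shale-normalized concentration to its
geometric interpolation from the flanking elements. The geometric mean
is used (not arithmetic) because normalized REY patterns are
log-linear locally; it also makes the anomaly exactly 1 for any flat
pattern and invariant under uniform scaling — the two properties the
test suite asserts. Values above 1 are positive anomalies (e.g. the
Eu enrichment typical of feldspar-rich feed coal), below 1 negative
(Ce oxidation state fractionation).

`rey_prospectivity()` computes the resource-screening quantities: total,
light and heavy REY sums, the critical-group sum, the critical
percentage, and the outlook coefficient (critical/excessive ratio). Ash
with critical percentage ≥ 30% and outlook ≥ 0.7 is flagged promising as
a secondary REY source.

```{r}
fly_means <- synthetic_default_means()$fly[element_set()$reys]
conc <- as_concentration_table(
  data.frame(sample_id = "fly_mean", t(fly_means), check.names = FALSE))
rey_prospectivity(conc)[, c("sum_rey", "pct_critical", "outlook", "promising")]
```

## Ecological risk indices

Three standard contamination indices, all against the UCC background
$C_N$:

* **Enrichment factor** $EF = (C_x/C_{Mn})_{sample} / (C_x/C_{Mn})_{UCC}$
  (`enrichment_factor()`). Manganese is the reference element: it is
  abundant, measured precisely, and not systematically enriched by coal
  combustion. EF is invariant under uniform dilution of the sample.
* **Geoaccumulation index** $I_{geo} = \log_2[C_x/(1.5\,C_N)]$
  (`geoaccumulation()`); the 1.5 factor absorbs natural background
  fluctuation, so 1.5× background scores exactly 0 and 3× scores 1.
* **Hakanson risk** $E_r = T_r\,C_x/C_N$ per element and
  $RI = \sum E_r$ per sample (`ecological_risk()`). The toxicity
  response coefficients $T_r$ (shipped in `toxicology.csv`) weight each
  element by its hazard: 40 for Hg down to 1 for Mn/Zn among the metals,
  and 20 (Lu) down to 1 (Ce, La) among the REYs; the 15 REY coefficients
  sum to 96, so a hypothetical ash exactly at crustal composition scores
  RI = 96 from REYs. Deliberately, $E_r$ uses the raw concentration
  ratio, with no Mn correction — the Mn double ratio belongs to EF only.

Class boundaries follow the standard literature bins and are
override-able in `classify_ef()`/`classify_igeo()`. RI classes use a
closed moderate band: low < 150 ≤ moderate ≤ 300 < high < 600 ≤ very
high, with ties at 600 resolving upward.

## Health risk: the USEPA residential-soil model

`daily_dose()`, `hazard()` and `cancer_risk()` implement the standard
USEPA residential exposure equations for incidental ingestion, dermal
contact and inhalation of resuspended particles:

$$ADD_{ing} = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT}\times 10^{-6},\quad
ADD_{derm} = \frac{C \cdot SA \cdot AF \cdot ABS \cdot EF \cdot ED}{BW \cdot AT}\times 10^{-6},\quad
ADD_{inh} = \frac{C \cdot InhR \cdot EF \cdot ED}{PEF \cdot BW \cdot AT}$$

with `C` in mg/kg and doses in mg per kg body weight per day. Defaults
(`default_exposure_profiles()`):

| factor | child | adult | units |
|---|---|---|---|
| ingestion rate IR | 200 | 100 | mg/day |
| exposure frequency EF | 350 | 350 | days/year |
| exposure duration ED | 6 | 24 | years |
| body weight BW | 15 | 70 | kg |
| skin area SA | 2373 | 6032 | cm² |
| adherence factor AF | 0.2 | 0.07 | mg/cm² |
| dermal absorption ABS | 0.001 | 0.001 | — |
| inhalation rate InhR | 7.6 | 20 | m³/day |
| particulate emission factor PEF | 1.36 × 10⁹ | 1.36 × 10⁹ | m³/kg |

The non-carcinogenic averaging time is `ED × 365` days; the
carcinogenic one is a fixed 70-year lifetime for both receptors.

Design choices worth stating explicitly:

* A single oral reference dose per element is applied to all three
  pathways — no gastrointestinal-absorption adjustment for dermal doses
  and no separate inhalation reference concentration. REY toxicology is
  too sparse to support pathway-specific values; a user who has them can
  supply a custom toxicology table.
* Cancer risk applies the slope factor to the **ingestion** lifetime
  dose only. For the REYs the single oral slope factor 3.2 × 10⁻¹²
  (mg kg⁻¹ day⁻¹)⁻¹ is shared by all 15 elements, as is the oral RfD of
  0.02 mg kg⁻¹ day⁻¹. Because all REYs share one RfD/CSF, a lumped
  total-REY concentration gives the same HI/TCR as any per-element
  split of it — a property the deterministic targets exploit.
* Elements with no established oral slope factor (Cu, Hg, Mn, Zn, V,
  Ba, Mo) contribute zero to TCR rather than erroring, so mixed
  REY+metal tables score without manual filtering.
* Under these defaults ingestion contributes > 95% of every HI; dermal
  and inhalation terms are second-order (asserted in the tests).

With the mean ash (total REY 240.5 mg/kg), this model gives child/adult
REY hazard indices of about 0.15 / 0.017 and cancer risks of
8.4 × 10⁻¹⁶ / 3.6 × 10⁻¹⁶ — three (HI) to ten (TCR) orders of magnitude
below the HI = 1 and 10⁻⁶ safety limits, confirming that REYs are a
negligible sliver of the risk an ash poses next to its heavy metals.

## Monte Carlo uncertainty and sensitivity

Deterministic point estimates hide the spread of plausible exposures.
`run_mcs()` samples element concentrations and exposure factors from
configurable distributions (`dist_spec()`: point, normal, lognormal,
triangular, uniform, all optionally truncated by rejection) and pushes
every draw through the same dose kernel as the deterministic model, so
a run in which every distribution is a point mass reproduces the
deterministic result *exactly* — the key consistency invariant.

Default distributions (`default_exposure_dists()`), chosen as the
simplest shapes consistent with exposure-factor handbooks since the
study this emulates does not state its choices: body weight normal with
CV 0.2 truncated at zero (anthropometric spread), ingestion rate
triangular with mode at the default and limbs at ±50% (bounded,
mode-anchored judgment), exposure frequency triangular (180, 350, 365)
days/year (between half-year and near-permanent residence), all other
factors fixed. Concentrations get per-element truncated normals with
the observed column mean/SD (`conc_dists_from_table()`), consistent
with the approximate normality the generator and the Ryan–Joiner test
assume. The non-carcinogenic averaging time tracks the *drawn*
exposure duration.

Sensitivity is the Spearman rank correlation between each varying input
and the endpoint, ranked by absolute value with alphabetical
tie-breaking (`sensitivity_ranking()`); Spearman is used because the
dose model is monotone but nonlinear in body weight. Under the default
distributions the sensitive exposure factors are body weight (negative),
ingestion rate and exposure frequency (positive) — the same trio the
underlying study reports. Runs default to 10,000 iterations and require
an explicit seed; results carry mean, SD, the 5/25/50/75/95 percentiles
and the probability of exceeding the safety limit (1 for HI, 10⁻⁶ for
TCR).

## Descriptive statistics

`pearson_matrix()` wraps the standard Pearson correlation across
samples (constant columns yield NA with a warning rather than an
error). `ryan_joiner()` computes the probability-plot correlation
between the ordered sample and Blom normal scores
$\Phi^{-1}((i-3/8)/(n+1/4))$ with the standard α = 0.05 critical-value
approximation $1.0063 - 0.1288/\sqrt{n} - 0.6118/n + 1.3505/n^2$.
The Blom plotting position is the conventional choice in the
statistical packages that popularized the test; the statistic is the
square root of the Shapiro–Francia W′ on the same plotting positions,
which the test suite uses as an independent cross-check.

## The synthetic generator

Real per-sample ash data are rarely redistributable, so
`generate_concentrations()` draws tables with the statistical structure
the analysis assumes:

* per-element means defaulting to published fly-/bottom-ash group means
  (totals ≈ 302 and 179 mg/kg REY; light-to-heavy ratio ≈ 4:1), with
  heavy-metal means at magnitudes typical of lignite ash;
* a common coefficient of variation (default 0.2, a typical
  between-sample spread for ashes from one region);
* a **single common factor** driving all REYs, with loadings spread so
  pairwise Pearson correlations span 0.80–0.98 — the simplest structure
  reproducing the strong co-occurrence band of REYs sharing one
  provenance. An As–Cd–Hg block shares a second factor (pairwise r
   0.7), since these volatile elements co-condense on fine particles;
  other metals vary independently;
* truncation at zero by whole-row rejection (the resample count is
  attached as an attribute); at CV 0.2 the truncation is essentially
  never active, so the achieved correlations match the factor-model
  closed form within sampling error.

What it does **not** emulate: spatial or between-plant structure,
analytical (ICP-MS) measurement error as distinct from natural
variability, correlated REY–major-element relationships, or heavy
tails/outliers in metals like As. Passing tests on synthetic data
therefore demonstrate internal consistency of the pipeline, not that
any particular real ash satisfies the normality and correlation
assumptions — check those with `ryan_joiner()` and `pearson_matrix()`
on your own table first.

## The pipeline

`run_pipeline()` chains everything — load or synthesize, descriptive
statistics, geochemistry, ecological indices, health risk, optional
Monte Carlo — writing one CSV per stage plus a versioned JSON summary
(full-precision floats; rounding is for display only). The run is a
pure function of config + seed: rerunning a config gives byte-identical
outputs, and each stage CSV can be re-consumed independently. Stage
errors abort with the stage name and offending sample/element. The
package is used from R; the pipeline function plus per-stage functions
are the equivalent of a subcommand interface, and a shell wrapper would
be a one-line `Rscript -e` around `run_pipeline()`.

## Numerical notes and limitations

* All index computations are closed-form; no optimization or iteration
  is involved anywhere except rejection sampling (bounded at 1000
  rounds, then a hard error suggesting a smaller CV).
* Printed literature values are rounded to 2 significant figures; the
  package reports full precision and leaves rounding to the caller.
* Test problem sizes are kept small (n = 1000 generator draws for
  correlation recovery, 10⁴ Monte Carlo iterations for convergence
  checks) — large enough that sampling error is well below the asserted
  tolerances, by the ±0.05 band for correlations and a 3-standard-error
  band for the MCS mean.
* The two fixed receptors (child, adult) are not age-integrated; dietary
  and groundwater-leaching pathways are out of scope, as are source
  apportionment and spatial interpolation.
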