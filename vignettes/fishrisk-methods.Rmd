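---
title: "Methods: screening dietary risk from organochlorine residues in fish products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening dietary risk from organochlorine residues in fish products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishrisk)
```

## The problem

Frozen fish fillets imported into Europe — Nile tilapia, panga, Pacific
cod, pollock and yellowfin sole among the most common — carry trace
residues of two families of persistent organochlorines: legacy
pesticides (HCH isomers, DDT and its metabolites, the endosulfans,
cyclodienes) and PCB congeners. Concentrations are measured by GC-MS in
ng per g of wet product and are small enough that many fall below the
detection limit. The public-health question is not whether residues are
present (almost all are) but whether the dietary dose implied by
ordinary fish consumption approaches any toxicological reference point.
`fishrisk` implements that screening end to end for a panel of 15
pesticides and 18 PCB congeners across five species.

Two reference frameworks apply, one per contaminant family:

* **Pesticides** are screened with the lifetime average daily dose,
  $\mathrm{LADD} = C \cdot \mathrm{ADC} / \mathrm{BW}$ (mg/kg/day, with
  the ng-to-mg bridge $10^{-6}$ applied inside the function), and the
  hazard quotient $\mathrm{HQ} = \mathrm{LADD}/\mathrm{RfD}$ against a
  chronic oral reference dose. HQ > 1 flags potential harm.
* **Dioxin-like PCBs** (the four non-ortho congeners 77, 81, 126, 169
  and eight mono-ortho congeners) are aggregated into a toxic
  equivalency, $\mathrm{TEQ} = \sum_i C_i \cdot \mathrm{TEF}_i$
  (pg-TEQ/g, factor 1000 pg/ng applied inside), converted to a weekly
  intake $\mathrm{WI} = \mathrm{TEQ}\cdot\mathrm{ADC}\cdot 7/\mathrm{BW}$
  and compared with the tolerable weekly intake — both the former limit
  of 14 pg-TEQ/kg bw/week and the current EFSA limit of 2, whose
  seven-fold reduction is the pivot of the assessment.

Non-dioxin-like congeners appear in summaries only; they carry no TEF
and no RfD.

## Parameters and their defaults

All constants are data (`inst/extdata/reference_config.yaml`), never
literals in formulas:

| parameter | default | unit | note |
|---|---|---|---|
| ADC, HQ path | 34.30 | g/day | national fish-consumption figure used for the pesticide dose |
| ADC, TEQ path | 34.19 | g/day | 12.48 kg/yr ÷ 365; the intake path is documented with this figure |
| BW | 70 | kg | adult body weight |
| TWI (former / current) | 14 / 2 | pg-TEQ/kg bw/week | the threshold change drives the conclusions |
| TEF set | WHO 2005 | – | 12 dl-congeners; 0.1 for PCB 126 down to 3e-5 for mono-ortho |
| pesticide LOD | 0.01 | ng/g | average method LOD; per-analyte override in config |
| PCB LOQ | 0.065 | ng/g | midpoint of the reported 0.03–0.1 range |

The two consumption figures are deliberately separate: each screening
path keeps the figure its framework was published with, and both are
configurable.

**Reference doses.** No RfD values accompany the underlying study, so
the packaged set is an editable config documented in the YAML header:
US EPA IRIS chronic oral RfDs where a listing exists, with
parent-compound surrogates for isomers and metabolites that have none
(HCH isomers → lindane, DDD/DDE → DDT, endosulfan forms → endosulfan,
endrin ketone → endrin). Under this set the per-species HQ sums land
around 0.003–0.005 — comfortably inside the 0.003–0.013 corridor the
study reports, but the corridor is treated as plausibility, not a
recomputation target, precisely because the original RfD choices are
unstated.

## Left-censored values

A `<LOD` record carries no number, only the censoring marker. Before
any arithmetic a `censoring_policy()` substitutes 0 (default), LOD/2 or
LOD. Zero-substitution is the default because it reproduces the
published endosulfan-sulfate shares exactly from the published means —
the one place where the substitution rule leaves a visible fingerprint
(the sulfate accounts for 65/53/73/56/78 % of total endosulfan across
the five species; the fourth value computes to 55.5 and is printed as
55 in the source tables). The three policies are provably ordered, so
switching to LOD-substitution can only raise exposure estimates; that
monotonicity is enforced by property tests.

```{r shares}
round(endosulfan_shares(paper_fixture())$sulfate_share_pct, 1)
```

## The deterministic fixture and what it can support

No raw per-sample data are deposited with the study; only per-species
summary tables are printed. `paper_fixture()` therefore encodes one
pseudo-record per species × analyte at the printed mean (censored cells
as censored records) plus the composition metadata (79 batches, 790
samples, glaze/fat/dry-weight moments). Since only means enter the
LADD, HQ, TEQ and WI formulas, this fixture is a complete input for the
assessment — but it cannot support Duncan's test or correlations, which
need replication; those run on simulated data.

Two published quantities are *inputs*, not recomputation targets:

* The species TEQ values (1.79 pg-TEQ/g for Nile tilapia, 2.14 for
  pollock) evidently derive from unrounded congener data: applying the
  WHO 2005 TEFs to the printed two-decimal congener means gives 3.52
  for tilapia, because a 0.01 ng/g rounding step on PCB 126 alone moves
  the TEQ by 1 pg-TEQ/g. The packaged `printed_teq.csv` carries the two
  published values, and the weekly-intake verification
  (1.79 × 34.19 × 7 / 70 = 6.12 pg-TEQ/kg bw/week) anchors on the
  tilapia pair, which is internally consistent (the pollock pair prints
  7.45 where the arithmetic gives 7.32; the discrepancy is reported as
  computed).
* The published PCB min/max/median rows for three species are on a
  different (lipid-like) basis than the mean rows and are not packaged.

A consequence for the orchestrated report: `run_full_assessment()`
keeps every section cross-consistent — the intake section's WI derives
from the TEQ the report itself computed — so on the fixture it shows
the resolution-limited TEQs (3.2–5.8) and their intakes, not the
published 6.12. The worked 6.12 example lives where it belongs, in the
`weekly_intake()` call on the published TEQ input
(`analysis/03_teq_weekly_intake.R`).

## Duncan's multiple range test

Between-species differences are tested per analyte with Duncan's
multiple range test at $\alpha = 0.05$. The implementation computes the
pooled MSE and residual df from the one-way layout, sorts the means,
and compares the range of every tested span of $p$ ordered means
against $R_p = q_{1-\alpha_p}(p, \nu)\sqrt{MSE/n_h}$ with protection
level $\alpha_p = 1-(1-\alpha)^{p-1}$; quantiles come from `qtukey`, so
no critical-value tables are embedded and any $\nu$ is supported.
Unbalanced layouts use the harmonic mean $n_h$. Subspans of a span
found homogeneous are never tested (the standard shielding rule), and
homogeneous subsets become letters. The test suite checks the letters
against an independently coded exhaustive-span oracle across hundreds
of random layouts.

One property that seems intuitive is *not* asserted, because it is
false: merging two groups with identical data can *increase* the number
of distinct letters. A duplicate group inflates the span sizes $p$ and
with them the protection levels and critical ranges, so the duplicated
layout can be more conservative than the pooled one. The suite asserts
instead what is true: identical-data groups always share a letter, and
the letter partition is invariant under positive rescaling.

## The synthetic-data generator

`simulate_measurements()` emulates the study design: per species, the
published number of batches; 10 samples per batch; per
(species, analyte) cell, the published mean and CV as targets.

* **Family.** Lognormal by default: residue concentrations are positive
  and right-skewed, and published CVs up to 243 % exclude normality. A
  truncated normal (moment-calibrated by solving the truncated-moment
  equations) is available for sensitivity checks at CV < 100 %, the
  mathematical ceiling for a normal truncated at zero.
* **Hierarchy.** The total CV splits multiplicatively into a
  between-batch component (default: half the target CV — the published
  tables pool all dispersion, so the split is a free parameter held
  fixed) and a within-batch remainder chosen so that
  $(1+cv^2) = (1+cv_b^2)(1+cv_w^2)$; under the lognormal family the
  overall mean and CV then match the targets exactly in expectation.
* **Censoring.** Draws below the analyte's LOD are emitted as censored
  records; the realized censored fraction matches the closed-form
  lognormal mass below the LOD (verified against binomial bounds).
  Cells printed wholly `<LOD` emit all-censored records. For
  calibration checks the censoring layer can be switched off
  (`apply_censoring = FALSE`): several cells sit barely above the
  0.01 ng/g LOD (yellowfin sole aldrin, mean 0.0114, has roughly 16 %
  of its mass below it), where any substitution policy would bias the
  recovered mean far beyond its sampling error and say nothing about
  the generator.
* **Composition covariates.** Glaze, fat and dry-weight percentages are
  drawn per batch from the published species moments; both they and the
  batch contamination level load $\sqrt{\rho}$ on a shared batch
  factor, giving latent correlation $\rho$ (default 0.4, mid-range of
  the published analyte-composition correlations) so correlation
  analyses are exercisable. Pearson r on the skewed concentration scale
  is attenuated relative to $\rho$; the simulator makes correlation
  structure *available*, it does not reproduce the published
  coefficient table, which would require the undeposited raw data.

What passing simulator-based tests shows, and what it does not: the
pipeline handles realistically dispersed, batch-structured, censored
data and recovers known truth. Real GC-MS data add features the
generator deliberately omits — recovery variation, co-elution,
batch-specific LODs, non-lognormal tails — so calibration results here
do not certify behaviour on raw instrument data.

## Numerical choices and known limitations

* Internal values are full precision; rounding happens only at
  serialization (CV two decimals, shares integers, correlations three
  decimals), matching the reporting precision of the source tables.
  Where a printed value disagrees with its own printed inputs at the
  last digit (the CV printed 30.82 where the printed mean/SD give
  30.81; a second case prints 12.81 vs recomputed 12.80), the package
  reports the recomputed value and does not chase the printed digit.
* Degenerate inputs are defined, not accidental: an all-censored group
  under zero-substitution has mean 0 and an explicitly undefined CV; a
  zero-variance series refuses a correlation; a group with fewer than
  two values refuses Duncan's test; an empty measurement set aborts the
  pipeline before any section is written.
* The per-species aggregate HQ is the sum of per-pesticide HQs — the
  conservative standard screening aggregate, reported as a separate
  `TOTAL` row.
* Sample-CV recovery at heavy tails is intrinsically noisy: for a
  lognormal with CV ≈ 243 % the sampling SD of the sample CV at
  n = 5000 is tens of percentage points (fourth-moment asymptotics), so
  tight per-cell CV tolerances are achievable only for the moderate-CV
  cells; the test suite documents this at the four heaviest-tailed
  cells.
* Problem sizes used by the checked examples: the full study design
  (79 batches × 10 samples × 33 analytes) simulates in seconds;
  calibration checks use 500 batches (n = 5000) per cell; Duncan oracle
  comparisons run over 200 random layouts of 2–5 groups.
* Out of scope by design: instrument-signal processing, recovery QC,
  lipid-basis reporting (derivable on demand as wet-weight /
  (fat %/100), never stored), dioxin/furan TEQ contributions, and
  cancer slope-factor risk.
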