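---
title: "Methods: targeted lipid-panel analysis and the calibrated simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted lipid-panel analysis and the calibrated simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidpanel)
```

## The analysis problem

Targeted complex-lipid panels quantify hundreds of lipid species (here: 941
species in 14 classes) as concentrations in nmol per mg tissue, by
flow-injection MRM against spiked internal standards. The scientific
questions asked of such data in a two-group liver study — here, a congenic
mouse model in which lipophagy (the autophagic degradation of lipid
droplets) is impaired in one genotype — are about *aggregates* of species,
not raw transitions:

* How much of each **lipid class** (TG, DG, MG, PC, PE, PI, LPC, LPE, Cer,
  HexCer, LacCer, dhCer, SM, CE) is present, absolutely (nmol/mg) and as a
  fraction of total lipid (mol%)?
* Which **fatty acids** make up each class, and how do the saturation
  (SFA/MUFA/PUFA), series (n-3/n-6) and chain-length (SC-/LC-PUFA) fractions
  shift between groups?
* What do **surrogate enzyme activities** — product-to-precursor mol% ratios
  for SCD1, ELOVL3/5/6, FADS1/2 — and **ratio biomarkers** (n-6/n-3 ratio,
  n-3 index, TG/DG, PC/PE) say about the underlying lipid metabolism?
* Which features differ between groups under **Welch's t-test**?

`lipidpanel` implements this pipeline end to end, plus a synthetic data
generator calibrated to the published class-level statistics of the
lipophagy study, so that every stage is testable although the study's raw
per-sample data are not publicly deposited ("available upon request").

## Nomenclature model

Species names use the shorthand `CLASS(c:d)` grammar:

* `PC(16:0/20:4)` — all esterified chains written out (DG, PC, PE, PI carry
  one or two chains as written);
* `CE(18:1)`, `SM(16:0)` — single-chain classes (CE, MG, LPC, LPE and the
  sphingolipids); for sphingolipids the token is the N-acyl chain — the
  sphingoid backbone is deliberately not modelled and never enters
  fatty-acid profiles;
* `TG(52:3) FA 18:2` — sum composition plus one specified esterified fatty
  acid. TG species must use this dialect, because the panel reports exactly
  one esterified fatty acid per triacylglycerol; the parser enforces it.

The vendor's exact export dialect is not published; this grammar is the
package's documented assumption, and `format_species_name()` provides the
canonical round-trip form.

**Series assignment.** Direct-infusion MRM cannot distinguish double-bond
positional isomers, so a chain written `18:3` could be alpha-linolenic
(n-3) or gamma-linolenic (n-6) acid. The package ships an editable lookup
table (`default_series_table()`, `inst/extdata/fa_series.tsv`) mapping each
`(carbons, double_bonds)` pair to the canonical physiological isomer
(18:2 to n-6, 18:3 to n-3, 20:4 to n-6, 20:5/22:5/22:6 to n-3, 16:1 to n-7,
18:1 to n-9, ...). An explicit suffix in a name (`18:3n-6`) overrides the
lookup. Combinations absent from the table stay `unassigned` and are
excluded from series rollups (they still count toward saturation rollups).

**Chain-length classes.** LC-PUFA is defined as a PUFA with at least 20
carbons — the standard convention, consistent with AA, EPA and DHA being the
canonical long-chain PUFAs — and the cutoff is a function argument
(`lc_cutoff`) for users who prefer 22.

## Aggregation conventions

* Class concentrations are plain sums of member species; categories
  (glycerolipids, phospholipids, sphingolipids, sterols) sum their classes.
* Compositions are per-sample mol%: class concentration over total lipid,
  times 100. Group-level compositions are computed **per sample, then
  averaged** (mean of ratios), matching the "mean ± SD" presentation of
  panel summary tables. The ratio-of-group-means alternative — the only one
  computable from printed tables — is available via
  `reference_class_ratio()` and is what desk checks against published
  summary values use.
* Fatty-acid profiles attribute each species' concentration **once per
  specified chain**: `PC(16:0/20:4)` at 1 nmol/mg contributes 1 to C16:0 and
  1 to C20:4; a TG contributes its full concentration to its single
  specified fatty acid. No molar-multiplicity weighting is applied beyond
  the chain count — a convention forced by the TG dialect (per-chain
  splitting is impossible when only one of three chains is known) and
  applied uniformly for consistency.
* Undetected species (zero in all samples) are excluded from composition
  denominators and from differential testing but retained in species counts
  as part of the panel description.

## Indices

Surrogate enzyme activities are product-to-precursor ratios of total-lipid
mol%: SCD1 is reported separately for its two canonical edges
(C16:1/C16:0 and C18:1/C18:0); ELOVL6 is C18:0/C16:0; ELOVL3, ELOVL5,
FADS1 and FADS2 are the mean of their two pathway edges (e.g. FADS1:
20:3n-6 to 20:4n-6 and 20:4n-3 to 20:5n-3). Only the SCD1 edges are stated
as formulas in the source study; the remaining edges follow the standard
MUFA / n-3 / n-6 biosynthesis schemes, are labelled figure-derived, and
live in an editable plain-text table (`inst/extdata/pathway_edges.tsv`).
Because profiles are bucketed by `carbons:double_bonds`, series-annotated
edge endpoints are matched to their bucket (18:3n-6 reads the C18:3
bucket); this is an explicit consequence of MRM isomer blindness.

Further indices: the Valenzuela desaturation-capacity estimates
(EPA+DHA)/ALA and AA/LA; the n-6/n-3 ratio (summed n-6 mol% over summed
n-3 mol%); the n-3 index (summed n-3 mol%, interpreted as a mol% sum over
all n-3 fatty acids); and the TG/DG and PC/PE class-concentration ratios.
All indices are invariant to rescaling a sample's concentrations. A zero
denominator yields an explicit `defined = FALSE` flag with `NA`, never a
silently dropped sample. Indices are computed on total-lipid profiles by
default, with per-class profiles available through
`fatty_acid_composition(scope = "class")`.

By default index group comparisons reuse the same Welch machinery as
species-level tests.

## Statistics

Welch's unpaired t-test (no equal-variance assumption,
Welch–Satterthwaite degrees of freedom, two-sided p) is the study's
statistical layer and is implemented directly from the formulas; the test
suite cross-checks it against R's reference implementation to 1e-12.
Significance is called at p <= 0.05 **inclusive**, with raw p-values — no
multiple-testing correction, matching the source analysis; a
Benjamini–Hochberg mode is available and clearly labelled as non-default.
Log fold changes are base 2 (community convention; recorded in the table
attributes) and defined only when both group means are positive; up/down
calls in summaries use the sign of the mean difference, which equals the
logFC sign wherever the latter is defined and remains defined when a group
mean is zero. Zero-variance features follow explicit conventions (t = 0,
p = 1 for identical groups; infinite t, p = 0 with a flag for separated
constant groups) rather than producing NaN. Per-species tests are run on
the concentration scale and, in the class summary, also on the mol% scale,
since both presentations are in scientific use and they answer different
questions (absolute change vs. change relative to total lipid).

The qPCR utility implements the delta-Ct method: delta-Ct = Ct(target) −
arithmetic mean of the reference-gene Cts (Eef2, Ppia, Hprt by default;
equivalent to a geometric mean in linear expression space), relative
expression 2^(−delta-Ct).

## The calibrated simulator

The generator's defaults are the study conditions: 877 detected species in
the published per-class counts (TG 518 ... CE 26), padded by 64
never-detected species to the 941 measured; two groups of 7 livers.

Per class, the simulator:

1. draws Dirichlet(alpha = 1) shares to split the class mean concentration
   (control group: the published control means) across member species;
2. multiplies case-group species means by the class multiplier — the ratio
   of the published case/control class means, about 2.14 for TG, 1.32 for
   DG, 1.88 for CE, 0.84 for HexCer;
3. applies fatty-acid tilts: species carrying an n-3 chain are scaled by
   0.65 and species carrying an 18:1 chain by 1.25 in the case group, then
   the class is renormalised to its target total. Class-level and
   fatty-acid-level effects are therefore independently controllable, and
   the tilt values are the package's own choice of a "clearly visible but
   not extreme" composition shift reproducing the published directions
   (n-3 depletion, oleic-acid accumulation);
4. draws independent lognormal values per species and sample, with the
   class coefficient of variation (published SD/mean of the control group,
   floored at 0.05 because one printed SD rounds to 0.000).

What this emulates: class totals, class-level between-group effects and
their directions, composition shifts, and positive skewed measurement
noise. What it does **not** emulate: per-species variance heterogeneity and
inter-species correlation (unknown — the raw data are not deposited; draws
are independent), batch effects, or missingness beyond the fixed
undetected set. Two visible consequences: simulated class-sum SDs are
smaller than the published ones (independent species noise averages out
within large classes), and species-level significant fractions are higher
than the published 29% (every member of a class shifts by the same
multiplier). Passing tests therefore demonstrate correct pipeline
arithmetic and faithful class-level calibration, not a per-species replica
of the original dataset; group-level published percentages are checked as
directions (up-fraction exceeds down-fraction, n-6/n-3 up, n-3 index
down), not magnitudes.

## Numerical and design choices

* Compositions are tested to sum to 100 mol% within 1e-9; aggregation is
  checked exactly against brute-force enumeration on small panels.
* Matrix TSVs are written at 17 significant digits and parsed with base R's
  correctly-rounded reader, so write/read round-trips are bit-identical.
* The report layer runs at the study's problem size (941 species, 14
  samples) in seconds; statistical property checks in the test suite use
  2,631 null features for the type-I error (observed rejection rate must
  lie in [3%, 7%] at alpha = 0.05) and 100 replicate simulations for effect
  recovery (sign recovery for TG, DG, CE, HexCer and direction recovery for
  the n-6/n-3 ratio and n-3 index in at least 90 of 100; TG and CE log2
  effects within 25% relative error).
* The command-line wrapper (`inst/cli/lipidpanel.R`) is a thin veneer over
  `run_pipeline()`; the R functions are the primary interface.

## Worked example

```{r example, eval = FALSE}
library(lipidpanel)

panel <- generate_panel(panel_spec(), seed = 1)
sim <- simulate_concentrations(panel, seed = 2)

stats <- class_group_stats(sim$concentrations, sim$design)
render_table1(stats)

idx <- compute_indices(sim$concentrations)
differential_summary(sim$concentrations, sim$design)
```

## Known limitations

* Series assignment and pathway edges are conventions, not measurements;
  both are overridable from plain-text tables.
* No sn-position, double-bond-position, isotope or adduct handling; no
  LIPID MAPS resolution; no free fatty acids (the panel does not measure
  them).
* The simulator's independence assumption understates class-sum variance;
  analyses of real panels are unaffected (the pipeline itself makes no
  distributional assumption beyond Welch's test).
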