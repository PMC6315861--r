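---
title: "Comparative rice bran metabolomics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative rice bran metabolomics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branmet)
library(dplyr)
```

## The problem

Non-targeted metabolomics of rice bran produces, per cultivar, a list of a
few hundred identified metabolites with unitless, ion-intensity-derived
relative abundances. Values are comparable *within* a metabolite across
samples, but not across metabolites; some metabolites are simply not
detected in some cultivars. From such a table for a panel of cultivars, the
pipeline asks: which metabolites distinguish individual cultivars, which
metabolic pathways do those distinctions concentrate in, and which rice
genes plausibly control them?

`branmet` implements that pipeline as composable tibble-in/tibble-out
steps: `read_abundance()` → `median_scale()` → `compute_zscores()` →
`find_discriminators()` → `enrich()` / `link_genes()` /
`discriminator_breakdown()`, with `generate_bran()` supplying synthetic
panels of the same shape for testing.

## The model and its assumptions

**Median scaling.** Each metabolite's abundances are divided by the median
of its detected values, making the per-metabolite median exactly 1. This is
scale-free: any per-metabolite multiplicative factor (ionization efficiency,
extraction yield) cancels. It assumes only that a majority of cultivars are
"typical" for each metabolite; it does not assume any distributional form.
Median scaling is idempotent, and Z-scores computed downstream are invariant
to per-metabolite positive rescaling of the input — both properties are
checked in the test suite.

**Z-score screen.** `Z = (x − μ)/σ` per (metabolite, cultivar) cell, with
μ and σ taken across the cultivars where the metabolite was detected. Cells
with |Z| strictly greater than 2 are discriminators. Three non-obvious
consequences of this design, all verified empirically in the tests:

- With `c` contributing cultivars and the sample-σ convention, a single
  extreme cell can reach at most `|Z| = (c − 1)/√c` — about 3.88 at
  `c = 17`. The threshold 2 is therefore not a tail probability on a
  reference distribution: it sits at roughly half the attainable range.
- Because μ and σ are estimated in-sample, the null exceedance rate of
  |Z| > 2 under pure noise is well below the Gaussian 4.6% (empirically
  ~1–3% for log-normal noise at σ_log = 0.35), but it is not zero: a
  thresholded screen over thousands of cells reports many noise entries.
  No multiple-testing correction is applied — that is a fidelity decision,
  and the reason reporting aggregates by class and pathway rather than by
  entry.
- On non-negative data the screen is asymmetric. An extreme *high* cell
  dominates the row variance and lands at the 3.88 ceiling, so large upward
  shifts are recovered with certainty. An extreme *low* cell saturates at
  zero abundance: its departure from the mean is capped near μ while σ is
  still inflated by the other cultivars' spread, so its |Z| plateaus around
  1.7–2.3 at σ_log = 0.35 regardless of how large the downward shift is.
  Perfect-sensitivity guarantees in the tests therefore plant upward
  shifts; downward shifts of real low-abundance outliers are detectable but
  not guaranteed.

**Tunable parameters.**

| parameter | default | meaning |
|---|---|---|
| `threshold` | 2 | |Z| cutoff, strict inequality |
| `sigma` | `"sample"` | σ denominator (`c − 1`); `"population"` uses `c` |
| `min_cultivars` | 3 | minimum detected values for a metabolite to enter the screen |
| missing policy | `"skip"` | Z over detected cells only; `"min_impute"` fills row minima |

The σ convention and the missing-value policy are exposed because the
reference workflow does not state them; the defaults (sample σ, skip) are
the most common choices in the ecosystem, and at two detected values σ is
defined but every pair yields |Z| = 0.707 exactly — hence `min_cultivars`
of 3. The strict `>` of the threshold follows the screen's definition
("greater than 2 or less than −2"); at float precision the distinction from
`≥` is immaterial for real data but is pinned by a test.

**Pathway enrichment score.** `PES = (k/m)/(n/N)` is a plain fold
enrichment, computed in closed form (`k·N/(m·n)`, exact in doubles at these
magnitudes). Within a scope unit the counts are conserved — Σk = n and
Σm = N over all pathways — which the tests verify against an independent
loop-based recount. Two scope conventions exist because per-cultivar
reporting needs per-cultivar denominators: the default `per_cultivar` scope
takes k, n from the cultivar's own distinct discriminators and m, N from its
detected (annotated) metabolites; `global` pools distinct metabolites over
the panel. `k` always counts distinct metabolites, never
(metabolite, cultivar) entries. A hypergeometric tail probability is
attached for context only; selection is by score ≠ 1, mirroring the
reporting convention this score comes from.

**Gene linkage.** The bundled gene map (curated from OryzaCyc 4.0 / PMN)
stores, per metabolite, the printed count of genes directly annotated to its
biosynthesis plus an enumerated (sometimes partial — only the top genes are
listed for e.g. glutamate) list of gene IDs and MSU loci. The headline gene
total sums *direct* counts only: the bracketed "common" counts (genes shared
by the generic class pathway, e.g. 153 for a standard amino acid) overlap
almost entirely across metabolites and would multiply-count the same loci.
Metabolites present in the map with zero direct genes (myristate) count as
matched. Taurine's four genes are transporters, not biosynthesis, and carry
a `role = "transport"` flag. Matching is by normalized name through a
curated synonym table (`bran_synonyms()`), since no stable shared identifier
exists across the sources.

## The synthetic generator

`generate_bran()` draws panels with the statistical structure the pipeline
assumes: per-cell abundance `scale_i · exp(σ_log · ε)` with standard normal
ε and a log-normal per-metabolite scale, one pathway per metabolite, one
class per pathway, independent per-cell dropout, and planted
single-cultivar multiplicative shifts of `exp(shift · σ_log)`.

Default conditions: 17 cultivars × 450 metabolites, class proportions
matching an annotated rice bran metabolome (lipids 0.39, amino acids 0.27,
carbohydrates 0.12, nucleotides 0.08, cofactors & vitamins 0.06, secondary
metabolites 0.06, peptides 0.02), 53 pathways, σ_log = 0.35, dropout 0.085.
The dropout default is calibrated so per-cultivar detected totals land in
the 378–430 range observed for the reference panel (at 450 metabolites,
expected detected ≈ 412, the panel mean); the noise level is chosen so that
null exceedances of |Z| > 2 stay in the low single-digit percent range, the
regime in which a 71-of-450 discriminator yield is plausible.

What the generator does *not* emulate — and therefore what passing tests do
not certify about real data: correlated metabolites (co-regulation,
shared pathways), abundance-dependent dropout (low abundance is likelier to
be missed in real LC-MS), heavy-tailed or batch-structured noise, and
isobaric co-elution. The generator is a model of the pipeline's
assumptions, not of a mass spectrometer.

## Numerical choices and degenerate inputs

- Missing means "not detected"; a measured zero is a legal value distinct
  from missing (presence counts include it). A metabolite detected nowhere
  is rejected at validation; a metabolite whose median is zero cannot be
  median-scaled and is named in the error.
- Constant rows (σ = 0) get Z = 0 everywhere and a `constant` flag rather
  than NaN.
- Score-vs-1 comparison in `select_enriched()` uses a 1e-12 tolerance;
  median-of-present equals 1 within 1e-9 after scaling.
- Ordination (`ordination_summary()`) is reporting plumbing: a centered,
  by default unscaled principal component decomposition of the
  cultivar × metabolite matrix, refusing missing values rather than
  silently imputing (run `impute_missing(policy = "min_impute")` first).
  Unit-variance scaling is a flag, off by default because the conventional
  input is median-scaled without standardization.

## Bundled reference tables

`inst/extdata/` ships transcriptions for a published 17-cultivar rice bran
panel: per-cultivar class counts (with printed totals), the 71-metabolite
discriminator list (74 metabolite–cultivar entries), its 15-pathway
annotation catalog, the 34-metabolite gene map, and the synonym table. Two
curation decisions matter when reading them. First, the source's
per-cultivar lipid enumerations name fewer distinct compounds than its own
33-lipid total; the repeated diacylglycerol names across cultivars are
treated as distinct isomers (the source itself reports "two isomers of"
several), which reconciles every per-class and per-pathway count
simultaneously. Second, the full 53-pathway vocabulary of the source panel
was never published; the catalog covers the 15 pathways its discriminators
occupy, so enrichment on the bundled tables is run with all cataloged
metabolites marked detected — sufficient for the pathway-occupancy
structure, but not a reconstruction of the source's per-pathway `m`
denominators, whose PES values are therefore not recomputable.

## Problem sizes used in the checks

The test suite exercises the brute-force enrichment equivalence on ~1000
random small instances, the single-extreme Z bound on 10⁴ random 17-sample
rows, and recovery on 17 × 450 panels over 20 seeds per condition; the
acceptance script re-runs the bundled-table bookkeeping plus 20 synthetic
panels. These sizes were chosen as the smallest that make the binomial
sampling error of the checked rates negligible relative to their assertion
margins.

## Known limitations

- Raw feature tables for the reference panel are not distributed, so
  identity-level reproduction (which 71 metabolites, the published PES
  values) rests on the bundled transcriptions, not on recomputation from
  spectra.
- The screen has no error-rate control; it is a ranking heuristic whose
  null behavior is characterized, not controlled.
- The gene map inherits the source database's japonica bias; links may not
  transfer to indica cultivars.
- Downward-shift detection is structurally weaker than upward (see above);
  claims of "no low outlier" from this screen are weaker than claims of
  "no high outlier".
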