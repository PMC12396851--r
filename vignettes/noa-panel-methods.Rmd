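---
title: "Methods: panel-based monogenic diagnosis of non-obstructive azoospermia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel-based monogenic diagnosis of non-obstructive azoospermia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noapanel)
```

## The diagnostic problem

Non-obstructive azoospermia (NOA) affects roughly 1% of men. Its only
therapeutic route, testicular sperm extraction (TESE) followed by ICSI,
fails in more than half of attempts, and no hormonal or histological
marker predicts failure reliably. A growing set of genes with established
gene–disease relationships (GDR) for spermatogenic failure makes a
virtual-panel approach attractive for two purposes at once: establishing
a monogenic diagnosis, and informing pre-TESE counselling, because for
several genes every reported carrier of a likely-pathogenic/pathogenic
(LP/P) variant has had a negative TESE outcome.

`noapanel` models this workflow end to end: panel registry, variant
filtration, a two-profile ACMG/AMP classification engine, per-gene
TESE-outcome evidence, and cohort association statistics, together with a
synthetic-cohort generator that stands in for patient-level data.

## Filtration model and its assumptions

A variant enters the candidate set when it passes four rule families:

1. **Consequence.** Non-synonymous exonic classes (missense, stop gain,
   frameshift, start loss, in-frame indel) and splice-region variants
   within ±3 bases of the exon boundary. The window is applied
   symmetrically on the signed offset of the nearest junction and the
   junction base itself (offset 0) is kept; the boundary offsets ±3 are
   kept. Splice-region variants without an annotated offset are an error
   rather than a silent drop.
2. **Population frequency.** The maximum population allele frequency
   (e.g. gnomAD popmax) must not exceed 0.01 for autosomal-recessive
   genes or 0.001 for dominant and sex-linked genes. Both boundaries are
   inclusive on the keep side, following the "≤" formulation of the
   rule. An absent frequency is stored as 0: absence from large reference
   populations is the strongest available rarity statement, the standard
   clinical-filtering convention.
3. **Sequencing QC.** Depth ≥ 10× and alternate-read fraction ≥ 0.15,
   again inclusive on the keep side. Copy-number deletions bypass this
   family, as their evidence is not site-level read counts.
4. **Inheritance consistency**, evaluated per patient–gene group among
   the survivors of the record-local rules (so a QC-failing partner
   cannot rescue a compound heterozygote): recessive genes keep
   homozygotes, or two or more heterozygotes (`confirmed_cHET` when a
   shared phase group marks the pair in trans, `candidate_cHET`
   otherwise — retained but flagged as requiring segregation
   confirmation, since the package cannot sequence parents); sex-linked
   genes in XY patients keep hemizygous calls (homozygous calls on X/Y
   are treated as hemizygous-equivalent — a common genotype-caller
   artefact — a deliberate choice the rule text leaves open), while a
   heterozygous call on the X in an XY patient is dropped with a warning;
   dominant genes keep heterozygotes and homozygotes (two copies of a
   dominant allele remain consistent).

Copy-number deletions additionally face a recurrence filter (similar
breakpoints in more than 10 unrelated carriers) and SV-panel frequency
ceilings of 1% (recessive) / 0.1% (sex-linked), exclusive on the drop
side ("≥" removes). Heterozygous deletions survive only as
compound-heterozygous candidates in recessive genes with a surviving
partner variant.

The record-local rules commute: any evaluation order yields the same kept
set, which the test suite checks against a brute-force oracle that
evaluates each predicate independently.

## Classification model

Evidence criteria map to points — supporting 1, moderate 2, strong 4,
very strong 8, benign-direction negated — and the summed score maps to
five tiers: ≥ 10 P, 6–9 LP, 0–5 VUS, −6…−1 LB, ≤ −7 B. The stand-alone
benign frequency criterion (BA1) is handled categorically: it
short-circuits the tier to B regardless of pathogenic points.

Two rule profiles ship with the package and differ, by default, in a
single deliberate place: the rarity criterion PM2 is **moderate** in
profile I (as commonly applied in the male-infertility literature) and
**supporting** in profile II (the diagnostics-grade refinement,
reflecting current recommendations that population allele rarity alone is
weak evidence). Because every other trigger and threshold is shared, for
any variant and context profile II's score is ≤ profile I's, and its tier
is never more pathogenic — the direction of every reclassification the
two-profile design is meant to expose. The suite verifies this ordering
on 10^5 randomized variants.

Frequency thresholds are not generic: they derive from the *maximum
credible allele frequency* for a fully penetrant causal allele,

* dominant: `prevalence × heterogeneity / (2 × penetrance)`,
* X-/Y-linked (male-limited expression, one effective allele):
  `prevalence × heterogeneity / penetrance`,
* recessive: `sqrt(prevalence × heterogeneity / penetrance)`,

with prevalence 0.01 and heterogeneity 0.05 for BA1 and 0.01 for
PM2/BS1/BS2. The algebra is the standard penetrance-adjusted derivation;
the disease-specific parameters are configuration
(`rule_profile()`), defaulting to these values. For a recessive gene this
puts BA1 at ≈ 0.0224 and the PM2/BS1 boundary at 0.01; for dominant
genes at 2.5 × 10⁻⁴ and 5 × 10⁻⁵.

Implemented triggers: PVS1 for predicted loss of function (stop gain,
frameshift, start loss, canonical ±2 splice) in genes where LoF is the
established mechanism, downgraded to strong for last-exon truncation —
a three-outcome simplification of the full ClinGen decision tree
(very strong / strong / not applicable), which trades granularity for
auditability; PM2/BS1/BA1 from the thresholds above; BS2 from
genotype-aware control counts (homozygous controls for recessive genes,
hemizygous male controls for X-linked); PM3 for recessive variants
confirmed in trans with a pathogenic partner; PP3 when REVEL > 0.644 or
SpliceAI ≥ 0.9; BP4 when both scores sit below benign cutoffs (REVEL
< 0.29, SpliceAI < 0.1, both scores required — a missing score never
argues for benignity). All remaining codes (PS1, PM1, PM5, PP1, PS4,
functional-assay codes) enter only through explicit context, since they
encode curated knowledge the package cannot derive. At most one
very-strong pathogenic criterion is allowed per variant; a second is
capped to strong with a warning. Contradictory context (e.g. an in-trans
flag on a dominant gene) is reported, not silently resolved.

Among VUS, four categories are flagged for follow-up: splice-region
variants, stop gains, frameshifts removing < 10% of the protein outside
known domains, and missense with REVEL > 0.644.

## Association statistics

Carrier status (≥ 1 LP/P variant under a profile) is tabulated against
TESE outcome and histology. The odds ratio uses the Wald method: cross
product with a log-scale normal CI. Zero cells are an error unless the
Haldane–Anscombe correction (0.5 per cell) is explicitly requested —
never silent, because the correction changes the estimand. The exact
binomial test is two-sided by the minimum-likelihood method with default
null p₀ = 0.5 ("a carrier is equally likely in either outcome"); a
cohort-proportion null is available as configuration since published
p-values in this design are not always unambiguous about the null.
Pairwise histology comparisons use chi-square with Yates continuity
correction (on by default, the common statistics-package convention;
toggleable) and Bonferroni adjustment `min(1, m·p)` with m = 3.
Percentages print at 2 decimals in tables and 1 in prose, with raw
fractions retained in machine output.

The printed literature values this design mirrors are reproducible for
every carrier percentage, but the published ORs and p-values do not match
standard Wald/binomial/chi-square recomputation from the published cell
counts; the package therefore reports the standard computations and
validates them against independent oracles (cross-product and CI
closed forms on a 10⁴-table grid, full enumeration for n ≤ 20, the
closed-form Yates statistic) rather than reverse-engineering unreported
analytic choices.

## What the synthetic cohort emulates — and what it does not

`sim_config()` defaults encode the modelled study conditions: 571
patients, 42.4% sperm-retrieval rate, histology mixed 238:171:143:6 over
SCO/MA/HSG/TS, a carrier rate of 0.021 among TESE-positive men (the
profile-II Table value 5/242), and a planted carrier-versus-outcome odds
ratio of 4. Planted causal variants are predicted LoF, absent from
reference populations, with mode-matched zygosity (15% of recessive
carriers as phased compound heterozygotes); they are guaranteed to pass
every filter and to classify LP/P under profile II (PVS1 + PM2 = 9
points). Noise variants (Poisson mean 6 per patient across the panel)
draw depth from NB(μ = 80, size = 8) with 5% forced low-depth sites,
allele fractions from genotype-appropriate Beta distributions with a 7%
low-fraction tail, and population frequencies from a mixture of a point
mass at zero (40%) and a Beta(0.5, 60) tail, so every filter rule sees
both passing and failing records.

Two deliberate simplifications bound what passing tests demonstrate.
First, noise contains no rare passing loss-of-function variant: standing
LoF noise is drawn at frequencies above every ceiling (0.02–0.2), and
noise splice offsets avoid the canonical ±2 positions. This reflects the
strong purifying selection on these genes, but it means the simulation
cannot measure a false-positive LP/P rate from rare benign LoF — on real
data that risk is controlled by the curated LoF-mechanism annotation and
manual review, not by the simulation. Second, carrier probability depends
only on TESE outcome, not on histology, so the generator reproduces the
outcome association but not the maturation-arrest enrichment; the
patient-level contingency fixture carries that structure instead. There
is no read-level error model, haplotype structure or linkage.

With these conditions, across 500 seeded replicates the full pipeline
recovers ≥ 99% (empirically 100%) of planted variants as LP/P under
profile II, and the Wald 95% CI of the estimated OR covers the planted
OR in ≥ 93% (empirically ~96%) of replicates — Wald coverage at these
carrier counts (≈ 26 vs 5) is expected slightly below nominal, and
replicates with an empty cell use the Haldane–Anscombe correction.

## Numerical choices and degenerate inputs

* All threshold comparisons are inclusive on the keep side for sequence
  filters and exclusive on the drop side for CNV frequencies, exactly as
  the rule texts state them; boundary cases are unit-tested.
* Points are integers; `classify_points()` is total and mutually
  exclusive over the integers (enumerated over [−30, 30]).
* Empty inputs propagate as empty outputs (empty panel file, empty
  variant set, zero-carrier cohorts — the latter flag the OR as
  undefined rather than inventing a correction).
* Panel loading is order-insensitive (genes re-sorted by symbol) and
  duplicate symbols, unknown vocabulary values and mode/chromosome
  contradictions are load-time errors with row numbers.
* The GDR-upgrade rubric must be monotone (more carriers never suggest a
  lower level) and suggestions never fall below the prior level.

## Problem sizes in the test suite

The suite exercises: the 571-patient contingency fixture; a 10⁴-table
odds-ratio grid; full binomial enumeration for n ≤ 20 at three nulls;
10⁵ randomized variants for the profile-ordering property; 20 seeds ×
1000 randomized variants against the brute-force filter oracle; and 500
seeded end-to-end cohort replicates (200 in the acceptance script).
These sizes were chosen so that each stochastic property is measured
with comfortable margin while a full run stays in the minutes range on
a single core.

## Known limitations

* The shipped panel fixture is partial (the 40 genes named in the main
  literature; a complete 145-gene panel must be supplied by the user),
  and the TESE carrier table beyond the well-attested genes is synthetic
  scaffolding for the fixture schema, labelled as such.
* Consequence and transcript-level annotations are inputs, taken at face
  value from the supplied canonical-transcript annotation; there is no
  re-annotation, liftover or phasing from reads.
* PVS1 is a three-outcome simplification; PS3/BS3 functional evidence and
  segregation (PP1) enter only as explicit context.
* The binomial/chi-square machinery intentionally stops at Bonferroni;
  no regression adjustment for centre or ancestry is attempted.
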