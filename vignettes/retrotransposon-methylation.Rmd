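---
title: "Repetitive-element methylation analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repetitive-element methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retromethyl)
```

# Scope and model

`retromethyl` analyses CpG-array methylation of LINE-1 and *Alu*
retrotransposons at three resolutions. Throughout, the unit of data is
the per-probe methylation fraction β ∈ [0, 1] and the unit of effect is
Δβ = mean(case) − mean(control); Δβ > 0 is hypermethylation. The
package deliberately works on the β scale because every effect size it
reports or filters on (family shifts of ±0.005–0.015, the ±0.05
candidate threshold) is conventionally stated in β units; the M-value
transform (`beta_to_m`) is kept for display and clustering, where its
variance stabilisation matters.

**Annotation.** A probe's CpG is modelled as the 2-bp half-open interval
`[pos − 1, pos + 1)` around the 1-based cytosine position — the CG
dinucleotide itself. A probe is repeat-resident iff this footprint
overlaps a repeat interval by at least 1 bp. Strand is ignored for the
overlap (CpG methylation is symmetric across strands) and kept as
metadata. When repeats are nested or adjacent, the repeat with maximal
overlap wins and ties break on (chrom, start, name), so the assignment
is a pure function of coordinates, never of file order. Repeat names map
to families by longest-prefix matching with precedence
L1HS > L1PA > L1PB > L1P > L1M (so "L1PA3" is young-L1PA, not
intermediate-L1P), AluJ/AluS/AluY, and HAL1/FLAM/FRAM/FAM for the
related half-L1 and Alu-monomer families. Unmatched names classify as
`unclassified` rather than erroring: such probes stay in the total and
locus analyses (they are genuinely repeat-resident) but are excluded
from family aggregation, which only reports named families.

**Testing.** All group comparisons are two-sided t tests, Welch by
default. The unequal-variance form is the safer default when cohort
sizes are as lopsided as 48 vs 7; a `var_equal` flag restores the pooled
test. Per-probe p values are BH-adjusted; by default the adjustment runs
separately within each element class (LINE-1 and *Alu* positions
analysed separately, with the related and unclassified classes each
forming their own stratum), with `stratify_fdr = FALSE` pooling
everything into one adjustment. Family-level p values are reported
unadjusted, following the asterisk-at-p<0.05 convention of family bar
plots; `adjust = TRUE` adds a BH column. Degenerate inputs (zero
variance in both groups) get defined results — t = 0, p = 1 on equal
means; p = 0 plus a `degenerate` flag otherwise — instead of NaN.

**Cohort logic.** With three case cohorts tested against one control,
the significant-DMP sets form a seven-region Venn partition. A
variant cohort's *target loci* are the probes unique to its comparison
(significant in no other case-vs-control comparison) that additionally
survive a re-test of variant vs the heterogeneous case cohort with its
own BH pass. The phrase "significant in all three conditions" is
implemented as exactly these two operative filters; the third
comparison participates through the uniqueness region, not as a third
test on the probe. Probes falling in shared Venn regions are reported
with their regions but never auto-selected.

**Integration.** Methylation-to-expression candidates are (probe, gene)
pairs with |Δβ| ≥ 0.05 whose gene is differentially expressed
(q < 0.05) with log2FC of *opposite* sign in at least two distinct
studies. Both effects are oriented case-vs-control, so "inverse" is a
sign comparison. Multiple qualifying records from one study count that
study once; same-signed records never count as support (a gene with
mixed-sign studies simply accrues support only from the inverse ones).
Gene matching is by exact symbol — the reproducible common denominator
across array and RNA-seq platforms; an alias map can be applied upstream
if needed.

**ROC.** Single CpGs are evaluated as classifiers with the raw β as
score — no model fitting, no orientation flip. AUC is the tie-corrected
Mann–Whitney U scaled by n₁n₂, identical (to 1e−12, and by test) to the
trapezoidal area under the threshold-at-distinct-scores curve.
Confidence intervals use the DeLong structural-component variance by
default because it is deterministic; a seeded percentile bootstrap
(2,000 resamples) is available for small-sample sanity checks. Perfect
separation yields a degenerate `[auc, auc]` interval with a flag.
Hypomethylated markers therefore score *below* 0.5; callers who want
"discrimination regardless of direction" should pass `1 − β`.

# The synthetic-data generator

The generator emulates the world the pipeline was built for: four
whole-blood cohorts (control n = 48, heterogeneous case n = 52, two
genetically defined variant cohorts n = 7 and n = 15), an array whose
repeat-resident probes are predominantly methylated, and a handful of
planted effects.

Noise model: per-probe baseline means are logit-normal,
`logit(μ_j) ~ N(logit(0.8), 0.5²)`, and observations are
`β_ij ~ Beta(μ ν, (1 − μ) ν)` with precision ν = 100, giving a
per-probe sd of about 0.04 at β = 0.8 — comparable to the Δβ scales the
pipeline must resolve (family shifts of 0.005–0.015, locus shifts
≥ 0.05). The Beta/logit choice respects the [0, 1] support and makes
hyper- and hypomethylation symmetric; the source analyses state no
generative model, so this is the package's own choice.

Effects shift the logit of the mean for targeted probes in affected
groups. Two parameterisations exist because they answer different
questions: `delta_logit` applies one log-odds shift to all targeted
probes (realised Δβ then shrinks toward the β boundaries — the natural
behaviour for family-wide biology), while `delta_beta` computes a
per-probe logit shift that moves *each probe's own baseline* by exactly
the stated β difference. The second exists because "plant |Δβ| = 0.10"
is ill-posed at a probe whose baseline is 0.96; when the generator
wires candidate loci it both uses `delta_beta` and places candidates
only on probes whose baseline can accommodate the shift (target mean
inside (0.02, 0.98)). Without this, high-baseline candidates
legitimately fail the ≥ 5% filter and "exact recovery of the planted
set" is unattainable — a generator artefact, not a pipeline property.

Expression studies are gene × sample log2 matrices (baselines N(7, 1),
residual sd 0.3, n = 40 per group) with planted mean shifts of ±0.5 for
candidate genes in a configurable number of supporting studies, and
decoy genes whose shift has the *same* sign as their methylation change
so the inverse filter must reject them. The default n = 40 per group
was chosen once so that a 0.5 log2-unit shift at sd 0.3 is detected at
q < 0.05 with essentially complete power (t ≈ 7.5) — in line with the
larger blood expression cohorts this module stands in for, and
necessary for the planted-set-recovery property to hold as stated; at
n = 20 the per-record power is only ~95% and exact recovery across 20
seeds fails for reasons that have nothing to do with the filter.

What the generator does **not** emulate: array chemistry (Type I/II
probes, dye bias), cell-type composition, sample-level batch or
correlation structure (observations are independent given the probe
mean), SNP/LD structure, and realistic genomic repeat density. A green
test therefore establishes the *logic and calibration* of the pipeline
under a clean generative model — not robustness to the technical
artefacts real arrays carry, which upstream normalisation is assumed to
have handled.

# Numerical and procedural choices

* **BH step-up** is computed as `q_(i) = min_{j≥i} min(1, p_(j) n/j)`
  in sorted order and verified against a brute-force double loop.
* **Fisher exact** two-sided p sums hypergeometric probabilities at
  most the observed table's, with a 1 + 1e−7 relative guard against
  floating-point ties (the standard practice); verified against full
  enumeration for every table with total ≤ 40.
* **Mann–Whitney** is enumerated exactly (midranks, so ties are exact)
  when both groups have ≤ 8 observations, and uses the tie-corrected
  normal approximation without continuity correction otherwise.
* **Chi-square** is Pearson's without continuity correction.
* **Degenerate/empty cases** are defined, not propagated: empty Venn
  sets, element classes with zero probes, all-DMP enrichment tables
  (p = 1 on an empty margin), zero-variance genes (flagged, never
  called), perfect-separation CIs (collapsed and flagged).
* **Determinism**: every stochastic routine takes a seed; the pipeline
  reruns byte-identically, and output TSVs carry their generating
  thresholds as header comments so funnel counts are auditable.

A note on type-I calibration worth knowing when reading the test suite:
under a global null, BH rejects at least one hypothesis with probability
≈ α *per adjustment family*. With class-stratified adjustment there are
up to four families per run, so "zero significant DMPs" occurs in about
0.95⁴ ≈ 81% of null runs — by design, not by error. The acceptance
check of false-positive control therefore pins the pooled (single
family) adjustment, where the zero-DMP rate is ≈ 95%, and the
stratified default is exercised by its own tests. Similarly, family
screens report raw p, so among 11 null families roughly one in two runs
flags *some* family at p < 0.05; the meaningful null property — asserted
in the tests — is that no individual null family is flagged
systematically across seeds.

# Known limitations

* Symbol-level gene matching cannot resolve platform probes that map to
  several genes or outdated aliases.
* The target-locus procedure inherits the false-discovery behaviour of
  its first BH pass: FDR-level false DMPs in the small variant cohort
  tend to survive the re-test, because the variant samples are shared
  between the two tests. Selections should be read with criterion-4
  style FDR expectations, not as error-free sets.
* No covariate adjustment is performed in the methylation model (the
  cohort sizes preclude it); `covariate_balance` only *checks* sex and
  age balance.
* DMR segmentation, normalisation of raw array data, pathway analysis,
  and brain-tissue validation are out of scope.
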