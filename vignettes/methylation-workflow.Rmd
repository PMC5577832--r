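---
title: "Differential methylation analysis for very small two-group array studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation analysis for very small two-group array studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsmeth)
```

## The setting

wsmeth implements a differential DNA-methylation workflow for the hardest
common design in clinical epigenomics: a handful of cases against a handful
of matched controls on an Illumina methylation array (EPIC or 450k), for
example three patients with a rare progeroid syndrome and three age- and
sex-matched healthy donors profiled in whole blood. At this sample size
nothing survives genome-wide multiple-testing correction, so the workflow
deliberately reports *non-adjusted* p-values combined with stringent
effect-size filters on the beta scale, and treats replication in external
datasets — not a corrected p-value — as the evidence standard. Every
operation consumes already-normalized beta values (methylation fractions in
[0, 1]); IDAT-level processing and normalization are out of scope.

## Single-probe calling (DMPs)

Each probe is tested with a two-group one-way ANOVA on beta values. With
two groups the ANOVA F statistic is exactly the square of the
pooled-variance t statistic, with df (1, n1 + n2 − 2); the implementation
is a vectorised pooled-variance F so that array-scale matrices (850k
probes) test in well under a second, and the test suite pins it against
`t.test(var.equal = TRUE)` to machine precision. A probe is a DMP when its
non-adjusted p is strictly below 0.001. Tests run on beta values rather
than M-values because every effect-size rule of the workflow (0.15 for
"large" single-probe differences, 0.3 for regions) is defined on the beta
difference Δβ = mean(case) − mean(ctrl); `HYPER` means higher methylation
in cases. A Benjamini–Hochberg column is emitted for reference but plays
no role in calling.

Summaries count probes per direction, the *distinct gene symbols* their
annotations cover (multi-gene annotation strings such as `HOXB2;HOXB-AS1`
are split first — this is why a probe count always exceeds its
genic-region count), and the subset with |Δβ| strictly above 0.15. Both
the distinct-gene and the distinct-annotation-string counting are exposed;
the distinct-gene one is the default, as it is the only reading under
which probes can outnumber regions.

## Region calling (DMRs)

Region calling is restricted to probes that are (a) annotated to at least
one gene and (b) located in a CpG island or its shores/shelves — open-sea
probes are excluded. Eligible probes are ordered by position (probe id
breaks exact position ties, for determinism) and grouped into *island
units*: all eligible probes sharing one manifest island name. Sliding
windows of three adjacent eligible probes are formed within each unit with
step 1; windows never span two units, and units with fewer than three
eligible probes contribute none. The island-unit adjacency rule is a
documented interpretation — published sliding-window pipelines differ in
whether they group by island, gene or genomic distance — and both the
window size and the grouping behaviour follow the manifest annotation, so
a user can re-map probes under a different annotation version if desired.

Each window is tested with a two-group MANOVA. For exactly two groups all
four classical MANOVA statistics (Wilks, Pillai, Hotelling–Lawley, Roy)
coincide, so the implementation uses the transparent equivalent form,
Hotelling's T²:

$$T^2 = \frac{n_1 n_2}{n_1+n_2}\, \mathbf{d}' S^{-1} \mathbf{d},
\qquad
F = T^2\,\frac{n-p-1}{p\,(n-2)} \sim F_{p,\;n-p-1},$$

with **d** the per-probe mean-difference vector, *S* the pooled
within-group covariance, *p* the window size and *n* the total sample
count. The tests assert agreement with `stats::manova` (Wilks) to machine
precision and with an exact balanced-relabeling permutation null on 3v3
toys. A numerically singular *S* (collinear probes) is inverted by
Moore–Penrose pseudoinverse, dropping singular values below 1e-10 of the
largest, with a warning.

A window is *significant* when its non-adjusted p is strictly below 0.001
**and** it contains at least two *consecutive* probes with |Δβ| ≥ 0.3
(inclusive, per the wording "a minimum difference of 0.3"; adjacency is
required of the exceeding probes themselves, otherwise the word would be
redundant in a three-probe window). Significant windows of one island unit
whose probe ranges overlap or touch are merged into a DMR; the reported
DMR p is the minimum member-window p (a single summary p per region is
conventional and the minimum is the least surprising choice given that
merging is driven by window significance). DMR direction is `HYPER`/`HYPO`
when all member deltas reaching 0.3 share a sign, else `MIXED`. BED export
converts the 1-based inclusive probe span to 0-based half-open intervals.

### What the design costs in power

The exact F transform has denominator df n − p − 1. With n = 6 and p = 3
that is **2**, so the 0.001 critical value is `qf(0.999, 3, 2)` ≈ 999 and
even an arbitrarily large effect cannot push power past
P(χ²₂/2 < λ/(3·999)) — about 0.18 per window at Δβ = 0.35 and
within-group sd 0.03 (non-centrality λ ≈ 612), and roughly 0.3 at island
level once overlapping windows are pooled. This is intrinsic to running a
three-variable MANOVA on six samples, not an implementation artefact: the
workflow trades sensitivity for a short, high-confidence region list, and
the acceptance script measures the resulting recovery rate directly
(`dmr_spike_sensitivity`) rather than assuming it. Users who need
sensitivity at this design should lower the window size or relax the p
threshold, both exposed in `dmr_params()`.

## Gene-set enrichment

Gene lists (hyper- and hypomethylated DMP genes, treated independently,
and DMR genes) are scored against GMT libraries. Each term receives

* a one-sided Fisher exact p for the overlap (hypergeometric upper tail),
* a rank-deviation z: terms are ranked by Fisher p (ties broken by term
  id), the rank distribution under random input lists of the same size is
  estimated, and z = (observed rank − mean null rank) / sd null rank, so
  negative z means better-than-expected;
* the combined score c = ln(p) · z, used for prioritisation (descending
  |c|, ties by ascending p then term id).

The natural log is used; the log base only rescales the ranking. The null
is enumerated exhaustively whenever the number of possible input sets is
at most 1e5 and sampled (1000 seeded draws) otherwise; exhaustive nulls
use the population sd, sampled nulls the sample sd. The background
defaults to the union of the library's genes and is overridable. Combined
scores printed by hosted enrichment services are *not* comparable across
implementations — they depend on the service's precomputed null tables and
library version — so only the score's defining identity (c = ln(p)·z,
asserted on every emitted row) and the determinism of the ranking under a
fixed seed are contractual.

## Expression and concordance

Differential expression uses the two-sided pooled-variance t-test with a
linear-scale fold change: FC = 2^(Δ log2 means) for log2 data, ratio of
means for linear data. The scale is auto-detected (non-negative values
with 99th percentile ≤ 20 are treated as log2) and overridable. When a
gene maps to several expression rows, the row with the largest IQR is used
by default (mean-collapse is available). The concordance table inner-joins
differentially methylated genes with the expression results and flags the
canonical repressive pairing (hyper + down, hypo + up). The flag is
descriptive only: discordant pairings are biologically real and are
reported as-is, with no causal claim.

## Cross-dataset replication

A DMP list is intersected (order-preserving) with the probe universe of a
second platform, re-tested in the second dataset with the same ANOVA, and
counted at two tiers — strict (p < 0.001) and loose (p < 0.05) — along
with the number of loose-tier probes whose Δβ sign matches the discovery
dataset. A per-probe case/control variance ratio in the second dataset is
reported descriptively, since re-tests in immortalised material (e.g.
lymphoblastoid lines vs whole blood) often fail because of inflated
within-group variance rather than absent effects.

## The synthetic generator

All calibration and recovery tests run on synthetic scenes with a
ground-truth registry, so the full pipeline is testable with no downloads.
The generator emulates:

* island-clustered manifests — consecutive island blocks with positional
  shelf/shore/island flanks, shared island names, 1–2 gene symbols per
  island, interleaved open-sea probes;
* bimodal beta baselines — per-probe means drawn half from Beta(1.5, 10)
  (mostly unmethylated) and half from Beta(10, 1.5) (mostly methylated),
  clamped to [0.03, 0.97];
* two noise models. `"gaussian"` (default for spike scenes) adds
  homoscedastic N(0, within_sd) noise, within_sd = 0.03, clipped to
  [0, 1] — simple and faithful to how effect sizes are specified.
  `"beta"` (used for null-calibration scenes) draws each value from
  Beta(mc, (1−m)c) with concentration c = 150, reproducing the
  heteroscedastic, boundary-respecting noise of real beta values
  (variance shrinks near 0 and 1; sd ≈ 0.04 at mid-methylation). The
  distinction matters for calibration: hard clipping at the boundary
  creates point masses that mildly violate the F tests' distributional
  assumptions and inflate the extreme tail by ~20% at α = 0.001, which
  would confound a check whose purpose is to verify the p-value
  computation itself;
* spiked effects — single-probe spikes with |Δβ| uniform in 0.15–0.45 and
  regional spikes of a common Δβ = 0.35 across 3 consecutive eligible
  probes of one island, signs random, spiked baselines redrawn so both
  group means stay in [0.05, 0.95] (the requested delta is never
  attenuated by the boundary); spiked single probes are placed outside
  spiked islands so the two truths stay disjoint;
* matched expression — log2 intensities, baseline uniform in [6, 10],
  N(0, 0.25) noise, 10 vs 10 samples, spiked genes taken from the
  methylation truth with |log2 FC| = 1 and direction agreeing with the
  repressive pairing with probability 0.75 (real studies show both
  repressive and co-directional pairs; a fraction strictly between 0.5
  and 1 keeps both behaviours represented).

What passing on these scenes does *not* show: robustness to cell-type
composition shifts, batch effects, probe cross-hybridisation, type I/II
probe chemistry, or age-dependent drift — none of which the generator
emulates.

## Numerical and reproducibility choices

* Strict inequalities at p thresholds (< 0.001, < 0.05); inclusive ≥ at
  the 0.3 effect threshold; strictly greater than at the 0.15 summary
  threshold.
* Zero total variance in a probe yields (F = 0, p = 1); an exactly zero
  within-group variance with a nonzero mean difference yields p = 0 from
  an infinite statistic.
* All randomised operations take explicit seeds and restore the caller's
  RNG state; pipeline reruns with the same config and seed are
  byte-identical (asserted in the tests).
* Problem sizes used by the test suite and the acceptance script — 1e5
  null probes, 1e4 null windows, 200 replicates for power and sensitivity
  — were chosen to make the 99% binomial acceptance intervals informative
  while keeping a full run in tens of seconds on one CPU.

## Limitations

No covariate adjustment, cell-composition deconvolution or batch
correction (none is meaningful at n = 3 per group); no smoothing/
bump-hunting DMR model; no support for sequencing-based (WGBS) input; the
region test's power ceiling at 3v3 discussed above. The pipeline will run
any two-group design with at least two samples per group, but its
thresholds were tuned for the small-n regime and should be revisited for
larger studies where corrected p-values become usable.
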