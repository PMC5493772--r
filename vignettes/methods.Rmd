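---
title: "Methods: fitness profiling of pooled deletion collections with ykofit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitness profiling of pooled deletion collections with ykofit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ykofit)
library(dplyr)
```

## The assay ykofit models

Genome-wide deletion collections of *Saccharomyces cerevisiae* carry two
unique 20-bp molecular barcodes (an *uptag* and a *downtag*) flanking each
deletion cassette. When all strains are pooled and grown competitively,
the relative abundance of each strain after a fixed number of doublings
reports its fitness in that condition. Abundance is read out either by
hybridizing amplified barcodes to a barcode microarray, where each probe
is printed as five replicate features, or by sequencing the barcodes
directly (Bar-seq) and counting reads.

ykofit implements the full analysis chain for both readouts:

1. **Array preprocessing** — artifact masking over replicate features and
   summarization to one log2 intensity per tag per array.
2. **Presence calling** — a two-component Gaussian mixture on each
   control array separates hybridized (present) from background (absent)
   tags; a strain is present only if all of its tags pass on all control
   replicates.
3. **Fitness-defect (FD) scoring** — tag-class normalization, best-tag
   selection, batch standardization, then
   `FD = control median − treatment log2 intensity`, so positive FD means
   depletion. Significance by a linear model with BH q-values.
4. **Signature subtraction** — shared fitness signatures across a
   condition group (e.g. the HLU signature of a plasmid-complemented
   prototrophic collection, visible in histidine-, leucine- and
   uracil-dropout media) are defined from the median FD across the group
   and subtracted to expose condition-specific biology.
5. **Bar-seq quantification** — direct Hamming-distance barcode matching,
   control-count filtering, tag summation, median-of-ratios
   normalization, and FD scores on the same scale as the array arm.
6. **Enrichment** — right-sided hypergeometric tests with term-size
   filters and Holm correction.

A synthetic-data module generates pools, arrays and reads with planted
ground truth so that every stage is testable end to end without any
external data.

## The abundance model

A strain with per-generation relative growth deficit $d \ge 0$ declines
in relative log2 abundance by $g \cdot d$ after $g$ doublings; the
default horizon is $g = 5$ doublings, the usual length of these
competitions. The generator plants a fitness defect of `fd` log2 units
as $d = \mathrm{fd}/g$, and both readouts are linear in log2 abundance:
array intensities shift additively, Bar-seq abundances scale as
$2^{-g d}$. No saturation or probe-affinity effects are modeled — the
map from abundance to signal is linear on the log2 scale, the simplest
model consistent with log-ratio arithmetic.

## Stage-by-stage notes and parameter choices

### Artifact masking (`mask_replicate_features`)

Each tag's five replicate features are trimmed robustly: features
farther than `mad_k = 4` scaled MADs from the feature median are
flagged, and the summary is the mean of the remainder. When the MAD is
zero (replicates essentially identical), a feature is flagged if it
lies more than 3 sd from the mean of the other features. If flagging
would leave fewer than `min_keep = 3` features, the three closest to
the median are kept instead. Flagged features are removed, not
corrected, and every removal is recorded in a mask log. On fixtures
with 1% planted +4-log2 artifacts at zero noise, ≥95% of artifacts are
flagged with no false flags; at realistic noise a few percent of clean
features are trimmed, which only costs a little averaging efficiency.

### Presence calling (`fit_background_mixture` and friends)

The log2 intensities of one control array are modeled as a
two-component Gaussian mixture fit by EM. Choices that matter:

- **Initialization** is deterministic — means at the 25th/75th
  percentiles, equal weights, pooled sd — so fits are reproducible
  without a clustering dependency; random restarts are available but
  off by default.
- **Convergence**: relative log-likelihood change below `1e-8`, at most
  1000 iterations, variances floored at `1e-4`. The log-likelihood
  trace is retained and is monotone non-decreasing.
- **Degenerate-input guard**: a two-component fit of genuinely unimodal
  data tends to split the sample in half with means about two
  component-sds apart, which a naive separation rule accepts. The fit
  is therefore accepted only if it beats a single-Gaussian fit on BIC
  *and* the means are at least half a pooled sd apart; otherwise the
  array is flagged "no separation" and every tag on it is treated as
  present. This is deliberately conservative: in a pool with no absent
  strains, calling everything present is correct, and mass false
  absences would silently delete real biology downstream.
- **Calling rule**: a tag passes an array when its posterior
  probability of presence is strictly greater than 0.5 (ties are
  absent); a strain is present only when every one of its tags passes
  on every control replicate. One mixture is fit per control array —
  the all-replicates rule is defined per array, and per-array fits
  also absorb array-to-array intensity shifts.

The strain-level rule is intentionally strict (a present strain with
one marginal tag on one replicate is dropped); its false-absence rate
is the price of never scoring fitness on tags that did not hybridize.

### FD scoring and significance

Uptags and downtags are normalized separately: each array's tag-class
median is shifted to the set's overall median, computed as the median
over arrays of per-array medians — that target makes normalization
exactly idempotent. A consequence worth knowing: when a large fraction
of strains (≳10%) is planted with strong defects, the treatment-array
median itself shifts and median normalization reabsorbs part of the
signal; at realistic hit fractions (a few percent of 4000+ strains)
the effect is negligible.

The representing tag per strain is the one with the lower coefficient
of variation across control replicates, computed on the linear scale
(`2^log2`), where the CV is conventionally defined; ties go to the
uptag. Batch effects are removed by per-strain location–scale
standardization within batches, restoring each strain's pooled mean and
sd (single-array batches get location-only correction; single-batch
sets are untouched). Full empirical-Bayes batch shrinkage is
deliberately not used: at the replicate counts of these designs the
closed-form standardization is transparent, deterministic and testable.

Significance of the replicate FDs is assessed with a linear model with
one mean per strain. The default (`var_pool = "condition"`) fits the
model jointly per condition, pooling the residual variance across
strains (df = observations − strains). With triplicates, a per-strain
variance estimate has 2 degrees of freedom and essentially no power —
about one in five strains with a true FD of 1 would be detected — so
pooling is the only workable choice at this design size; a per-strain
one-sample t (`var_pool = "none"`) is kept for completeness. The
standard error also propagates the uncertainty of the shared
control-median reference,
$se = \hat\sigma\sqrt{1/n_{\mathrm{trt}} + c_{\mathrm{med}}(n_{\mathrm{ctl}})}$,
where $c_{\mathrm{med}}(n)$ is the variance of a median of $n$ standard
normals (computed by numerical integration for odd $n$). The reference
median is a single draw shared by all replicates, so its noise shifts a
strain's mean FD without appearing in the replicate variance; ignoring
it inflates the empirical false discovery rate several-fold. q-values
are Benjamini–Hochberg within condition, and the conventional hit
definition is FD ≥ 1 with q < 0.05.

### Signature definition and subtraction

The shared signature of a condition group is the per-strain median of
per-condition median FDs; members are strains with FD ≥ `threshold`
(default 1.0) in *every* group condition. The membership rule is
configurable (`rule = "any"`) because published core-gene counts rarely
state their exact rule; "all" matches the notion of a signature shared
by the whole group. Correction subtracts the signature profile from a
group condition's FD medians — strains without a profile pass through
flagged. Subtraction is exact arithmetic, so planted shared strains
return to 0 ± noise and condition-specific strains keep their planted
defect; cross-collection profile correlations use strains with FD > 1
in at least one shared condition.

### Bar-seq matching and count fitness

Reads are trimmed to 50 bases and scanned for the 20-base barcode:
first an exact lookup at the position following the uptag/downtag
primer context, then best Hamming distance over the anchored window, or
over all 20-base windows when no anchor survives sequencing error. A
read is counted only when its best hit is unique with distance ≤
`max_mismatch = 2`; equidistant reads are ambiguous and discarded, the
matcher's analogue of discarding ambiguous alignments by mapping
quality. Counts conserve reads exactly: matched + ambiguous +
unmatched = total, per sample.

Tags must reach ≥ 50 counts in every control replicate to survive
filtering, then a strain's uptag and downtag counts are summed. Samples
are normalized with median-of-ratios size factors against the
geometric-mean reference, and
`FD = log2(normalized control median + 0.5) − log2(normalized count + 0.5)`
puts count fitness on the same scale as the array arm (the 0.5
pseudo-count only matters below ~50 counts, which the filter excludes).
Size factors make FDs exactly invariant to global depth changes.

### Enrichment

Right-tail hypergeometric p-values, $P(X \ge k)$, over a user-supplied
term → gene table; terms with fewer than 5 or more than 300 genes in
the universe are excluded before testing, and the Bonferroni step-down
(Holm) correction is applied across tested terms with a pass threshold
of 0.0005 on the *adjusted* p (the stricter of the two possible
gatings). The annotation table is taken as-is: no ontology
up-propagation is performed, so GO parent terms must be expanded
upstream if desired.

## What the generator emulates — and what it does not

The generator reproduces the statistical structure the pipeline relies
on: bimodal control intensities (present $N(10, 0.8)$, absent
$N(6.5, 0.7)$ log2 units, well separated as on real barcode arrays),
five replicate features per tag with additive per-feature noise
(default sd 0.3 log2 units — the magnitude is a testability choice, as
intensity noise is rarely reported), sporadic additive spatial
artifacts, per-batch offsets, deterministic dropout fractions per
collection, planted per-condition and shared-group fitness defects
realized as $-g d$ log2 shifts, and multinomial Bar-seq reads with
primer-context structure and independent per-base errors.

It does not emulate probe-specific affinity or cross-hybridization,
spatially correlated artifacts, PCR amplification bias, GC effects,
overdispersed counts, or growth-curve dynamics beyond the fixed
$g$-doubling endpoint. Passing recovery tests on these fixtures
therefore shows the *inference machinery* is correct under the stated
noise model, not that real arrays meet that model; on real data the
main unmodeled risks are probe effects (absorbed partly by best-tag
selection) and batch structure beyond location–scale.

Condition-specific planted hits are drawn disjointly across conditions
and from the shared-signature members, so "specific" is true by
construction; otherwise a strain planted independently in two of three
group conditions would contaminate the shared-signature truth.

## Reference recovery conditions

The recovery suites (and `scripts/acceptance.R`) run at fixed,
documented sizes chosen to give stable statistics at interactive
runtimes: mixture recovery on 4000 present + 800 absent tags; FD
recovery on a 4000-strain screen with 150 strains planted at FD ∈
{1, 2, 3}, noise sd 0.3, triplicates; signature recovery on a
500-strain pool with a 50-strain shared signature and 20
condition-specific strains across three dropout conditions; Bar-seq
round trips at 5000 reads × 6 samples over 150 strains (clean and at 1%
per-base error); cross-platform concordance on 300 strains at 50,000
reads per sample. Under these conditions the pipeline recovers mixture
means within ±0.1, calls tag presence with ~99% accuracy, scores FD
medians with MAE ≈ 0.11, detects planted defects with sensitivity 1.0
at empirical FDR ≈ 0.05–0.08, recovers shared-signature membership
exactly, matches clean reads exactly and >99% of recoverable noisy
reads, and correlates the two platforms at r ≈ 0.98 — each of these is
recomputed, not quoted, by the test suite and acceptance script.

## Known limitations

- The strict all-tags/all-replicates presence rule trades sensitivity
  for specificity; collections with systematically weaker hybridization
  will lose more strains at the presence gate.
- Median normalization assumes most strains are unaffected in any one
  condition; screens where a large fraction of the pool responds will
  see compressed FDs.
- The pooled-variance significance model assumes comparable replicate
  noise across strains within a condition; strongly
  heteroscedastic strains would be better served by moderated-variance
  methods, which are outside this package's scope.
- Bar-seq matching is quality-blind and single-end; paired reads must
  be merged upstream.
- Enrichment treats the annotation table as flat; no term hierarchy or
  redundancy grouping is applied.

## A worked example

```{r example, eval = FALSE}
dir <- tempfile("ykofit_demo_")
fx <- write_fixture_bundle(dir, n_strains = 120, seed = 42)

cfg <- run_config(
  intensities = fx$paths$intensities,
  manifest = fx$paths$manifest,
  library = fx$paths$library,
  outdir = file.path(dir, "out"),
  seed = 1)
res <- run_array_pipeline(cfg)

tidy(res$fitness$YKO)      # per-strain FD medians with p/q
glance(res$fitness$YKO)    # hits per condition
autoplot(res$fitness$YKO)  # ranked FD profile
```
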