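---
title: "Detecting and monitoring circulating tumor DNA from targeted deep sequencing"
author: "plasmatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and monitoring circulating tumor DNA from targeted deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Circulating tumor DNA (ctDNA) is the tumor-derived fraction of the cell-free
DNA (cfDNA) that circulates in blood plasma. In cancers where biopsy is
risky — pancreatic ductal adenocarcinoma being the canonical example — deep
targeted sequencing of plasma DNA offers a way to detect disease and follow
its response to therapy from blood draws alone. The statistical difficulty
is that true somatic signal in plasma sits at allele fractions of a fraction
of a percent, the same order as the position- and allele-specific error
introduced by library preparation and sequencing. Every component of this
package exists to separate those two.

`plasmatrack` implements three layers:

1. **Tumor-informed tracking** (`track_variants()`): given mutations already
   known from a tumor tissue sample, decide per mutation whether the matched
   plasma carries it above background.
2. **Biopsy-free calling** (`call_biopsy_free()`): call somatic SNVs from
   plasma alone, against a matched germline and a cross-plasma background
   panel, with a stringent multi-stage filter cascade.
3. **Burden monitoring** (`merge_mptr()`, `burden_summaries()`): merge both
   call sets per sample, reduce them to burden metrics (number of mutations,
   mean allele fraction) and test group differences over the disease course
   with one-way ANOVA and Fisher's LSD.

The substrate of everything is the *pileup table*: per targeted position,
strand-split counts of reads supporting each base, restricted to base
qualities of Phred 30 or better and to deduplicated ("unique") reads. All
depth thresholds in the package refer to this unique Q30 depth, and a mutant
allele fraction (MAF) is always supporting reads divided by *total* depth at
the position, not ref+alt.

## The background error model

For a plasma sample under test, the background panel is the set of *other*
plasma samples. At each (position, alternative allele), a panel sample
contributes its allele fraction only when

* its own plasma depth is ≥ 500,
* its paired tumor carries the allele below 2.5% at tumor depth ≥ 250, and
* its paired germline carries it below 0.5% at PBL depth ≥ 500,

so that genuine somatic or germline signal in a panel member never inflates
the error model. `build_background()` summarizes the surviving panel allele
fractions into the mean and standard deviation (z-test), the empirical 95th
percentile (tracking rule, linear interpolation between order statistics)
and the pooled error rate (total alt reads over total depth; binomial
tests). When a paired tumor or germline pileup is not supplied for a panel
member, the corresponding filter passes: absence of evidence of real signal
does not exclude a site.

Sites with fewer than 5 contributing panel samples (configurable) are
untestable by the z-test; tracking then falls back to the binomial rule at
the pooled error rate.

## Tumor-informed tracking

A tissue mutation is detected in plasma when *all* of the following hold:
the observed plasma allele fraction strictly exceeds the site's background
95th percentile; a one-sided binomial test of the supporting reads against
the pooled error rate gives p < 0.001; at least 3 supporting reads; strand
bias < 0.9; depth ≥ 200. The percentile rule and the p < 0.001 rule are
stated side by side in the underlying protocol without an explicit
connective; we combine them conjunctively and keep each independently
switchable (`use_percentile_rule`, `use_binomial_rule`), which is the more
stringent and therefore more specific reading. The minimum supporting reads
(3) and minimum tracking depth (200) are documented defaults for quantities
the protocol says were "considered" without printed values.

Two calibration facts are worth knowing. First, the empirical 95th
percentile of an *n*-sample panel does not have exactly 95% coverage for a
held-out sample: for continuous data its rank-based coverage is
`(0.95 (n - 1) + 1) / (n + 1)` — about 90.5% at n = 20 and 94.1% at
n = 100, approaching 95% from below as panels grow. Second, allele counts
at most sites are zero-inflated, and ties count as covered under the strict
`>` detection rule, which pushes realized coverage back up. The calibration
tests assert the order-statistic floor, not a naive 95%.

## The biopsy-free cascade

Candidates are all (position, alternative allele) pairs with depth over
500, strand bias under 0.9 and at least one supporting read; the three
non-reference alleles of a position are independent hypotheses. The cascade
then applies, in order:

1. **Germline gate** — the matched germline must carry the allele below
   0.5%; otherwise the allele is treated as germline, not somatic.
2. **Binomial test vs germline** — one-sided upper tail,
   `p0 = (germ_alt + 0.5) / (germ_depth + 1)`. The pseudocount keeps the
   null proper when the germline shows zero supporting reads (the protocol
   does not state its zero-count handling; +0.5/+1 is the standard
   continuity choice). Bonferroni over the hypotheses tested in the sample;
   keep adjusted p < 0.05 (the post-adjustment level is not printed in the
   protocol; 0.05 is our documented default).
3. **z-test vs the background panel** — `z = (af - mean) / max(sd, floor)`
   with `floor = max(1 / panel mean depth, 1e-5)`, one-sided (somatic signal
   is an excess). p-values are carried in log10 space: true signal at a few
   percent MAF against a background sd of a few 1e-4 yields z in the
   hundreds, far below double underflow. The Bonferroni-adjusted p is
   compared against 1e-18 in log space without clamping. The Bonferroni
   family for each test is the set of hypotheses actually entering that
   test in that sample.
4. **Supporting reads** — fewer than 8 reads is discarded. Note that
   against a near-zero background the z gate almost subsumes this rule:
   with sd at its floor `1/D` and panel depth equal to plasma depth, z
   approximately equals the supporting-read count, and z ≈ 8.8 is needed to
   reach 1e-18. The 8-read rule binds independently when the panel is much
   deeper than the sample.
5. **Proximity window** — if two or more surviving candidates lie within
   10 bp (|Δpos| ≤ 10, applied once, not iterated), those with allele
   fraction below 20% are discarded; clustered low-fraction candidates are
   characteristic of alignment artifacts.
6. **Lane SNPs** — candidates matching a germline SNP seen in another
   patient's sample from the same flow-cell lane are discarded
   (multiplexing cross-contamination). A site counts as a lane SNP at
   germline allele fraction ≥ 25% (the protocol gives no numeric rule;
   25% separates heterozygous carriage from error comfortably).
7. **Consequence** — only nonsynonymous, stop-gain, stop-loss and
   splicing-disrupting variants are reported. When no annotation source is
   supplied (`annotations = NULL`) every candidate is treated as
   reportable; this is deliberate for technical assays such as the
   replicate false-positive experiment, where letting missing annotations
   absorb candidates would hide the statistical false-positive behaviour.

Every candidate leaves the cascade exactly once, either as a call or in the
drop log tagged with the first filter it failed — the tests assert this
conservation property.

Boundary conventions: plasma depth "over 500" is strict (`> 500`); tumor
allele fraction for tissue mutations is **inclusive** `>= 4%` (the
protocol's two statements disagree, "higher than 4%" vs "≥ 4%"; the
inclusive reading is the default and `tumor_af_inclusive = FALSE` restores
the strict one); germline "< 0.5%" is strict everywhere.

## Burden monitoring and cohort statistics

Per plasma sample, the tracked detections and the biopsy-free calls merge
by site into the target-region mutation set; on overlap the biopsy-free
record (which carries the richer statistics) is kept once. Burden records
hold the number of mutations and their mean and maximum MAF; samples with
no detections contribute a count of zero and are excluded from MAF
averages (they are qualitatively "not detected", not "zero fraction").

Group comparisons across disease states (diagnosis, complete/partial
response, stable disease, progression) use one-way ANOVA via `stats::aov`
with Fisher's LSD post-hoc: pairwise t statistics on the pooled
within-group mean square with the ANOVA residual degrees of freedom,
two-tailed, unadjusted (that is what LSD means). Because rising ctDNA tends
to precede the radiological progression call, `reassign_pd_window()` can
move records taken less than 90 days (3 months) before a patient's
progression date into the progression group first.

Detection rates and concordance metrics (sensitivity, specificity against
e.g. droplet digital PCR) carry exact two-sided Clopper–Pearson 95%
intervals via `stats::binom.test`; the printed intervals of the source
protocol match the exact method, which is why it is the default.

Limit-of-detection arithmetic: the caller has no explicit MAF threshold, so
the lowest callable fraction at a site is `8 / unique_depth`
(`theoretical_lod()`), and unique depth itself is capped by the input DNA
mass at 3.3 pg per haploid genome equivalent (`genome_equivalents()`,
`lod_with_input_cap()`).

## The synthetic cohort generator

No patient-level data ships with the package; every downstream stage is
exercised on synthetic cohorts that emulate the *statistical structure* of
a targeted ctDNA study:

* matched germline (PBL), tumor (FNA) and longitudinal plasma samples per
  patient, with mean unique depths 1929× / 987× / 2227× respectively;
* a shared per-(position, allele) error model: rates drawn from a scaled
  beta distribution with mean 2e-4 capped at 1e-2. Real panels show
  heterogeneous allele-specific error with no published parametric form;
  these defaults are configurable stand-ins chosen to give a realistic
  spread of quiet and noisy sites, not values calibrated to any dataset;
* negative-binomial per-position depth (dispersion configurable; the
  protocol reports only means and ranges);
* somatic truth variants spiked per patient at tissue fractions of 5–40%
  and plasma fractions of 0.5–4%, a configurable fraction of them absent
  from the tissue sample (intra-tumor heterogeneity: plasma-only
  subclones), never colliding with the patient's own germline SNP sites;
* germline SNPs (AF 0.5 or 1.0) shared across all materials of a patient;
* per-position strand imbalance, exon-like 120 bp position blocks (so the
  proximity window is exercised), lane batches of eight samples, and
  log-normal plasma input masses around 30 ng.

A master seed drives everything; per-sample substreams are derived
deterministically so that adding a sample never perturbs the draws of
existing ones, and identical configuration and seed reproduce every pileup
byte for byte. `simulate_reference_standard()` mimics a commercial cfDNA
reference standard (a handful of hotspot SNVs at fixed dilutions over the
same error model, with a tight depth distribution, as reference material
has), and `simulate_replicate_pairs()` produces technical germline
replicate pairs for the false-positive assay.

What the generator does **not** emulate: read-level artifacts (mapping
error, fragment-length structure, GC bias), error-rate correlation between
neighbouring positions, trinucleotide context effects, sample
cross-contamination, and tumor evolution beyond a per-timepoint scalar
trajectory. Passing tests therefore demonstrate that the statistics behave
as designed under the assumed error model — binomial sampling around
position-specific rates — not that the thresholds are optimal for any
particular instrument or laboratory.

## Problem sizes and numerical choices

The test suite and the acceptance script run on desk-scale panels of
600–2000 positions with background panels of 12–100 samples — large enough
that every filter is exercised and the calibration properties have tight
Monte Carlo error, and small enough that the whole suite runs in minutes.
Panel size is a free parameter of the generator; nothing in the statistics
depends on it beyond multiple-testing counts, which are always computed
from the data at hand.

Numerical conventions collected in one place: percentile = linear
interpolation between order statistics; binomial null pseudocount
+0.5/+1; z-test sd floor `max(1/panel mean depth, 1e-5)`; pooled-error
floor 1e-5 for the tracking binomial test; z p-values and their Bonferroni
adjustment handled in log10 space; strand bias = majority-strand fraction
of total position depth, gate strict `< 0.9`; zero-depth positions are
untestable rather than zero-fraction; ties at the background percentile do
not count as detections (strict `>`).

## Limitations

The biopsy-free caller's stringency (notably the 1e-18 z gate and the
8-read minimum) buys a near-zero technical false-positive rate at the cost
of sensitivity below roughly 0.4–1% MAF depending on depth — by design it
will miss low-burden disease that the tumor-informed test can still see,
which is exactly why the two are merged for monitoring. The ANOVA layer
treats repeated samples of a patient as independent observations, as the
source protocol does; a mixed-effects treatment would be more conservative.
Consequence annotation is an input, not a prediction: without an annotation
source, biopsy-free calls cannot be restricted to protein-altering
variants.
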