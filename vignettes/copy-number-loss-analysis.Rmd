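---
title: "Allele-specific copy-number loss analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific copy-number loss analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascnloss)
```

# The problem

A tumor DNA sample is a mixture of malignant cells — aneuploid, with
segmental integer allele copy numbers — and diploid normal cells. SNP arrays
observe two signals per probe: the log R ratio (LRR), the log2 total
intensity of the tumor relative to its matched normal, and the B-allele
frequency (BAF), the fraction of signal from the non-reference allele. Only
SNPs heterozygous in the matched normal ("informative" SNPs) carry
information about allelic imbalance.

This package estimates, per tumor, the aberrant-cell fraction `rho`, the
average ploidy `psi` (mean total copy number over informative SNPs), and
segmental allele-specific integer copy numbers `(nA, nB)`; calls
ploidy-relative copy-number loss (total copy number strictly below
`0.7 * psi`) and LOH (minor allele at zero copies); summarizes recurrent
loss regions across a cohort; and tests gene sets — suppressors of
proliferation ("STOP"-type sets) and incidentally deleted, therapeutically
exploitable genes ("CYCLOPS"-type sets) — against a copy-number ranking of
the genome.

# The mixture model

For a SNP in a segment with allele copy numbers `(nA, nB)` in a sample with
aberrant-cell fraction `rho`:

* total mixture copy number: `m = 2(1 - rho) + rho (nA + nB)`
* expected LRR: `gamma * log2(m / psi_mix)`, where `psi_mix` is the
  genome-wide mean of `m` (the sample is centered on its own mixture
  ploidy, matching tumor-versus-matched-normal ratios) and `gamma` is the
  platform compression factor (default 0.55, typical of the array family;
  configurable),
* expected BAF at an informative SNP: `(1 - rho + rho nB') / m`, where
  `nB'` is `nA` or `nB` with equal probability per segment — the B allele is
  as likely to sit on the major as on the minor haplotype, so BAF is
  symmetric about 0.5 and only the mirrored BAF `0.5 + |BAF - 0.5|` is
  identifiable.

The synthetic generator (`render_snp_track()`) draws Gaussian noise around
these expectations and clips BAF to [0, 1]; the estimator
(`fit_purity_ploidy()`) inverts the same equations.

# Estimation

`fit_ascn()` chains four steps and returns a classed model object.

**Quality control** (`qc_sample()`) reproduces the three sample-exclusion
reasons applied to real cohorts before fitting: flat BAF (fraction of
informative SNPs with `|BAF - 0.5| > 0.1` below 0.005 — essentially no
aberrant DNA), excessively variable LRR (median absolute successive
difference above 0.5), and low content (neither of the above, but binned-LRR
variance below 0.002 and BAF divergence below 0.02 — too little signal to
fit). The LRR-variability and minimal-signal thresholds are calibrated on
synthetic data only; the source cohorts do not state numeric values.

**Segmentation** (`segment_track()`) runs binary segmentation jointly on the
two-dimensional signal (LRR, mirrored BAF) of informative SNPs, each
dimension standardized by a robust noise estimate from successive
differences. A split is accepted when it reduces the squared-error cost by
more than `penalty * log(n)` (default penalty 4), with at least `min_snps`
(default 5) informative SNPs per segment. Chromosome boundaries are always
changepoints; chromosomes without informative SNPs are carried through as
unassessable rows rather than dropped. Per-segment mirrored BAF uses a
second-moment bias correction, `0.5 + sqrt(max(0, mean((BAF - 0.5)^2) -
sd^2))`: the naive mean of `|BAF - 0.5|` is inflated by `sd * sqrt(2/pi)` on
balanced segments, which masquerades as allelic imbalance and, uncorrected,
biases the downstream purity estimate upward by several percent.

**Grid search** (`fit_purity_ploidy()`) inverts the mixture model at every
point of a `rho` in [0.10, 1.00] (step 0.01) by `psi` in [1.0, 5.5] (step
0.05) grid, yielding continuous `(nA, nB)` per segment, and scores each
point two ways:

* the *goodness*: informative-SNP-weighted mean squared distance of the
  continuous values to the nearest nonnegative integers (reported per
  candidate, and exactly zero at the generating parameters on noise-free
  input);
* the *observation-space residual*: the segment LRR/BAF means predicted
  from the rounded integers versus the observed means.

Candidates are collected at local minima of the observation-space surface
and ordered by that residual plus a small ploidy-parsimony penalty
(`psi_penalty`, default 2e-4 per ploidy unit). Two facts force this design.
First, the mixture model has an exact alias ladder: adding one copy to every
allele while moving `rho` to `rho / (1 - rho)` reproduces every segment mean
perfectly, so for `rho <= 0.5` the data cannot distinguish a profile from
its "everything plus one" counterpart; the parsimony penalty selects the
lowest-ploidy member of the equivalence class, and the penalty is small
enough (two orders of magnitude below typical between-basin differences)
never to override a genuinely better fit. Second, the copy-number-space
goodness shrinks with the candidate's noise amplification (`dn/dLRR` is
proportional to `1/rho`), so ranking noisy fits by goodness alone
systematically drifts toward high-`rho` and halved-ploidy solutions; the
observation-space residual is invariant to that rescaling. Genomes in which
every segment is balanced with flat LRR are reported as unidentifiable
rather than fitted.

**Selection** (`select_solution()`) applies the homozygous-deletion
adjustment: a best candidate carrying more than 10 Mb of homozygous deletion
is biologically implausible (cells do not survive) and symptomatic of an
underestimated ploidy, so the next-best candidate with strictly higher
`psi` and an acceptable homozygous-deletion load is chosen instead; when no
such candidate exists the best is returned flagged. This same rule resolves
the rare residual aliases whose integer states collapse to `(0, 0)` over
large regions.

# Calling and summarization

Loss is total copy number strictly below `factor * psi` (default factor
0.7; e.g. with `psi = 2.31` the threshold is `0.7 * 2.31 = 1.617`). LOH is
minor copy number zero, *including* homozygous deletions — the loss and LOH
tracks are computed independently and nothing in the definitions excludes
`(0, 0)` from LOH; both conventions are a single switch away in the calls
if a user prefers otherwise. Gene-level total copy number is the
overlap-length-weighted mean of overlapping segments (a small intragenic
sliver should not call a whole gene lost) while the gene-level minor copy
number is the minimum over overlapping segments (any overlapping LOH
segment confers LOH). Fractions of genome lost and under LOH are
base-pair-weighted over the assessable autosomal extent; sex chromosomes
are excluded throughout.

The cohort loss-frequency track is evaluated at SNP positions (the native
resolution of the data); tumors unassessable at a position leave that
position's denominator. Recurrent regions are maximal runs of positions at
frequency >= 0.2, merged across gaps under 0.5 Mb, and reported only when
strictly larger than 1 Mb, each with its maximum internal frequency.
Raising the frequency threshold can split one long region into two, so the
monotone quantity is the total reported extent, not the region count.

# Enrichment analysis

Genes are filtered to those whose relative copy number (gene total copy
number over sample ploidy) correlates positively and significantly with
expression (Spearman `rho > 0`, two-sided `p < 0.05` by default; the alpha
is exposed because the source analyses state "significant" without a
value). Surviving genes are ranked by increasing mean relative copy number,
ties broken by decreasing correlation coefficient, residual ties by a
seeded random ordering; because residual ties are random, the analysis is
rerun under several orderings and the maximum p value reported
(`max_p_over_orderings()`).

The enrichment score is the classic unweighted running-sum statistic: set
members add `1/n_hit`, non-members subtract `1/(N - n_hit)`, and the score
is the running sum's maximum absolute deviation, signed (ties between the
positive and negative extreme go to the positive one, within 1e-12). Two
null distributions are attached: `permutation_nes()` normalizes against
random same-size gene sets (NES = score over mean absolute same-sign null
score), and `random_set_empirical_p()` draws `n_resample` random same-size
sets from the ranking universe, computes each one's NES identically, and
reports the fraction strictly exceeding the observed NES (`k/n`, matching
the published 4/1000 = 0.004 arithmetic; `(k+1)/(n+1)` available). The
resampling universe defaults to the post-filter ranking, since sets are
tested against that ranking; drawing from the whole genome is possible by
passing a different universe but collapses to the same test after
intersection with the ranking.

# CYCLOPS accounting

Per-tumor counts of deleted set members use the same 0.7-ploidy loss call
as everything else. Deletion-associated downregulation is a one-sided
Wilcoxon rank-sum test (deleted < intact) at nominal alpha 0.05 with at
least 3 tumors per side — below that the gene is "untestable", never
silently negative. The sources report nine downregulated genes without
naming a test or correction, so the test and alpha are configuration
options and no multiplicity adjustment is applied by default. Qualifying
genes (deleted at least once and downregulated) are reported as an integer
percentage of the candidate set; tumors carrying at least one qualifying
loss as a percentage with one decimal — the two rounding conventions the
published numbers use (16 %, 51.4 %). Cross-cohort deletion frequencies are
compared with an exact two-sided test computed by summation of
hypergeometric table probabilities not exceeding the observed table's.

# The synthetic generator and what it does not emulate

`simulate_cohort_truth()` draws, per tumor, an aberrant-cell fraction from
`rho_range` (default [0.3, 1]) and a base copy state from `ploidy_choices`
(default 1.7, 2.0, 3.6 — near-diploid with substantial loss, diploid, and
hypotetraploid with losses; the base state is the rounded choice and extra
loss segments realize the sub-base target). Losses are contiguous segments
with lengths log-uniform between 1 Mb and half a chromosome, reducing the
total copy number to `floor(0.7 * base)` — strictly below the loss
threshold — from the minor allele first, so diploid single-copy losses also
create LOH. STOP-like genes are placed in spatial clusters
(`make_gene_sets()`) and each cluster is covered by one targeted loss event
with the probability that makes the member genes' marginal loss rate equal
`loss_rate_in_set` (default 0.4) given the background coverage (default
0.1); targeting dispersed genes individually with megabase-scale events
would blanket the genome. CYCLOPS-like genes are placed uniformly: their
deletions arise only from background events, the "incidental bystander"
model. Tumors with base state 4 additionally receive shallow single-copy
losses over about 8 % of the genome; these stay above the loss threshold
but give the genome odd copy states, without which an all-even profile is
genuinely ambiguous under ploidy halving. Expression for a labeled fraction
of genes (default 0.6) is `baseline + slope * relative copy number + noise`
(slope 1, noise SD 0.5 in expression units).

Defaults the sources do not state and that were fixed once here: LRR noise
SD 0.25 and BAF noise SD 0.03 (chosen so that clean synthetic samples pass
the QC thresholds while degenerate configurations are flagged, the same
qualitative funnel the real cohort shows), germline heterozygosity fraction
0.3, platform compression 0.55.

What the generator does not emulate — and hence what green tests do not
establish about real arrays: probe-level intensity artifacts (cross-talk,
fragment-length and GC effects), wave artifacts along the genome,
subclonal (non-integer) copy numbers, genotyping error in the matched
normal, and centromere/telomere structure. Parameter-recovery results here
show the estimator is correct under its own generative model, not that the
model captures every failure mode of real data.

# Numerical choices and degenerate inputs

Grid steps (0.01 in `rho`, 0.05 in `psi`) keep the full search under a
second per sample; finer steps change estimates by less than the reported
tolerances. Rounding to integers clamps at zero; negative continuous copy
numbers therefore penalize a candidate rather than crash it. Plateau ties
in candidate ordering break toward lower ploidy, then higher aberrant-cell
fraction. Empty candidate lists (all-balanced genomes), empty post-filter
gene universes, sets that are empty or cover the whole ranking, and
zero-assessable-extent samples all raise informative errors. File formats
are 0-based half-open; BED rows with `end <= start` are rejected with line
numbers, never silently reinterpreted.

# Problem sizes used by the test-suite and acceptance runs

Synthetic cohorts in the tests use three to five chromosomes of 40–60 Mb at
20–50 kb SNP spacing (5,000–9,000 probes), 300–800 genes, and cohorts of
20–74 tumors; enrichment calibration uses 200 replicate p values at 100
resamples each, and the power run 20 cohorts of 50 tumors. These sizes were
chosen as the smallest at which segment lengths (>= 1 Mb), set sizes and
binomial tolerances are comfortably resolved.

# Known limitations

* The `rho`/`psi` alias ladder is intrinsic to the mixture model; the
  parsimony preference recovers the lowest-ploidy representative, which for
  genuinely genome-doubled tumors without odd copy states would be the
  halved profile.
* Samples with `rho` below about 0.2 at default noise are expected to fail
  QC (flat BAF) rather than fit — matching the behavior of the real
  pipeline on low-content tumors, but meaning recovery guarantees only
  cover `rho >= 0.3`.
* The empirical p value has resolution `1/n_resample`; reported zeros mean
  "below one over the resample count".
* Gene-level calls at segment boundaries inherit the boundary placement of
  the segmentation (midpoints between informative SNPs), so genes
  straddling a breakpoint can differ from the generating truth by up to
  one inter-SNP gap even on noise-free input.
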