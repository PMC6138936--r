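---
title: "Methods: linking histone-modification changes to alternative splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking histone-modification changes to alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `hmsplice`: the
models and conventions each stage assumes, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
design choices that were genuinely open, with the reasoning behind the
option the package adopts.

## Coordinates and conventions

All coordinates inside the package are 0-based, half-open (the BED
convention); conversion to 1-based inclusive coordinates is a pure
display step (`to_display_1based()`). The sign convention for splicing
is fixed throughout: `delta_psi = psi(reference) - psi(differentiated)`,
so a positive value past the threshold is an inclusion **loss** upon
differentiation and a negative one an inclusion **gain**. For a mutually
exclusive exon (MXE) pair only the transcript-upstream exon (strand
aware: on the minus strand it is the genomically rightmost of the pair)
is carried through the analysis; the pair's inclusion estimates must sum
to 1 within 0.02, which the generator realizes exactly by drawing both
exons' junction reads from one total.

## Differential inclusion

PSI is the effective-length-weighted junction ratio
`(I/len_I) / (I/len_I + S/len_S)`; with unit lengths it reduces to the
raw count ratio, and it is invariant to rescaling both lengths. Events
with `I + S = 0` in a cell are dropped from that comparison (counted in
the run report).

The differential test is a two-sided Fisher exact test on the pooled
(replicate-summed) inclusion/skipping 2x2 table between the two cells.
Full-likelihood splicing callers model replicate variability explicitly;
this package deliberately substitutes a transparent exact test whose
calibration can be verified against enumeration, and instead reports
replicate concordance (the within-cell range of per-replicate PSI)
alongside each call. The test is computed by a vectorized
hypergeometric-mass summation (thousands of events per comparison);
`stats::fisher.test` serves as its independent cross-check in the test
suite. FDR is Benjamini-Hochberg per comparison, with the event table
pre-sorted by (p, event id) so that ties adjust identically on every
platform. Calls require all three of `|delta_psi| > 0.1`, `p <= 0.01`
and `FDR <= 0.05` — each threshold is a `run_config()` parameter, and
`cutoff_sweep()` re-applies the delta-PSI cutoff over a grid to show how
the event set shrinks while screen correlations stay put.

## Splice-site profiles

Around each splice site of an exon, the package bins +/-150 bp on both
the intronic and exonic side into 15-bp bins; a side shorter than 150 bp
is instead divided into 10 equal bins (boundaries rounded, last bin
absorbing the remainder), so profiles from exons of different lengths
align. Bin order is transcript 5'->3', which makes the profile matrix
invariant under a strand flip of the whole locus (a property test).
Exons shorter than 10 bp are rejected.

The per-bin statistic is the depth-normalized differential read count
`(reads_ref * 1e6/lib_ref - reads_alt * 1e6/lib_alt) / bin_bp`. The
normalization scale (counts per million) is immaterial downstream
because the panel test is rank-based.

**Per-region summary (an open choice, resolved by a null property).**
The panel test compares AS against matched CS exons on a per-region
(exon x splice-site side) summary over the exonic bins. Summarizing by
the mean of |delta| per bin turns out to be length-biased: AS exons are
systematically shorter, short sides get sub-15-bp bins, and smaller bins
have larger per-bp Poisson noise, so AS exons would "win" under a pure
null. The package therefore summarizes by the variance-stabilized net
change `|sum(delta * bin_len)| / sqrt(sum(bin_len))`, whose null
distribution does not depend on exon length; with it, the false-positive
rate of the downstream link-strength call sits at its nominal level in
the package's null simulations. The Mann-Whitney test is two-sided;
panels with fewer than three regions per class are flagged underpowered
with p set to 1.

Matched CS exons are sampled one per AS event from the same gene's
internal constitutive exons, without replacement while the gene allows
it; genes without any CS exon skip their events with a logged count.

**Link strength.** For one HM, panels (lineage x AS type) split into
AS-preferred vs CS-preferred are compared against the pooled split of
all other HMs' panels by a two-sided Fisher exact test;
`-log10(p)` is the link strength. Contrasting against the
experiment-wide base rate (rather than a fixed 50/50) measures whether
this HM's preference for AS exons is consistent beyond what the assay
shows globally. "Preferred" requires only a median difference, not panel
significance, to avoid double thresholding; a significance-gated variant
is a one-line change on the panel table.

## Distance-normalized differential peak signal

A peak counts toward an exon only with >= 1 bp overlap; among several,
the greatest height (narrowPeak `signalValue`) wins; no peak means
signal 0. The retained height is divided by the distance in kb between
the peak summit and the exon's 3' splice site (the acceptor, strand
aware), floored at 0.1 kb: the acceptor is the regulatory reference
point, division by distance preserves "closer implies stronger", and the
floor bounds the statistic when a summit sits on the splice site (the
floor is a parameter, `floor_bp = 100`). `delta_hm` is the normalized
reference signal minus the differentiated one — antisymmetric under
swapping the cells, and unaffected by peaks that do not overlap the exon
(both are property tests).

## Association screen, clustering, mirror subsets

Observations are event x lineage instances with a non-`none` call.
Three screens run per AS type at `alpha = 0.05` on raw p values (a
BH-adjusted variant is available): per-HM Pearson correlation; one
ordinary least-squares fit of delta-PSI on all 16 delta-HM columns
jointly with per-coefficient t tests (aliased columns dropped with a
message); and a logistic regression of the inclusion direction
(`delta_psi > 0`, the only natural dichotomy of a signed response) on
the same columns with Wald tests. Perfect separation is flagged and the
logistic coefficients are recomputed by a Firth bias-reduced fit
(Jeffreys-prior score correction, written in-package), whose finite
estimates make the separation case reportable. An HM enters clustering
if any screen selects it (union rule — the most inclusive reading when
three parallel tests are specified without a combination rule).

K-means (k = 6, 25 restarts, Euclidean) runs separately on
inclusion-gain and inclusion-loss instances over the selected delta-HM
features, with the RMSE over k = 2..8 recorded so the default k is
auditable. Two deliberate choices:

* **Raw features by default.** Variance-equalizing each HM column
  (z-scoring) inflates mostly-unregulated marks to unit variance; in
  simulations k-means then splits those noise axes and antiparallel
  noise splits masquerade as mirror pairs with strong selection-induced
  correlations. The delta-HM scale itself carries the association
  signal, so clustering runs on raw features by default
  (`standardize = TRUE` switches to a median/MAD standardization in
  which the unregulated bulk sets each column's scale).
* **Mirror gate.** A gain and a loss cluster form a mirror pair when
  their centroids are antiparallel (cosine <= -0.8), share the dominant
  feature (largest |coordinate|), and — because cosine similarity is
  scale-invariant — each dominant coordinate is at least half that
  feature's pooled standard deviation. Without the magnitude gate, two
  large null clusters with tiny antiparallel centroids can register as
  a "mirror" and absorb most of the event universe. Pairs are matched
  greedily by most-negative cosine, one use per cluster.

Pairs that describe the same association (same dominant HM, same sign of
the pair-level correlation) are merged into one subset before
evaluation: at k = 6 a large planted group is routinely split into two
clusters, and the biological object of interest is one subset per
(HM, sign). The merged subset's within-subset Pearson correlation
between delta-PSI and the dominant HM's delta-HM gives its sign and its
keep/drop decision (p <= 0.05). Membership and the coverage fraction
(members over all significant AS events) are reported at the event
(exon) level, while the correlation itself uses the event x lineage
instances for power.

Note a selection effect worth knowing about: because subset members are
chosen partly for extreme delta-HM, the within-subset |r| of a recovered
subset exceeds the generative correlation of its planted members. The
acceptance checks therefore validate recovered membership against the
truth ledger rather than treating the within-subset r as an estimate of
the planted r.

## Expression companions

DEGs are genes with `max(fc, 1/fc) > 2` where
`fc = (fpkm_alt + 0.1) / (fpkm_ref + 0.1)`, within the universe of genes
at FPKM >= 1 in at least one of the two cells; the pseudocount (0.1)
guards zero FPKM and makes the call direction-symmetric. Gene-set
enrichment is an upper-tail hypergeometric test against a user-supplied
background, with optional Bonferroni or BH adjustment; no curated gene
sets ship with the package. Isoform relative expression is each
isoform's FPKM over the gene total, with missing values when the total
is zero.

## The synthetic-data generator

The generator emulates a stem-like reference cell and five
differentiated lineages, two junction-count replicates each, and 16
histone marks (nine acetylation, seven methylation). Its defaults define
the simulated study:

* 5000 genes with 5-15 exons; 40% host an SE event, 30% an MXE pair
  (2000 and 1500 events). AS exons are drawn shorter (log-normal around
  110 bp vs 170 bp), with longer flanking introns (around 3.5 kb vs
  1.5 kb), and half of AS exon lengths are snapped to multiples of
  three — the frame-preservation and length contrasts the descriptive
  statistics test for.
* True reference PSI uniform on [0.25, 0.75]; each event is
  differential in a lineage with probability 0.35, shifting PSI by
  0.15-0.55 (clipped to [0.02, 0.98]) with a direction bias (SE 65%
  loss; MXE upstream 65% gain) that produces the SE-loss/MXE-gain
  asymmetry. Junction totals are Poisson(100) per replicate, inclusion
  reads binomial at the effective-length-adjusted PSI so the estimator
  is unbiased; both MXE exons share one total so their PSI estimates
  are exactly complementary.
* Three planted subsets per AS type (H3K36me3 positive and negative plus
  a small H4K8ac-negative subset for SE; H3K36me3 both signs plus a
  small H3K27ac-positive subset for MXE), with fractions
  0.28/0.18/0.05 and 0.26/0.22/0.05 of the differential events and a
  target within-member correlation of |r| = 0.6. The planting is
  linear-Gaussian at the distance-normalized peak scale:
  `delta = sign * beta * delta_psi + N(0, noise_sd)` with
  `noise_sd = 1` and beta solved from the realized spread of the
  members' true delta-PSI so the target r is met; requesting |r| < 1
  with `noise_sd = 0` is an error (noiseless planting forces r = 1).
  Peak records realize these values exactly: both cells' peaks share a
  summit at a fixed draw within 300 bp of the acceptor, so the
  distance normalization cancels.
* Unregulated event x HM pairs draw their delta from
  `N(0, null_noise_sd)` with `null_noise_sd = 0.3`: the peak heights of
  an exon whose mark is not differentially regulated are strongly
  correlated between cell types, so their difference is small relative
  to the regulated response. (Setting the two noise scales equal makes
  the feature space nearly isotropic and no clustering method could
  separate members from the bulk.) With probability 0.3 an unregulated
  pair has no called peak in any cell, exercising the signal-zero rule.
* Coverage tracks (optional, `with_coverage`) are 15-bp-resolution
  Poisson read counts over the splice-site neighbourhoods of AS genes,
  with unequal library sizes (30M reference vs 20M) so depth
  normalization is actually exercised, and a planted fractional coverage
  loss (50%) over AS exon bodies in the differentiated cells for
  `profile_hms` (H3K36me3 and H3K79me1 by default).
* Expression: log-normal FPKM (median 10), 20% DEGs at fold 2.5-6 in a
  random non-empty subset of lineages, AS-hosting genes down-weighted
  4:1 when sampling DEGs, and 10% log-normal measurement noise.

What the generator does **not** emulate: read-level artifacts (mapping
bias, PCR duplicates), nucleosome-scale coverage structure, peak-calling
uncertainty (narrowPeak files are emitted directly), correlated HMs
(each mark's noise is independent), overlapping genes, and annotation
error. Passing recovery tests therefore demonstrates that the analysis
chain is correct and calibrated under the declared generative model,
not that it is robust to every failure mode of real ChIP-seq/RNA-seq
data.

All randomness flows from one master seed through labelled hashes
(`derive_seed(seed, "stage")`), so stages are reproducible independently
of execution order, reruns are byte-identical, and no global RNG state
leaks.

## Problem sizes in the test suite

The suite validates exact arithmetic and enumeration oracles at toy
sizes; calibration at 850-2500 genes over 20-30 replicates; PSI and
differential-event recovery at 600 genes and junction coverage 100;
profile preference at 120 genes over 20 planted and 20 null seeds; and
end-to-end subset recovery at the full default SE scale (2000 events)
over 20 seeds. These sizes were chosen so the whole suite, and each
recovery check individually, gives stable Monte-Carlo estimates while
remaining runnable on a laptop in minutes.

## Known limitations

* The exact-test substitution for differential splicing ignores
  replicate overdispersion; with two replicates at moderate coverage the
  pooled test is slightly anticonservative for truly overdispersed data.
  The generator draws replicates i.i.d., matching the test's assumption.
* Member recovery of a mirror subset is information-limited by the
  target correlation: at |r| = 0.6 the residual spread of members around
  the planted line is 1.33x the signal, so even a Bayes-optimal
  assignment misclassifies a substantial minority of members against the
  unregulated bulk (F1 around 0.7 for a subset holding ~18% of events).
  K-means with a fixed k = 6 operates somewhat below that ceiling,
  and small subsets (5% of events) recover less stably than large ones.
  The subset's existence, HM identity and sign are recovered much more
  reliably than its exact membership.
* The logistic screen's Wald p values are mildly liberal at moderate n,
  as Wald tests are; the Firth path only engages under separation.
* The distance floor (100 bp) and the mirror thresholds (cosine -0.8,
  magnitude 0.5 sd) are judgment calls exposed as parameters; results
  for subsets near the gate can change with them.
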