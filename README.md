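# hmsplice

Genome-wide association of differential histone-modification (HM) ChIP-seq
signal with differential exon inclusion (alternative splicing, AS) across
cell-fate transitions — for example, a human embryonic stem cell line
differentiating into several lineages. The package is aimed at
computational epigenomics groups who want a tested, reproducible
implementation of the full analysis chain, together with a seeded
synthetic-data generator whose ground-truth ledger makes every stage
verifiable.

## The analysis

For each AS event (skipped exon, SE, or mutually exclusive exons, MXE —
for MXE only the transcript-upstream exon is analysed, since the pair's
inclusion levels satisfy Ψ_up + Ψ_down = 1) and each differentiation
lineage, the pipeline computes:

1. **Differential inclusion.** Ψ = (I/ℓ_I) / (I/ℓ_I + S/ℓ_S) from
   inclusion/skipping junction counts with effective lengths ℓ; a
   two-sided Fisher exact test on the pooled 2×2 count table between the
   reference and differentiated cell; Benjamini–Hochberg FDR per
   comparison. An event is inclusion-**loss** when ΔΨ = Ψ_ref − Ψ_diff
   > 0.1 and inclusion-**gain** when ΔΨ < −0.1, each requiring p ≤ 0.01
   and FDR ≤ 0.05.
2. **Splice-site ChIP profiles.** Depth-normalized differential reads
   per bin, Δ = (reads_ref·10⁶/lib_ref − reads_alt·10⁶/lib_alt)/bin_bp,
   over ±150 bp of each splice site in 15-bp bins (a side shorter than
   150 bp is divided into 10 equal bins), for AS exons versus matched
   constitutive (CS) exons sampled from the same genes; Mann–Whitney
   panel tests and per-HM Fisher "link strengths" across lineages.
3. **Differential peak signal (ΔHM).** The strongest narrowPeak
   overlapping an exon by ≥ 1 bp (zero if none), its height divided by
   the summit → 3′-splice-site distance in kb (floored at 0.1 kb);
   ΔHM = normalized signal in the reference minus the differentiated
   cell.
4. **Association screen and subsets.** Pearson correlation, multiple
   linear regression, and logistic regression of ΔΨ on the 16 ΔHM
   features; HMs significant (p ≤ 0.05) in any screen feed k-means
   (k = 6, 25 restarts) run separately on inclusion-gain and
   inclusion-loss events; antiparallel cluster pairs ("mirror patterns",
   cosine ≤ −0.8 with matching dominant HM) are merged into
   HM-associated AS subsets whose sign is the sign of the within-subset
   Pearson correlation.
5. **Expression companions.** Fold-change (> 2) DEG calls on FPKM with
   an FPKM ≥ 1 expression universe, hypergeometric gene-set enrichment,
   and isoform relative expression (FPKM_i / ΣFPKM).

The synthetic generator plants all of this structure — binomial junction
counts around true Ψ, peak evidence realizing ΔHM = sign·β·ΔΨ + noise
with β solved for a target correlation, exonic coverage shifts, DEG
fractions — and records it in a truth ledger for recovery testing.

## Worked example

```r
library(hmsplice)

cfg <- sim_config(seed = 7)          # 5000 genes: 2000 SE + 1500 MXE events
sim <- simulate_dataset(cfg)

calls <- do.call(rbind, lapply(cfg$lineages, function(lin) {
  cl <- call_differential(sim$counts[sim$counts$exon == "target", ],
                          "H1", lin)
  cl$lineage <- lin
  cl
}))
table(type = calls$type, direction = calls$direction)
#>      direction
#> type  gain loss none
#>   MXE 1690  947 4863
#>   SE  1193 2268 6539

direction_asymmetry_test(calls)$p_value
#> [1] 5.85e-118
```

SE exons predominantly lose inclusion upon differentiation while MXE
upstream exons gain it; the Fisher test quantifies that asymmetry.

```r
dhm <- do.call(rbind, lapply(unique(sim$peaks$hm), function(hm) {
  d <- delta_hm_table(sim$truth$events,
                      sim$peaks[sim$peaks$hm == hm, ], "H1", cfg$lineages)
  d$hm <- hm; d
}))
cl   <- calls[calls$direction != "none" & calls$type == "SE", ]
key  <- paste(cl$event_id, cl$lineage, sep = "|")
dmat <- hmsplice:::dhm_matrix(dhm)
assoc <- associate_hm_as(setNames(cl$delta_psi, key), dmat[key, ],
                         k = 6, seed = derive_seed(7, "SE"))
unique(assoc$subsets[c("subset_id", "hm", "sign", "r")])
#>      subset_id       hm sign          r
#> 1    H3K36me3- H3K36me3    - -0.8358307
#> 613  H3K36me3+ H3K36me3    +  0.8473436
#> 1442   H4K8ac-   H4K8ac    - -0.8746028
assoc$coverage_fraction
#> [1] 0.567
```

The three planted SE subsets (H3K36me3 in both orientations plus a small
negative H4K8ac subset) are recovered with their correct signs, and the
merged subsets cover 56.7% of the significant SE events.

`run_pipeline(run_config(seed = ...))` chains every stage (including the
splice-site profile panels when coverage tracks are simulated) and writes
TSV outputs plus a JSON run report; `exec/hmsplice` exposes the same
functionality as a command line with subcommands `simulate`, `call-as`,
`profile`, `delta-hm`, `associate`, `enrich`, `run-all` and `sweep`.

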