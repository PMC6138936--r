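test_that("generation is fully deterministic under (config, seed)", {
  cfg <- small_sim_config(seed = 4)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  t1 <- generate_truth(a1, cfg)
  c1 <- generate_junction_counts(t1, cfg)
  c2 <- generate_junction_counts(generate_truth(a2, cfg), cfg)
  expect_identical(c1, c2)
  # a different seed changes the draw
  cfg2 <- small_sim_config(seed = 5)
  expect_false(identical(generate_annotation(cfg2), a1))
})

test_that("annotation honours exon counts, roles and length structure", {
  cfg <- sim_config(n_genes = 10L, exons_per_gene = c(5L, 5L),
                    se_gene_fraction = 0, mxe_gene_fraction = 0, seed = 2)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 50L)
  expect_true(all(ann$role %in% c("CS", "other")))
  expect_error(sim_config(n_genes = 0), "positive")

  big <- generate_annotation(sim_config(n_genes = 500L, seed = 6))
  # AS exons shorter than CS exons on average, introns near AS longer
  expect_lt(mean(big$end[big$role == "AS"] - big$start[big$role == "AS"]),
            mean(big$end[big$role == "CS"] - big$start[big$role == "CS"]))
  # exons of one gene are non-overlapping and ordered
  one <- big[big$gene_id == big$gene_id[1], ]
  one <- one[order(one$start), ]
  expect_true(all(one$start[-1] >= one$end[-nrow(one)]))
  # first and last transcript exons are never AS or CS
  firsts <- big[big$exon_index == 1, ]
  expect_true(all(firsts$role == "other"))
})

test_that("planted subset invariants hold in the truth ledger", {
  cfg <- small_sim_config(seed = 9)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  expect_true(all(truth$psi_alt >= 0.02 & truth$psi_alt <= 0.98))
  expect_true(all(abs(truth$delta_psi) <= 1))
  # every planted member is differential (|delta psi| >= 0.1) somewhere
  mem_rows <- match(truth$membership$event_id, truth$events$event_id)
  expect_true(all(rowSums(abs(truth$delta_psi[mem_rows, , drop = FALSE])
                          >= 0.1) >= 1))
  # memberships are disjoint across subsets
  expect_equal(anyDuplicated(truth$membership$event_id), 0L)
})

test_that("junction counts are binomial around true PSI and MXE-complementary", {
  cfg <- sim_config(n_genes = 250L, exons_per_gene = c(5L, 8L),
                    se_gene_fraction = 0.8, mxe_gene_fraction = 0.2,
                    junction_coverage = 10000, seed = 13)
  sim <- simulate_dataset(cfg)
  ref <- sim$counts[sim$counts$cell == "H1" & sim$counts$exon == "target", ]
  pooled_I <- tapply(ref$I, ref$event_id, sum)
  pooled_S <- tapply(ref$S, ref$event_id, sum)
  len_I <- tapply(ref$len_I, ref$event_id, `[`, 1)
  psi_hat <- compute_psi(pooled_I, pooled_S, len_I, 1)
  truth_psi <- sim$truth$psi_ref[match(names(psi_hat),
                                       sim$truth$events$event_id)]
  expect_lte(mean(abs(psi_hat - truth_psi)), 0.02)

  # MXE complementarity is exact per replicate
  up <- sim$counts[sim$counts$type == "MXE" & sim$counts$exon == "target", ]
  dn <- sim$counts[sim$counts$exon == "mxe_down", ]
  key <- function(d) paste(sub(":down$", "", d$event_id), d$cell,
                           d$replicate)
  dn <- dn[match(key(up), key(dn)), ]
  psi_up <- compute_psi(up$I, up$S)
  psi_dn <- compute_psi(dn$I, dn$S)
  ok <- !is.na(psi_up) & !is.na(psi_dn)
  expect_equal(psi_up[ok] + psi_dn[ok], rep(1, sum(ok)))
})

test_that("planted correlations are realized near their target", {
  rs <- c()
  for (s in 1:4) {
    sim <- simulate_dataset(sim_config(n_genes = 1500L,
                                       exons_per_gene = c(5L, 8L),
                                       seed = 100 + s))
    rr <- sim$realized_r
    big <- rr[rr$n_instances >= 100, ]
    rs <- c(rs, abs(big$realized_r))
  }
  expect_lt(abs(mean(rs) - 0.6), 0.05)
})

test_that("unplanted marks carry no delta-PSI dependence", {
  sim <- simulate_dataset(sim_config(n_genes = 1200L,
                                     exons_per_gene = c(5L, 8L),
                                     seed = 37))
  ev <- sim$truth$events
  d <- delta_hm_table(ev, sim$peaks[sim$peaks$hm == "H3K9me3", ],
                      "H1", sim$config$lineages)
  truth_delta <- sim$truth$delta_psi[cbind(match(d$event_id, ev$event_id),
                                           match(d$lineage,
                                                 sim$config$lineages))]
  sel <- abs(truth_delta) >= 0.1
  expect_gt(sum(sel), 1000)
  expect_lt(abs(cor(truth_delta[sel], d$delta_hm[sel])), 0.1)
})

test_that("noiseless planting with a sub-unit target correlation errors", {
  cfg <- small_sim_config(
    seed = 3, noise_sd = 0,
    planted_subsets = data.frame(as_type = "SE", hm = "H3K36me3",
                                 sign = "+", fraction = 0.3,
                                 target_r = 0.6))
  ann <- generate_annotation(cfg)
  expect_error(generate_truth(ann, cfg), "unreachable")
})

test_that("config validation rejects inconsistent planting requests", {
  expect_error(sim_config(planted_subsets = data.frame(
    as_type = "SE", hm = "H3K36me3", sign = "+", fraction = 0.7,
    target_r = 0.6) [c(1, 1), ]), "sum above 1")
  expect_error(sim_config(planted_subsets = data.frame(
    as_type = "SE", hm = "NOPE", sign = "+", fraction = 0.1,
    target_r = 0.6)), "unknown HM")
  expect_error(sim_config(se_gene_fraction = 0.8, mxe_gene_fraction = 0.5),
               "sum to at most 1")
})

test_that("written datasets round-trip through the readers", {
  cfg <- sim_config(n_genes = 40L, exons_per_gene = c(5L, 6L),
                    with_coverage = TRUE, seed = 8)
  sim <- simulate_dataset(cfg)
  d <- withr::local_tempdir()
  paths <- write_dataset(sim, d)
  expect_true(all(file.exists(paths)))
  ann <- read_bed(file.path(d, "annotation.bed"))
  expect_equal(nrow(ann), nrow(sim$annotation))
  expect_equal(ann$start, sim$annotation$start)
  counts <- read_tsv(file.path(d, "junction_counts.tsv"))
  expect_equal(counts$I, sim$counts$I)
  pk_files <- list.files(file.path(d, "peaks"), full.names = TRUE)
  expect_equal(length(pk_files),
               length(unique(sim$peaks$hm)) * 6L)
  pk <- read_narrowpeak(grep("H3K36me3.H1", pk_files, value = TRUE))
  ours <- sim$peaks[sim$peaks$hm == "H3K36me3" & sim$peaks$cell == "H1", ]
  expect_equal(pk$start, ours$start)
  expect_equal(pk$signal, round(ours$signal, 6))
  cov_files <- list.files(file.path(d, "coverage"), pattern = "bedGraph$")
  expect_equal(length(cov_files), 16L * 6L)
  libs <- read_tsv(file.path(d, "coverage", "lib_sizes.tsv"))
  expect_setequal(libs$cell, c("H1", cfg$lineages))
})
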