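test_that("bin_region yields 15-bp bins with the short-side rule", {
  b <- bin_region("chr1", 1000L, 1300L, "+", 1000L, 1000L)
  expect_equal(nrow(b), 40L) # 20 per splice site
  ss3 <- b[b$side == "ss3", ]
  expect_equal(unique(ss3$end - ss3$start), 15L)
  expect_equal(ss3$region, rep(c("intron", "exon"), each = 10))
  # transcript order on '+': intronic bins climb toward the acceptor
  expect_equal(ss3$start[1], 1000L - 150L)
  expect_equal(ss3$start[11], 1000L)
  # 60-bp exon: exonic side becomes 10 bins of 6 bp
  b2 <- bin_region("chr1", 1000L, 1060L, "+", 1000L, 1000L)
  exo <- b2[b2$side == "ss3" & b2$region == "exon", ]
  expect_equal(nrow(exo), 10L)
  expect_equal(unique(exo$end - exo$start), 6L)
  expect_equal(range(c(exo$start, exo$end)), c(1000L, 1060L))
  expect_error(bin_region("chr1", 0L, 5L, "+", 100L, 100L), "10 bp")
})

test_that("minus-strand bins mirror the genomic order", {
  bp <- bin_region("chr1", 1000L, 1300L, "+", 600L, 400L)
  bm <- bin_region("chr1", 1000L, 1300L, "-", 400L, 600L)
  # the acceptor sits at the exon end on '-': first ss3 intron bin is the
  # one furthest into the upstream (rightmost) intron
  expect_equal(bm$start[bm$side == "ss3"][1], 1300L + 150L - 15L)
  # strand flip maps ss3 bins onto the mirrored ss3 window
  p3 <- bp[bp$side == "ss3", ]
  m3 <- bm[bm$side == "ss3", ]
  expect_equal(sort(unique(c(m3$start, m3$end))),
               sort(unique(2300L - c(p3$end, p3$start))))
})

test_that("delta_reads applies per-million depth normalization per bp", {
  bins <- data.frame(chrom = "chr1", start = 0L, end = 15L)
  ref <- make_track(0L, 15L, 4, lib = 30e6)  # 60 reads
  alt <- make_track(0L, 15L, 20 / 15, lib = 20e6) # 20 reads
  expect_equal(delta_reads(bins, ref, alt), (2 - 1) / 15)
  expect_equal(delta_reads(bins, ref, ref), 0)
  expect_lt(delta_reads(bins, alt, ref), 0)
})

test_that("binned deltas conserve the whole-region normalized difference", {
  set.seed(9)
  n <- 40
  starts <- seq(0L, by = 15L, length.out = n)
  ref <- make_track(starts, starts + 15L, runif(n, 0, 5), lib = 25e6)
  alt <- make_track(starts, starts + 15L, runif(n, 0, 5), lib = 18e6)
  b <- bin_region("chr1", 195L, 400L, "+", 180L, 150L)
  d <- delta_reads(b, ref, alt)
  len <- b$end - b$start
  whole <- data.frame(chrom = "chr1", start = min(b$start),
                      end = max(b$end))
  # ss3 and ss5 windows may overlap; compare over the union via long sums
  sel <- b$side == "ss3"
  expect_equal(sum((d * len)[sel]),
               sum(delta_reads(b[sel, ], ref, alt) *
                     (b$end - b$start)[sel]))
  one <- b[1, , drop = FALSE]
  expect_equal(d[1] * len[1],
               coverage_sum(ref, one$chrom, one$start, one$end) * 1e6 / 25e6 -
                 coverage_sum(alt, one$chrom, one$start, one$end) * 1e6 / 18e6)
})

test_that("profile matrices are invariant under a strand flip of the locus", {
  set.seed(11)
  L <- 3000L
  n <- L %/% 15L
  starts <- seq(0L, by = 15L, length.out = n)
  vals_ref <- runif(n, 0, 4)
  vals_alt <- runif(n, 0, 4)
  ref <- make_track(starts, starts + 15L, vals_ref, lib = 1e7)
  alt <- make_track(starts, starts + 15L, vals_alt, lib = 1e7)
  exons <- data.frame(exon_id = "e1", chrom = "chr1", start = 1200L,
                      end = 1500L, strand = "+",
                      intron_up_len = 600L, intron_down_len = 700L)
  pm_fwd <- profile_matrix(exons, ref, alt)
  # mirrored locus: position x -> L - x
  ref_m <- make_track(L - rev(starts) - 15L, L - rev(starts),
                      rev(vals_ref), lib = 1e7)
  alt_m <- make_track(L - rev(starts) - 15L, L - rev(starts),
                      rev(vals_alt), lib = 1e7)
  exons_m <- data.frame(exon_id = "e1", chrom = "chr1",
                        start = L - 1500L, end = L - 1200L, strand = "-",
                        intron_up_len = 600L, intron_down_len = 700L)
  pm_rev <- profile_matrix(exons_m, ref_m, alt_m)
  expect_equal(pm_rev$delta, pm_fwd$delta, tolerance = 1e-12)
})

test_that("CS exon sampling is deterministic, within-gene and logged", {
  ann <- data.frame(
    gene_id = rep(c("gA", "gB"), c(10, 1)),
    exon_id = c(sprintf("gA.E%02d", 1:10), "gB.E01"),
    role = c("other", "AS", rep("CS", 7), "AS", "AS"))
  events <- data.frame(event_id = c("ev1", "ev2", "ev3"),
                       gene_id = c("gA", "gA", "gB"))
  expect_warning(cs <- sample_cs_exons(events, ann, seed = 7),
                 "no CS exon")
  expect_equal(nrow(cs), 2L) # gB event skipped
  expect_true(all(cs$exon_id %in% ann$exon_id[ann$role == "CS"]))
  expect_false(anyDuplicated(cs$exon_id) > 0)
  expect_equal(attr(cs, "n_skipped"), 1L)
  cs2 <- suppressWarnings(sample_cs_exons(events, ann, seed = 7))
  expect_identical(cs$exon_id, cs2$exon_id)
  cs3 <- suppressWarnings(sample_cs_exons(events, ann, seed = 8))
  expect_false(identical(cs$exon_id, cs3$exon_id) &&
                 identical(cs$exon_id, sort(cs$exon_id))) # seed matters
})

test_that("panel Mann-Whitney agrees with permutation enumeration", {
  pm_as <- pm_from_summaries(c(5, 6, 7))
  pm_cs <- pm_from_summaries(c(1, 2, 3))
  r <- profile_panel_test(pm_as, pm_cs)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(r$p_value, mw_enum(c(5, 6, 7), c(1, 2, 3)),
               tolerance = 1e-12)
  expect_equal(r$preferred, "AS")

  same <- profile_panel_test(pm_from_summaries(c(2, 3, 4)),
                             pm_from_summaries(c(2, 3, 4)))
  expect_gt(same$p_value, 0.99)

  rev_ <- profile_panel_test(pm_from_summaries(c(1, 2, 3)),
                             pm_from_summaries(c(4, 5, 6)))
  expect_equal(rev_$preferred, "CS")
  expect_equal(rev_$p_value, mw_enum(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)

  under <- profile_panel_test(pm_from_summaries(c(1, 2)),
                              pm_from_summaries(c(3, 4)))
  expect_true(under$underpowered)
  expect_equal(under$p_value, 1)
})

test_that("link strength contrasts a focal HM against all others", {
  panels <- rbind(
    data.frame(hm = "H3K36me3", preferred = rep("AS", 10)),
    data.frame(hm = "other", preferred = rep(c("AS", "CS"), each = 75)))
  r <- link_strength(panels, "H3K36me3")
  expect_equal(r$p_value, fisher_enum_2x2(10, 0, 75, 75), tolerance = 1e-10)
  expect_gt(r$link_strength, 1.3)

  balanced <- rbind(
    data.frame(hm = "X", preferred = rep(c("AS", "CS"), each = 5)),
    data.frame(hm = "other", preferred = rep(c("AS", "CS"), each = 50)))
  expect_equal(link_strength(balanced, "X")$link_strength, 0)

  solo <- data.frame(hm = "X", preferred = rep("AS", 4))
  expect_error(link_strength(solo, "X"), "two HMs")
  expect_error(link_strength(balanced, "nope"), "no panels")
})
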