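test_that("compute_psi follows the effective-length-weighted ratio", {
  expect_equal(compute_psi(8, 2), 0.8)
  expect_equal(compute_psi(0, 5), 0)
  expect_equal(compute_psi(5, 0), 1)
  expect_equal(compute_psi(10, 10, len_I = 2, len_S = 1), 5 / 15)
  # invariant to common rescaling of both lengths
  expect_equal(compute_psi(7, 3, 2, 1), compute_psi(7, 3, 200, 100))
  # monotone in I for fixed S
  psis <- compute_psi(0:20, 5)
  expect_true(all(diff(psis) > 0))
  expect_true(is.na(compute_psi(0, 0)))
  expect_error(compute_psi(-1, 2), "negative")
})

test_that("vectorized Fisher p matches stats::fisher.test", {
  set.seed(42)
  a <- sample(0:30, 300, TRUE); b <- sample(0:30, 300, TRUE)
  c_ <- sample(0:30, 300, TRUE); d <- sample(0:30, 300, TRUE)
  ours <- hmsplice:::fisher_p_2x2(a, b, c_, d)
  ref <- mapply(function(a, b, c, d)
    stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
    a, b, c_, d)
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("differential calls match the exact-test oracle and thresholds", {
  counts <- make_counts(
    event_id = c("e1", "e2", "e3"), type = c("SE", "SE", "SE"),
    I_ref = c(90, 50, 3), S_ref = c(10, 50, 7),
    I_alt = c(10, 50, 0), S_alt = c(90, 50, 1))
  calls <- call_differential(counts, "H1", "MSC")
  calls <- calls[match(c("e1", "e2", "e3"), calls$event_id), ]

  # e1: 90/10 vs 10/90: delta = 0.8, loss
  expect_equal(calls$delta_psi[1], 0.8)
  expect_equal(calls$p_value[1],
               fisher_enum_2x2(90, 10, 10, 90), tolerance = 1e-12)
  expect_lt(calls$p_value[1], 1e-6)
  expect_equal(calls$direction[1], "loss")
  # e2: identical counts: no change
  expect_equal(calls$delta_psi[2], 0)
  expect_equal(calls$direction[2], "none")
  # e3: large delta but hopeless power: stays none
  expect_gt(calls$delta_psi[3], 0.1)
  expect_equal(calls$p_value[3],
               fisher_enum_2x2(3, 7, 0, 1), tolerance = 1e-12)
  expect_equal(calls$direction[3], "none")
})

test_that("caller FDR equals brute-force Benjamini-Hochberg", {
  set.seed(7)
  n <- 60
  counts <- make_counts(
    event_id = sprintf("e%02d", 1:n), type = rep("SE", n),
    I_ref = rbinom(n, 80, 0.6), S_ref = rbinom(n, 80, 0.4),
    I_alt = rbinom(n, 80, 0.5), S_alt = rbinom(n, 80, 0.5))
  calls <- call_differential(counts, "H1", "MSC")
  expect_equal(calls$fdr, bh_bruteforce(calls$p_value), tolerance = 1e-12)
})

test_that("events missing one cell raise an error", {
  counts <- make_counts("e1", "SE", 10, 10, 10, 10)
  counts <- counts[counts$cell == "H1", ]
  expect_error(call_differential(counts, "H1", "MSC"), "cell")
})

test_that("MXE reduction keeps the upstream call and checks complementarity", {
  up <- data.frame(event_id = "m1", psi_ref = 0.3, psi_alt = 0.6)
  down_ok <- data.frame(event_id = "m1d", psi_ref = 0.7, psi_alt = 0.4)
  down_bad <- data.frame(event_id = "m1d", psi_ref = 0.5, psi_alt = 0.4)
  expect_identical(mxe_upstream_delta(up, down_ok), up)
  expect_error(mxe_upstream_delta(up, down_bad), "not complementary")
})

test_that("direction asymmetry matches hypergeometric enumeration", {
  mk <- function(tab) {
    data.frame(
      type = rep(rep(c("SE", "MXE"), each = 2), times = as.vector(t(tab))),
      direction = rep(rep(c("gain", "loss"), 2), times = as.vector(t(tab))))
  }
  r <- direction_asymmetry_test(mk(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)))
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(r$p_value, fisher_enum_2x2(10, 0, 0, 10), tolerance = 1e-12)

  r2 <- direction_asymmetry_test(mk(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)))
  expect_equal(r2$p_value, 1)

  r3 <- direction_asymmetry_test(mk(matrix(c(1, 0, 0, 1), 2, byrow = TRUE)))
  expect_equal(r3$p_value, 1) # too small for two-sided significance

  empty <- data.frame(type = c("SE", "MXE"), direction = c("gain", "gain"))
  expect_warning(r4 <- direction_asymmetry_test(empty), "empty margin")
  expect_equal(r4$p_value, 1)
})

test_that("lineage specificity labels events and reports percentages", {
  lineages <- paste0("L", 1:5)
  mk_event <- function(id, sig_in) {
    data.frame(event_id = id, type = "SE", gene_id = paste0("g_", id),
               lineage = lineages,
               direction = ifelse(lineages %in% sig_in, "loss", "none"))
  }
  calls <- rbind(mk_event("e1", "L1"), mk_event("e2", lineages),
                 mk_event("e3", c("L1", "L2")), mk_event("e4", "L3"),
                 mk_event("e5", character(0)))
  ls <- lineage_specificity(calls)
  lab <- setNames(ls$events$label, ls$events$event_id)
  expect_equal(unname(lab[c("e1", "e2", "e3", "e5")]),
               c("lineage-specific", "common", "shared", "none"))
  pct <- ls$percent[ls$percent$type == "SE", ]
  expect_equal(pct$n_called, 4)
  expect_equal(pct$pct_specific, 50) # e1, e4 of 4 called
  g <- setNames(ls$genes$label, ls$genes$gene_id)
  expect_equal(unname(g["g_e2"]), "common")
})

test_that("frame preservation fractions and test match the oracle", {
  expect_equal(frame_preservation_stats(99, c(100, 101))$frac_as, 1)
  r <- frame_preservation_stats(c(99, 150, 100), c(100, 101, 103))
  expect_equal(r$frac_as, 2 / 3)
  big <- frame_preservation_stats(
    c(rep(99, 80), rep(100, 20)), c(rep(99, 33), rep(100, 67)))
  expect_lt(big$p_value, 1e-10)
  expect_equal(big$p_value, fisher_enum_2x2(80, 20, 33, 67),
               tolerance = 1e-10)
  expect_error(frame_preservation_stats(integer(0), 1L), "no events")
})

test_that("length statistics detect shorter AS exons", {
  same <- length_stats(1:20 * 10, 1:20 * 10)
  expect_gt(same$p_value, 0.9)
  shifted <- length_stats(rep(50, 8) + 1:8, rep(150, 8) + 1:8)
  expect_lt(shifted$median_as, shifted$median_bg)
  expect_lte(shifted$p_value, 0.05)
  expect_error(length_stats(numeric(0), 1), "no events")
})
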