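mk_mat <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  rownames(m) <- paste0("k", seq_len(nrow(m)))
  m
}

test_that("Pearson screen recovers exact linear relations", {
  x <- seq(-1, 1, length.out = 10)
  m <- mk_mat(up = 2 * x, down = -3 * x, flat = rep(1, 10))
  r <- pearson_screen(x, m)
  expect_equal(r$statistic[r$hm == "up"], 1)
  expect_lt(r$p_value[r$hm == "up"], 1e-10)
  expect_equal(r$statistic[r$hm == "down"], -1)
  expect_true(is.na(r$statistic[r$hm == "flat"]))
  expect_false(r$selected[r$hm == "flat"])
  expect_error(pearson_screen(x[1:5], m[1:5, ]), "at least 10")
})

test_that("screen p-values are calibrated under an independent null", {
  set.seed(31)
  hits <- 0L; total <- 0L
  for (rep_i in 1:150) {
    y <- rnorm(100)
    m <- mk_mat(a = rnorm(100), b = rnorm(100), c = rnorm(100))
    r <- pearson_screen(y, m)
    hits <- hits + sum(r$selected)
    total <- total + nrow(r)
  }
  expect_gt(hits / total, 0.02)
  expect_lt(hits / total, 0.09)
})

test_that("MLR screen returns joint-fit coefficients and drops aliases", {
  set.seed(5)
  m <- mk_mat(HM1 = rnorm(60), HM2 = rnorm(60))
  y <- 0.5 * m[, "HM1"]
  r <- mlr_screen(y, m)
  expect_equal(r$statistic[r$hm == "HM1"], 0.5, tolerance = 1e-10)
  expect_equal(r$statistic[r$hm == "HM2"], 0, tolerance = 1e-10)
  expect_true(r$selected[r$hm == "HM1"])

  m2 <- cbind(m, HM1copy = m[, "HM1"])
  expect_message(r2 <- mlr_screen(y, m2), "rank-deficient")
  expect_true(is.na(r2$statistic[r2$hm == "HM1copy"]))
})

test_that("LLR screen flags separation and keeps the coefficient sign", {
  set.seed(6)
  x <- c(rnorm(50, -2), rnorm(50, 2))
  y_sep <- c(rep(-0.5, 50), rep(0.5, 50)) # direction == sign(x): separable
  m <- mk_mat(HM1 = x, HM2 = rnorm(100))
  r <- llr_screen(y_sep, m)
  expect_true(all(r$separation))
  expect_gt(r$statistic[r$hm == "HM1"], 0)

  y_noisy <- ifelse(rnorm(100, x) > 0, 0.5, -0.5)
  r2 <- llr_screen(y_noisy, m)
  expect_false(any(r2$separation))
  expect_true(r2$selected[r2$hm == "HM1"])
  expect_error(llr_screen(rep(0.5, 100), m), "single-class")
})

test_that("Firth refit approximates the ML fit away from separation", {
  set.seed(8)
  x <- rnorm(300)
  y <- rbinom(300, 1, plogis(0.8 * x))
  fr <- hmsplice:::firth_logistic(y, cbind(HM = x))
  ml <- glm(y ~ x, family = binomial())
  expect_equal(unname(fr$coef), unname(coef(ml)[2]), tolerance = 0.05)
})

test_that("feature selection takes the union over the three screens", {
  screens <- data.frame(
    hm = rep(c("A", "B", "C"), times = 3),
    test = rep(c("PC", "MLR", "LLR"), each = 3),
    selected = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, TRUE))
  expect_equal(select_features(screens), c("A", "C"))
  screens$selected <- FALSE
  expect_equal(select_features(screens), character(0))
})

test_that("k-means recovers point-mass clusters deterministically", {
  x <- rbind(matrix(1, 20, 4), matrix(-1, 20, 4))
  rownames(x) <- paste0("e", 1:40)
  colnames(x) <- paste0("hm", 1:4)
  cl <- cluster_directions(x, k = 2, seed = 3, standardize = FALSE)
  expect_equal(length(unique(cl$assignments[1:20])), 1L)
  expect_equal(length(unique(cl$assignments[21:40])), 1L)
  expect_lt(cl$rmse_by_k[["k2"]], 1e-8)
  cl2 <- cluster_directions(x, k = 2, seed = 3, standardize = FALSE)
  expect_identical(cl$assignments, cl2$assignments)
  expect_equal(names(cl$rmse_by_k), paste0("k", 2:8))
  expect_error(cluster_directions(x[1:3, ], k = 6, seed = 1), "smaller k")
})

test_that("mirror pairing demands antiparallel centroids, same dominant HM", {
  g <- rbind(c(2, 0.1), c(0, 1), c(1, 1))
  colnames(g) <- c("A", "B")
  l <- rbind(-g[1, ], c(0.05, 2), c(-0.5, -0.5))
  colnames(l) <- c("A", "B")
  p <- find_mirror_pairs(g, l)
  expect_equal(nrow(p), 2L)
  exact <- p[p$gain_cluster == 1, ]
  expect_equal(exact$loss_cluster, 1L)
  expect_equal(exact$hm, "A")
  expect_equal(exact$cosine, -1)
  # orthogonal centroids never pair
  g2 <- rbind(c(1, 0)); colnames(g2) <- c("A", "B")
  l2 <- rbind(c(0, 1)); colnames(l2) <- c("A", "B")
  expect_message(p2 <- find_mirror_pairs(g2, l2), "no centroid pair")
  expect_equal(nrow(p2), 0L)
  # antiparallel but dominant features differ: rejected
  g3 <- rbind(c(1, 0.9)); colnames(g3) <- c("A", "B")
  l3 <- rbind(c(-0.9, -1)); colnames(l3) <- c("A", "B")
  expect_message(p3 <- find_mirror_pairs(g3, l3), "no centroid pair")
  expect_equal(nrow(p3), 0L)
})

test_that("mirror pairing is symmetric under swapping gain and loss", {
  set.seed(12)
  g <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  l <- rbind(-g[1, ] + rnorm(3, 0, 0.01), matrix(rnorm(9), 3, 3))
  colnames(l) <- c("A", "B", "C")
  p_fwd <- find_mirror_pairs(g, l)
  p_rev <- find_mirror_pairs(l, g)
  expect_equal(p_fwd$gain_cluster, p_rev$loss_cluster)
  expect_equal(p_fwd$loss_cluster, p_rev$gain_cluster)
  expect_equal(p_fwd$cosine, p_rev$cosine)
})

test_that("subsets merge same-sign pairs, carry signs and coverage", {
  # two planted groups on HM 'A' (+ and -), clean geometry
  keys_g <- paste0("g", 1:40); keys_l <- paste0("l", 1:40)
  dpsi <- setNames(c(rep(-0.4, 40), rep(0.4, 40)), c(keys_g, keys_l))
  # gain members of '+': delta = dpsi < 0; two gain clusters split them
  dhm <- mk_mat(A = c(rep(-0.4, 20), rep(-0.41, 20), rep(0.4, 40)),
                B = rep(0, 80))
  rownames(dhm) <- c(keys_g, keys_l)
  gain_assign <- setNames(rep(1:2, each = 20), keys_g)
  loss_assign <- setNames(rep(1L, 40), keys_l)
  pairs <- data.frame(gain_cluster = 1:2, loss_cluster = 1L,
                      hm = "A", cosine = -1)
  subs <- build_subsets(pairs, gain_assign, loss_assign, dpsi, dhm)
  expect_equal(unique(subs$subset_id), "A+")
  expect_equal(sort(unique(subs$event_key)), sort(c(keys_g, keys_l)))
  expect_gte(subs$r[1], 0.99)
  expect_lt(subs$p_value[1], 1e-10)
  expect_equal(attr(subs, "coverage_fraction"), 1)

  # a pair whose members carry no correlation is dropped with a warning
  dhm_null <- mk_mat(A = rnorm(80, 0, 1e-3), B = rep(0, 80))
  rownames(dhm_null) <- c(keys_g, keys_l)
  expect_warning(
    subs2 <- build_subsets(pairs[1, ], gain_assign, loss_assign,
                           setNames(rnorm(80, 0, 0.2), c(keys_g, keys_l)),
                           dhm_null),
    "dropped")
  expect_equal(nrow(subs2), 0L)
})
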