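## association: the three-test correlation screen (Pearson, multiple
## linear regression, logistic regression) between delta PSI and delta HM,
## feature selection, k-means clustering of inclusion-gain and
## inclusion-loss events, mirror-pattern merging, and subset construction.

#' Pearson correlation screen
#'
#' Per-HM Pearson correlation between delta PSI and that HM's delta-HM
#' column, with the two-sided p from the t distribution of
#' `r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param delta_psi numeric vector (one value per event observation).
#' @param delta_hm numeric matrix, columns named by HM.
#' @param alpha selection threshold on p (default 0.05).
#' @return data.frame with `hm`, `test = "PC"`, `statistic` (r),
#'   `p_value`, `selected`. HMs with zero variance get `NA` statistics and
#'   are never selected.
#' @export
pearson_screen <- function(delta_psi, delta_hm, alpha = 0.05) {
  if (length(delta_psi) < 10L)
    stop("need at least 10 paired observations")
  res <- lapply(colnames(delta_hm), function(hm) {
    x <- delta_hm[, hm]
    if (sd(x) == 0 || sd(delta_psi) == 0) {
      return(data.frame(hm = hm, test = "PC", statistic = NA_real_,
                        p_value = NA_real_, selected = FALSE))
    }
    ct <- cor.test(delta_psi, x, method = "pearson")
    data.frame(hm = hm, test = "PC", statistic = unname(ct$estimate),
               p_value = ct$p.value,
               selected = ct$p.value <= alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Multiple-linear-regression screen
#'
#' One ordinary-least-squares fit of delta PSI on all delta-HM columns
#' jointly; each HM's statistic is its coefficient with the usual
#' two-sided t-test p. Duplicated (aliased) columns are dropped with a
#' message before fitting.
#'
#' @inheritParams pearson_screen
#' @return data.frame with `hm`, `test = "MLR"`, `statistic`
#'   (coefficient), `p_value`, `selected`; dropped columns appear with
#'   `NA`.
#' @export
mlr_screen <- function(delta_psi, delta_hm, alpha = 0.05) {
  if (length(delta_psi) <= ncol(delta_hm) + 1L)
    stop("need more observations than features")
  fit <- lm(delta_psi ~ ., data = as.data.frame(delta_hm))
  co <- suppressWarnings(summary(fit))$coefficients
  aliased <- names(which(is.na(coef(fit))))
  if (length(aliased) > 0L) {
    message(sprintf("mlr_screen: dropped rank-deficient column(s): %s",
                    paste(aliased, collapse = ", ")))
    if (sum(!is.na(coef(fit))) <= 1L)
      stop("design matrix rank-deficient after dropping columns")
  }
  hms <- colnames(delta_hm)
  # lm backtick-quotes non-syntactic names
  key <- make.names(hms)
  rn <- make.names(rownames(co))
  idx <- match(key, rn)
  out <- data.frame(hm = hms, test = "MLR",
                    statistic = ifelse(is.na(idx), NA, co[idx, 1L]),
                    p_value = ifelse(is.na(idx), NA, co[idx, 4L]))
  out$selected <- !is.na(out$p_value) & out$p_value <= alpha
  rownames(out) <- NULL
  out
}

# Firth bias-reduced logistic regression (Jeffreys-prior penalty), used
# only as the declared refit when the plain fit separates perfectly.
firth_logistic <- function(y, X, max_iter = 100, tol = 1e-8) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    XW <- X1 * W
    info <- crossprod(X1, XW)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) break
    H <- rowSums((X1 %*% inv) * XW) # hat diagonal
    U <- crossprod(X1, y - p + H * (0.5 - p))
    step <- drop(inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X1 %*% beta)
  p <- 1 / (1 + exp(-eta))
  info <- crossprod(X1, X1 * (p * (1 - p)))
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  list(coef = beta[-1L], se = se[-1L],
       p_value = 2 * pnorm(-abs(z[-1L])))
}

#' Logistic-regression screen
#'
#' Logistic fit of the inclusion direction (`1{delta_psi > 0}`, i.e. loss
#' vs gain) on all delta-HM columns jointly, with per-coefficient Wald p.
#' If the fit separates perfectly the result is flagged and recomputed
#' with a Firth bias-reduced fit.
#'
#' @inheritParams pearson_screen
#' @return data.frame with `hm`, `test = "LLR"`, `statistic`
#'   (coefficient), `p_value`, `selected`, `separation` flag.
#' @export
llr_screen <- function(delta_psi, delta_hm, alpha = 0.05) {
  y <- as.integer(delta_psi > 0)
  if (length(unique(y)) < 2L)
    stop("single-class response: need both gain and loss events")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = as.data.frame(delta_hm), family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  hms <- colnames(delta_hm)
  if (sep) {
    fr <- firth_logistic(y, as.matrix(delta_hm))
    out <- data.frame(hm = hms, test = "LLR", statistic = fr$coef,
                      p_value = fr$p_value)
  } else {
    co <- summary(fit)$coefficients
    rn <- make.names(rownames(co))
    idx <- match(make.names(hms), rn)
    out <- data.frame(hm = hms, test = "LLR",
                      statistic = ifelse(is.na(idx), NA, co[idx, 1L]),
                      p_value = ifelse(is.na(idx), NA, co[idx, 4L]))
  }
  out$selected <- !is.na(out$p_value) & out$p_value <= alpha
  out$separation <- sep
  rownames(out) <- NULL
  out
}

#' Select HM features for clustering
#'
#' An HM is carried into clustering if any of the three screens calls it
#' significant (union rule).
#'
#' @param screens data.frame of stacked screen outputs (`hm`, `test`,
#'   `selected`).
#' @return character vector of selected HM names (stable input order).
#' @export
select_features <- function(screens) {
  sel <- tapply(screens$selected, screens$hm, any)
  hms <- unique(screens$hm)
  hms[hms %in% names(sel)[sel]]
}

# Per-HM standardization with pooled statistics so that gain and loss
# clusterings live in a common feature space. Centre/scale are the median
# and MAD (falling back to sd, then 1): the unregulated bulk of exons
# defines each HM's scale, so a minority of strongly regulated exons
# cannot compress its own axis.
standardize_features <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- apply(x, 2, median)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::mad)
    fallback <- scale == 0
    scale[fallback] <- apply(x[, fallback, drop = FALSE], 2, sd)
    scale[scale == 0] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' K-means clustering of one direction set
#'
#' Clusters the events of one inclusion direction on their (standardized)
#' delta-HM features with `stats::kmeans` (fixed seed, 25 restarts), and
#' records the RMSE over `k = 2..8` so the choice of `k` is auditable.
#'
#' @param features numeric matrix (events x selected HMs), rownames =
#'   event keys; already standardized if `standardize = FALSE`.
#' @param k number of clusters (default 6).
#' @param seed integer seed.
#' @param standardize z-score features before clustering (default TRUE).
#' @param k_range k values over which RMSE is recorded.
#' @return list with `assignments` (named integer vector), `centroids`
#'   (k x features), `rmse_by_k`, `k`, `seed`.
#' @export
cluster_directions <- function(features, k = 6L, seed,
                               standardize = TRUE, k_range = 2:8) {
  stopifnot(!missing(seed))
  if (nrow(features) < k)
    stop(sprintf("only %d events but k = %d; use a smaller k",
                 nrow(features), k))
  x <- if (standardize) standardize_features(features)$x else features
  n_distinct <- nrow(unique(x))
  rmse <- setNames(numeric(length(k_range)), paste0("k", k_range))
  fit <- NULL
  for (i in seq_along(k_range)) {
    kk <- k_range[i]
    if (n_distinct < kk) {
      rmse[i] <- NA_real_
      next
    }
    f <- with_seed(derive_seed(seed, paste0("kmeans", kk)),
                   kmeans(x, centers = kk, nstart = 25, iter.max = 50))
    rmse[i] <- sqrt(f$tot.withinss / nrow(x))
    if (kk == k) fit <- f
  }
  if (is.null(fit))
    fit <- with_seed(derive_seed(seed, paste0("kmeans", k)),
                     kmeans(x, centers = k, nstart = 25, iter.max = 50))
  assignments <- setNames(fit$cluster, rownames(features))
  list(assignments = assignments, centroids = fit$centers,
       rmse_by_k = rmse, k = k, seed = seed)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Find mirror-pattern cluster pairs
#'
#' A gain cluster and a loss cluster form a mirror pair when their
#' centroids point in opposite directions (cosine similarity at most
#' `cos_threshold`) and share the same dominant feature (largest absolute
#' centroid coordinate). Pairs are matched greedily by most-negative
#' cosine, each cluster used at most once.
#'
#' @param gain_centroids,loss_centroids centroid matrices (clusters x
#'   features, shared feature columns).
#' @param cos_threshold mirror threshold (default -0.8).
#' @param feature_scale optional named vector of per-feature spreads (sd
#'   of each delta-HM column over the clustered events). When supplied, a
#'   cluster only qualifies for pairing if its dominant coordinate has
#'   magnitude at least `min_magnitude` times that feature's spread:
#'   cosine similarity is scale-invariant, so without this gate two large
#'   null clusters with tiny antiparallel centroids would register as a
#'   "mirror" despite showing no pattern.
#' @param min_magnitude dominant-coordinate threshold in feature-spread
#'   units (default 0.5; only used with `feature_scale`).
#' @return data.frame with `gain_cluster`, `loss_cluster`, `hm`
#'   (dominant feature), `cosine`; zero rows if nothing pairs.
#' @export
find_mirror_pairs <- function(gain_centroids, loss_centroids,
                              cos_threshold = -0.8, feature_scale = NULL,
                              min_magnitude = 0.5) {
  stopifnot(identical(colnames(gain_centroids), colnames(loss_centroids)))
  ng <- nrow(gain_centroids); nl <- nrow(loss_centroids)
  cand <- expand.grid(g = seq_len(ng), l = seq_len(nl))
  cand$cosine <- mapply(function(g, l)
    cosine_sim(gain_centroids[g, ], loss_centroids[l, ]),
    cand$g, cand$l)
  dom_g <- colnames(gain_centroids)[apply(abs(gain_centroids), 1, which.max)]
  dom_l <- colnames(loss_centroids)[apply(abs(loss_centroids), 1, which.max)]
  ok_mag_g <- rep(TRUE, ng); ok_mag_l <- rep(TRUE, nl)
  if (!is.null(feature_scale)) {
    thr <- min_magnitude * feature_scale
    ok_mag_g <- apply(abs(gain_centroids), 1, max) >= thr[dom_g]
    ok_mag_l <- apply(abs(loss_centroids), 1, max) >= thr[dom_l]
  }
  cand <- cand[cand$cosine <= cos_threshold &
                 dom_g[cand$g] == dom_l[cand$l] &
                 ok_mag_g[cand$g] & ok_mag_l[cand$l], , drop = FALSE]
  cand <- cand[order(cand$cosine), , drop = FALSE]
  used_g <- logical(ng); used_l <- logical(nl)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_g[cand$g[i]] && !used_l[cand$l[i]]) {
      keep[i] <- TRUE
      used_g[cand$g[i]] <- TRUE
      used_l[cand$l[i]] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    message("find_mirror_pairs: no centroid pair below the mirror threshold")
    return(data.frame(gain_cluster = integer(), loss_cluster = integer(),
                      hm = character(), cosine = double()))
  }
  data.frame(gain_cluster = out$g, loss_cluster = out$l,
             hm = dom_g[out$g], cosine = out$cosine,
             stringsAsFactors = FALSE)
}

#' Build HM-associated AS subsets from mirror pairs
#'
#' Each mirror pair contributes the union of its gain and loss cluster;
#' pairs describing the same association (same dominant HM and the same
#' sign of the pair-level correlation) are merged into one subset. The
#' merged subset is tested for within-subset Pearson correlation between
#' delta PSI and the dominant HM's delta HM; its sign is the sign of that
#' correlation. Subsets whose correlation fails `alpha` are dropped with a
#' warning. The coverage fraction (members over all significant events in
#' the universe) is attached as an attribute.
#'
#' @param pairs output of [find_mirror_pairs()].
#' @param gain_assign,loss_assign named assignment vectors from
#'   [cluster_directions()] (names = event keys).
#' @param delta_psi named numeric vector over all event keys.
#' @param delta_hm numeric matrix (event keys x HM) of raw delta-HM values.
#' @param alpha significance needed to keep a subset (default 0.05).
#' @param event_of optional named character vector mapping clustering keys
#'   (e.g. `event|lineage` instances) to event ids; member sets and the
#'   coverage fraction are reported at event level. Defaults to the keys
#'   themselves.
#' @param n_universe number of significant AS events the coverage
#'   fraction is relative to (default: all distinct events among the
#'   clustered keys).
#' @return data.frame with one row per member key: `subset_id`, `hm`,
#'   `sign`, `event_key`, `event_id`, plus per-subset columns `r` and
#'   `p_value`; attribute `coverage_fraction`.
#' @export
build_subsets <- function(pairs, gain_assign, loss_assign, delta_psi,
                          delta_hm, alpha = 0.05, event_of = NULL,
                          n_universe = NULL) {
  keys_all <- c(names(gain_assign), names(loss_assign))
  if (is.null(event_of))
    event_of <- setNames(keys_all, keys_all)
  if (is.null(n_universe))
    n_universe <- length(unique(event_of[keys_all]))
  empty <- data.frame(subset_id = character(), hm = character(),
                      sign = character(), event_key = character(),
                      event_id = character(), r = double(),
                      p_value = double())
  if (nrow(pairs) == 0L) {
    attr(empty, "coverage_fraction") <- 0
    return(empty)
  }
  # pair-level members and association sign, then merge pairs that
  # describe the same association (same dominant HM, same sign) into one
  # subset before the within-subset correlation is assessed
  pair_members <- vector("list", nrow(pairs))
  pair_sign <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    members <- c(names(gain_assign)[gain_assign == pairs$gain_cluster[i]],
                 names(loss_assign)[loss_assign == pairs$loss_cluster[i]])
    pair_members[[i]] <- members
    r_i <- suppressWarnings(cor(delta_psi[members],
                                delta_hm[members, pairs$hm[i]]))
    pair_sign[i] <- if (!is.na(r_i) && r_i >= 0) "+" else "-"
  }
  groups <- split(seq_len(nrow(pairs)), paste0(pairs$hm, pair_sign))
  subsets <- vector("list", length(groups))
  gi <- 0L
  for (grp in groups) {
    gi <- gi + 1L
    hm <- pairs$hm[grp[1L]]
    sgn <- pair_sign[grp[1L]]
    members <- unique(unlist(pair_members[grp]))
    if (length(members) < 3L) {
      warning(sprintf("subset %s%s dropped: only %d member(s)",
                      hm, sgn, length(members)))
      next
    }
    ct <- cor.test(delta_psi[members], delta_hm[members, hm])
    if (is.na(ct$p.value) || ct$p.value > alpha) {
      warning(sprintf(
        "subset %s%s dropped: within-subset r = %.3f, p = %.3g",
        hm, sgn, ct$estimate, ct$p.value))
      next
    }
    subsets[[gi]] <- data.frame(
      subset_id = paste0(hm, sgn),
      hm = hm, sign = sgn, event_key = members,
      event_id = unname(event_of[members]),
      r = unname(ct$estimate), p_value = ct$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, subsets[!vapply(subsets, is.null, logical(1))])
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  attr(out, "coverage_fraction") <-
    length(unique(out$event_id)) / n_universe
  out
}

#' Run the full association stage for one AS type
#'
#' Convenience wrapper: screens, feature selection, per-direction k-means
#' (standardized with pooled statistics), mirror pairing and subset
#' construction.
#'
#' @param delta_psi named numeric vector of delta PSI per event key.
#' @param delta_hm numeric matrix (event keys x HM).
#' @param k,seed,alpha,cos_threshold stage parameters.
#' @param dpsi threshold separating gain (`< -dpsi`) from loss
#'   (`> dpsi`); observations in between are excluded from clustering.
#' @param standardize cluster on per-HM standardized features instead of
#'   raw delta HM (default `FALSE`: the delta-HM scale carries the
#'   association signal, and variance-equalizing mostly-unregulated marks
#'   promotes spurious mirror pairs; see the methods vignette).
#' @return list with `screens`, `selected`, `gain`, `loss` (cluster
#'   results), `pairs`, `subsets`, `coverage_fraction`.
#' @export
associate_hm_as <- function(delta_psi, delta_hm, k = 6L, seed,
                            alpha = 0.05, cos_threshold = -0.8,
                            dpsi = 0.1, standardize = FALSE) {
  stopifnot(!missing(seed))
  screens <- rbind(pearson_screen(delta_psi, delta_hm, alpha),
                   mlr_screen(delta_psi, delta_hm, alpha),
                   llr_screen(delta_psi, delta_hm, alpha)[,
                     c("hm", "test", "statistic", "p_value", "selected")])
  selected <- select_features(screens)
  if (length(selected) == 0L) {
    return(list(screens = screens, selected = selected, gain = NULL,
                loss = NULL,
                pairs = data.frame(), subsets = data.frame(),
                coverage_fraction = 0))
  }
  feats <- delta_hm[, selected, drop = FALSE]
  gain_keys <- names(delta_psi)[delta_psi < -dpsi]
  loss_keys <- names(delta_psi)[delta_psi > dpsi]
  if (standardize) {
    std <- standardize_features(feats[c(gain_keys, loss_keys), ,
                                      drop = FALSE])
    zg <- standardize_features(feats[gain_keys, , drop = FALSE],
                               std$center, std$scale)$x
    zl <- standardize_features(feats[loss_keys, , drop = FALSE],
                               std$center, std$scale)$x
  } else {
    zg <- feats[gain_keys, , drop = FALSE]
    zl <- feats[loss_keys, , drop = FALSE]
  }
  gain <- cluster_directions(zg, k = k, seed = derive_seed(seed, "gain"),
                             standardize = FALSE)
  loss <- cluster_directions(zl, k = k, seed = derive_seed(seed, "loss"),
                             standardize = FALSE)
  fsc <- apply(feats[c(gain_keys, loss_keys), , drop = FALSE], 2, sd)
  if (standardize) fsc <- fsc / std$scale
  pairs <- find_mirror_pairs(gain$centroids, loss$centroids, cos_threshold,
                             feature_scale = fsc)
  keys_all <- c(gain_keys, loss_keys)
  event_of <- setNames(sub("\\|.*$", "", keys_all), keys_all)
  subsets <- build_subsets(pairs, gain$assignments, loss$assignments,
                           delta_psi, delta_hm, alpha,
                           event_of = event_of)
  list(screens = screens, selected = selected, gain = gain, loss = loss,
       pairs = pairs, subsets = subsets,
       coverage_fraction = attr(subsets, "coverage_fraction"))
}
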