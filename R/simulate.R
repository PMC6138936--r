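## synthetic_data: seeded generator for annotations, junction counts,
## HM peak/coverage evidence, expression tables and the ground-truth
## ledger with planted HM-AS associations.
##
## The planting model is linear-Gaussian on the distance-normalized peak
## scale: for a planted (hm, sign) subset, delta_hm = sign * beta *
## delta_psi + N(0, noise_sd), with beta solved so the within-subset
## Pearson correlation hits the configured target r given the realized
## spread of the members' true delta PSI.

#' The sixteen profiled histone marks
#'
#' Nine histone acetylation and seven histone methylation marks measured
#' in all six cell types.
#'
#' @return character vector of length 16.
#' @export
default_hm_names <- function() {
  c("H2AK5ac", "H2BK120ac", "H2BK5ac", "H3K18ac", "H3K23ac", "H3K27ac",
    "H3K4ac", "H3K9ac", "H4K8ac",
    "H3K27me3", "H3K36me3", "H3K4me1", "H3K4me2", "H3K4me3", "H3K79me1",
    "H3K9me3")
}

#' Default planted HM-associated subsets
#'
#' Three subsets per AS type mirroring the observed association structure:
#' for SE exons H3K36me3 in both orientations plus a small negative H4K8ac
#' subset; for MXE exons H3K36me3 in both orientations plus a small
#' positive H3K27ac subset. Fractions are of differential AS events.
#'
#' @return data.frame with `as_type`, `hm`, `sign`, `fraction`,
#'   `target_r`.
#' @export
default_planted_subsets <- function() {
  data.frame(
    as_type = c("SE", "SE", "SE", "MXE", "MXE", "MXE"),
    hm = c("H3K36me3", "H3K36me3", "H4K8ac",
           "H3K36me3", "H3K36me3", "H3K27ac"),
    sign = c("+", "-", "-", "+", "-", "+"),
    fraction = c(0.28, 0.18, 0.05, 0.26, 0.22, 0.05),
    target_r = 0.6,
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every generator parameter with the defaults that define the
#' simulated study: a stem-like reference cell, five differentiated
#' lineages with two replicates each, 16 histone marks, three planted
#' HM-associated subsets per AS type at target |r| = 0.6, and binomial
#' junction counts around true PSI at mean junction coverage 100.
#'
#' @param n_genes number of genes (default 5000; with the default event
#'   fractions this hosts 2000 SE and 1500 MXE events).
#' @param exons_per_gene inclusive range of exon counts per gene.
#' @param lineages differentiated cell labels.
#' @param ref_cell reference cell label.
#' @param n_replicates junction-count replicates per cell.
#' @param hm_names histone marks (16 by default).
#' @param se_gene_fraction,mxe_gene_fraction fraction of genes hosting an
#'   SE event / an MXE event pair.
#' @param diff_prob probability that an event is truly differential in a
#'   given lineage.
#' @param se_loss_prob,mxe_gain_prob direction bias of differential SE /
#'   MXE(upstream) events.
#' @param planted_subsets data.frame as [default_planted_subsets()].
#' @param junction_coverage mean junction reads per event, cell and
#'   replicate.
#' @param noise_sd residual sd of delta HM around the planted line for
#'   subset members (normalized-signal units).
#' @param null_noise_sd sd of delta HM for unregulated event x HM pairs
#'   (peak heights of an unregulated exon are strongly correlated between
#'   cell types, so their difference is small relative to the regulated
#'   response).
#' @param deg_fraction fraction of differentially expressed genes.
#' @param expr_noise_sd lognormal sd of replicate expression noise.
#' @param intron_mean,as_intron_mean mean intron length (background /
#'   flanking an AS exon), bp.
#' @param with_coverage generate per-base coverage tracks (needed only for
#'   splice-site profiling; off by default).
#' @param cov_depth baseline coverage, reads per bp in the reference
#'   library.
#' @param profile_shift fractional coverage loss at AS exon bodies in the
#'   differentiated cells for `profile_hms` (0 disables planting).
#' @param profile_hms marks carrying the planted exonic coverage shift.
#' @param profile_lineages lineages carrying the shift (default all).
#' @param lib_size_ref,lib_size_alt library sizes (total mapped reads).
#' @param peak_absent_prob probability that an unplanted event x HM pair
#'   has no called peak in any cell (the set-to-zero case).
#' @param seed master seed; every stage seed derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000L,
                       exons_per_gene = c(5L, 15L),
                       lineages = c("ME", "TBL", "MSC", "NPC", "IMR90"),
                       ref_cell = "H1",
                       n_replicates = 2L,
                       hm_names = default_hm_names(),
                       se_gene_fraction = 0.4,
                       mxe_gene_fraction = 0.3,
                       diff_prob = 0.35,
                       se_loss_prob = 0.65,
                       mxe_gain_prob = 0.65,
                       planted_subsets = default_planted_subsets(),
                       junction_coverage = 100,
                       noise_sd = 1,
                       null_noise_sd = 0.3,
                       deg_fraction = 0.2,
                       expr_noise_sd = 0.1,
                       intron_mean = 1500,
                       as_intron_mean = 3500,
                       with_coverage = FALSE,
                       cov_depth = 2,
                       profile_shift = 0.5,
                       profile_hms = c("H3K36me3", "H3K79me1"),
                       profile_lineages = NULL,
                       lib_size_ref = 30e6,
                       lib_size_alt = 20e6,
                       peak_absent_prob = 0.3,
                       seed = 1L) {
  if (n_genes <= 0) stop("n_genes must be positive")
  if (se_gene_fraction + mxe_gene_fraction > 1)
    stop("event gene fractions must sum to at most 1")
  if (!is.null(planted_subsets) && nrow(planted_subsets) > 0L) {
    if (!all(planted_subsets$hm %in% hm_names))
      stop("planted subset references an unknown HM")
    if (!all(abs(planted_subsets$target_r) <= 1))
      stop("|target_r| must be at most 1")
    fr <- tapply(planted_subsets$fraction, planted_subsets$as_type, sum)
    if (any(fr > 1)) stop("planted subset fractions sum above 1")
  }
  if (is.null(profile_lineages)) profile_lineages <- lineages
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              lineages = lineages, ref_cell = ref_cell,
              n_replicates = as.integer(n_replicates),
              hm_names = hm_names,
              se_gene_fraction = se_gene_fraction,
              mxe_gene_fraction = mxe_gene_fraction,
              diff_prob = diff_prob, se_loss_prob = se_loss_prob,
              mxe_gain_prob = mxe_gain_prob,
              planted_subsets = planted_subsets,
              junction_coverage = junction_coverage,
              noise_sd = noise_sd, null_noise_sd = null_noise_sd,
              deg_fraction = deg_fraction,
              expr_noise_sd = expr_noise_sd,
              intron_mean = intron_mean, as_intron_mean = as_intron_mean,
              with_coverage = with_coverage, cov_depth = cov_depth,
              profile_shift = profile_shift, profile_hms = profile_hms,
              profile_lineages = profile_lineages,
              lib_size_ref = lib_size_ref, lib_size_alt = lib_size_alt,
              peak_absent_prob = peak_absent_prob,
              seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

# exon length draws; AS exons shorter and more often frame-preserving
draw_exon_len <- function(n, as_exon) {
  mu <- ifelse(as_exon, log(110), log(170))
  len <- pmax(30L, as.integer(round(exp(rnorm(n, mu, 0.3)))))
  keep_frame <- as_exon & runif(n) < 0.5
  len[keep_frame] <- pmax(30L, len[keep_frame] - len[keep_frame] %% 3L)
  len
}

#' Generate the synthetic exon annotation
#'
#' Lays genes along one synthetic chromosome. A configured fraction of
#' genes hosts an SE event (one internal AS exon) or an MXE event (two
#' adjacent internal AS exons). AS exons are drawn shorter than
#' constitutive exons and their flanking introns longer, and AS exon
#' lengths are enriched for multiples of three. First/last exons have role
#' `other`, internal non-AS exons role `CS`.
#'
#' @param config a [sim_config()].
#' @return data.frame of exons: `gene_id`, `exon_id`, `exon_index`
#'   (transcript order), `chrom`, `start`, `end`, `strand`, `role`,
#'   `intron_up_len`, `intron_down_len`, `event_type`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "annotation"), {
    ng <- config$n_genes
    n_se <- round(ng * config$se_gene_fraction)
    n_mxe <- round(ng * config$mxe_gene_fraction)
    kind <- sample(c(rep("SE", n_se), rep("MXE", n_mxe),
                     rep("none", ng - n_se - n_mxe)))
    ex_range <- seq(config$exons_per_gene[1L], config$exons_per_gene[2L])
    n_ex <- ex_range[sample.int(length(ex_range), ng, replace = TRUE)]
    n_ex[kind == "MXE" & n_ex < 5L] <- 5L # room for an internal pair
    n_ex[kind == "SE" & n_ex < 3L] <- 3L
    strand <- sample(c("+", "-"), ng, replace = TRUE)

    out <- vector("list", ng)
    cursor <- 10000L
    for (g in seq_len(ng)) {
      n <- n_ex[g]
      # transcript-internal AS indices
      as_tidx <- integer(0)
      if (kind[g] == "SE") as_tidx <- sample(2:(n - 1L), 1L)
      if (kind[g] == "MXE") {
        i <- if (n >= 6L) sample(2:(n - 3L), 1L) else 2L
        as_tidx <- c(i, i + 1L)
      }
      tidx <- if (strand[g] == "+") seq_len(n) else rev(seq_len(n))
      as_gidx <- which(tidx %in% as_tidx)
      is_as <- seq_len(n) %in% as_gidx
      len <- draw_exon_len(n, is_as)
      # intron j sits between genomic exons j and j+1; longer next to AS
      near_as <- is_as[-n] | is_as[-1L]
      imu <- ifelse(near_as, log(config$as_intron_mean),
                    log(config$intron_mean))
      ilen <- pmax(100L, as.integer(round(exp(rnorm(n - 1L, imu, 0.4)))))
      starts <- cursor + cumsum(c(0L, len[-n] + ilen))
      ends <- starts + len
      role <- ifelse(is_as, "AS",
                     ifelse(tidx == 1L | tidx == n, "other", "CS"))
      out[[g]] <- data.frame(
        gene_id = sprintf("G%05d", g),
        exon_id = sprintf("G%05d.E%02d", g, tidx),
        exon_index = tidx,
        chrom = "chr1", start = starts, end = ends, strand = strand[g],
        role = role,
        intron_up_len = if (strand[g] == "+") c(NA_integer_, ilen)
                        else c(ilen, NA_integer_),
        intron_down_len = if (strand[g] == "+") c(ilen, NA_integer_)
                          else c(NA_integer_, ilen),
        event_type = kind[g],
        stringsAsFactors = FALSE)
      cursor <- ends[n] + 5000L
    }
    ann <- do.call(rbind, out)
    rownames(ann) <- NULL
    ann
  })
}

# Build the event table from an annotation: SE events use the single AS
# exon; MXE events the transcript-upstream AS exon of the adjacent pair
# (downstream exon coordinates are retained for counts and checks).
events_from_annotation <- function(annotation) {
  as_ex <- annotation[annotation$role == "AS", , drop = FALSE]
  as_ex <- as_ex[order(as_ex$gene_id, as_ex$exon_index), , drop = FALSE]
  out <- vector("list", length(unique(as_ex$gene_id)))
  i <- 0L
  for (g in unique(as_ex$gene_id)) {
    e <- as_ex[as_ex$gene_id == g, , drop = FALSE]
    i <- i + 1L
    if (nrow(e) == 1L) {
      out[[i]] <- data.frame(
        event_id = paste0("SE.", g), type = "SE", gene_id = g,
        chrom = e$chrom, start = e$start, end = e$end,
        strand = e$strand, exon_id = e$exon_id,
        intron_up_len = e$intron_up_len,
        intron_down_len = e$intron_down_len,
        down_start = NA_integer_, down_end = NA_integer_,
        stringsAsFactors = FALSE)
    } else {
      up <- e[1L, ]; dn <- e[2L, ] # sorted by transcript index
      out[[i]] <- data.frame(
        event_id = paste0("MXE.", g), type = "MXE", gene_id = g,
        chrom = up$chrom, start = up$start, end = up$end,
        strand = up$strand, exon_id = up$exon_id,
        intron_up_len = up$intron_up_len,
        intron_down_len = up$intron_down_len,
        down_start = dn$start, down_end = dn$end,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate the ground truth ledger
#'
#' Draws true PSI values per event and lineage (reference PSI uniform in
#' [0.25, 0.75]; differential lineages shift by 0.15-0.55 with the
#' type-specific direction bias), then assigns planted-subset memberships
#' among differential events and solves each subset's planting slope beta
#' for its target correlation.
#'
#' @param annotation output of [generate_annotation()].
#' @param config the [sim_config()].
#' @return list of class `sim_truth`: `events`, `psi_ref`, `psi_alt`
#'   (events x lineages), `delta_psi`, `direction`, `membership`
#'   (event_id, hm, sign, subset, beta), `subset_params`.
#' @export
generate_truth <- function(annotation, config) {
  events <- events_from_annotation(annotation)
  nl <- length(config$lineages)
  ne <- nrow(events)
  with_seed(derive_seed(config$seed, "truth"), {
    psi_ref <- runif(ne, 0.25, 0.75)
    is_diff <- matrix(runif(ne * nl) < config$diff_prob, ne, nl)
    loss_prob <- ifelse(events$type == "SE",
                        config$se_loss_prob, 1 - config$mxe_gain_prob)
    is_loss <- matrix(runif(ne * nl) < loss_prob, ne, nl)
    mag <- matrix(runif(ne * nl, 0.15, 0.55), ne, nl)
    psi_alt <- matrix(psi_ref, ne, nl)
    # loss: differentiated cell loses inclusion (delta = ref - alt > 0)
    psi_alt[is_diff & is_loss] <- psi_ref[row(psi_alt)[is_diff & is_loss]] -
      mag[is_diff & is_loss]
    psi_alt[is_diff & !is_loss] <- psi_ref[row(psi_alt)[is_diff & !is_loss]] +
      mag[is_diff & !is_loss]
    psi_alt <- pmin(pmax(psi_alt, 0.02), 0.98)
    delta <- psi_ref - psi_alt
    direction <- matrix("none", ne, nl)
    direction[is_diff & delta > 0.1] <- "loss"
    direction[is_diff & delta < -0.1] <- "gain"
    dimnames(psi_alt) <- dimnames(delta) <- dimnames(direction) <-
      list(events$event_id, config$lineages)

    # planted memberships among differential events, per AS type
    membership <- NULL
    subset_params <- NULL
    ps <- config$planted_subsets
    if (!is.null(ps) && nrow(ps) > 0L) {
      mem_list <- list(); par_list <- list()
      for (ty in unique(ps$as_type)) {
        sel <- which(events$type == ty & rowSums(direction != "none") > 0L)
        sel <- sel[sample.int(length(sel))] # shuffle before carving
        pool_start <- 1L
        pss <- ps[ps$as_type == ty, , drop = FALSE]
        for (i in seq_len(nrow(pss))) {
          n_mem <- round(pss$fraction[i] * length(sel))
          if (n_mem == 0L) next
          mem <- sel[pool_start:(pool_start + n_mem - 1L)]
          pool_start <- pool_start + n_mem
          dsub <- delta[mem, , drop = FALSE]
          inst <- dsub[direction[mem, , drop = FALSE] != "none"]
          sd_d <- sd(inst)
          if (length(inst) < 2L || is.na(sd_d) || sd_d == 0) {
            message(sprintf(
              "subset %s.%s%s skipped: too few differential instances",
              ty, pss$hm[i], pss$sign[i]))
            next
          }
          r <- abs(pss$target_r[i])
          if (config$noise_sd == 0 && r < 1) {
            stop(sprintf(
              paste("target r = %.2f unreachable with noise_sd = 0",
                    "(noiseless planting forces |r| = 1); required beta",
                    "would need positive noise_sd"), pss$target_r[i]))
          }
          beta <- if (config$noise_sd == 0) 1 else
            config$noise_sd * r / (sd_d * sqrt(1 - r^2))
          sid <- sprintf("%s.%s%s", ty, pss$hm[i], pss$sign[i])
          mem_list[[sid]] <- data.frame(
            event_id = events$event_id[mem], hm = pss$hm[i],
            sign = pss$sign[i], subset = sid, beta = beta,
            stringsAsFactors = FALSE)
          par_list[[sid]] <- data.frame(
            subset = sid, as_type = ty, hm = pss$hm[i],
            sign = pss$sign[i], target_r = pss$target_r[i],
            fraction = pss$fraction[i], beta = beta,
            n_members = n_mem, stringsAsFactors = FALSE)
        }
      }
      membership <- do.call(rbind, mem_list)
      subset_params <- do.call(rbind, par_list)
      rownames(membership) <- rownames(subset_params) <- NULL
    }
    structure(list(events = events, psi_ref = psi_ref, psi_alt = psi_alt,
                   delta_psi = delta, direction = direction,
                   membership = membership, subset_params = subset_params,
                   lineages = config$lineages),
              class = "sim_truth")
  })
}

#' Generate junction counts
#'
#' For every event, cell and replicate: total junction reads
#' `n ~ Poisson(junction_coverage)`, inclusion reads
#' `I ~ Binomial(n, psi*)` where `psi*` is the true PSI adjusted for the
#' effective-length weighting (SE events use len_I = 2, len_S = 1; MXE
#' events unit lengths), and `S = n - I`. The two exons of an MXE event
#' share `n`, so their estimated PSIs sum to exactly 1; downstream-exon
#' rows carry `event_id` suffixed `:down`.
#'
#' @param truth a `sim_truth`.
#' @param config the [sim_config()].
#' @return counts data.frame: `event_id`, `type`, `gene_id`, `cell`,
#'   `replicate`, `I`, `S`, `len_I`, `len_S`, `exon`
#'   (`target`/`mxe_down`).
#' @export
generate_junction_counts <- function(truth, config) {
  ev <- truth$events
  cells <- c(config$ref_cell, config$lineages)
  psi_by_cell <- cbind(truth$psi_ref, truth$psi_alt)
  colnames(psi_by_cell) <- cells
  with_seed(derive_seed(config$seed, "junctions"), {
    rows <- list()
    for (cell in cells) for (rep_i in seq_len(config$n_replicates)) {
      psi <- psi_by_cell[, cell]
      n <- rpois(nrow(ev), config$junction_coverage)
      len_I <- ifelse(ev$type == "SE", 2, 1)
      len_S <- 1
      p_incl <- psi * len_I / (psi * len_I + (1 - psi) * len_S)
      I <- rbinom(nrow(ev), n, p_incl)
      S <- n - I
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = ev$event_id, type = ev$type, gene_id = ev$gene_id,
        cell = cell, replicate = rep_i, I = I, S = S,
        len_I = len_I, len_S = len_S, exon = "target",
        stringsAsFactors = FALSE)
      mxe <- ev$type == "MXE"
      if (any(mxe)) {
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = paste0(ev$event_id[mxe], ":down"), type = "MXE",
          gene_id = ev$gene_id[mxe], cell = cell, replicate = rep_i,
          I = S[mxe], S = I[mxe], len_I = 1, len_S = 1,
          exon = "mxe_down", stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate HM peak and coverage evidence
#'
#' Plants the configured subset structure at peak level (exactly: the
#' distance-normalized differential signal of a member event equals
#' `sign * beta * delta_psi + noise`) and, when `with_coverage` is on,
#' a coherent exon-body coverage loss in the differentiated cells for
#' `profile_hms`. Unplanted event x HM pairs have, with probability
#' `peak_absent_prob`, no called peak in any cell.
#'
#' @param truth a `sim_truth`.
#' @param annotation the annotation the truth was built from.
#' @param config the [sim_config()].
#' @return list with `peaks` (long data.frame: `hm`, `cell`, `chrom`,
#'   `start`, `end`, `summit_offset`, `signal`, `name`), `tracks`
#'   (nested list `tracks[[hm]][[cell]]` of `coverage_track`, or `NULL`),
#'   and `realized_r` (per-subset empirical correlation over planted
#'   member instances, logged for the generation-time check).
#' @export
generate_hm_evidence <- function(truth, annotation, config) {
  ev <- truth$events
  ne <- nrow(ev)
  nl <- length(config$lineages)
  hms <- config$hm_names
  with_seed(derive_seed(config$seed, "hm_evidence"), {
    exon_len <- ev$end - ev$start
    d_summit <- floor(runif(ne, 0, pmin(300, exon_len)))
    dist_kb <- pmax(d_summit, 100) / 1000
    ss3 <- ss3_position(ev$start, ev$end, ev$strand)
    summit_pos <- ifelse(ev$strand == "+", ss3 + d_summit, ss3 - d_summit)
    pk_start <- ev$start - 50L
    pk_end <- ev$end + 50L

    planted_pair <- matrix(FALSE, ne, length(hms),
                           dimnames = list(ev$event_id, hms))
    delta_norm <- array(rnorm(ne * length(hms) * nl, 0,
                              config$null_noise_sd),
                        dim = c(ne, length(hms), nl),
                        dimnames = list(ev$event_id, hms, config$lineages))
    realized <- list()
    if (!is.null(truth$membership)) {
      for (sid in unique(truth$membership$subset)) {
        m <- truth$membership[truth$membership$subset == sid, ]
        ridx <- match(m$event_id, ev$event_id)
        hm <- m$hm[1L]
        sgn <- if (m$sign[1L] == "+") 1 else -1
        planted <- sgn * m$beta[1L] * truth$delta_psi[ridx, , drop = FALSE]
        delta_norm[ridx, hm, ] <- planted +
          rnorm(length(planted), 0, config$noise_sd)
        planted_pair[ridx, hm] <- TRUE
        inst <- truth$direction[ridx, , drop = FALSE] != "none"
        realized[[sid]] <- data.frame(
          subset = sid,
          realized_r = cor(truth$delta_psi[ridx, ][inst],
                           delta_norm[ridx, hm, ][inst]),
          n_instances = sum(inst))
      }
    }

    zero_pair <- matrix(runif(ne * length(hms)) < config$peak_absent_prob,
                        ne, length(hms)) & !planted_pair

    peak_rows <- list()
    for (h in seq_along(hms)) {
      raw_delta <- delta_norm[, h, , drop = FALSE]
      dim(raw_delta) <- c(ne, nl)
      raw_delta <- raw_delta * dist_kb
      base <- 2 + rexp(ne, 0.5)
      sig_ref <- base + pmax(0, apply(raw_delta, 1, max))
      keep <- !zero_pair[, h]
      mk <- function(cell, sig) data.frame(
        hm = hms[h], cell = cell, chrom = ev$chrom[keep],
        start = pk_start[keep], end = pk_end[keep],
        summit_offset = summit_pos[keep] - pk_start[keep],
        signal = sig[keep],
        name = paste0(hms[h], ".", cell, ".", ev$event_id[keep]),
        stringsAsFactors = FALSE)
      peak_rows[[length(peak_rows) + 1L]] <- mk(config$ref_cell, sig_ref)
      for (l in seq_len(nl)) {
        peak_rows[[length(peak_rows) + 1L]] <-
          mk(config$lineages[l], sig_ref - raw_delta[, l])
      }
    }
    peaks <- do.call(rbind, peak_rows)
    rownames(peaks) <- NULL

    tracks <- NULL
    if (isTRUE(config$with_coverage))
      tracks <- generate_coverage_tracks(truth, annotation, config)

    list(peaks = peaks, tracks = tracks,
         realized_r = if (length(realized) > 0L)
           do.call(rbind, realized) else NULL)
  })
}

# Coverage tracks at 15-bp resolution over the splice-site neighbourhoods
# of AS-gene exons. Reference library carries baseline depth; for
# profile_hms the differentiated cells lose a profile_shift fraction of
# coverage over AS exon bodies in profile_lineages.
generate_coverage_tracks <- function(truth, annotation, config) {
  as_genes <- unique(truth$events$gene_id)
  exons <- annotation[annotation$gene_id %in% as_genes, , drop = FALSE]
  # min.gapwidth 30 keeps reduced windows further apart than the 14-bp
  # lattice overshoot, so emitted bins never overlap
  win <- reduce(IRanges(pmax(0L, exons$start - 165L) + 1L,
                        exons$end + 165L), min.gapwidth = 30L)
  # snap to a 15-bp lattice
  bin_start <- unlist(lapply(seq_along(win), function(i) {
    seq(start(win)[i] - 1L, end(win)[i] - 1L, by = 15L)
  }))
  bin_end <- bin_start + 15L
  nb <- length(bin_start)
  # fraction of each bin lying inside an AS exon body
  as_ex <- exons[exons$role == "AS", , drop = FALSE]
  ov <- findOverlaps(IRanges(bin_start + 1L, bin_end),
                     IRanges(as_ex$start + 1L, as_ex$end))
  as_frac <- numeric(nb)
  if (length(ov) > 0L) {
    bs <- bin_start[queryHits(ov)]; be <- bin_end[queryHits(ov)]
    es <- as_ex$start[subjectHits(ov)]; ee <- as_ex$end[subjectHits(ov)]
    olap <- pmin(be, ee) - pmax(bs, es)
    as_frac[queryHits(ov)] <- pmin(1, olap / 15)
  }

  lib <- c(config$lib_size_ref,
           rep(config$lib_size_alt, length(config$lineages)))
  names(lib) <- c(config$ref_cell, config$lineages)
  lam_base <- config$cov_depth * 15
  tracks <- list()
  for (hm in config$hm_names) {
    tracks[[hm]] <- list()
    shift_hm <- hm %in% config$profile_hms && config$profile_shift > 0
    for (cell in names(lib)) {
      lam <- lam_base * lib[[cell]] / config$lib_size_ref
      if (shift_hm && cell %in% config$profile_lineages) {
        lam <- lam * (1 - config$profile_shift * as_frac)
      }
      counts <- rpois(nb, lam)
      tracks[[hm]][[cell]] <- coverage_track(
        data.frame(chrom = "chr1", start = bin_start, end = bin_end,
                   value = counts / 15),
        library_size = lib[[cell]])
    }
  }
  tracks
}

#' Generate the expression table
#'
#' Log-normal gene FPKM with a planted fraction of differentially
#' expressed genes (fold change 2.5-6, in at least one lineage); AS-hosting
#' genes are down-weighted when sampling DEGs.
#'
#' @param truth a `sim_truth`.
#' @param annotation the matching annotation.
#' @param config the [sim_config()].
#' @return list with `expr` (long data.frame `gene_id`, `cell`, `fpkm`)
#'   and `genes` (`gene_id`, `as_host`, `deg`).
#' @export
generate_expression <- function(truth, annotation, config) {
  genes <- unique(annotation$gene_id)
  as_host <- genes %in% truth$events$gene_id
  with_seed(derive_seed(config$seed, "expression"), {
    n_deg <- round(config$deg_fraction * length(genes))
    w <- ifelse(as_host, 0.25, 1)
    deg <- rep(FALSE, length(genes))
    if (n_deg > 0L)
      deg[sample(seq_along(genes), n_deg, prob = w)] <- TRUE
    base <- rlnorm(length(genes), log(10), 1)
    cells <- c(config$ref_cell, config$lineages)
    fold <- matrix(1, length(genes), length(cells),
                   dimnames = list(genes, cells))
    if (any(deg)) {
      for (gi in which(deg)) {
        up <- sample(c(TRUE, FALSE), 1L)
        f <- runif(1, 2.5, 6)
        in_lin <- runif(length(config$lineages)) < 0.6
        if (!any(in_lin)) in_lin[sample(length(config$lineages), 1L)] <- TRUE
        fold[gi, config$lineages[in_lin]] <- if (up) f else 1 / f
      }
    }
    noise <- matrix(rlnorm(length(genes) * length(cells), 0,
                           config$expr_noise_sd),
                    length(genes), length(cells))
    fpkm <- base * fold * noise
    expr <- data.frame(
      gene_id = rep(genes, times = length(cells)),
      cell = rep(cells, each = length(genes)),
      fpkm = as.vector(fpkm),
      stringsAsFactors = FALSE)
    list(expr = expr,
         genes = data.frame(gene_id = genes, as_host = as_host, deg = deg,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a complete dataset
#'
#' Runs annotation, truth, junction-count, HM-evidence and expression
#' generation under one master seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with elements `config`,
#'   `annotation`, `truth`, `counts`, `peaks`, `tracks`, `expr`, `genes`,
#'   `realized_r`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  annotation <- generate_annotation(config)
  truth <- generate_truth(annotation, config)
  counts <- generate_junction_counts(truth, config)
  hm <- generate_hm_evidence(truth, annotation, config)
  ex <- generate_expression(truth, annotation, config)
  structure(list(config = config, annotation = annotation, truth = truth,
                 counts = counts, peaks = hm$peaks, tracks = hm$tracks,
                 expr = ex$expr, genes = ex$genes,
                 realized_r = hm$realized_r),
            class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Emits annotation BED, junction-count TSV, one narrowPeak (and one
#' bedGraph, when tracks were generated) per HM x cell, the FPKM TSV and
#' a truth JSON.
#'
#' @param sim a `sim_dataset`.
#' @param outdir output directory (created if needed).
#' @return invisibly a character vector of written paths.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(outdir, "annotation.bed")
  write_bed(data.frame(chrom = sim$annotation$chrom,
                       start = sim$annotation$start,
                       end = sim$annotation$end,
                       name = sim$annotation$exon_id,
                       score = 0, strand = sim$annotation$strand), p)
  paths <- c(paths, p)
  p <- file.path(outdir, "annotation.tsv")
  write_tsv(sim$annotation, p); paths <- c(paths, p)
  p <- file.path(outdir, "events.tsv")
  write_tsv(sim$truth$events, p); paths <- c(paths, p)
  p <- file.path(outdir, "junction_counts.tsv")
  write_tsv(sim$counts, p); paths <- c(paths, p)
  p <- file.path(outdir, "fpkm.tsv")
  write_tsv(sim$expr, p); paths <- c(paths, p)
  pk_dir <- file.path(outdir, "peaks")
  dir.create(pk_dir, showWarnings = FALSE)
  for (hm in unique(sim$peaks$hm)) for (cell in unique(sim$peaks$cell)) {
    sel <- sim$peaks$hm == hm & sim$peaks$cell == cell
    p <- file.path(pk_dir, sprintf("%s.%s.narrowPeak", hm, cell))
    write_narrowpeak(sim$peaks[sel, , drop = FALSE], p)
    paths <- c(paths, p)
  }
  if (!is.null(sim$tracks)) {
    cov_dir <- file.path(outdir, "coverage")
    dir.create(cov_dir, showWarnings = FALSE)
    libs <- list()
    for (hm in names(sim$tracks)) for (cell in names(sim$tracks[[hm]])) {
      p <- file.path(cov_dir, sprintf("%s.%s.bedGraph", hm, cell))
      write_bedgraph(sim$tracks[[hm]][[cell]], p)
      libs[[cell]] <- sim$tracks[[hm]][[cell]]$library_size
      paths <- c(paths, p)
    }
    p <- file.path(cov_dir, "lib_sizes.tsv")
    write_tsv(data.frame(cell = names(libs),
                         library_size = unlist(libs)), p)
    paths <- c(paths, p)
  }
  p <- file.path(outdir, "truth.json")
  truth_json <- list(
    events = sim$truth$events,
    psi_ref = sim$truth$psi_ref,
    psi_alt = as.data.frame(sim$truth$psi_alt),
    delta_psi = as.data.frame(sim$truth$delta_psi),
    direction = as.data.frame(sim$truth$direction),
    membership = sim$truth$membership,
    subset_params = sim$truth$subset_params,
    genes = sim$genes)
  jsonlite::write_json(truth_json, p, digits = NA, na = "null")
  paths <- c(paths, p)
  invisible(paths)
}
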