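## pipeline_cli: orchestration of the full analysis from one config, with
## deterministic seeding and a machine-readable run report.

#' Build a run configuration
#'
#' Every threshold defaults to the study value: |delta PSI| >= 0.1,
#' p <= 0.01, FDR <= 0.05 for differential splicing; screen alpha 0.05;
#' k = 6 clusters; 150-bp flanks in 15-bp bins; 100-bp peak-distance
#' floor; mirror cosine -0.8.
#'
#' @param seed master seed (required; all stage seeds derive from it).
#' @param outdir output directory.
#' @param sim list of [sim_config()] overrides (e.g. `list(n_genes =
#'   150, with_coverage = TRUE)`); the simulation seed is derived from
#'   `seed`.
#' @param dpsi,p_max,fdr_max differential-splicing thresholds.
#' @param alpha screen / subset significance threshold.
#' @param k number of k-means clusters.
#' @param flank_bp,bin_bp profile bin scheme.
#' @param floor_bp peak summit distance floor.
#' @param mirror_cos mirror-pattern cosine threshold.
#' @param fc_threshold,min_fpkm DEG call parameters.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, outdir = tempfile("hmsplice_run_"),
                       sim = list(), dpsi = 0.1, p_max = 0.01,
                       fdr_max = 0.05, alpha = 0.05, k = 6L,
                       flank_bp = 150L, bin_bp = 15L, floor_bp = 100,
                       mirror_cos = -0.8, fc_threshold = 2, min_fpkm = 1) {
  if (missing(seed) || is.null(seed))
    stop("run configuration requires a seed")
  stopifnot(dpsi > 0, dpsi <= 1, p_max > 0, p_max <= 1,
            fdr_max > 0, fdr_max <= 1, alpha > 0, alpha <= 1, k >= 2)
  structure(list(seed = as.integer(seed), outdir = outdir, sim = sim,
                 dpsi = dpsi, p_max = p_max, fdr_max = fdr_max,
                 alpha = alpha, k = as.integer(k),
                 flank_bp = as.integer(flank_bp),
                 bin_bp = as.integer(bin_bp), floor_bp = floor_bp,
                 mirror_cos = mirror_cos, fc_threshold = fc_threshold,
                 min_fpkm = min_fpkm),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("run configuration requires a seed")
  do.call(run_config, y)
}

# Differential calls for every lineage, stacked, with the MXE
# complementarity assertion applied per cell on pooled counts.
call_all_lineages <- function(counts, ref_cell, lineages, dpsi, p_max,
                              fdr_max, mxe_tol = 0.02) {
  target <- counts[counts$exon == "target", , drop = FALSE]
  down <- counts[counts$exon == "mxe_down", , drop = FALSE]
  if (nrow(down) > 0L) {
    pooled_psi <- function(d) {
      I <- tapply(d$I, list(d$event_id, d$cell), sum)
      S <- tapply(d$S, list(d$event_id, d$cell), sum)
      I / (I + S) # unit lengths for MXE exons
    }
    up_psi <- pooled_psi(target[target$type == "MXE", , drop = FALSE])
    dn_psi <- pooled_psi(down)
    rownames(dn_psi) <- sub(":down$", "", rownames(dn_psi))
    dn_psi <- dn_psi[rownames(up_psi), colnames(up_psi), drop = FALSE]
    dev <- abs(up_psi + dn_psi - 1)
    if (any(dev > mxe_tol, na.rm = TRUE))
      stop(sprintf("MXE PSIs not complementary for event %s (deviation %.3f)",
                   rownames(up_psi)[which(dev > mxe_tol, arr.ind = TRUE)[1L]],
                   max(dev, na.rm = TRUE)))
  }
  calls <- lapply(lineages, function(lin) {
    cl <- call_differential(target, ref_cell, lin, dpsi, p_max, fdr_max)
    cl$lineage <- lin
    cl
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

# Long delta-HM table over all HMs.
all_delta_hm <- function(events, peaks, ref_cell, lineages, floor_bp) {
  out <- lapply(unique(peaks$hm), function(hm) {
    d <- delta_hm_table(events, peaks[peaks$hm == hm, , drop = FALSE],
                        ref_cell, lineages, floor_bp)
    d$hm <- hm
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# event|lineage instance matrix of delta HM (instances x HM)
dhm_matrix <- function(dhm) {
  key <- paste(dhm$event_id, dhm$lineage, sep = "|")
  hms <- unique(dhm$hm)
  ukey <- unique(key)
  m <- matrix(NA_real_, length(ukey), length(hms),
              dimnames = list(ukey, hms))
  m[cbind(match(key, ukey), match(dhm$hm, hms))] <- dhm$delta_hm
  m
}

# Panel summaries for one exon set: per exon x side, the
# variance-stabilized net change |sum(delta * len)| / sqrt(sum(len)) over
# the selected bins, computed from a prebuilt long bin table.
panel_summaries <- function(bins_long, track_ref, track_alt,
                            bins = "exon") {
  delta <- delta_reads(bins_long, track_ref, track_alt)
  sel <- bins_long$region == bins
  len <- (bins_long$end - bins_long$start)[sel]
  key <- paste(bins_long$exon_id, bins_long$side, sep = "|")[sel]
  num <- tapply(delta[sel] * len, key, sum)
  den <- tapply(len, key, sum)
  as.numeric(abs(num) / sqrt(den))
}

panel_test_from_summaries <- function(s_as, s_cs) {
  underpowered <- length(s_as) < 3L || length(s_cs) < 3L
  p <- if (underpowered) 1 else
    suppressWarnings(wilcox.test(s_as, s_cs)$p.value)
  list(p_value = p,
       preferred = if (median(s_as) >= median(s_cs)) "AS" else "CS",
       underpowered = underpowered)
}

bins_for_exons <- function(exons, scheme) {
  rows <- vector("list", nrow(exons))
  for (i in seq_len(nrow(exons))) {
    b <- bin_region(exons$chrom[i], exons$start[i], exons$end[i],
                    exons$strand[i], exons$intron_up_len[i],
                    exons$intron_down_len[i], scheme)
    b$exon_id <- exons$exon_id[i]
    rows[[i]] <- b
  }
  do.call(rbind, rows)
}

# hm_profile stage: panel tests for every HM x lineage x AS type plus
# per-HM link strengths.
profile_stage <- function(sim, calls, config) {
  scheme <- bin_scheme(config$flank_bp, config$bin_bp)
  ev <- sim$truth$events
  panels <- list()
  for (ty in unique(ev$type)) {
    evt <- ev[ev$type == ty, , drop = FALSE]
    cs <- sample_cs_exons(
      data.frame(event_id = evt$event_id, gene_id = evt$gene_id),
      sim$annotation, seed = derive_seed(config$seed, paste0("cs_", ty)))
    cs_ex <- sim$annotation[match(cs$exon_id, sim$annotation$exon_id), ]
    as_bins <- bins_for_exons(
      data.frame(exon_id = evt$event_id, chrom = evt$chrom,
                 start = evt$start, end = evt$end, strand = evt$strand,
                 intron_up_len = evt$intron_up_len,
                 intron_down_len = evt$intron_down_len), scheme)
    cs_bins <- bins_for_exons(cs_ex, scheme)
    for (hm in names(sim$tracks)) {
      ref_tr <- sim$tracks[[hm]][[sim$config$ref_cell]]
      for (lin in sim$config$lineages) {
        alt_tr <- sim$tracks[[hm]][[lin]]
        s_as <- panel_summaries(as_bins, ref_tr, alt_tr)
        s_cs <- panel_summaries(cs_bins, ref_tr, alt_tr)
        pt <- panel_test_from_summaries(s_as, s_cs)
        panels[[length(panels) + 1L]] <- data.frame(
          hm = hm, lineage = lin, as_type = ty, p_value = pt$p_value,
          preferred = pt$preferred, stringsAsFactors = FALSE)
      }
    }
  }
  panels <- do.call(rbind, panels)
  links <- do.call(rbind, lapply(unique(panels$hm), function(hm) {
    ls <- link_strength(panels, hm)
    data.frame(hm = hm, p_value = ls$p_value,
               link_strength = ls$link_strength)
  }))
  list(panels = panels, links = links)
}

# association stage for one AS type; returns NULL when too sparse.
association_stage <- function(calls, dhm_mat, ty, config) {
  cl <- calls[calls$type == ty & calls$direction != "none", , drop = FALSE]
  if (nrow(cl) == 0L) return(NULL)
  key <- paste(cl$event_id, cl$lineage, sep = "|")
  key <- key[key %in% rownames(dhm_mat)]
  if (length(key) < 2L * config$k) return(NULL)
  dpsi_v <- setNames(cl$delta_psi[match(key,
                                        paste(cl$event_id, cl$lineage,
                                              sep = "|"))], key)
  m <- dhm_mat[key, , drop = FALSE]
  n_gain <- sum(dpsi_v < -config$dpsi)
  n_loss <- sum(dpsi_v > config$dpsi)
  if (n_gain < config$k || n_loss < config$k) return(NULL)
  associate_hm_as(dpsi_v, m, k = config$k,
                  seed = derive_seed(config$seed, paste0("assoc_", ty)),
                  alpha = config$alpha, cos_threshold = config$mirror_cos,
                  dpsi = config$dpsi)
}

#' Run the full analysis pipeline
#'
#' Simulates a dataset (or ingests one), calls differential splicing per
#' lineage, runs the splice-site profile stage (when coverage tracks are
#' present), computes delta-HM tables, runs the association stage per AS
#' type, calls DEGs and the AS-gene/DEG enrichment, writes all stage
#' tables under `config$outdir` and returns a run report. Reruns with the
#' same config are byte-identical.
#'
#' @param config a [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @param sim optionally a pre-built `sim_dataset` to analyse instead of
#'   simulating (its config must match the seed-derived one for
#'   reproducibility claims to hold).
#' @return list of class `run_result`: `report`, `calls`, `asym`,
#'   `specificity`, `profile`, `dhm`, `assoc` (per AS type), `deg`,
#'   `enrichment`, `sim`.
#' @export
run_pipeline <- function(config, sim = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(sim)) {
    sim_args <- config$sim
    sim_args$seed <- derive_seed(config$seed, "simulate")
    sim <- simulate_dataset(do.call(sim_config, sim_args))
  }
  ev <- sim$truth$events

  calls <- call_all_lineages(sim$counts, sim$config$ref_cell,
                             sim$config$lineages, config$dpsi,
                             config$p_max, config$fdr_max)
  asym <- direction_asymmetry_test(calls)
  spec <- lineage_specificity(calls)
  ann <- sim$annotation
  frame <- frame_preservation_stats(
    ev$end - ev$start,
    ann$end[ann$role == "CS"] - ann$start[ann$role == "CS"])
  lens <- length_stats(
    ev$end - ev$start,
    ann$end[ann$role == "CS"] - ann$start[ann$role == "CS"],
    c(ev$intron_up_len, ev$intron_down_len),
    ann$intron_up_len[ann$role == "CS" & !is.na(ann$intron_up_len)])

  prof <- NULL
  if (!is.null(sim$tracks)) prof <- profile_stage(sim, calls, config)

  dhm <- all_delta_hm(ev, sim$peaks, sim$config$ref_cell,
                      sim$config$lineages, config$floor_bp)
  dmat <- dhm_matrix(dhm)

  assoc <- list()
  for (ty in unique(ev$type))
    assoc[[ty]] <- association_stage(calls, dmat, ty, config)

  degs_by_lin <- lapply(sim$config$lineages, function(lin)
    deg_call(sim$expr, sim$config$ref_cell, lin, config$fc_threshold,
             config$min_fpkm))
  deg_union <- sort(unique(unlist(lapply(degs_by_lin, `[[`, "degs"))))
  universe <- sort(unique(unlist(lapply(degs_by_lin, `[[`, "universe"))))
  as_genes <- intersect(unique(ev$gene_id), universe)
  enr <- hypergeom_enrich(as_genes, deg_union, universe)

  # ---- write stage outputs ----
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(config$outdir, name)
    write_tsv(x, p)
    paths <<- c(paths, p)
  }
  wr(calls, "splicing_calls.tsv")
  wr(spec$events, "lineage_specificity.tsv")
  wr(dhm, "delta_hm.tsv")
  if (!is.null(prof)) {
    wr(prof$panels, "profile_panels.tsv")
    wr(prof$links, "link_strength.tsv")
  }
  for (ty in names(assoc)) {
    if (is.null(assoc[[ty]])) next
    wr(assoc[[ty]]$screens, sprintf("screens_%s.tsv", ty))
    if (nrow(assoc[[ty]]$subsets) > 0L)
      wr(assoc[[ty]]$subsets, sprintf("subsets_%s.tsv", ty))
  }
  wr(data.frame(gene_id = deg_union), "degs.tsv")

  n_called <- sum(calls$direction != "none")
  report <- list(
    seed = config$seed,
    n_events = nrow(ev),
    n_event_lineage = nrow(calls),
    n_called = n_called,
    n_not_called = nrow(calls) - n_called,
    counts_reconcile = (n_called + (nrow(calls) - n_called)) == nrow(calls),
    dropped_missing_psi = attr(calls, "dropped_missing"),
    asymmetry_p = asym$p_value,
    frame_p = frame$p_value,
    coverage_fraction = vapply(assoc, function(a)
      if (is.null(a)) NA_real_ else a$coverage_fraction, numeric(1)),
    n_subsets = vapply(assoc, function(a)
      if (is.null(a)) 0L else length(unique(a$subsets$subset_id)),
      integer(1)),
    n_degs = length(deg_union),
    enrichment_p = enr$p_value,
    wall_time_s = proc.time()[["elapsed"]] - t0,
    outputs = paths,
    digests = as.list(tools::md5sum(paths)))
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

  structure(list(report = report, calls = calls, asym = asym,
                 specificity = spec, frame = frame, lengths = lens,
                 profile = prof, dhm = dhm, dhm_matrix = dmat,
                 assoc = assoc, deg = deg_union, enrichment = enr,
                 sim = sim, config = config),
            class = "run_result")
}

#' Delta-PSI cutoff sweep
#'
#' Re-applies the differential-splicing cutoff over a grid and reports,
#' per cutoff and HM, the number of retained event-lineage instances and
#' the Pearson screen statistic on them, mirroring the robustness check
#' that raising the cutoff shrinks the event set without systematically
#' changing the correlations.
#'
#' @param result a `run_result` from [run_pipeline()].
#' @param dpsi_values cutoffs to sweep (default 0.1-0.5).
#' @param as_type AS type to sweep (default `"SE"`).
#' @return data.frame with `cutoff`, `hm`, `n_events`, `r`, `p_value`.
#' @export
cutoff_sweep <- function(result, dpsi_values = c(0.1, 0.2, 0.3, 0.4, 0.5),
                         as_type = "SE") {
  stopifnot(inherits(result, "run_result"))
  cl <- result$calls
  cl <- cl[cl$type == as_type & !is.na(cl$p_value), , drop = FALSE]
  cfg <- result$config
  out <- list()
  for (cut in dpsi_values) {
    sel <- cl$p_value <= cfg$p_max & cl$fdr <= cfg$fdr_max &
      abs(cl$delta_psi) >= cut
    key <- paste(cl$event_id[sel], cl$lineage[sel], sep = "|")
    key <- key[key %in% rownames(result$dhm_matrix)]
    n <- length(key)
    for (hm in colnames(result$dhm_matrix)) {
      if (n >= 10L) {
        keep <- match(key, paste(cl$event_id, cl$lineage, sep = "|"))
        ct <- suppressWarnings(
          cor.test(cl$delta_psi[keep], result$dhm_matrix[key, hm]))
        r <- unname(ct$estimate); p <- ct$p.value
      } else {
        r <- NA_real_; p <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        cutoff = cut, hm = hm, n_events = n, r = r, p_value = p)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
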