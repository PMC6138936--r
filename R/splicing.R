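## splicing: PSI estimation, differential-inclusion calls and the
## descriptive statistics of differentiation-related AS exons.
##
## Sign convention used everywhere: delta_psi = psi(reference, stem-like)
## - psi(differentiated). delta_psi > +0.1 is therefore an inclusion-LOSS
## upon differentiation and delta_psi < -0.1 an inclusion-GAIN.

#' Percent-spliced-in from junction counts
#'
#' `psi = (I/len_I) / (I/len_I + S/len_S)`: the inclusion and skipping
#' junction counts are first divided by their effective lengths so that the
#' longer inclusion form does not inflate the estimate. With unit lengths
#' this reduces to the raw count ratio.
#'
#' @param I,S inclusion / skipping read counts (non-negative, vectorized).
#' @param len_I,len_S effective lengths (positive); default 1.
#' @return psi in `[0, 1]`; `NA` where `I + S == 0`.
#' @export
compute_psi <- function(I, S, len_I = 1, len_S = 1) {
  if (any(I < 0 | S < 0, na.rm = TRUE)) stop("negative junction counts")
  if (any(len_I <= 0 | len_S <= 0)) stop("effective lengths must be positive")
  num <- I / len_I
  den <- num + S / len_S
  out <- num / den
  out[I + S == 0] <- NA_real_
  out
}

# Vectorized two-sided Fisher exact p for 2x2 tables [[a, b], [c, d]],
# summing dhyper mass <= observed (with the standard relative-error guard,
# matching stats::fisher.test). Written out because the differential caller
# evaluates thousands of tables per comparison.
fisher_p_2x2 <- function(a, b, c, d) {
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]
    m2 <- c[i] + d[i]
    k <- a[i] + c[i]
    if (m1 + m2 == 0L || k == 0L || k == m1 + m2) {
      p[i] <- 1
      next
    }
    lo <- max(0L, k - m2)
    hi <- min(k, m1)
    dens <- dhyper(lo:hi, m1, m2, k)
    obs <- dens[a[i] - lo + 1L]
    p[i] <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  p
}

#' Call differential exon inclusion between two cell types
#'
#' Replicates are summed per cell type, PSI is computed with
#' [compute_psi()], and each event is tested with a two-sided Fisher exact
#' test on the pooled 2x2 inclusion/skipping table. FDR is
#' Benjamini-Hochberg across all events of the comparison. An event is
#' called `loss` when `delta_psi > dpsi`, `gain` when `delta_psi < -dpsi`,
#' in both cases requiring `p <= p_max` and `fdr <= fdr_max`; otherwise
#' `none`.
#'
#' @param counts data.frame with columns `event_id`, `type`, `gene_id`,
#'   `cell`, `replicate`, `I`, `S`, `len_I`, `len_S`.
#' @param ref_cell,alt_cell cell-type labels present in `counts$cell`.
#' @param dpsi,p_max,fdr_max call thresholds (defaults 0.1, 0.01, 0.05).
#' @return data.frame (one row per event) with per-cell pooled PSI,
#'   per-replicate PSI range, `delta_psi`, `p_value`, `fdr`, `direction`,
#'   plus a `dropped_missing` attribute counting events without coverage in
#'   either cell.
#' @export
call_differential <- function(counts, ref_cell, alt_cell,
                              dpsi = 0.1, p_max = 0.01, fdr_max = 0.05) {
  need <- c("event_id", "type", "gene_id", "cell", "replicate",
            "I", "S", "len_I", "len_S")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0L)
    stop("counts table missing columns: ", paste(miss, collapse = ", "))
  cc <- counts[counts$cell %in% c(ref_cell, alt_cell), , drop = FALSE]
  if (!all(c(ref_cell, alt_cell) %in% cc$cell))
    stop(sprintf("counts lack cell '%s'",
                 setdiff(c(ref_cell, alt_cell), unique(cc$cell))[1L]))

  pool <- function(cell) {
    d <- cc[cc$cell == cell, , drop = FALSE]
    agg_I <- tapply(d$I, d$event_id, sum)
    agg_S <- tapply(d$S, d$event_id, sum)
    len_I <- tapply(d$len_I, d$event_id, function(x) x[1L])
    len_S <- tapply(d$len_S, d$event_id, function(x) x[1L])
    rep_psi_rng <- tapply(compute_psi(d$I, d$S, d$len_I, d$len_S),
                          d$event_id,
                          function(x) diff(range(x, na.rm = TRUE)))
    list(I = agg_I, S = agg_S, len_I = len_I, len_S = len_S,
         rng = rep_psi_rng, ids = names(agg_I))
  }
  r <- pool(ref_cell)
  a <- pool(alt_cell)
  ids <- sort(intersect(r$ids, a$ids))
  if (length(setdiff(unique(cc$event_id), ids)) > 0L) {
    missing_ids <- setdiff(unique(cc$event_id), ids)
    stop(sprintf("event '%s' lacks counts in one of the cells",
                 missing_ids[1L]))
  }
  meta <- cc[!duplicated(cc$event_id), c("event_id", "type", "gene_id")]
  meta <- meta[match(ids, meta$event_id), ]

  psi_ref <- compute_psi(r$I[ids], r$S[ids], r$len_I[ids], r$len_S[ids])
  psi_alt <- compute_psi(a$I[ids], a$S[ids], a$len_I[ids], a$len_S[ids])
  keep <- !is.na(psi_ref) & !is.na(psi_alt)
  n_drop <- sum(!keep)

  out <- data.frame(event_id = ids, type = meta$type, gene_id = meta$gene_id,
                    psi_ref = psi_ref, psi_alt = psi_alt,
                    psi_ref_rep_range = as.numeric(r$rng[ids]),
                    psi_alt_rep_range = as.numeric(a$rng[ids]),
                    delta_psi = psi_ref - psi_alt,
                    p_value = NA_real_, fdr = NA_real_,
                    direction = "none",
                    stringsAsFactors = FALSE)
  out$p_value[keep] <- fisher_p_2x2(round(r$I[ids][keep]),
                                    round(r$S[ids][keep]),
                                    round(a$I[ids][keep]),
                                    round(a$S[ids][keep]))
  # stable order (p, event_id) so BH ties resolve reproducibly
  ord <- order(out$p_value[keep], out$event_id[keep])
  fdr <- rep(NA_real_, sum(keep))
  fdr[ord] <- p.adjust(out$p_value[keep][ord], method = "BH")
  out$fdr[keep] <- fdr
  sig <- keep & out$p_value <= p_max & out$fdr <= fdr_max
  out$direction[sig & out$delta_psi > dpsi] <- "loss"
  out$direction[sig & out$delta_psi < -dpsi] <- "gain"
  attr(out, "dropped_missing") <- n_drop
  rownames(out) <- NULL
  out
}

#' Reduce an MXE call pair to its upstream-exon call
#'
#' For a mutually exclusive exon (MXE) event only the transcript-upstream
#' exon is carried forward; the two exons' inclusion levels must be
#' complementary (`psi_up + psi_down = 1 +/- tol`) in each cell.
#'
#' @param call_up,call_down single-row call data.frames for the upstream
#'   and downstream exon of one MXE event (as from [call_differential()]).
#' @param tol allowed deviation of the PSI sum from 1 (default 0.02).
#' @return `call_up`, unchanged.
#' @export
mxe_upstream_delta <- function(call_up, call_down, tol = 0.02) {
  sums <- c(call_up$psi_ref + call_down$psi_ref,
            call_up$psi_alt + call_down$psi_alt)
  if (any(abs(sums - 1) > tol, na.rm = TRUE))
    stop(sprintf("MXE PSIs not complementary: sums %s",
                 paste(round(sums, 4), collapse = ", ")))
  call_up
}

#' Direction asymmetry between SE and MXE events
#'
#' Tests whether skipped exons (SE) and upstream mutually-exclusive exons
#' (MXE) differ in their balance of inclusion-gain vs inclusion-loss calls,
#' with a two-sided Fisher exact test on the 2x2 type-by-direction table.
#'
#' @param calls data.frame with `type` (`SE`/`MXE`) and `direction`
#'   columns; rows with `direction == "none"` are ignored.
#' @return list with the 2x2 `table`, `odds_ratio` and `p_value`.
#' @export
direction_asymmetry_test <- function(calls) {
  d <- calls[calls$direction %in% c("gain", "loss"), , drop = FALSE]
  tab <- matrix(0, 2, 2, dimnames = list(type = c("SE", "MXE"),
                                         direction = c("gain", "loss")))
  for (ty in c("SE", "MXE")) for (di in c("gain", "loss"))
    tab[ty, di] <- sum(d$type == ty & d$direction == di)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin in direction asymmetry table; p = 1")
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1))
  }
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Lineage specificity of differential AS events
#'
#' Labels each event by the number of lineages in which it is called
#' (`direction != "none"`): `lineage-specific` (exactly one),
#' `common` (all), `shared` otherwise, `none` if never called. Gene labels
#' use the union of the gene's events.
#'
#' @param calls_by_lineage data.frame of stacked [call_differential()]
#'   outputs with an added `lineage` column; every lineage must cover the
#'   same event universe.
#' @return list with `events` (event_id, type, gene_id, n_lineages, label),
#'   `genes` (gene_id, label), and `percent` (per AS type, percentage of
#'   called events that are lineage-specific or common).
#' @export
lineage_specificity <- function(calls_by_lineage) {
  n_lin <- length(unique(calls_by_lineage$lineage))
  sig <- calls_by_lineage$direction != "none"
  n_by_event <- tapply(sig, calls_by_lineage$event_id, sum)
  meta <- calls_by_lineage[!duplicated(calls_by_lineage$event_id),
                           c("event_id", "type", "gene_id")]
  meta <- meta[match(names(n_by_event), meta$event_id), ]
  lab <- ifelse(n_by_event == 0L, "none",
                ifelse(n_by_event == 1L, "lineage-specific",
                       ifelse(n_by_event == n_lin, "common", "shared")))
  events <- data.frame(event_id = names(n_by_event), type = meta$type,
                       gene_id = meta$gene_id,
                       n_lineages = as.integer(n_by_event),
                       label = unname(lab), stringsAsFactors = FALSE)
  # gene label from the union of its events' per-lineage calls
  gsig <- calls_by_lineage[sig, c("gene_id", "lineage")]
  g_n <- tapply(gsig$lineage, gsig$gene_id,
                function(x) length(unique(x)))
  genes <- data.frame(gene_id = names(g_n),
                      label = ifelse(g_n == 1L, "lineage-specific",
                                     ifelse(g_n == n_lin, "common",
                                            "shared")),
                      stringsAsFactors = FALSE)
  pct <- do.call(rbind, lapply(split(events, events$type), function(e) {
    called <- e[e$label != "none", , drop = FALSE]
    data.frame(type = e$type[1L],
               n_called = nrow(called),
               pct_specific = 100 * mean(called$label == "lineage-specific"),
               pct_common = 100 * mean(called$label == "common"))
  }))
  rownames(pct) <- NULL
  list(events = events, genes = genes, percent = pct)
}

#' Reading-frame preservation of AS exon lengths
#'
#' Fraction of exon lengths divisible by 3, compared between AS exons and a
#' background (constitutive) set with a two-sided Fisher exact test.
#'
#' @param as_lengths,cs_lengths integer vectors of exon lengths.
#' @return list with per-class fractions, the 2x2 table and `p_value`.
#' @export
frame_preservation_stats <- function(as_lengths, cs_lengths) {
  if (length(as_lengths) == 0L || length(cs_lengths) == 0L)
    stop("no events: both length vectors must be non-empty")
  a3 <- sum(as_lengths %% 3 == 0)
  c3 <- sum(cs_lengths %% 3 == 0)
  tab <- matrix(c(a3, length(as_lengths) - a3,
                  c3, length(cs_lengths) - c3), 2, 2, byrow = TRUE,
                dimnames = list(class = c("AS", "CS"),
                                frame = c("divisible", "not")))
  list(frac_as = a3 / length(as_lengths),
       frac_cs = c3 / length(cs_lengths),
       table = tab,
       p_value = fisher.test(tab)$p.value)
}

#' Exon and intron length statistics of AS events
#'
#' Medians and two-sided Mann-Whitney tests comparing AS exon lengths (and
#' their flanking intron lengths) against background exons/introns.
#'
#' @param as_exon_len,bg_exon_len exon length vectors.
#' @param as_intron_len,bg_intron_len flanking / background intron length
#'   vectors (optional).
#' @return data.frame with one row per comparison: medians and p.
#' @export
length_stats <- function(as_exon_len, bg_exon_len,
                         as_intron_len = NULL, bg_intron_len = NULL) {
  if (length(as_exon_len) == 0L) stop("no events")
  cmp <- function(a, b, label) {
    p <- suppressWarnings(wilcox.test(a, b)$p.value)
    data.frame(comparison = label, median_as = median(a),
               median_bg = median(b), p_value = p)
  }
  out <- cmp(as_exon_len, bg_exon_len, "exon_length")
  if (!is.null(as_intron_len) && !is.null(bg_intron_len))
    out <- rbind(out, cmp(as_intron_len, bg_intron_len, "intron_length"))
  rownames(out) <- NULL
  out
}
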