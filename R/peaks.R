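## hm_peaks: per-exon, distance-normalized differential narrow-peak signal
## (delta HM). A peak counts only if it overlaps the exon by >= 1 bp; among
## several overlapping peaks the one with the greater signal wins; exons
## without an overlapping peak get signal 0. The retained signal is divided
## by the summit-to-3'-splice-site distance in kb, floored at 0.1 kb.

#' Assign the strongest overlapping peak to an exon
#'
#' @param exon_start,exon_end exon coordinates (0-based half-open).
#' @param peaks data.frame of peaks on the same chromosome (`start`, `end`,
#'   `summit_offset`, `signal`).
#' @return the 1-row peak data.frame with the greatest signal among peaks
#'   overlapping the exon by at least 1 bp, or `NULL` if none overlaps.
#' @export
assign_peak <- function(exon_start, exon_end, peaks) {
  if (nrow(peaks) == 0L) return(NULL)
  ov <- peaks$start < exon_end & peaks$end > exon_start
  if (!any(ov)) return(NULL)
  cand <- peaks[ov, , drop = FALSE]
  cand[which.max(cand$signal), , drop = FALSE]
}

#' Distance-normalized peak signal
#'
#' Divides the peak height by the distance (in kb) from the peak summit to
#' the 3' splice site (acceptor) of the target exon; the distance is
#' floored at `floor_bp` so that a summit sitting on the splice site does
#' not produce an unbounded statistic.
#'
#' @param signal peak height (non-negative).
#' @param summit_pos genomic position of the summit (`start +
#'   summit_offset`).
#' @param ss3_pos genomic position of the exon's 3' splice site (exon start
#'   on `+`, exon end on `-`).
#' @param floor_bp distance floor in bp (default 100).
#' @return `signal / max(|summit_pos - ss3_pos|, floor_bp) * 1000`
#'   (i.e. signal per kb of summit distance).
#' @export
normalized_signal <- function(signal, summit_pos, ss3_pos, floor_bp = 100) {
  if (any(signal < 0)) stop("negative peak signal")
  dist_kb <- pmax(abs(summit_pos - ss3_pos), floor_bp) / 1000
  signal / dist_kb
}

# 3' splice-site genomic position of target exons, strand-aware.
ss3_position <- function(start, end, strand) {
  ifelse(strand == "+", start, end)
}

#' Differential HM signal table for one histone mark
#'
#' For every event x lineage, assigns the strongest overlapping peak in the
#' reference and in the differentiated cell, distance-normalizes both
#' signals, and records `delta_hm = signal_ref - signal_alt`. MXE events
#' must already be reduced to their upstream exon (one row per event).
#'
#' @param events data.frame with `event_id`, `chrom`, `start`, `end`,
#'   `strand` (target-exon coordinates).
#' @param peaks long data.frame of peaks with columns `cell`, `chrom`,
#'   `start`, `end`, `summit_offset`, `signal` (one HM).
#' @param ref_cell reference (stem-like) cell label.
#' @param lineages character vector of differentiated cell labels; each
#'   must have peak rows present in `peaks$cell` (an empty set of peaks for
#'   a listed cell is an error naming the cell).
#' @param floor_bp distance floor passed to [normalized_signal()].
#' @return data.frame with `event_id`, `lineage`, `signal_ref`,
#'   `signal_alt`, `delta_hm`.
#' @export
delta_hm_table <- function(events, peaks, ref_cell, lineages,
                           floor_bp = 100) {
  cells <- c(ref_cell, lineages)
  missing_cells <- setdiff(cells, unique(peaks$cell))
  if (length(missing_cells) > 0L)
    stop(sprintf("no peaks provided for cell '%s'", missing_cells[1L]))
  ss3 <- ss3_position(events$start, events$end, events$strand)

  cell_signal <- function(cell) {
    pk <- peaks[peaks$cell == cell, , drop = FALSE]
    sig <- numeric(nrow(events))
    for (ch in unique(events$chrom)) {
      esel <- which(events$chrom == ch)
      psel <- which(pk$chrom == ch)
      if (length(psel) == 0L) next
      hits <- findOverlaps(
        IRanges(events$start[esel] + 1L, events$end[esel]),
        IRanges(pk$start[psel] + 1L, pk$end[psel]))
      if (length(hits) == 0L) next
      qi <- queryHits(hits); si <- subjectHits(hits)
      ns <- normalized_signal(
        pk$signal[psel][si],
        pk$start[psel][si] + pk$summit_offset[psel][si],
        ss3[esel][qi], floor_bp)
      # greater raw peak height wins, then its normalized value is kept
      ord <- order(qi, -pk$signal[psel][si])
      qi <- qi[ord]; ns <- ns[ord]
      first <- !duplicated(qi)
      sig[esel[qi[first]]] <- ns[first]
    }
    sig
  }

  ref_sig <- cell_signal(ref_cell)
  out <- vector("list", length(lineages))
  for (j in seq_along(lineages)) {
    alt_sig <- cell_signal(lineages[j])
    out[[j]] <- data.frame(event_id = events$event_id,
                           lineage = lineages[j],
                           signal_ref = ref_sig,
                           signal_alt = alt_sig,
                           delta_hm = ref_sig - alt_sig,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
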