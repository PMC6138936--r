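## hm_profile: binned, depth-normalized differential ChIP signal around
## splice sites of AS exons versus matched constitutive (CS) exons.

#' Bin scheme for splice-site profiles
#'
#' +/-150 bp around each splice site, 15-bp bins; a side (exonic or
#' intronic) shorter than `flank_bp` is instead divided evenly into
#' `short_region_bins` bins.
#'
#' @param flank_bp flank width in bp (default 150).
#' @param bin_bp bin width in bp (default 15; must divide `flank_bp`).
#' @param short_region_bins bins for a short side (default 10).
#' @return list of class `bin_scheme`.
#' @export
bin_scheme <- function(flank_bp = 150L, bin_bp = 15L,
                       short_region_bins = 10L) {
  if (flank_bp %% bin_bp != 0L)
    stop("flank_bp must be divisible by bin_bp")
  structure(list(flank_bp = as.integer(flank_bp),
                 bin_bp = as.integer(bin_bp),
                 short_region_bins = as.integer(short_region_bins)),
            class = "bin_scheme")
}

# Evenly split [lo, hi) into n bins; boundaries rounded, last bin absorbs
# the remainder.
split_even <- function(lo, hi, n) {
  b <- round(seq(lo, hi, length.out = n + 1L))
  b[n + 1L] <- hi
  data.frame(start = b[-(n + 1L)], end = b[-1L])
}

# Bins covering one side of a splice site, returned in genomic ascending
# order. `region_len` is the available length on that side; a side of at
# least flank_bp contributes flank_bp/bin_bp bins of width bin_bp adjacent
# to the boundary, a shorter side is divided evenly into short_region_bins.
# `direction` +1 extends the window right of `boundary`, -1 left.
side_bins <- function(boundary, region_len, direction, scheme) {
  if (region_len >= scheme$flank_bp) {
    n <- scheme$flank_bp %/% scheme$bin_bp
    len <- scheme$flank_bp
    if (direction > 0)
      data.frame(start = boundary + seq(0L, by = scheme$bin_bp,
                                        length.out = n),
                 end = boundary + seq(scheme$bin_bp, by = scheme$bin_bp,
                                      length.out = n))
    else
      data.frame(start = boundary - seq(len, by = -scheme$bin_bp,
                                        length.out = n),
                 end = boundary - seq(len - scheme$bin_bp,
                                      by = -scheme$bin_bp, length.out = n))
  } else {
    if (direction > 0) split_even(boundary, boundary + region_len,
                                  scheme$short_region_bins)
    else split_even(boundary - region_len, boundary,
                    scheme$short_region_bins)
  }
}

#' Bins around the splice sites of one exon
#'
#' Produces the profile bins for both splice sites of an exon: for each
#' site, the intronic bins then the exonic bins, ordered 5'->3' in
#' transcript orientation (strand-aware). The 3' splice site (acceptor) is
#' the transcript-upstream exon boundary; the 5' splice site (donor) the
#' downstream one.
#'
#' @param chrom,start,end,strand exon coordinates (0-based half-open).
#' @param intron_up_len,intron_down_len lengths of the transcript-upstream
#'   and downstream flanking introns.
#' @param scheme a [bin_scheme()].
#' @return data.frame with `chrom`, `start`, `end`, `side` (`ss3`/`ss5`),
#'   `region` (`intron`/`exon`), `bin` (1..2*short_region_bins per side,
#'   transcript order).
#' @export
bin_region <- function(chrom, start, end, strand, intron_up_len,
                       intron_down_len, scheme = bin_scheme()) {
  exon_len <- end - start
  if (exon_len < 10L) stop("exon shorter than 10 bp cannot be profiled")
  if (intron_up_len < 1L || intron_down_len < 1L)
    stop("flanking intron lengths must be positive")
  # acceptor (3'ss) is the transcript-upstream exon boundary
  if (strand == "+") {
    b_int3 <- side_bins(start, intron_up_len, -1L, scheme)
    b_exo3 <- side_bins(start, exon_len, +1L, scheme)
    b_exo5 <- side_bins(end, exon_len, -1L, scheme)
    b_int5 <- side_bins(end, intron_down_len, +1L, scheme)
  } else {
    b_int3 <- side_bins(end, intron_up_len, +1L, scheme)
    b_exo3 <- side_bins(end, exon_len, -1L, scheme)
    b_exo5 <- side_bins(start, exon_len, +1L, scheme)
    b_int5 <- side_bins(start, intron_down_len, -1L, scheme)
  }
  orient <- function(df) {
    # side_bins returns genomic order; transcript order on '-' is reversed
    if (strand == "-") df[rev(seq_len(nrow(df))), , drop = FALSE] else df
  }
  b_int3 <- orient(b_int3); b_exo3 <- orient(b_exo3)
  b_exo5 <- orient(b_exo5); b_int5 <- orient(b_int5)
  out <- rbind(
    cbind(b_int3, side = "ss3", region = "intron"),
    cbind(b_exo3, side = "ss3", region = "exon"),
    cbind(b_exo5, side = "ss5", region = "exon"),
    cbind(b_int5, side = "ss5", region = "intron"))
  out$chrom <- chrom
  out$bin <- c(seq_len(nrow(b_int3) + nrow(b_exo3)),
               seq_len(nrow(b_exo5) + nrow(b_int5)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "side", "region", "bin")]
}

#' Depth-normalized differential read count per bin
#'
#' `delta = (reads_ref * 1e6 / lib_ref - reads_alt * 1e6 / lib_alt) /
#' bin_len`: read counts are scaled to counts-per-million of their library
#' before differencing (reference minus differentiated), then divided by
#' the bin length in bp.
#'
#' @param bins data.frame from [bin_region()] (needs `chrom`, `start`,
#'   `end`).
#' @param track_ref,track_alt `coverage_track` objects for the reference
#'   and differentiated cell.
#' @return numeric vector of delta-reads values, one per bin row.
#' @export
delta_reads <- function(bins, track_ref, track_alt) {
  len <- bins$end - bins$start
  if (any(len <= 0)) stop("bin length must be positive")
  r <- coverage_sum(track_ref, bins$chrom, bins$start, bins$end)
  a <- coverage_sum(track_alt, bins$chrom, bins$start, bins$end)
  (r * 1e6 / track_ref$library_size - a * 1e6 / track_alt$library_size) / len
}

#' Sample matched constitutive exons
#'
#' For each AS event, samples one constitutive (role `CS`) exon from the
#' same gene, without replacement within a gene while possible (falling
#' back to replacement, which is counted). Genes without any CS exon are
#' skipped with a warning.
#'
#' @param events data.frame with `event_id`, `gene_id`.
#' @param annotation exon table with `gene_id`, `exon_id`, `role`.
#' @param seed integer seed making the draw reproducible.
#' @return data.frame pairing each retained `event_id` with a sampled CS
#'   `exon_id`; attribute `n_skipped` counts skipped events and
#'   `n_replacement` the draws that needed replacement.
#' @export
sample_cs_exons <- function(events, annotation, seed) {
  stopifnot(!missing(seed))
  cs <- annotation[annotation$role == "CS", , drop = FALSE]
  out <- vector("list", length(unique(events$gene_id)))
  n_skip <- 0L; n_repl <- 0L
  with_seed(derive_seed(seed, "sample_cs_exons"), {
    i <- 0L
    for (g in unique(events$gene_id)) {
      ev <- events$event_id[events$gene_id == g]
      pool <- cs$exon_id[cs$gene_id == g]
      if (length(pool) == 0L) {
        n_skip <- n_skip + length(ev)
        next
      }
      if (length(pool) >= length(ev)) {
        pick <- sample(pool, length(ev), replace = FALSE)
      } else {
        pick <- c(sample(pool, length(pool), replace = FALSE),
                  sample(pool, length(ev) - length(pool), replace = TRUE))
        n_repl <- n_repl + (length(ev) - length(pool))
      }
      i <- i + 1L
      out[[i]] <- data.frame(event_id = ev, exon_id = pick,
                             gene_id = g, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out[seq_len(sum(!vapply(out, is.null, logical(1))))])
  if (n_skip > 0L)
    warning(sprintf("%d event(s) skipped: host gene has no CS exon", n_skip))
  if (is.null(res))
    res <- data.frame(event_id = character(), exon_id = character(),
                      gene_id = character())
  attr(res, "n_skipped") <- n_skip
  attr(res, "n_replacement") <- n_repl
  res
}

#' Profile matrix of delta-reads around splice sites
#'
#' Builds the region x bin matrix of depth-normalized delta reads for a set
#' of exons: one row per exon x splice-site side, columns the bins in
#' transcript order.
#'
#' @param exons data.frame with `exon_id`, `chrom`, `start`, `end`,
#'   `strand`, `intron_up_len`, `intron_down_len`.
#' @param track_ref,track_alt `coverage_track` objects.
#' @param scheme a [bin_scheme()].
#' @return list with `delta` (numeric matrix, rownames `exon_id|side`),
#'   `region` (matrix of `"intron"`/`"exon"` labels per column position),
#'   and `long` (long-format data.frame).
#' @export
profile_matrix <- function(exons, track_ref, track_alt,
                           scheme = bin_scheme()) {
  n_bins <- 2L * scheme$short_region_bins
  rows <- vector("list", nrow(exons))
  for (i in seq_len(nrow(exons))) {
    b <- bin_region(exons$chrom[i], exons$start[i], exons$end[i],
                    exons$strand[i], exons$intron_up_len[i],
                    exons$intron_down_len[i], scheme)
    b$delta <- delta_reads(b, track_ref, track_alt)
    b$exon_id <- exons$exon_id[i]
    rows[[i]] <- b
  }
  long <- do.call(rbind, rows)
  key <- paste(long$exon_id, long$side, sep = "|")
  ukey <- unique(key)
  delta <- matrix(NA_real_, nrow = length(ukey), ncol = n_bins,
                  dimnames = list(ukey, paste0("bin", seq_len(n_bins))))
  region <- matrix(NA_character_, nrow = length(ukey), ncol = n_bins,
                   dimnames = dimnames(delta))
  idx <- cbind(match(key, ukey), long$bin)
  delta[idx] <- long$delta
  region[idx] <- long$region
  list(delta = delta, region = region, long = long)
}

# Per-region summary used by the panel test: variance-stabilized net
# change |sum(delta * bin_len)| / sqrt(sum(bin_len)) over the selected
# bins. A per-bin mean of |delta| would be length-biased under the null
# (short exons get short bins, so noisier per-bp differences and larger
# absolute means); the net change scaled by sqrt(region length) has a
# length-free null distribution.
region_summary <- function(pm, bins = c("exon", "intron")) {
  bins <- match.arg(bins)
  long <- pm$long
  sel <- long$region == bins
  len <- (long$end - long$start)[sel]
  key <- paste(long$exon_id, long$side, sep = "|")[sel]
  num <- tapply(long$delta[sel] * len, key, sum)
  den <- tapply(len, key, sum)
  as.numeric(abs(num) / sqrt(den))
}

#' Panel test: do HM changes prefer AS over CS exons?
#'
#' Summarizes each region (exon x side) by the magnitude of its net
#' depth-normalized read change over exonic bins (intronic via
#' `bins = "intron"`), scaled by the square root of the summed bin length
#' so that the null distribution of the summary does not depend on exon
#' length, then compares AS against CS summaries with a two-sided
#' Mann-Whitney test. `preferred` is the class with the larger median
#' summary.
#'
#' @param pm_as,pm_cs profile matrices from [profile_matrix()] for AS and
#'   CS exons.
#' @param bins which bins enter the per-region summary.
#' @return list with `p_value`, `preferred` (`"AS"`/`"CS"`),
#'   `median_as`, `median_cs`, `n_as`, `n_cs`, `underpowered`.
#' @export
profile_panel_test <- function(pm_as, pm_cs, bins = c("exon", "intron")) {
  bins <- match.arg(bins)
  s_as <- region_summary(pm_as, bins)
  s_cs <- region_summary(pm_cs, bins)
  underpowered <- length(s_as) < 3L || length(s_cs) < 3L
  if (underpowered) {
    p <- 1
  } else if (all(s_as == s_as[1L]) && all(s_cs == s_cs[1L]) &&
             s_as[1L] == s_cs[1L]) {
    p <- 1
  } else {
    p <- suppressWarnings(wilcox.test(s_as, s_cs)$p.value)
  }
  list(p_value = p,
       preferred = if (median(s_as) >= median(s_cs)) "AS" else "CS",
       median_as = median(s_as), median_cs = median(s_cs),
       n_as = length(s_as), n_cs = length(s_cs),
       underpowered = underpowered)
}

#' Link strength of one HM across lineages and AS types
#'
#' Measures whether an HM's changes consistently prefer AS exons: the
#' panels (lineage x AS type) of the focal HM, split into AS-preferred vs
#' CS-preferred, are compared against the pooled split of all other HMs'
#' panels with a two-sided Fisher exact test; the link strength is
#' `-log10(p)`.
#'
#' @param panels data.frame with columns `hm`, `preferred` (one row per
#'   panel; at least two HMs present).
#' @param hm the focal HM name.
#' @return list with the 2x2 `table`, `p_value`, `link_strength`.
#' @export
link_strength <- function(panels, hm) {
  if (!hm %in% panels$hm) stop(sprintf("no panels for HM '%s'", hm))
  if (length(unique(panels$hm)) < 2L)
    stop("link strength needs panels from at least two HMs")
  focal <- panels$hm == hm
  tab <- matrix(c(sum(focal & panels$preferred == "AS"),
                  sum(focal & panels$preferred == "CS"),
                  sum(!focal & panels$preferred == "AS"),
                  sum(!focal & panels$preferred == "CS")),
                2, 2, byrow = TRUE,
                dimnames = list(hm = c(hm, "others"),
                                preferred = c("AS", "CS")))
  p <- fisher.test(tab)$p.value
  list(table = tab, p_value = p, link_strength = -log10(p))
}
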