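# Shared builders for small in-code fixtures.

# A one-comparison junction-count table, two replicates per cell with the
# given pooled counts split evenly.
make_counts <- function(event_id, type, I_ref, S_ref, I_alt, S_alt,
                        ref = "H1", alt = "MSC", len_I = 1, len_S = 1) {
  rows <- list()
  for (i in seq_along(event_id)) {
    for (cell in c(ref, alt)) {
      I <- if (cell == ref) I_ref[i] else I_alt[i]
      S <- if (cell == ref) S_ref[i] else S_alt[i]
      half_I <- I %/% 2
      half_S <- S %/% 2
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = event_id[i], type = type[i], gene_id = paste0("g", i),
        cell = cell, replicate = 1:2,
        I = c(half_I, I - half_I), S = c(half_S, S - half_S),
        len_I = len_I, len_S = len_S, exon = "target")
    }
  }
  do.call(rbind, rows)
}

# A coverage track from parallel vectors.
make_track <- function(start, end, value, lib, chrom = "chr1") {
  coverage_track(data.frame(chrom = chrom, start = start, end = end,
                            value = value), library_size = lib)
}

# A small profile-matrix object whose per-region exonic summaries are
# exactly `summaries` (single exonic bin of width 1 per region).
pm_from_summaries <- function(summaries, ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(summaries))
  long <- data.frame(chrom = "chr1", start = 0L, end = 1L, side = "ss3",
                     region = "exon", bin = 1L, delta = summaries,
                     exon_id = ids)
  list(delta = matrix(summaries, ncol = 1,
                      dimnames = list(paste0(ids, "|ss3"), "bin1")),
       region = matrix("exon", length(ids), 1,
                       dimnames = list(paste0(ids, "|ss3"), "bin1")),
       long = long)
}

# Fast default-shape simulation at reduced size.
small_sim_config <- function(seed, ...) {
  sim_config(n_genes = 150L, exons_per_gene = c(5L, 8L), seed = seed, ...)
}
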