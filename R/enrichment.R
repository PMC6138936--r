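## expression_enrichment: FPKM handling, fold-change DEG calls, isoform
## relative expression, and generic hypergeometric gene-set enrichment.

#' FPKM from raw counts
#'
#' `counts * 1e9 / (length_bp * total_reads)` — fragments per kilobase of
#' feature per million mapped reads. Provided as a helper; FPKM tables are
#' the primary input.
#'
#' @param counts,length_bp,total_reads numeric vectors/scalars.
#' @return numeric FPKM vector.
#' @export
fpkm_from_counts <- function(counts, length_bp, total_reads) {
  if (any(length_bp <= 0) || any(total_reads <= 0))
    stop("length_bp and total_reads must be positive")
  counts * 1e9 / (length_bp * total_reads)
}

#' Call differentially expressed genes by fold change
#'
#' The universe is restricted to genes expressed (`fpkm >= min_fpkm`) in
#' at least one of the two cells. A gene is a DEG when
#' `max(fc, 1/fc) > fc_threshold`, with `fc = (fpkm_alt + pseudocount) /
#' (fpkm_ref + pseudocount)`; the pseudocount guards zero FPKM. The call
#' is direction-symmetric: swapping the two cells returns the same set.
#'
#' @param expr data.frame with columns `gene_id`, `cell`, `fpkm`.
#' @param ref_cell,alt_cell cell labels.
#' @param fc_threshold fold-change cutoff (default 2, strict).
#' @param min_fpkm expression filter for the universe (default 1).
#' @param pseudocount added to both FPKMs (default 0.1).
#' @return list with `degs` (character vector) and `universe`.
#' @export
deg_call <- function(expr, ref_cell, alt_cell, fc_threshold = 2,
                     min_fpkm = 1, pseudocount = 0.1) {
  r <- expr[expr$cell == ref_cell, ]
  a <- expr[expr$cell == alt_cell, ]
  if (nrow(r) == 0L || nrow(a) == 0L)
    stop("both cells must be present in the expression table")
  genes <- intersect(r$gene_id, a$gene_id)
  fr <- setNames(r$fpkm, r$gene_id)[genes]
  fa <- setNames(a$fpkm, a$gene_id)[genes]
  universe <- genes[fr >= min_fpkm | fa >= min_fpkm]
  fc <- (fa[universe] + pseudocount) / (fr[universe] + pseudocount)
  degs <- universe[pmax(fc, 1 / fc) > fc_threshold]
  list(degs = unname(degs), universe = unname(universe))
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test `P(X >= overlap)` of a query gene set
#' against a gene set within a background universe. The gene set is first
#' intersected with the background.
#'
#' @param query character vector (must be a subset of `background`).
#' @param gene_set character vector.
#' @param background character vector (the universe).
#' @param adjust `"none"`, `"bonferroni"` or `"bh"`; with `n_tests` the
#'   number of parallel tests the adjustment is for.
#' @param n_tests number of tests for the adjustment (default 1).
#' @return data.frame with sizes, `overlap`, `p_value`, `p_adjusted`,
#'   `adjust_method`.
#' @export
hypergeom_enrich <- function(query, gene_set, background,
                             adjust = c("none", "bonferroni", "bh"),
                             n_tests = 1L) {
  adjust <- match.arg(adjust)
  off <- setdiff(query, background)
  if (length(off) > 0L)
    stop("query genes outside background: ",
         paste(head(off, 5), collapse = ", "))
  set_in_bg <- intersect(gene_set, background)
  ov <- length(intersect(query, set_in_bg))
  N <- length(unique(background))
  K <- length(set_in_bg)
  n <- length(unique(query))
  p <- if (K == 0L || n == 0L) 1 else
    phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
  p_adj <- switch(adjust,
                  none = p,
                  bonferroni = min(1, p * n_tests),
                  bh = p) # BH over one value equals the value
  data.frame(query_size = n, background_size = N, set_size = K,
             overlap = ov, p_value = p, p_adjusted = p_adj,
             adjust_method = adjust)
}

#' Relative expression of isoforms of one gene
#'
#' Each isoform's FPKM divided by the gene's total FPKM.
#'
#' @param fpkms numeric vector of isoform FPKMs (length >= 2).
#' @return fractions summing to 1, or all-`NA` when the total is 0.
#' @export
isoform_relative_expression <- function(fpkms) {
  if (length(fpkms) < 2L) stop("need at least two isoforms")
  if (any(fpkms < 0)) stop("negative FPKM")
  total <- sum(fpkms)
  if (total == 0) return(rep(NA_real_, length(fpkms)))
  fpkms / total
}
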