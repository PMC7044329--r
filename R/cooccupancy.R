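# Peak filtering and TSS-proximal co-occupancy analysis.
#
# Peaks arrive as BED6+ records with a significance score (a q-value on the
# probability scale or -log10 of it). A gene counts as occupied by a factor
# when at least one retained peak touches the closed window
# [tss - window_bp, tss + window_bp]; co-occupancy across factors is an
# exclusive Venn partition of the per-factor gene sets.

#' Filter peaks by q-value
#'
#' Retains peaks with q < `q_max`. Scores can be probabilities ("q") or
#' -log10-transformed q-values ("neg_log10", as emitted by common peak
#' callers), declared via `score_scale`.
#'
#' @param peaks data.frame of intervals with a `score` column (see
#'   [read_bed()]).
#' @param q_max retention threshold on the probability scale (default 1e-4).
#' @param score_scale "q" or "neg_log10".
#' @return The retained subset of `peaks`.
#' @export
filter_peaks <- function(peaks, q_max = 1e-4,
                         score_scale = c("q", "neg_log10")) {
  score_scale <- match.arg(score_scale)
  if (is.null(peaks$score) || (nrow(peaks) > 0 && all(is.na(peaks$score)))) {
    abort("peaks lack a score column")
  }
  q <- if (score_scale == "neg_log10") 10^(-peaks$score) else peaks$score
  peaks[!is.na(q) & q < q_max, , drop = FALSE]
}

#' Genes with a peak near their transcription start site
#'
#' A gene is returned when at least one peak interval intersects the closed
#' window `[tss - window_bp, tss + window_bp]` on the same chromosome
#' (strand-independent distance from the TSS point; the boundary base is
#' included).
#'
#' @param peaks data.frame of peak intervals.
#' @param genes a `gene_table`.
#' @param window_bp window half-width in bases (default 1000).
#' @return Character vector of gene ids.
#' @export
tss_proximal_genes <- function(peaks, genes, window_bp = 1000) {
  if (window_bp <= 0) abort("window_bp must be positive")
  tss <- gene_tss(genes)
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    sel <- peaks$chrom == genes$chrom[i]
    if (!any(sel)) return(FALSE)
    # half-open peak [s, e) touches closed [tss - w, tss + w]
    any(peaks$start[sel] <= tss[i] + window_bp &
          peaks$end[sel] - 1 >= tss[i] - window_bp)
  }, logical(1))
  genes$gene_id[hit]
}

#' Co-occupied genes across factors
#'
#' @param gene_sets named list (>= 2 factors) of gene-id vectors.
#' @return list(intersection = gene ids present in every set,
#'   venn = exclusive partition counts from [venn_partition()]).
#' @export
cooccupied_genes <- function(gene_sets) {
  if (length(gene_sets) < 2L) abort("co-occupancy needs >= 2 factors")
  list(intersection = sort(Reduce(intersect, gene_sets)),
       venn = venn_partition(gene_sets))
}
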