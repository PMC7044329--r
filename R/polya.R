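# Dual-library aberrant-polyadenylation calling.
#
# Normally non-polyadenylated transcripts (replication-dependent histone
# mRNAs, snRNAs) that fail 3'-end processing acquire a poly(A) tail from a
# downstream polyadenylation signal. Such transcripts look strongly
# "upregulated" in polyA-selected RNA-seq while being unchanged or reduced in
# ribo-depleted libraries, which see polyadenylated and non-polyadenylated
# RNA alike. The caller classifies each transcript from a pair of
# differential results (perturbation vs control) per library type.

#' Default thresholds for polyadenylation calls
#'
#' @param up_log2fc_min minimum polyA-selected log2 fold change to count as
#'   up (default 1.5).
#' @param fdr_max maximum FDR in the polyA-selected library (default 0.05).
#' @param ribo_not_up_log2fc_max maximum ribo-depleted log2 fold change still
#'   considered "unchanged or reduced" (default 0).
#' @return list of class `call_thresholds`.
#' @export
call_thresholds <- function(up_log2fc_min = 1.5, fdr_max = 0.05,
                            ribo_not_up_log2fc_max = 0) {
  if (up_log2fc_min <= 0) abort("up_log2fc_min must be positive")
  if (fdr_max < 0 || fdr_max > 1) abort("fdr_max must be in [0, 1]")
  structure(list(up_log2fc_min = up_log2fc_min, fdr_max = fdr_max,
                 ribo_not_up_log2fc_max = ribo_not_up_log2fc_max),
            class = "call_thresholds")
}

#' Simple two-group differential expression on a count matrix
#'
#' Declared plumbing standing in for a negative-binomial GLM analysis:
#' log2 fold change of mean counts-per-million (pseudocount added to counts),
#' a two-sample pooled-variance t test on per-sample log2 CPM, and
#' Benjamini-Hochberg FDR across transcripts. All-zero transcripts are
#' reported with log2_fc = 0 and fdr = 1.
#'
#' @param counts non-negative integer matrix, transcripts x samples, with
#'   rownames as transcript ids.
#' @param group_labels per-sample labels with exactly two levels and at least
#'   two replicates each; the FIRST level (factor order) is the reference.
#' @param pseudocount added to counts before CPM (default 0.5).
#' @return data.frame with transcript_id, log2_fc, p_value, fdr.
#' @export
simple_differential <- function(counts, group_labels, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  g <- factor(group_labels)
  if (nlevels(g) != 2L) abort("exactly two groups required")
  if (any(table(g) < 2L)) abort("each group needs >= 2 replicates")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("t%04d", seq_len(nrow(counts)))
  }
  libsize <- colSums(counts)
  cpm <- t(t(counts + pseudocount) / (libsize + 2 * pseudocount)) * 1e6
  lcpm <- log2(cpm)
  ref <- g == levels(g)[1L]
  alt <- !ref
  m1 <- rowMeans(lcpm[, ref, drop = FALSE])
  m2 <- rowMeans(lcpm[, alt, drop = FALSE])
  n1 <- sum(ref); n2 <- sum(alt)
  v1 <- apply(lcpm[, ref, drop = FALSE], 1L, stats::var)
  v2 <- apply(lcpm[, alt, drop = FALSE], 1L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  # degenerate rows: zero pooled variance
  p[se == 0 & m1 == m2] <- 1
  p[se == 0 & m1 != m2] <- 0
  lfc <- log2(rowMeans(cpm[, alt, drop = FALSE])) -
    log2(rowMeans(cpm[, ref, drop = FALSE]))
  allzero <- rowSums(counts) == 0
  lfc[allzero] <- 0
  p[allzero] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  fdr[allzero] <- 1
  data.frame(transcript_id = rownames(counts), log2_fc = unname(lfc),
             p_value = unname(p), fdr = unname(fdr),
             stringsAsFactors = FALSE)
}

#' Classify transcripts from paired dual-library differential results
#'
#' A transcript is called `aberrant_polyA` when it is up in the
#' polyA-selected library (log2 FC >= `up_log2fc_min` and
#' FDR <= `fdr_max`) but unchanged or reduced in the ribo-depleted library
#' (log2 FC <= `ribo_not_up_log2fc_max`); `concordant_up` when it passes the
#' up rule in both libraries; otherwise `not_called`. Transcripts missing a
#' library are excluded (counted in attribute `n_excluded`).
#'
#' @param records data.frame with columns transcript_id, library_type
#'   ("polyA_selected" or "ribo_depleted"), log2_fc, fdr.
#' @param thresholds a [call_thresholds()] object.
#' @return data.frame (class `polya_calls`) with transcript_id, call,
#'   polya_log2_fc, ribo_log2_fc, polya_fdr.
#' @export
call_aberrant_polyadenylation <- function(records,
                                          thresholds = call_thresholds()) {
  need <- c("transcript_id", "library_type", "log2_fc", "fdr")
  if (!all(need %in% names(records))) {
    abort("records need columns: %s", paste(need, collapse = ", "))
  }
  bad <- !records$library_type %in% c("polyA_selected", "ribo_depleted")
  if (any(bad)) abort("unknown library_type: %s",
                      paste(unique(records$library_type[bad]), collapse = ", "))
  pa <- records[records$library_type == "polyA_selected", ]
  rd <- records[records$library_type == "ribo_depleted", ]
  if (anyDuplicated(pa$transcript_id) || anyDuplicated(rd$transcript_id)) {
    abort("one record per (transcript, library_type) required")
  }
  ids <- intersect(pa$transcript_id, rd$transcript_id)
  n_excluded <- length(union(pa$transcript_id, rd$transcript_id)) - length(ids)
  i_pa <- match(ids, pa$transcript_id)
  i_rd <- match(ids, rd$transcript_id)
  up_pa <- pa$log2_fc[i_pa] >= thresholds$up_log2fc_min &
    pa$fdr[i_pa] <= thresholds$fdr_max
  up_rd <- rd$log2_fc[i_rd] >= thresholds$up_log2fc_min &
    rd$fdr[i_rd] <= thresholds$fdr_max
  not_up_rd <- rd$log2_fc[i_rd] <= thresholds$ribo_not_up_log2fc_max
  call <- rep("not_called", length(ids))
  call[up_pa & up_rd] <- "concordant_up"
  call[up_pa & not_up_rd] <- "aberrant_polyA"
  out <- data.frame(transcript_id = ids, call = call,
                    polya_log2_fc = pa$log2_fc[i_pa],
                    ribo_log2_fc = rd$log2_fc[i_rd],
                    polya_fdr = pa$fdr[i_pa], stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("polya_calls", "data.frame")
  out
}

#' Exclusive Venn partition of a family of sets
#'
#' For k named sets, counts every one of the 2^k - 1 exclusive membership
#' regions (elements in exactly that combination of sets). Counts sum to the
#' size of the union.
#'
#' @param sets named list of vectors.
#' @return data.frame with columns region (set names joined by "&"), count.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 1L || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("venn_partition needs a named list of sets")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(combos) <- names(sets)
  region <- apply(combos, 1L, function(z) paste(names(sets)[z], collapse = "&"))
  count <- apply(combos, 1L, function(z) {
    if (length(universe) == 0L) return(0L)
    sum(apply(memb, 1L, function(m) all(m == z)))
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE)
}

#' Knockdown set logic: genes up in some conditions but not others
#'
#' Returns the transcripts present in every `include` condition's up-set and
#' absent from every `exclude` condition's, plus the full exclusive Venn
#' partition of all up-sets.
#'
#' @param up_sets named list of transcript-id vectors, one per condition.
#' @param include condition names whose up-sets are intersected.
#' @param exclude condition names whose up-sets are subtracted.
#' @return list(selected = character vector, venn = data.frame).
#' @export
knockdown_set_logic <- function(up_sets, include, exclude = character(0)) {
  unknown <- setdiff(c(include, exclude), names(up_sets))
  if (length(unknown)) abort("unknown condition(s): %s",
                             paste(unknown, collapse = ", "))
  if (length(include) == 0L) abort("at least one include condition required")
  sel <- Reduce(intersect, up_sets[include])
  if (length(exclude)) {
    sel <- setdiff(sel, unique(unlist(up_sets[exclude], use.names = FALSE)))
  }
  list(selected = sort(sel), venn = venn_partition(up_sets))
}
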