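# Read-through ratio statistics at the 3' end of genes and their
# between-condition comparison.
#
# Two statistics are defined per gene, both strand-aware and computed on
# exact per-base interval sums:
#   * proseq: sum of nascent 3'-end signal over [TES+500, TES+1000)
#             divided by the sum over [TES-50, TES)       (transcript coords)
#   * polii:  sum of occupancy over [TES, TES+1000)
#             divided by the sum over [TSS, TES+1000); valid values lie in
#             [0, 1] because the numerator window is nested in the
#             denominator window.
# Both ratios are invariant under global scaling of the track, so spike-in
# normalization cannot change them.

#' Window parameters for the read-through statistics
#'
#' @param pro_down_start,pro_down_end downstream window for the nascent
#'   statistic, default `[500, 1000)` bases past the TES.
#' @param pro_up_len length of the upstream (denominator) window ending at
#'   the TES, default 50 bases.
#' @param pol_down_len downstream extent of both polymerase-occupancy
#'   windows, default 1000 bases.
#' @return list of class `readthrough_params`.
#' @export
readthrough_params <- function(pro_down_start = 500, pro_down_end = 1000,
                               pro_up_len = 50, pol_down_len = 1000) {
  if (!(pro_down_start >= 0 && pro_down_start < pro_down_end)) {
    abort("need 0 <= pro_down_start < pro_down_end")
  }
  if (pro_up_len <= 0 || pol_down_len <= 0) {
    abort("pro_up_len and pol_down_len must be positive")
  }
  structure(list(pro_down_start = pro_down_start, pro_down_end = pro_down_end,
                 pro_up_len = pro_up_len, pol_down_len = pol_down_len),
            class = "readthrough_params")
}

# one gene, one statistic -> named list (internal workhorse)
readthrough_one <- function(track, gene, statistic, params) {
  if (statistic == "proseq") {
    num_win <- strand_window(gene, params$pro_down_start, params$pro_down_end,
                             anchor = "tes")
    den_win <- strand_window(gene, -params$pro_up_len, 0, anchor = "tes")
    qstrand <- gene$strand
  } else {
    len <- gene$end - gene$start
    num_win <- strand_window(gene, 0, params$pol_down_len, anchor = "tes")
    den_win <- strand_window(gene, -len, params$pol_down_len, anchor = "tes")
    qstrand <- "."               # Pol II ChIP signal is not strand-resolved
  }
  if (!window_in_bounds(num_win, track$chrom_sizes) ||
      !window_in_bounds(den_win, track$chrom_sizes)) {
    return(list(numerator = NA_real_, denominator = NA_real_,
                ratio = NA_real_, valid = FALSE,
                invalid_reason = "window_out_of_bounds"))
  }
  num <- interval_sum(track, num_win$chrom, num_win$start, num_win$end, qstrand)
  den <- interval_sum(track, den_win$chrom, den_win$start, den_win$end, qstrand)
  if (den <= 0) {
    return(list(numerator = num, denominator = den, ratio = NA_real_,
                valid = FALSE, invalid_reason = "zero_denominator"))
  }
  list(numerator = num, denominator = den, ratio = num / den,
       valid = TRUE, invalid_reason = "none")
}

#' Nascent-transcription read-through ratio for one gene
#'
#' Signal 500-1000 bases downstream of the TES divided by signal in the 50
#' bases immediately upstream of the TES, on the gene's strand.
#'
#' @param track strand-specific `coverage_track` of nascent 3'-end counts.
#' @param gene one-row `gene_table`.
#' @param params a [readthrough_params()] object.
#' @return list with numerator, denominator, ratio, valid, invalid_reason.
#' @export
proseq_readthrough_ratio <- function(track, gene,
                                     params = readthrough_params()) {
  readthrough_one(track, gene, "proseq", params)
}

#' Polymerase-occupancy read-through ratio for one gene
#'
#' Occupancy from TES to 1000 bases downstream divided by occupancy from the
#' TSS to 1000 bases downstream of the TES (both strands summed, since the
#' occupancy assay is unstranded). Valid ratios lie in `[0, 1]`.
#'
#' @inheritParams proseq_readthrough_ratio
#' @export
polii_readthrough_ratio <- function(track, gene,
                                    params = readthrough_params()) {
  readthrough_one(track, gene, "polii", params)
}

#' Compute a read-through statistic for every gene in a table
#'
#' @param track a `coverage_track`.
#' @param genes a `gene_table`.
#' @param statistic "proseq" or "polii".
#' @param params a [readthrough_params()] object.
#' @return data.frame (class `readthrough_result`) with one row per gene:
#'   gene_id, gene_class, statistic, numerator, denominator, ratio, valid,
#'   invalid_reason.
#' @export
readthrough_ratios <- function(track, genes,
                               statistic = c("proseq", "polii"),
                               params = readthrough_params()) {
  statistic <- match.arg(statistic)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    readthrough_one(track, genes[i, ], statistic, params)
  })
  out <- data.frame(
    gene_id = genes$gene_id,
    gene_class = genes$gene_class,
    statistic = statistic,
    numerator = vapply(rows, `[[`, 0, "numerator"),
    denominator = vapply(rows, `[[`, 0, "denominator"),
    ratio = vapply(rows, `[[`, 0, "ratio"),
    valid = vapply(rows, `[[`, TRUE, "valid"),
    invalid_reason = vapply(rows, `[[`, "", "invalid_reason"),
    stringsAsFactors = FALSE)
  class(out) <- c("readthrough_result", "data.frame")
  out
}

# Tukey box-plot summary: quartiles by linear interpolation, whiskers at the
# most extreme data point within 1.5 * IQR of the quartiles.
box_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - 1.5 * iqr
  hi_lim <- q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(x[x >= lo_lim]),
       whisker_high = max(x[x <= hi_lim]))
}

#' Compare read-through ratio distributions between two conditions
#'
#' For one gene class, summarizes both conditions' valid ratios as box-plot
#' statistics (median, quartiles, 1.5 * IQR whiskers) and tests the
#' difference with a two-sided pooled-variance (Student's) t test. Invalid
#' genes are excluded and counted. Optionally tests on `log2(ratio + eps)`.
#'
#' @param results_a,results_b `readthrough_result` tables from the two
#'   conditions, computed with identical parameters.
#' @param gene_class class to compare ("histone", "snRNA_snoRNA",
#'   "protein_coding" or "other").
#' @param log2_transform test on log2(ratio + epsilon) instead of raw ratios.
#' @param epsilon offset used by the log transform.
#' @return list of class `readthrough_comparison`.
#' @export
compare_groups <- function(results_a, results_b, gene_class,
                           log2_transform = FALSE, epsilon = 1e-3) {
  pick <- function(res) {
    sel <- res$gene_class == gene_class
    list(x = res$ratio[sel & res$valid], n_excluded = sum(sel & !res$valid))
  }
  a <- pick(results_a)
  b <- pick(results_b)
  if (length(a$x) < 2L || length(b$x) < 2L) {
    abort("fewer than 2 valid genes of class '%s' in a condition (%d vs %d)",
          gene_class, length(a$x), length(b$x))
  }
  ta <- if (log2_transform) log2(a$x + epsilon) else a$x
  tb <- if (log2_transform) log2(b$x + epsilon) else b$x
  tt <- stats::t.test(ta, tb, var.equal = TRUE)
  structure(list(gene_class = gene_class,
                 n = c(a = length(a$x), b = length(b$x)),
                 n_excluded = c(a = a$n_excluded, b = b$n_excluded),
                 box_a = box_stats(a$x), box_b = box_stats(b$x),
                 log2_transform = log2_transform,
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value),
            class = "readthrough_comparison")
}

#' @export
print.readthrough_comparison <- function(x, ...) {
  cat(sprintf("Read-through comparison, class %s (n = %d vs %d, excluded %d/%d)\n",
              x$gene_class, x$n[["a"]], x$n[["b"]],
              x$n_excluded[["a"]], x$n_excluded[["b"]]))
  cat(sprintf("  median a = %.4g, median b = %.4g\n",
              x$box_a$median, x$box_b$median))
  cat(sprintf("  Student's t = %.4g (df = %g), two-sided p = %.4g%s\n",
              x$t_statistic, x$df, x$p_value,
              if (x$log2_transform) " [log2 scale]" else ""))
  invisible(x)
}

#' Scale a coverage track by spike-in totals
#'
#' Multiplies every value by `reference_spike_signal / sample_spike_signal`.
#' Because both read-through ratios are scale-invariant, this normalization
#' can change absolute coverage but never a ratio.
#'
#' @param track a `coverage_track`.
#' @param sample_spike_signal,reference_spike_signal positive spike-in totals.
#' @return The rescaled `coverage_track`.
#' @export
spike_in_scale <- function(track, sample_spike_signal,
                           reference_spike_signal) {
  if (sample_spike_signal <= 0 || reference_spike_signal <= 0) {
    abort("spike-in totals must be positive")
  }
  k <- reference_spike_signal / sample_spike_signal
  for (s in names(track$cov)) {
    track$cov[[s]] <- lapply(track$cov[[s]], function(r) r * k)
  }
  track
}
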