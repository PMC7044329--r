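# qPCR-derived statistics: unprocessed-transcript fraction (2^-dCt) and
# ChIP percent-of-input, with per-replicate pairing and condition tests.
#
# Assumes amplification efficiency 2 (one doubling per cycle), so a Ct
# difference of d corresponds to a 2^-d abundance ratio. Ratios are computed
# per paired replicate, then summarized.

#' Read a tidy Ct table
#'
#' @param path tab-separated file with header and columns sample, condition,
#'   target, amplicon, replicate, ct. Amplicons are UT (unprocessed
#'   transcript), CT (coding transcript), chip_ip or chip_input.
#' @return data.frame of Ct measurements.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) abort("Ct table not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "condition", "target", "amplicon", "replicate", "ct")
  if (!all(need %in% names(df))) {
    abort("Ct table needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(df$ct <= 0)) abort("Ct values must be positive")
  df
}

# pair two amplicons of one (condition, target) by replicate index (internal)
paired_ct <- function(ct_table, condition, target, amp_a, amp_b) {
  sel <- ct_table$condition == condition & ct_table$target == target
  a <- ct_table[sel & ct_table$amplicon == amp_a, ]
  b <- ct_table[sel & ct_table$amplicon == amp_b, ]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    abort("missing amplicon %s or %s for (%s, %s)", amp_a, amp_b,
          condition, target)
  }
  reps <- sort(intersect(a$replicate, b$replicate))
  if (length(reps) != nrow(a) || length(reps) != nrow(b)) {
    abort("unpaired replicates for (%s, %s): %d %s vs %d %s", condition,
          target, nrow(a), amp_a, nrow(b), amp_b)
  }
  list(a = a$ct[match(reps, a$replicate)], b = b$ct[match(reps, b$replicate)],
       replicates = reps)
}

new_relative_level <- function(condition, target, ratios) {
  structure(list(condition = condition, target = target, ratios = ratios,
                 mean = mean(ratios),
                 sd = if (length(ratios) > 1L) stats::sd(ratios) else NA_real_,
                 n = length(ratios)),
            class = "relative_level")
}

#' @export
print.relative_level <- function(x, ...) {
  cat(sprintf("%s / %s: mean = %.4g, sd = %.4g, n = %d\n", x$condition,
              x$target, x$mean, x$sd, x$n))
  invisible(x)
}

#' Unprocessed-transcript fraction from paired UT/CT amplicons
#'
#' Per replicate i, dCt_i = Ct(UT)_i - Ct(CT)_i and ratio_i = 2^-dCt_i, the
#' relative level of transcripts reading through the 3'-end processing site
#' versus total coding transcript.
#'
#' @param ct_table tidy Ct table (see [read_ct_table()]).
#' @param condition,target the condition and target gene to summarize.
#' @return A `relative_level`: per-replicate ratios, mean, sd, n.
#' @export
unprocessed_fraction <- function(ct_table, condition, target) {
  p <- paired_ct(ct_table, condition, target, "UT", "CT")
  new_relative_level(condition, target, 2^-(p$a - p$b))
}

#' ChIP enrichment as percent of input
#'
#' Per replicate: `100 * 2^((Ct_input - input_dilution_log2) - Ct_IP)`. The
#' dilution term corrects for input measured on a diluted aliquot (log2 of
#' the dilution factor; 0 for undiluted input).
#'
#' @inheritParams unprocessed_fraction
#' @param input_dilution_log2 log2 of the input dilution factor (default 0).
#' @return A `relative_level` of percent-input values.
#' @export
chip_percent_input <- function(ct_table, condition, target,
                               input_dilution_log2 = 0) {
  p <- paired_ct(ct_table, condition, target, "chip_ip", "chip_input")
  pct <- 100 * 2^((p$b - input_dilution_log2) - p$a)
  new_relative_level(condition, target, pct)
}

#' Student's t test between two conditions' replicate levels
#'
#' Two-sided pooled-variance t test on per-replicate ratio values.
#'
#' @param levels_a,levels_b `relative_level` objects or numeric vectors of
#'   per-replicate values (n >= 2 each).
#' @return list(t, df, p).
#' @export
condition_ttest <- function(levels_a, levels_b) {
  xa <- if (inherits(levels_a, "relative_level")) levels_a$ratios else levels_a
  xb <- if (inherits(levels_b, "relative_level")) levels_b$ratios else levels_b
  if (length(xa) < 2L || length(xb) < 2L) {
    abort("condition_ttest needs n >= 2 per condition")
  }
  tt <- stats::t.test(xa, xb, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
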