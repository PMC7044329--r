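# Gene annotation, peak and strand-split coverage I/O, plus the
# strand-aware coordinate algebra every windowed statistic depends on.
#
# Conventions: all coordinates are 0-based half-open (BED). For a + strand
# gene tss = start and tes = end; for a - strand gene tss = end and
# tes = start. "Downstream" always means transcript orientation: increasing
# genomic coordinate on +, decreasing on -.

#' Read a two-column chromosome-sizes file
#'
#' @param path tab-separated file with columns chromosome name and length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) abort("chrom-sizes file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric"))
  if (any(df[[2]] <= 0)) abort("non-positive chromosome length in %s", path)
  stats::setNames(df[[2]], df[[1]])
}

#' Write a chromosome-sizes file
#'
#' @param chrom_sizes named numeric vector.
#' @param path output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  writeLines(paste(names(chrom_sizes), format(chrom_sizes, scientific = FALSE,
                                              trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' Read a BED3/BED6 file of genomic intervals
#'
#' Parses records into a data frame of half-open intervals. Malformed lines
#' (fewer than 3 fields, non-integer coordinates, start > end) are reported
#' with their line numbers. Three-column records get strand ".", no name and
#' NA score; extra columns beyond 6 are kept as given in `extra` columns.
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end, name, score, strand
#'   (class `genomic_intervals`).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- character(0)
  if (any(nf < 3)) {
    bad <- c(bad, sprintf("line %d: fewer than 3 fields", lineno[nf < 3]))
  }
  ok <- nf >= 3
  chrom <- vapply(fields, `[`, "", 1L)
  s_raw <- vapply(fields, `[`, "", 2L)
  e_raw <- vapply(fields, `[`, "", 3L)
  start <- suppressWarnings(as.numeric(s_raw))
  end <- suppressWarnings(as.numeric(e_raw))
  nonint <- ok & (is.na(start) | is.na(end) |
                    start != floor(start) | end != floor(end))
  if (any(nonint)) {
    bad <- c(bad, sprintf("line %d: non-integer coordinates", lineno[nonint]))
  }
  rev_coord <- ok & !nonint & (start > end)
  if (any(rev_coord)) {
    bad <- c(bad, sprintf("line %d: start > end", lineno[rev_coord]))
  }
  if (length(bad)) {
    abort("malformed BED records in %s:\n  %s", path,
          paste(bad, collapse = "\n  "))
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[4], ""), NA_character_)
  score <- ifelse(nf >= 5,
                  suppressWarnings(as.numeric(vapply(fields,
                                                     function(f) if (length(f) >= 5) f[5] else NA_character_, ""))),
                  NA_real_)
  strand <- ifelse(nf >= 6, vapply(fields, function(f) if (length(f) >= 6) f[6] else ".", ""), ".")
  if (!all(strand %in% c("+", "-", "."))) {
    badstr <- which(!strand %in% c("+", "-", "."))
    abort("malformed BED records in %s:\n  %s", path,
          paste(sprintf("line %d: invalid strand '%s'",
                        lineno[badstr], strand[badstr]), collapse = "\n  "))
  }
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    score = score, strand = strand,
                    stringsAsFactors = FALSE)
  if (max(nf) > 6) {
    for (j in 7:max(nf)) {
      out[[paste0("extra", j - 6)]] <-
        vapply(fields, function(f) if (length(f) >= j) f[j] else NA_character_, "")
    }
  }
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Write intervals back to BED
#'
#' Emits exactly the columns present (3 or 6+), preserving records so that a
#' read/write/read round trip reproduces the same table.
#'
#' @param intervals data.frame as returned by [read_bed()].
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (all(is.na(intervals$name)) && all(intervals$strand == ".")) {
    lines <- paste(intervals$chrom, fmt_num(intervals$start),
                   fmt_num(intervals$end), sep = "\t")
  } else {
    score <- ifelse(is.na(intervals$score), "0", fmt_num(intervals$score))
    name <- ifelse(is.na(intervals$name), ".", intervals$name)
    lines <- paste(intervals$chrom, fmt_num(intervals$start),
                   fmt_num(intervals$end), name, score, intervals$strand,
                   sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a gene table from a BED file and an optional class map
#'
#' Genes are BED6 records with strictly positive length and strand + or -.
#' The class map is a two-column tab-separated file (gene_id, class) with
#' classes among histone, snRNA_snoRNA, protein_coding, other; unmapped genes
#' default to "other".
#'
#' @param bed_path BED6 gene annotation.
#' @param class_map_path optional two-column gene-class file.
#' @return data.frame (class `gene_table`) with columns gene_id, chrom,
#'   start, end, strand, gene_class.
#' @export
read_genes <- function(bed_path, class_map_path = NULL) {
  iv <- read_bed(bed_path)
  if (any(iv$start >= iv$end)) {
    abort("gene records must have start < end (%d violations in %s)",
          sum(iv$start >= iv$end), bed_path)
  }
  if (any(!iv$strand %in% c("+", "-"))) {
    abort("gene records must be stranded (+/-) in %s", bed_path)
  }
  gene_id <- ifelse(is.na(iv$name), sprintf("gene_%04d", seq_len(nrow(iv))),
                    iv$name)
  cls <- rep("other", nrow(iv))
  if (!is.null(class_map_path)) {
    cm <- utils::read.table(class_map_path, sep = "\t", header = FALSE,
                            colClasses = "character")
    hit <- match(gene_id, cm[[1]])
    cls[!is.na(hit)] <- cm[[2]][hit[!is.na(hit)]]
  }
  gene_table(gene_id, iv$chrom, iv$start, iv$end, iv$strand, cls)
}

#' Construct a gene table in memory
#'
#' @param gene_id,chrom,start,end,strand,gene_class parallel vectors; see
#'   [read_genes()].
#' @return data.frame of class `gene_table`.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand,
                       gene_class = "other") {
  known <- c("histone", "snRNA_snoRNA", "protein_coding", "other")
  gene_class <- rep_len(gene_class, length(gene_id))
  gene_class[!gene_class %in% known] <- "other"
  if (any(start >= end)) abort("gene_table requires start < end")
  if (!all(strand %in% c("+", "-"))) abort("gene strand must be + or -")
  if (anyDuplicated(gene_id)) abort("duplicate gene ids")
  out <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                    start = as.numeric(start), end = as.numeric(end),
                    strand = as.character(strand),
                    gene_class = gene_class, stringsAsFactors = FALSE)
  class(out) <- c("gene_table", "data.frame")
  out
}

#' TSS and TES coordinates of genes
#'
#' The TSS is the 5' boundary in transcript orientation (start for +, end
#' for -); the TES is the annotated 3'-end processing site (end for +, start
#' for -). Both are points on the 0-based half-open scale.
#'
#' @param genes a `gene_table`.
#' @return numeric vector of coordinates.
#' @export
gene_tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end)

#' @rdname gene_tss
#' @export
gene_tes <- function(genes) ifelse(genes$strand == "+", genes$end, genes$start)

# ---- coverage tracks -------------------------------------------------------

#' Create an empty strand-split coverage track
#'
#' A coverage track stores one non-negative per-base signal vector (as an
#' S4Vectors run-length encoding) per chromosome and strand. Positions not
#' covered by any record read 0.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(chrom_sizes) {
  empty <- lapply(chrom_sizes, function(n) S4Vectors::Rle(0, n))
  structure(list(cov = list(`+` = empty, `-` = empty),
                 chrom_sizes = chrom_sizes),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  tot_p <- sum(vapply(x$cov[["+"]], sum, 0))
  tot_m <- sum(vapply(x$cov[["-"]], sum, 0))
  cat(sprintf("coverage_track: %d chromosome(s), total signal + %.6g / - %.6g\n",
              length(x$chrom_sizes), tot_p, tot_m))
  invisible(x)
}

# parse one bedGraph file into a list of per-chromosome Rles
read_bedgraph_one <- function(path, chrom_sizes) {
  if (!file.exists(path)) abort("bedGraph file not found: %s", path)
  empty <- lapply(chrom_sizes, function(n) S4Vectors::Rle(0, n))
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(df) || nrow(df) == 0L) return(empty)
  if (any(df$value < 0)) abort("negative coverage value in %s", path)
  unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
  if (length(unknown)) abort("unknown chromosome(s) in %s: %s", path,
                             paste(unknown, collapse = ", "))
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$end > chrom_sizes[[ch]]) || any(d$start < 0)) {
      abort("record outside chromosome bounds on %s in %s", ch, path)
    }
    if (any(d$start > d$end)) abort("start > end on %s in %s", ch, path)
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
      abort("overlapping bedGraph records on %s in %s", ch, path)
    }
    # interleave zero gaps between sorted non-overlapping records
    gaps <- c(d$start, chrom_sizes[[ch]]) - c(0, d$end)
    vals <- c(rbind(0, c(d$value, 0)))          # gap, record, gap, record ...
    lens <- c(rbind(gaps, c(d$end - d$start, 0)))
    keep <- lens > 0
    empty[[ch]] <- S4Vectors::Rle(vals[keep], lens[keep])
  }
  empty
}

#' Read a strand-split bedGraph pair into a coverage track
#'
#' Each file holds non-overlapping half-open records `chrom start end value`
#' for one strand. Bases not covered by any record read 0.
#'
#' @param plus_path bedGraph for the + strand.
#' @param minus_path bedGraph for the - strand (NULL for an unstranded track,
#'   which is stored entirely on +).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return A `coverage_track`.
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, chrom_sizes) {
  trk <- coverage_track(chrom_sizes)
  trk$cov[["+"]] <- read_bedgraph_one(plus_path, chrom_sizes)
  if (!is.null(minus_path)) {
    trk$cov[["-"]] <- read_bedgraph_one(minus_path, chrom_sizes)
  }
  trk
}

# write one strand of a track as bedGraph (zero runs omitted)
write_bedgraph_one <- function(rles, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(rles)) {
    r <- rles[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)
    vals <- S4Vectors::runValue(r)
    nz <- vals != 0
    if (!any(nz)) next
    writeLines(paste(ch,
                     format(starts[nz], scientific = FALSE, trim = TRUE),
                     format(ends[nz], scientific = FALSE, trim = TRUE),
                     format(vals[nz], scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write a coverage track as a strand-split bedGraph pair
#'
#' @param track a `coverage_track`.
#' @param plus_path,minus_path output paths (minus_path may be NULL).
#' @export
write_bedgraph_pair <- function(track, plus_path, minus_path = NULL) {
  write_bedgraph_one(track$cov[["+"]], plus_path)
  if (!is.null(minus_path)) write_bedgraph_one(track$cov[["-"]], minus_path)
  invisible(track)
}

#' Exact signal sum over a half-open genomic interval
#'
#' @param track a `coverage_track`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds (clipped to the chromosome).
#' @param strand "+", "-" or "." (both strands summed).
#' @return The sum of per-base values over `[start, end)`.
#' @export
interval_sum <- function(track, chrom, start, end, strand = ".") {
  if (!chrom %in% names(track$chrom_sizes)) {
    abort("unknown chromosome: %s", chrom)
  }
  if (start > end) abort("interval_sum requires start <= end")
  n <- track$chrom_sizes[[chrom]]
  start <- max(0, start)
  end <- min(n, end)
  if (start >= end) return(0)
  strands <- if (strand == ".") c("+", "-") else strand
  tot <- 0
  for (s in strands) {
    tot <- tot + sum(S4Vectors::window(track$cov[[s]][[chrom]],
                                       start = start + 1L, end = end))
  }
  tot
}

# add integer event counts at 0-based positions onto one strand (internal)
add_events <- function(track, chrom, positions, strand) {
  counts <- tabulate(positions + 1L, nbins = track$chrom_sizes[[chrom]])
  track$cov[[strand]][[chrom]] <- track$cov[[strand]][[chrom]] +
    S4Vectors::Rle(counts)
  track
}

# add a per-base numeric vector over [start, start+length(values)) (internal)
add_segment <- function(track, chrom, start, values, strand) {
  r <- track$cov[[strand]][[chrom]]
  idx <- (start + 1L):(start + length(values))
  r[idx] <- as.numeric(r[idx]) + values
  track$cov[[strand]][[chrom]] <- r
  track
}

#' Translate a transcript-oriented window into genomic coordinates
#'
#' Offsets are measured from the anchor (TSS or TES) in transcript
#' orientation: positive offsets are downstream of the anchor. For a - strand
#' gene the window is mirrored so "downstream" means decreasing genomic
#' coordinate. Offsets are half-open, so the window has length
#' `offset_end - offset_start`.
#'
#' @param gene one-row `gene_table` (or list with chrom/start/end/strand).
#' @param offset_start,offset_end transcript-oriented half-open offsets,
#'   `offset_start < offset_end`.
#' @param anchor "tss" or "tes".
#' @return list(chrom, start, end, strand) — a half-open genomic interval.
#' @export
strand_window <- function(gene, offset_start, offset_end,
                          anchor = c("tes", "tss")) {
  anchor <- match.arg(anchor)
  if (offset_start >= offset_end) {
    abort("strand_window requires offset_start < offset_end")
  }
  a <- if (anchor == "tss") {
    if (gene$strand == "+") gene$start else gene$end
  } else {
    if (gene$strand == "+") gene$end else gene$start
  }
  if (gene$strand == "+") {
    list(chrom = gene$chrom, start = a + offset_start, end = a + offset_end,
         strand = "+")
  } else {
    list(chrom = gene$chrom, start = a - offset_end, end = a - offset_start,
         strand = "-")
  }
}

# TRUE when a window lies fully inside its chromosome (internal)
window_in_bounds <- function(win, chrom_sizes) {
  win$start >= 0 && win$end <= chrom_sizes[[win$chrom]]
}
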