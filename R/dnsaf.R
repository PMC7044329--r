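# Distributed normalized spectral abundance factors (dNSAF).
#
# Spectral counts from peptides unique to one protein (uSpC) are kept as is;
# counts from peptides shared among M proteins are distributed to each
# sharer i in proportion uSpC_i / sum_{m in M} uSpC_m. The distributed SAF is
#   dSAF_i = (uSpC_i + distributed_shared_i) / Length_i
# and dNSAF_i = dSAF_i / sum_k dSAF_k, so dNSAF sums to 1 across the
# proteins in a run and is proportional to molar abundance under uniform
# sampling of peptides along the chain.

#' Assemble peptide-level spectral-count evidence
#'
#' @param proteins data.frame with columns protein_id and length (residues,
#'   > 0).
#' @param peptides data.frame with columns peptide_id, protein_ids (either a
#'   list column of character vectors or semicolon-joined strings) and
#'   spectral_count (non-negative integers).
#' @return object of class `spectral_count_data`.
#' @export
spectral_count_data <- function(proteins, peptides) {
  if (!all(c("protein_id", "length") %in% names(proteins))) {
    abort("proteins needs columns protein_id, length")
  }
  if (any(proteins$length <= 0)) abort("protein lengths must be positive")
  if (anyDuplicated(proteins$protein_id)) abort("duplicate protein ids")
  if (!all(c("peptide_id", "protein_ids", "spectral_count") %in%
           names(peptides))) {
    abort("peptides needs columns peptide_id, protein_ids, spectral_count")
  }
  ids <- peptides$protein_ids
  if (!is.list(ids)) ids <- strsplit(as.character(ids), ";", fixed = TRUE)
  ids <- lapply(ids, unique)
  if (any(lengths(ids) == 0L)) abort("every peptide must map to >= 1 protein")
  unknown <- setdiff(unique(unlist(ids)), proteins$protein_id)
  if (length(unknown)) {
    abort("peptides map to unknown protein(s): %s",
          paste(unknown, collapse = ", "))
  }
  if (any(peptides$spectral_count < 0) ||
      any(peptides$spectral_count != floor(peptides$spectral_count))) {
    abort("spectral counts must be non-negative integers")
  }
  structure(list(proteins = data.frame(protein_id = proteins$protein_id,
                                       length = proteins$length,
                                       stringsAsFactors = FALSE),
                 peptide_id = as.character(peptides$peptide_id),
                 protein_ids = ids,
                 spectral_count = as.numeric(peptides$spectral_count)),
            class = "spectral_count_data")
}

#' Distribute shared spectral counts among sharing proteins
#'
#' Unique counts (peptides mapping to one protein) define uSpC. Each shared
#' peptide's count is split among its sharers in proportion to their uSpC.
#' Shared peptides whose sharers all have uSpC = 0 are degenerate: by
#' default their counts are split equally and the sharers flagged; with
#' `degenerate = "discard"` such counts are dropped and reported in attribute
#' `discarded_counts`.
#'
#' @param data a [spectral_count_data()] object.
#' @param degenerate "split" (default) or "discard".
#' @return data.frame with protein_id, uSpC, distributed_shared,
#'   undistributed_flag (attribute `discarded_counts` gives dropped counts).
#' @export
distribute_shared_counts <- function(data, degenerate = c("split", "discard")) {
  degenerate <- match.arg(degenerate)
  pid <- data$proteins$protein_id
  u <- stats::setNames(numeric(length(pid)), pid)
  shared <- stats::setNames(numeric(length(pid)), pid)
  flag <- stats::setNames(logical(length(pid)), pid)
  is_unique <- lengths(data$protein_ids) == 1L
  for (i in which(is_unique)) {
    u[data$protein_ids[[i]]] <- u[data$protein_ids[[i]]] +
      data$spectral_count[i]
  }
  discarded <- 0
  for (i in which(!is_unique)) {
    members <- data$protein_ids[[i]]
    denom <- sum(u[members])
    cnt <- data$spectral_count[i]
    if (denom > 0) {
      shared[members] <- shared[members] + cnt * u[members] / denom
    } else if (degenerate == "split") {
      shared[members] <- shared[members] + cnt / length(members)
      flag[members] <- TRUE
    } else {
      discarded <- discarded + cnt
      flag[members] <- TRUE
    }
  }
  out <- data.frame(protein_id = pid, uSpC = unname(u),
                    distributed_shared = unname(shared),
                    undistributed_flag = unname(flag),
                    stringsAsFactors = FALSE)
  attr(out, "discarded_counts") <- discarded
  out
}

#' Distributed normalized spectral abundance factors
#'
#' `dSAF_i = (uSpC_i + distributed_shared_i) / Length_i`;
#' `dNSAF_i = dSAF_i / sum(dSAF)`. Returns an empty table with a warning when
#' every dSAF is zero.
#'
#' @param distributed output of [distribute_shared_counts()].
#' @param lengths named numeric vector of protein lengths (residues), or a
#'   proteins data.frame with protein_id and length.
#' @return data.frame with protein_id, uSpC, distributed_shared, dSAF, dNSAF,
#'   undistributed_flag.
#' @export
compute_dnsaf <- function(distributed, lengths) {
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$length, lengths$protein_id)
  }
  miss <- setdiff(distributed$protein_id[distributed$uSpC +
                                           distributed$distributed_shared > 0],
                  names(lengths))
  if (length(miss)) abort("missing length for protein(s): %s",
                          paste(miss, collapse = ", "))
  len <- lengths[distributed$protein_id]
  dsaf <- (distributed$uSpC + distributed$distributed_shared) / len
  total <- sum(dsaf)
  if (total == 0) {
    warning("all dSAF values are zero; returning empty result")
    return(data.frame(protein_id = character(0), uSpC = numeric(0),
                      distributed_shared = numeric(0), dSAF = numeric(0),
                      dNSAF = numeric(0), undistributed_flag = logical(0)))
  }
  data.frame(protein_id = distributed$protein_id, uSpC = distributed$uSpC,
             distributed_shared = distributed$distributed_shared,
             dSAF = unname(dsaf), dNSAF = unname(dsaf / total),
             undistributed_flag = distributed$undistributed_flag,
             stringsAsFactors = FALSE)
}

#' One-shot dNSAF from peptide evidence
#'
#' @param data a [spectral_count_data()] object.
#' @param degenerate passed to [distribute_shared_counts()].
#' @return See [compute_dnsaf()].
#' @export
dnsaf <- function(data, degenerate = c("split", "discard")) {
  compute_dnsaf(distribute_shared_counts(data, degenerate), data$proteins)
}

#' Label proteins as bait-specific or background versus a negative control
#'
#' A protein is `bait_specific` when absent from the control (control dNSAF
#' 0 or missing) or enriched at least `fold_min`-fold over it; otherwise
#' `background`.
#'
#' @param results_bait,results_control dNSAF tables from [compute_dnsaf()].
#' @param fold_min minimum bait/control dNSAF ratio (default 3).
#' @return data.frame with protein_id, bait_dnsaf, control_dnsaf, label.
#' @export
bait_vs_control <- function(results_bait, results_control, fold_min = 3) {
  ctrl <- stats::setNames(results_control$dNSAF, results_control$protein_id)
  c_d <- ctrl[results_bait$protein_id]
  c_d[is.na(c_d)] <- 0
  label <- ifelse(c_d == 0 | results_bait$dNSAF / c_d >= fold_min,
                  "bait_specific", "background")
  data.frame(protein_id = results_bait$protein_id,
             bait_dnsaf = results_bait$dNSAF, control_dnsaf = unname(c_d),
             label = unname(label), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read protein and peptide tables into spectral-count evidence
#'
#' @param protein_path tab-separated table with header: protein_id, length.
#' @param peptide_path tab-separated table with header: peptide_id,
#'   protein_ids (semicolon-joined), spectral_count.
#' @return A `spectral_count_data` object.
#' @export
read_spectral_counts <- function(protein_path, peptide_path) {
  pr <- utils::read.table(protein_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  pe <- utils::read.table(peptide_path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"))
  spectral_count_data(pr, pe)
}
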