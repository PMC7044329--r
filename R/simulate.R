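# Seeded generators for every input the pipeline consumes, with known
# ground truth.
#
# The nascent-transcription generator emits single-base 3'-end events (one
# per sequenced read): with probability 1 - f the event falls uniformly in
# the gene body, with probability f it falls a geometric distance past the
# TES (a memoryless read-through tail with mean lambda, truncated at the
# intergenic clearance). The occupancy generator draws per-base Poisson
# counts at a flat rate over the body and an exponentially decaying rate
# downstream of the TES. All generators are pure functions of
# (config, seed): the global RNG state is restored after each call.

#' Simulation configuration
#'
#' Defaults describe the study conditions the analyses are exercised under:
#' a mutant condition with elevated read-through probability at histone and
#' snRNA/snoRNA genes only, dual-library counts with a planted aberrantly
#' polyadenylated subset, and replicate qPCR / spectral-count data.
#'
#' @param ... name = value overrides of any default listed below.
#' @return list of class `sim_config` with fields:
#' \describe{
#'   \item{n_genes}{named counts per class (histone 60, snRNA_snoRNA 40,
#'     protein_coding 100, other 0).}
#'   \item{gene_length}{per-class length ranges in bp (histone 400-1000,
#'     snRNA_snoRNA 100-300, protein_coding 2000-50000, other 1000-5000).}
#'   \item{depth}{nascent 3'-end events per gene (5000); also sets the
#'     occupancy rate as depth / gene length.}
#'   \item{readthrough_prob}{per condition (WT, MUT), per class: probability
#'     f that a polymerase reads through the TES. WT = 0.05 everywhere;
#'     MUT = 0.3 for histone and snRNA_snoRNA, 0.05 elsewhere.}
#'   \item{lambda}{mean of the geometric read-through tail, bases (200).}
#'   \item{clearance}{intergenic gap flanking every gene, bases (2500);
#'     at least the downstream window extent so no window leaves bounds.}
#'   \item{nb_dispersion, replicates, n_transcripts, n_aberrant,
#'     polya_effect}{dual-library count design: NB dispersion 0.05, 4
#'     replicates per group, 500 transcripts, 50 planted aberrant, 4-fold
#'     polyA-selected effect.}
#'   \item{qpcr_q}{true unprocessed fraction per condition
#'     (control 0.02, depleted 0.15).}
#'   \item{qpcr_noise_sd, qpcr_baseline_ct, qpcr_replicates, qpcr_targets}{Ct
#'     noise sd 0.2 cycles, CT-amplicon baseline 24 cycles, 3 replicates,
#'     3 histone-like targets.}
#'   \item{n_proteins, sharing_fraction, abundance_sdlog,
#'     spectra_per_unit}{spectral-count design: 50 proteins, 20% of
#'     peptides shared, log-normal abundances (sdlog 1), Poisson rate
#'     spectra_per_unit * abundance per peptide (10).}
#' }
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = c(histone = 60, snRNA_snoRNA = 40, protein_coding = 100,
                other = 0),
    gene_length = list(histone = c(400, 1000), snRNA_snoRNA = c(100, 300),
                       protein_coding = c(2000, 50000),
                       other = c(1000, 5000)),
    depth = 5000,
    readthrough_prob = list(
      WT = c(histone = 0.05, snRNA_snoRNA = 0.05, protein_coding = 0.05,
             other = 0.05),
      MUT = c(histone = 0.3, snRNA_snoRNA = 0.3, protein_coding = 0.05,
              other = 0.05)),
    lambda = 200,
    clearance = 2500,
    nb_dispersion = 0.05, replicates = 4, n_transcripts = 500,
    n_aberrant = 50, polya_effect = 4, ribo_effect = 0.5,
    qpcr_q = c(control = 0.02, depleted = 0.15),
    qpcr_noise_sd = 0.2, qpcr_baseline_ct = 24, qpcr_replicates = 3,
    qpcr_targets = c("RDH1", "RDH2", "RDH3"),
    n_proteins = 50, sharing_fraction = 0.2, abundance_sdlog = 1,
    spectra_per_unit = 10)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) abort("unknown sim_config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$lambda <= 0 || cfg$depth <= 0) abort("lambda and depth must be > 0")
  probs <- unlist(cfg$readthrough_prob)
  if (any(probs < 0 | probs > 1)) abort("readthrough_prob must lie in [0,1]")
  structure(cfg, class = "sim_config")
}

#' Simulate a gene annotation with guaranteed window clearance
#'
#' Places non-overlapping genes of the configured classes along one
#' simulated chromosome, on random strands, with `clearance` bases of empty
#' sequence on both sides of every gene so that no read-through window can
#' leave the chromosome or touch a neighbor.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list(genes = `gene_table`, chrom_sizes = named numeric).
#' @export
simulate_genome <- function(config = sim_config(), seed = 1) {
  with_seed(seed, {
    classes <- rep(names(config$n_genes), config$n_genes)
    if (length(classes) == 0L) abort("no genes requested")
    classes <- sample(classes)
    lens <- vapply(classes, function(cl) {
      r <- config$gene_length[[cl]]
      floor(stats::runif(1, r[1], r[2] + 1))
    }, 0)
    strand <- sample(c("+", "-"), length(classes), replace = TRUE)
    gap <- config$clearance
    start <- numeric(length(lens))
    cur <- gap
    for (i in seq_along(lens)) {
      start[i] <- cur
      cur <- cur + lens[i] + gap
    }
    genes <- gene_table(
      gene_id = sprintf("g%04d", seq_along(classes)),
      chrom = "simchr1", start = start, end = start + lens,
      strand = strand, gene_class = classes)
    list(genes = genes, chrom_sizes = c(simchr1 = unname(cur)))
  })
}

# truncated geometric sample of size n: support 0..(trunc_at - 1), mean
# lambda when untruncated (success prob 1 / (lambda + 1))
rgeom_trunc <- function(n, lambda, trunc_at) {
  p <- 1 / (lambda + 1)
  u <- stats::runif(n)
  stats::qgeom(u * stats::pgeom(trunc_at - 1, p), p)
}

# assemble a coverage_track from plain per-chromosome numeric vectors
track_from_vectors <- function(vecs, chrom_sizes) {
  trk <- coverage_track(chrom_sizes)
  for (s in names(vecs)) {
    for (ch in names(vecs[[s]])) {
      trk$cov[[s]][[ch]] <- S4Vectors::Rle(vecs[[s]][[ch]])
    }
  }
  trk
}

#' Simulate a strand-specific nascent 3'-end coverage track
#'
#' Per gene, `depth` single-base events: uniform in the gene body with
#' probability 1 - f, else TES + G with G geometric (mean `lambda`,
#' truncated at the clearance), mirrored for - strand genes.
#'
#' @param genome output of [simulate_genome()].
#' @param config a [sim_config()].
#' @param condition "WT" or "MUT" (names of `config$readthrough_prob`).
#' @param seed integer seed.
#' @return A strand-split `coverage_track` of event counts.
#' @export
simulate_nascent_track <- function(genome, config = sim_config(),
                                   condition = "WT", seed = 1) {
  f_by_class <- config$readthrough_prob[[condition]]
  if (is.null(f_by_class)) abort("unknown condition: %s", condition)
  genes <- genome$genes
  with_seed(seed, {
    pos_by <- list()                       # positions keyed by strand|chrom
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      L <- g$end - g$start
      f <- f_by_class[[g$gene_class]]
      n_tail <- stats::rbinom(1, config$depth, f)
      n_body <- config$depth - n_tail
      body_off <- if (n_body) sample.int(L, n_body, replace = TRUE) - 1L else
        integer(0)
      tail_off <- if (n_tail) rgeom_trunc(n_tail, config$lambda,
                                          config$clearance) else integer(0)
      pos <- if (g$strand == "+") {
        c(g$start + body_off, g$end + tail_off)
      } else {
        c(g$start + body_off, g$start - 1 - tail_off)
      }
      key <- paste0(g$strand, "|", g$chrom)
      pos_by[[key]] <- c(pos_by[[key]], pos)
    }
    vecs <- lapply(list(`+` = 1, `-` = 1), function(.)
      lapply(genome$chrom_sizes, numeric))
    for (key in names(pos_by)) {
      sc <- strsplit(key, "|", fixed = TRUE)[[1]]
      vecs[[sc[1]]][[sc[2]]] <- tabulate(pos_by[[key]] + 1L,
                                         nbins = genome$chrom_sizes[[sc[2]]])
    }
    track_from_vectors(vecs, genome$chrom_sizes)
  })
}

#' Simulate a polymerase-occupancy coverage track
#'
#' Per-base Poisson counts: rate `rho = depth / L` across the gene body and
#' `rho * f * exp(-d / lambda)` at distance d (0-based) into the 1000 bases
#' downstream of the TES.
#'
#' @inheritParams simulate_nascent_track
#' @param down_len downstream extent receiving decaying signal (default
#'   1000, the occupancy statistic's window).
#' @return A `coverage_track` (signal on the gene's strand; the occupancy
#'   statistic queries it unstranded).
#' @export
simulate_polii_track <- function(genome, config = sim_config(),
                                 condition = "WT", seed = 1,
                                 down_len = 1000) {
  f_by_class <- config$readthrough_prob[[condition]]
  if (is.null(f_by_class)) abort("unknown condition: %s", condition)
  genes <- genome$genes
  with_seed(seed, {
    # per-gene segments (gene body + decaying downstream) are disjoint by
    # construction, so each is assigned once into a preallocated vector
    seg <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      L <- g$end - g$start
      rho <- config$depth / L
      f <- f_by_class[[g$gene_class]]
      body <- stats::rpois(L, rho)
      down <- stats::rpois(down_len, rho * f * exp(-(seq_len(down_len) - 1) /
                                                     config$lambda))
      seg[[i]] <- if (g$strand == "+") {
        list(at = (g$start + 1):(g$end + down_len), values = c(body, down))
      } else {
        # downstream = decreasing coordinate: distance d maps to start - 1 - d
        list(at = (g$start - down_len + 1):g$end,
             values = c(rev(down), body))
      }
    }
    vecs <- list(`+` = lapply(genome$chrom_sizes, numeric),
                 `-` = lapply(genome$chrom_sizes, numeric))
    for (s in c("+", "-")) {
      for (ch in names(genome$chrom_sizes)) {
        idx <- which(genes$strand == s & genes$chrom == ch)
        if (!length(idx)) next
        v <- numeric(genome$chrom_sizes[[ch]])
        for (i in idx) v[seg[[i]]$at] <- seg[[i]]$values
        vecs[[s]][[ch]] <- v
      }
    }
    track_from_vectors(vecs, genome$chrom_sizes)
  })
}

#' Simulate dual-library negative-binomial count matrices
#'
#' Baseline means are log-normal. Planted aberrant transcripts change in the
#' perturbation group by `polya_effect`-fold in the polyA-selected library
#' (they gain a poly(A) tail and enter the selected pool) and by
#' `ribo_effect`-fold (default reduced: unprocessed transcripts are
#' destabilized) in the ribo-depleted library. Effects are specified on the
#' relative-abundance scale a fixed-depth library measures: the count-level
#' multiplier is adjusted for the compositional renormalization that a
#' counts-per-million analysis applies, so the planted transcripts' expected
#' CPM fold change equals the configured effect.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list(polya, ribo = count matrices with ctrl_/pert_ columns,
#'   truth = data.frame(transcript_id, aberrant)).
#' @export
simulate_counts_dual_library <- function(config = sim_config(), seed = 1) {
  with_seed(seed, {
    n <- config$n_transcripts
    reps <- config$replicates
    size <- 1 / config$nb_dispersion
    ids <- sprintf("t%04d", seq_len(n))
    mu <- stats::rlnorm(n, meanlog = log(200), sdlog = 1)
    aberrant <- sort(sample.int(n, config$n_aberrant))
    # count multiplier m giving CPM fold F when the planted set holds a
    # share a of the library: F = m / (1 + a (m - 1))
    multiplier <- function(F) {
      a <- sum(mu[aberrant]) / sum(mu)
      if (F * a >= 1) abort("effect %g infeasible at planted share %.3f", F, a)
      F * (1 - a) / (1 - F * a)
    }
    draw <- function(mu_vec) {
      matrix(stats::rnbinom(n * reps, mu = rep(mu_vec, reps), size = size),
             nrow = n)
    }
    eff_pa <- rep(1, n); eff_pa[aberrant] <- multiplier(config$polya_effect)
    eff_rd <- rep(1, n); eff_rd[aberrant] <- multiplier(config$ribo_effect)
    polya <- cbind(draw(mu), draw(mu * eff_pa))
    ribo <- cbind(draw(mu), draw(mu * eff_rd))
    dimnames(polya) <- list(ids, c(sprintf("ctrl_%d", seq_len(reps)),
                                   sprintf("pert_%d", seq_len(reps))))
    dimnames(ribo) <- dimnames(polya)
    list(polya = polya, ribo = ribo,
         truth = data.frame(transcript_id = ids,
                            aberrant = seq_len(n) %in% aberrant,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate peptide-level spectral counts from known protein abundances
#'
#' Protein lengths are uniform on 150-1500 residues and abundances
#' log-normal. Each protein carries ~1 tryptic peptide per 100 residues; a
#' configured fraction of peptides is additionally mapped to one other
#' random protein (shared evidence). Peptide counts are Poisson with rate
#' `spectra_per_unit * sum(abundance of mapped proteins)`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list(data = `spectral_count_data`,
#'   truth = data.frame(protein_id, abundance, length)).
#' @export
simulate_spectral_counts <- function(config = sim_config(), seed = 1) {
  with_seed(seed, {
    n <- config$n_proteins
    pid <- sprintf("P%03d", seq_len(n))
    len <- floor(stats::runif(n, 150, 1501))
    abundance <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
    owner <- rep(seq_len(n), pmax(2L, round(len / 100)))
    n_pep <- length(owner)
    shared <- stats::runif(n_pep) < config$sharing_fraction
    partner <- ifelse(shared,
                      vapply(owner, function(o)
                        sample(setdiff(seq_len(n), o), 1L), 0L),
                      NA_integer_)
    maps <- lapply(seq_len(n_pep), function(j) {
      if (shared[j]) pid[c(owner[j], partner[j])] else pid[owner[j]]
    })
    rate <- config$spectra_per_unit *
      (abundance[owner] + ifelse(shared, abundance[partner], 0))
    counts <- stats::rpois(n_pep, rate)
    data <- spectral_count_data(
      proteins = data.frame(protein_id = pid, length = len,
                            stringsAsFactors = FALSE),
      peptides = data.frame(peptide_id = sprintf("pep%05d", seq_len(n_pep)),
                            protein_ids = I(maps),
                            spectral_count = counts))
    list(data = data,
         truth = data.frame(protein_id = pid, abundance = abundance,
                            length = len, stringsAsFactors = FALSE))
  })
}

#' Simulate a replicate qPCR Ct table
#'
#' For each condition with true unprocessed fraction q and each target, the
#' coding-transcript Ct is drawn around the baseline and the
#' unprocessed-transcript Ct is `Ct_CT - log2(q)` plus Gaussian noise, so
#' that `2^-dCt` recovers q (exactly at zero noise).
#'
#' @param config a [sim_config()]; `qpcr_q` names the conditions.
#' @param seed integer seed.
#' @return Tidy Ct data.frame (sample, condition, target, amplicon,
#'   replicate, ct).
#' @export
simulate_qpcr <- function(config = sim_config(), seed = 1) {
  q <- config$qpcr_q
  if (any(q <= 0 | q > 1)) abort("qpcr_q values must lie in (0, 1]")
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(config$qpcr_replicates),
                        target = config$qpcr_targets,
                        condition = names(q), stringsAsFactors = FALSE)
    ct_ct <- config$qpcr_baseline_ct +
      stats::rnorm(nrow(grid), 0, config$qpcr_noise_sd)
    ct_ut <- ct_ct - log2(q[grid$condition]) +
      stats::rnorm(nrow(grid), 0, config$qpcr_noise_sd)
    long <- rbind(
      data.frame(grid, amplicon = "CT", ct = ct_ct,
                 stringsAsFactors = FALSE),
      data.frame(grid, amplicon = "UT", ct = ct_ut,
                 stringsAsFactors = FALSE))
    data.frame(sample = paste(long$condition, long$replicate, sep = "_"),
               condition = long$condition, target = long$target,
               amplicon = long$amplicon, replicate = long$replicate,
               ct = long$ct, stringsAsFactors = FALSE, row.names = NULL)
  })
}
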