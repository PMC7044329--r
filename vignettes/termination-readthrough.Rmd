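---
title: "Quantifying termination read-through and 3'-end processing defects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying termination read-through and 3'-end processing defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terminus)
```

## The biological question

Replication-dependent histone (RDH) mRNAs and snRNAs are the two major
classes of RNA-polymerase-II transcripts that are normally **not**
polyadenylated: RDH mRNAs end in a stem-loop generated by endonucleolytic
cleavage, snRNAs are processed at a 3'-box element. When the machinery that
couples transcription termination to 3'-end processing at these genes is
impaired, two measurable things happen:

1. polymerase keeps transcribing past the normal 3'-end processing site
   (TES), leaving a decaying tail of nascent-transcription and polymerase
   occupancy signal downstream of the gene, and
2. the read-through transcripts are captured by downstream polyadenylation
   signals, so normally non-polyadenylated transcripts acquire a poly(A)
   tail and suddenly appear in polyA-selected RNA-seq libraries while their
   total abundance (ribo-depleted libraries) is unchanged or reduced.

`terminus` implements the quantitative procedures used to detect both
signatures, plus the accompanying qPCR arithmetic, spectral-count proteomics
(dNSAF) and TSS-proximal co-occupancy analyses, and seeded simulators that
generate every input with known ground truth.

## Read-through ratio statistics

Both statistics work on strand-aware, exact per-base interval sums over
coverage tracks, with all coordinates 0-based half-open and "downstream"
meaning transcript orientation (decreasing genomic coordinate on the minus
strand).

For a gene with 3'-end processing site TES:

* **Nascent (PRO-seq style) read-through ratio** — the sum of 3'-end signal
  over the transcript-oriented window `[TES+500, TES+1000)` divided by the
  sum over `[TES-50, TES)`. The numerator window starts 500 bp downstream
  so that signal from normal cleavage-and-termination zones does not
  contaminate it; the short upstream window measures polymerase flux
  arriving at the TES, so the ratio is a per-gene, depth-free index of how
  much of that flux fails to terminate.
* **Polymerase-occupancy read-through ratio** — occupancy over
  `[TES, TES+1000)` divided by occupancy over `[TSS, TES+1000)`. Because the
  numerator window is nested in the denominator, valid values always lie in
  `[0, 1]`: the fraction of the gene's total polymerase residency that sits
  past the TES. Occupancy ChIP is not strand-resolved, so this statistic
  sums both strands; the nascent statistic queries only the gene's strand.

Window inclusivity is half-open on both ends ("500 to 1000 bp downstream" is
`[TES+500, TES+1000)`, "TES to 50 bp upstream" is `[TES-50, TES)`), keeping
window lengths exactly 500 and 50 and sums additive. Genes whose windows
would cross a chromosome boundary are flagged invalid rather than silently
clipped — clipping would shrink numerator and denominator asymmetrically —
and genes with a zero denominator are flagged and excluded from group
statistics, with exclusion counts reported.

Group comparisons summarize each gene class per condition as Tukey box-plot
statistics (type-7 linear-interpolation quartiles, whiskers at the most
extreme point within 1.5 IQR) and test the difference with a two-sided
pooled-variance Student's t test on the raw ratios. A switch enables
testing on `log2(ratio + eps)` (default eps `1e-3`) for heavy-tailed ratio
distributions; the default stays on raw ratios.

Both ratios are invariant under global scaling of a track, so spike-in
normalization (`spike_in_scale()`, a plain ratio-of-totals rescale) can
never change a ratio — it is provided for absolute-coverage comparisons
only, and whether tracks were spike-scaled or raw is immaterial to every
statistic in this package.

## Aberrant polyadenylation from dual libraries

A transcript is called `aberrant_polyA` when it looks strongly up in the
polyA-selected differential result (log2 fold change >= 1.5 at FDR <= 0.05)
while being unchanged or reduced (log2 fold change <= 0) in the
ribo-depleted result; transcripts up in both are `concordant_up`. The
"not up" arm deliberately carries no significance requirement — demanding
statistical significance of a null effect would be incoherent. All three
thresholds are configurable via `call_thresholds()`.

`simple_differential()` is declared plumbing, not a negative-binomial GLM:
log2 fold change of mean counts-per-million (pseudocount 0.5 added to
counts, library sizes adjusted accordingly), per-transcript pooled-variance
t test on log2 CPM, Benjamini–Hochberg FDR across transcripts. It exists so
the caller can be exercised end-to-end on count matrices; for real data any
differential table with `transcript_id, log2_fc, fdr` can be supplied
instead.

## qPCR arithmetic

The unprocessed fraction of a target's transcripts is estimated from paired
amplicons: UT spans the 3'-end processing site (amplifies only read-through
transcripts), CT sits in the coding region (amplifies all). Per replicate,
`dCt = Ct(UT) - Ct(CT)` and the fraction is `2^-dCt`, assuming
amplification efficiency 2; no standard-curve calibration is attempted.
Ratios are computed per paired replicate (paired by replicate index) and
then averaged — not computed from mean Cts — so the reported sd reflects
replicate scatter of the quantity of interest. ChIP enrichment is
`100 * 2^((Ct_input - d) - Ct_IP)` with `d` the log2 input dilution factor,
default 0 (undiluted input reproduces plain input normalization).

## dNSAF

Spectral counts are length-normalized into distributed normalized spectral
abundance factors. With `uSpC_i` the counts from peptides unique to protein
i, each shared peptide j with count `c_j` and sharer set `M_j` contributes
`c_j * uSpC_i / sum_{m in M_j} uSpC_m` to protein i, then

```
dSAF_i  = (uSpC_i + distributed_shared_i) / Length_i
dNSAF_i = dSAF_i / sum_k dSAF_k
```

so dNSAF sums to 1 over the run and reduces exactly to plain NSAF when no
peptide is shared. The distribution rule is undefined (0/0) for a shared
peptide all of whose sharers lack unique evidence; by default such counts
are split equally among the sharers and the proteins flagged
(`undistributed_flag`), preserving count conservation and auditability; a
switch discards them instead, reporting the discarded total. Bait-vs-control
labeling is a simple enrichment rule — `bait_specific` when absent from the
control or enriched >= 3-fold in dNSAF — since no published numeric rule
exists for this comparison; the fold threshold is a parameter.

## Co-occupancy

Peaks are retained at q < 1e-4 (scores may be probabilities or -log10
values, declared by flag). A gene is "occupied" when any retained peak
touches the closed window within 1 kb of the TSS point; distance is
strand-independent and the 1000-bp boundary base is included (the
inclusivity at exactly 1 kb is arbitrary and fixed for determinism). A gene
counts once regardless of how many peaks hit. Co-occupancy across k factors
reports the full-intersection gene set and all `2^k - 1` exclusive Venn
partition counts.

## What the simulators generate — and what they do not

All generators are pure functions of (config, seed); the global RNG state is
saved and restored around every call.

* **Genome** — non-overlapping genes of the four classes (defaults: 60
  histone of 0.4–1 kb, 40 snRNA/snoRNA of 0.1–0.3 kb, 100 protein-coding of
  2–50 kb) on random strands with 2.5 kb of clearance on both sides, so
  every analysis window is guaranteed in bounds and no downstream window
  overlaps a neighbor.
* **Nascent track** — per gene, 5000 single-base 3'-end events (one per
  read, mimicking last-base coverage extraction): uniform in the gene body
  with probability `1 - f`, else `TES + G` with G geometric with mean 200 bp
  truncated at the clearance. The memoryless tail is the simplest decaying
  shape with closed-form window probabilities; real read-through decay need
  not be memoryless. Defaults: `f = 0.05` in WT everywhere; `f = 0.3` in the
  mutant condition for histone and snRNA/snoRNA classes only.
* **Occupancy track** — per-base Poisson at rate `depth / L` over the body
  and `rho * f * exp(-d / lambda)` at distance d into the 1 kb downstream of
  the TES, so the expected occupancy ratio has a closed form.
* **Dual-library counts** — negative-binomial (dispersion 0.05, 4
  replicates/group, 500 transcripts, log-normal baselines) with 50 planted
  aberrant transcripts. Effect sizes are specified on the
  **relative-abundance scale** the CPM analysis measures: planting a 4-fold
  count-level change in 10% of a fixed-depth library compositionally
  deflates the observed fold change (to ~3.1-fold here), so the generator
  converts the configured CPM-scale effect into the equivalent count
  multiplier. Planted transcripts default to a 0.5-fold (reduced) effect in
  the ribo-depleted library: transcripts that escape normal 3'-end
  processing are destabilized, and "unchanged" total abundance would sit
  exactly on the call boundary, which is a property of the caller's
  threshold, not of the biology being emulated.
* **qPCR** — `Ct(CT)` around a baseline of 24 cycles, `Ct(UT) = Ct(CT) -
  log2(q)` plus Gaussian noise (sd 0.2 cycles per amplicon), with true
  unprocessed fractions 0.02 (control) and 0.15 (depleted) by default.
* **Spectral counts** — 50 proteins, lengths uniform on 150–1500 residues,
  log-normal abundances, about one peptide per 100 residues with 20% of
  peptides shared with one other random protein, Poisson counts at rate
  `10 * abundance` per peptide (thousands of spectra per run, a typical
  MudPIT scale).

These simulators reproduce the *statistical structure* the analyses assume
— not real data. They have no sequence content, mappability or GC bias, no
correlated biological replicates, no neighboring-gene signal bleeding into
downstream windows, uniform (not positionally biased) gene-body signal, and
spike-ins appear only as scalar totals. Passing tests therefore demonstrate
correctness of the computations and recoverability of planted effects under
the stated models, not robustness to artifacts of real sequencing data.

## Numerical choices and degenerate inputs

* Interval sums are exact run-length-encoded sums, never binned
  approximations; additivity over adjacent windows holds to machine
  precision.
* Quantiles are type-7 (linear interpolation), matching base R defaults.
* Zero-variance rows in `simple_differential()` get p = 1 when the group
  means agree and p = 0 otherwise; all-zero transcripts are reported with
  log2 fold change 0 and FDR 1.
* Group comparisons refuse classes with fewer than 2 valid genes in either
  condition rather than returning an unstable t statistic.
* The truncated geometric tail is sampled by inverse CDF, so identical
  seeds give identical tracks across platforms.

## Problem sizes

The shipped defaults — 200 genes at depth 5000, 500 transcripts with 4
replicates, 50 proteins, 100-dataset fuzz loops — were chosen so that every
property check, including the 20-seed null calibrations, completes on a
single CPU in well under a minute per analysis while leaving planted-effect
recovery comfortably powered. All sizes are configuration, not constants.

## Known limitations

* The read-through ratios assume annotation TES positions are accurate;
  mis-annotated 3' ends shift both windows.
* No masking of downstream neighboring genes is applied by default (the
  simulator guarantees clearance; real annotations do not). An optional
  pre-filter dropping genes with another TSS within 1 kb of their TES can
  be applied by the caller on the gene table.
* `simple_differential()` is a t-test stand-in; for real count data use a
  negative-binomial framework and feed the resulting table to the caller.
* dNSAF inherits spectral counting's biases (length normalization assumes
  uniform peptide observability along the chain).
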