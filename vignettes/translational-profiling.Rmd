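---
title: "Feature-resolved translational profiling with riboTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-resolved translational profiling with riboTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboTE)
```

# Motivation

Some transcriptional programs — the canonical example being a pulse of the
embryonic transcription factor DUX4 in myoblasts — suppress protein
synthesis globally while their own target mRNAs keep being translated.
Three complementary sequencing readouts dissect such reprogramming:

* **Ribo-seq / RNA-seq**: ribosome-protected fragments (RPFs) localize
  ribosomes at nucleotide resolution; changes in ribosome occupancy
  relative to mRNA abundance define changes in translation efficiency
  (TE). Resolving occupancy by mRNA *feature* — 5'UTR, the translation
  initiation site (TIS) window, first coding exon, CDS, 3'UTR — localizes
  where on the transcript initiation is lost.
* **Polysome profiling**: sucrose-gradient fractionation into
  sub-polysome, low (1–3 ribosomes) and high (>3 ribosomes) pools,
  quantified by RNA-seq against a total-input library and normalized to
  an exogenous (Drosophila) spike-in, measures ribosome load per mRNA.
* **5'UTR structure**: minimum-free-energy (MFE) folding of 5'UTRs,
  scaled per 100 nt, asks whether translationally resistant mRNAs carry
  less structured leaders.

riboTE implements all three arms plus a fully deterministic synthetic
study generator with planted effects, so every stage is testable without
any external data.

# The differential framework

## Counting

RPFs are filtered to the dominant 26–29 nt size class. The P-site of each
read is `five_prime_pos + offset(length)`; the offset defaults to 12 nt
and can be calibrated per length class by maximizing the fraction of
P-sites in reading frame 0 over CDS positions (candidates 10–14, ties
broken toward 12, fallback to 12 below 100 start-codon-overlapping
reads). P-sites are tallied into five feature intervals per gene (one
representative transcript per gene, by default the longest coding
isoform):

| feature | interval (transcript coordinates, 0-based half-open) |
|---|---|
| utr5 | `[0, cds_start)` |
| tis | `[cds_start - 13, cds_start + 3 + 13)`, clipped |
| first_cds_exon | CDS portion of the exon holding the start codon |
| cds | `[cds_start, cds_end)` |
| utr3 | `[cds_end, L)` |

The TIS window includes the start codon itself (width 29 when
unclipped), making it symmetric about the codon; the flank width is a
parameter. utr5/cds/utr3 partition the transcript exactly; the TIS
window intentionally overlaps its neighbours, so one P-site may count
toward several features (once per feature).

## The TE interaction test

For a unit (gene × feature) with Ribo-seq counts and gene-level RNA-seq
counts, the null hypothesis is that ribosome occupancy changed no more
than mRNA abundance:

$$H_0:\; \log_2\frac{\text{treated}}{\text{untreated}}\Big|_{\text{ribo}}
 - \log_2\frac{\text{treated}}{\text{untreated}}\Big|_{\text{rna}} = 0$$

Both assays enter one negative-binomial GLM with log link,
`~ assay + condition + assay:condition`, a log size-factor offset per
sample, and a fixed per-unit dispersion; the interaction coefficient is
the log2 TE change, tested by Wald statistic with Benjamini–Hochberg
adjustment within each feature class. The same machinery drives the
polysome ratio-of-ratios contrasts (assay ↦ gradient fraction) and, with
a `~ condition` design, simple differential abundance.

On saturated 2×2 designs with dispersion → 0 the interaction MLE equals
the plug-in ratio of ratios exactly, which the tests assert to 1e-9 —
including the identity
`log2FC(high/sub) = log2FC(high/total) − log2FC(sub/total)`.

## Size factors and filtering

`median_of_ratios` is the standard count normalization (the median, per
sample, of ratios to unit-wise geometric means, computed over units
positive in all samples); `spike_in` derives factors from exogenous
spike totals. Factors obey a geometric-mean-1 convention. Note a
consequence checked by the tests: rescaling one sample's counts is
absorbed into its factor exactly at the normalized-count level (up to
one global constant), but no count-likelihood method is *exactly*
invariant in its estimates, because raw counts set each sample's weight
in the likelihood; the effect is first-order (≈0.01–0.02 log2 here).

The nonspecific filter removes units below a mean-normalized-count
threshold before testing; the threshold is per-feature-class
configurable (default 10 for ribosome-profiling features, 50 for
polysome genes at the volcano thresholds). Genes transcriptionally
altered by the treatment itself (RNA `|log2FC| > 1`, `padj < 0.05`;
strict inequalities) are excluded from steady-state TE and polysome
ratio analyses, and retained in the high-fraction translatome contrast.

## Dispersion

Per unit, a method-of-moments estimate pooled over replicate groups,
$\hat\alpha_{raw} = \sum_g (n_g{-}1)(v_g - m_g) \,/\, \sum_g (n_g{-}1) m_g^2$,
is shrunk halfway in log space toward a mean–dispersion trend
$\alpha(\mu) = a/\mu + b$ fitted by trimmed least squares. Three
finite-sample details matter and are validated by simulation:

* the trend is fitted on *unfloored* moment estimates — conditioning on
  positive values biases the low-mean end of the trend upward;
* inside the log-space average the raw value is floored at a quarter of
  the trend; otherwise a floored value (`1e-8`) dominates the geometric
  mean and collapses units whose sample variance happened to look
  Poisson, inflating the type-I error;
* the $\chi^2$ log-bias of the moment estimate
  ($\psi(k/2) - \log(k/2)$ at pooled residual df $k$) is removed.

Because the plugged-in dispersion is half-shrunk toward a trend pooled
across thousands of units, its sampling variance is roughly a quarter of
the raw estimator's; Wald statistics are therefore referred to a *t*
distribution with 4× the residual df rather than a normal. With 3
replicates per arm this brings the null fraction of `p < 0.05` to
0.04–0.06 for every feature class (a plain normal reference is
anticonservative, plain residual df markedly conservative). This is a
deliberately lighter apparatus than DESeq2's Cox–Reid empirical Bayes;
agreement with DESeq2 on simple contrasts is cross-checked in the test
suite (median |Δlog2FC| < 0.05), and calibration is established by
simulation rather than byte-identity.

# Polysome analysis

Three formulations, mirroring standard practice:

1. **fraction vs. total** — interaction of each gradient fraction
   against total input between conditions (altered genes excluded);
2. **high/sub ratio** — the initiation-sensitive ratio of ratios
   (altered genes excluded), with volcano-style significance at
   `baseMean > 50`, `|log2FC| > 1`, `padj < 0.01`;
3. **high-fraction DGE** — simple contrast of high-polysome abundance
   with induced genes retained (the translatome comparison).

Spike-in normalization exists because gradient fractions differ in true
mRNA content and extraction efficiency: a constant amount of exogenous
material is carried through extraction with each sample, so the
endogenous/spike ratio tracks absolute abundance. The simulator models
sequencing yield as proportional to recovered RNA, so a per-condition
extraction-efficiency multiplier scales both the endogenous counts and
the spike totals; spike-derived factors remove it exactly, whereas
raw-count analysis (libraries nominally depth-matched) reports it as a
spurious global fold change. Any normalization computed from the
endogenous counts alone (total-count, median-of-ratios) would also
absorb genuine global shifts — which is precisely what it must not do
here; this is why the "naive" comparator in the invariance analysis is
raw counts. Gene-set shifts (e.g. TOP mRNAs vs. all others) are
summarized by group medians and a two-sided Mann–Whitney U test.

# 5'UTR structure

The builtin folding engine is a pair-additive dynamic program (Nussinov
energy minimization: GC −3, AU −2, GU −1; hairpin loops ≥ 3 unpaired nt;
no pseudoknots) with deterministic traceback (unpaired branch preferred,
then the smallest-index partner). Its scores are *rank proxies* in
arbitrary units — adequate for comparing groups of sequences, not a
substitute for nearest-neighbor thermodynamics; the `external` engine
shells out to an RNAfold-compatible executable for kcal/mol values. The
DP is verified against brute-force enumeration of all pseudoknot-free
structures on short sequences, exactly. One subtlety: with G·U wobble
pairs the pair-additive model is *not* reverse-complement symmetric (a
G·U pair maps to an unpairable A·C), so the exact symmetry property is
stated and tested for the Watson–Crick-only model (`gu_wobble = FALSE`).

UTR sets are filtered as is standard: expressed genes only (mean
normalized count ≥ 1 by default; the threshold is a parameter), minimum
length 4 nt, duplicates collapsed. MFE is scaled per 100 nt and groups
are compared by Mann–Whitney U test. An override table can replace
annotated 5'UTRs of specific genes (e.g. re-annotated leaders of direct
target genes); overridden transcripts lose their genomic projection and
are flagged `source = "override"`.

# The synthetic study

`simulation_truth()` fixes every planted effect; all generators are
byte-identical under a fixed seed. The default study:

* 2,000 genes, 2 conditions (`IFNg` control, `DUX4_pulse_IFNg` pulse),
  3 replicates each; log-normal expression (sdlog 1).
* Transcripts with 1–4 exons on both strands across 4 chromosomes;
  log-normal 5'UTR (~120 nt), CDS (~200 codons) and 3'UTR (~200 nt)
  lengths; target-like genes get AU-rich (GC 0.3) 5'UTRs,
  repressed-class genes GC-rich (0.7) ones.
* Ribo-seq: 2×10^6 RPFs/sample, lengths uniform on 26–29 nt plus 2%
  out-of-range contaminants, P-site offset 12, frame fidelity 0.85
  (remainder 2:1 over frames 1/2); base occupancy 0.4/1/0.05 per nt over
  5'UTR/CDS/3'UTR with a 10× initiation peak on the start codon.
  RNA-seq: 10^6 counts/sample. Shared NB dispersion 0.02
  (gamma–Poisson).
* 20% of genes carry the pulse TE drop: 2^-2 over the 5'UTR, grading to
  70%/40% of the log2 effect over the first 13/39 CDS nt. 3.5% are
  induced targets (transcriptional log2FC +4, polysome-loaded), 5%
  TOP-like (polysome-retained), 30% initiation-blocked in the pulse
  (high/sub ratio × 2^-2), 5% elongation-stalled.
* Polysome: fractions sub/low/high/total × both conditions, fraction
  masses (0.2, 0.3, 0.5) at baseline, spike totals ~10^6 with a planted
  2× extraction-efficiency multiplier between conditions.

Problem sizes were chosen so every planted effect is identifiable by
design, not by luck. Two are worth spelling out because they follow from
the Wald information bound
$\mathrm{Var}(\widehat{\Delta TE}_{\ln}) \ge 4\alpha/n$ for a 2×2
interaction with $n$ replicates per cell, *independent of depth*:

* at $\alpha = 0.05$, $n = 3$ the bound gives SE ≥ 0.37 log2, so no
  estimator can detect a 1-log2 change with 80% sensitivity at
  `padj < 0.05`; the recovery benchmark therefore runs at
  $\alpha = 0.01$ (SE ≈ 0.24), where the target is attainable. The
  null-calibration study keeps $\alpha = 0.05$.
* the per-feature significance gate mirrors the volcano definition
  (`|log2FC| > 1`), so planted effects shallower than 1 log2 can never
  be "significant decreases" regardless of power; the default study
  plants a 2-log2 5'UTR drop so that the graded 5'→3' profile
  (utr5 −2, TIS −1.4, first exon weak) is measurable through that gate.
  The resulting detected-decrease ordering — most frequent at the
  5'UTR, then the TIS, then the first coding exon, with CDS/3'UTR at
  zero — is structural.

Similarly, the spike-invariance study uses near-technical dispersion
($\alpha = 0.005$) because at $\alpha = 0.05$ the per-gene |log2FC|
sampling noise alone has median ≈ 0.19, obscuring the ≤ 0.1
normalization-bias readout it isolates.

What the simulator does *not* emulate: sequence-dependent biases
(ligation, nuclease), codon-level dwell times, uORF translation, isoform
mixtures within genes, batch structure, multimapping. Passing tests
demonstrate that the statistical machinery recovers known truths under
an idealized generative model — they do not certify performance on real
libraries with those artifacts.

# Numerical conventions

* Coordinates are 0-based half-open everywhere internally; GTF (1-based
  closed) is converted on import; minus-strand transcripts are
  reverse-complemented so transcript coordinates run 5'→3'.
* IRLS: log link, expected-information Wald covariance, convergence at
  deviance tolerance 1e-10, cap 100 iterations; non-converged or
  all-zero units report `NA` and propagate through BH without counting
  toward the number of tests.
* All thresholds are strict inequalities.
* Degenerate group comparisons (all values identical) return p = 1 with
  a warning rather than an error.
* Folding tie-breaks are deterministic, so structures are reproducible.

# Worked example

```{r example, eval = FALSE}
truth <- simulation_truth(n_genes = 500, seed = 42)
txs   <- generate_transcriptome(truth)
sim   <- simulate_ribo_rna(truth, txs, depth_rpf = 5e5, depth_rna = 5e5)

te <- run_te_analysis(list(
  txs = txs, reads = sim$reads, rna = sim$rna,
  treated = "DUX4_pulse_IFNg", untreated = "IFNg"))
te$summary

poly <- simulate_polysome(truth)
pa <- run_polysome_analysis(list(
  counts = poly, treated = "DUX4_pulse_IFNg", untreated = "IFNg",
  gene_sets = list(top = truth$genes$gene_id[truth$genes$class == "top"])))
summary(pa$high_over_sub)

utr <- run_utr_analysis(list(
  utrs = extract_utr5_set(txs),
  groups = data.frame(
    gene_id = truth$genes$gene_id[truth$genes$class == "dux4_target"],
    group = "dux4_target")))
utr$comparisons$dux4_target
```

# Known limitations

* The builtin folding energies are unitless; absolute MFE values are not
  comparable with RNAfold output (ranks and group contrasts are).
* One representative (longest coding) transcript per gene; an
  all-isoforms mode exists but gene-level counting does not model
  isoform switching.
* The dispersion estimator targets calibration at small replicate
  numbers with many units; with very few units (< ~20) the trend
  degenerates to a constant.
* Genome-coordinate BAM input is out of scope; reads are consumed in
  transcript coordinates (the format the simulator emits).
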