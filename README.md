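# riboTE

Feature-resolved translational profiling in R: differential translation
efficiency from Ribo-seq + RNA-seq, spike-in normalized differential
polysome association, and 5'UTR minimum-free-energy structure analysis —
with a deterministic synthetic-study generator that plants known effects
so the whole pipeline can be validated end to end.

## The problem

A burst of a strong transcriptional program (the motivating case is a
pulse of the embryonic factor DUX4 in myoblasts) can suppress global
protein synthesis while the program's own transcripts stay translated.
Dissecting that requires asking, per mRNA and per mRNA *region*, whether
ribosome occupancy changed beyond what mRNA abundance explains.

riboTE implements the three analysis arms:

1. **Ribo-seq / RNA-seq translation efficiency (TE).** RPF reads are
   length-filtered (26–29 nt), P-sites assigned (5' end + calibrated
   offset), and counted into five mRNA features per gene — 5'UTR, a
   ±13 nt window around the start codon (TIS), the first coding exon,
   CDS, 3'UTR. Per unit, a negative-binomial GLM with design
   `~ assay + condition + assay:condition` tests

   `H0: log2(treated/untreated | Ribo-seq) − log2(treated/untreated | RNA-seq) = 0`

   by Wald statistic with BH adjustment, independently per feature.
   Size factors (median-of-ratios), a trend-shrunk method-of-moments
   dispersion estimator, per-feature nonspecific filtering, and
   exclusion of transcriptionally altered genes are built in.
2. **Polysome profiling.** Sub/low/high gradient fractions plus total
   input, normalized to exogenous spike-in totals, analyzed three ways:
   each fraction vs. total (ratio of ratios), the initiation-sensitive
   high/sub ratio, and simple differential expression within the high
   fraction; plus gene-set shift summaries (e.g. TOP mRNAs) with
   Mann–Whitney tests.
3. **5'UTR structure.** Minimum free energy per 100 nt from a built-in
   pair-additive folding DP (rank-proxy scores, brute-force-verified) or
   an external RNAfold-compatible engine, compared between gene groups.

The synthetic-data module generates an entire study — GTF + genome
FASTA, RPF reads with 3-nt periodicity and planted start-proximal
depletion, RNA-seq counts, polysome fraction counts with spike-in totals
encoding an extraction-efficiency difference — byte-identically
reproducible from a seed.

## Worked example

```r
library(riboTE)

truth <- simulation_truth(n_genes = 500, seed = 42)
txs   <- generate_transcriptome(truth)
sim   <- simulate_ribo_rna(truth, txs, depth_rpf = 5e5, depth_rna = 5e5)

te <- run_te_analysis(list(
  txs = txs, reads = sim$reads, rna = sim$rna,
  treated = "DUX4_pulse_IFNg", untreated = "IFNg"))
te$summary
#>          feature tested sig_down sig_up frac_down
#> 1           utr5    373       54      1 0.1447721
#> 2            tis    392       46      2 0.1173469
#> 3 first_cds_exon    473        0      0 0.0000000
#> 4            cds    481        0      0 0.0000000
#> 5           utr3    170        0      0 0.0000000
```

Significant TE decreases (|log2FC| > 1, padj < 0.05) concentrate at the
5'UTR, then the TIS window, and vanish by the first coding exon — the
planted start-proximal initiation defect, localized. The metagene QC
confirms the planted 85% frame-0 periodicity:

```r
te$metagene[["DUX4_pulse_IFNg"]]
#> metagene profile at start_codon, window [-50, 100], 273841 P-sites
#> frame fractions: 0.849 / 0.100 / 0.050
```

Polysome arm — the high/sub contrast calls the initiation-blocked class
down, and the TOP-like set stays polysome-associated while the
background is depleted:

```r
poly <- simulate_polysome(truth)
pa <- run_polysome_analysis(list(
  counts = poly, treated = "DUX4_pulse_IFNg", untreated = "IFNg",
  gene_sets = list(top = truth$genes$gene_id[truth$genes$class == "top"])))
summary(pa$high_over_sub, padj_thresh = 0.01)
#> contrast 'polysome': 482 units (482 tested)
#>   up (log2FC > 1, padj < 0.01):   0
#>   down (log2FC < -1, padj < 0.01): 137
pa$gene_set_shifts$top[c("median", "p_value")]
#> $median
#>        set background
#>  0.0934669 -0.1587492
#> $p_value
#> [1] 0.000941
```

Folding, with the hand-checkable classic:

```r
fold_mfe("GGGAAACCC")
#> GGGAAACCC
#> (((...))) (-9, builtin)
```

## Package layout

* `R/annotation.R`, `R/features.R` — GTF/FASTA parsing, transcript
  models, feature derivation, 5'UTR sets and overrides
* `R/ribo.R` — RPF filtering, P-site calibration/assignment, feature
  counting, metagene QC
* `R/count-matrix.R`, `R/size-factors.R`, `R/dispersion.R`,
  `R/nb-glm.R`, `R/diff-test.R` — the NB differential framework
* `R/polysome.R` — spike-in normalization and the three polysome
  formulations
* `R/fold.R`, `src/nussinov.cpp` — structure prediction
* `R/simulate.R` — the synthetic study generator
* `R/workflow.R` — `run_te_analysis()`, `run_polysome_analysis()`,
  `run_utr_analysis()`
* `vignettes/translational-profiling.Rmd` — models, assumptions,
  parameter choices, limitations
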