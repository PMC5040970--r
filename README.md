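# netprep

Pre-processing and co-expression network inference for large, heterogeneous
microarray compendia.

## The problem

Public repositories hold tens of thousands of expression arrays, and pooling
them ought to give genome-scale co-expression networks. It usually does the
opposite: genes expressed only in particular tissues or biological processes
are silent in most columns of a pooled matrix, variance (IQR) filtering
discards them, and the network built from the pooled dataset covers fewer
genes than networks from small homogeneous collections. `netprep` implements
the pipeline that works around this: rigorous per-array quality control and
normalization, data-driven IQR threshold selection, keyword classification
of submissions into tissue- and process-specific datasets, independent
per-class preprocessing, and union networks that recover the
category-specific genes the aggregate run loses.

## What it computes

Given a probe-level expression matrix, submission metadata and a probe-set
to gene annotation map, the pipeline runs:

* **dedup + QC** — exact duplicates by content digest; description matching
  (exact matches auto-removed, token-set Jaccard ≥ 0.8 flagged for review);
  scale factors (fail if > 3× the submission mean), spike-in presence, and
  RLE/NUSE diagnostics from a median-polish probe-level model (fail if IQR
  > 0.75 or median further than 0.075 from centre);
* **normalization** — Tukey-biweight probe-set summarization, trimmed-mean
  scaling to target intensity 1000, log2, per-gene mean centering, quantile
  normalization;
* **IQR filtering** — per-gene IQR (type-7 quantiles), thresholded either at
  the minimum of the IQR-profile derivative (steepest slope) or at the
  centre of the fullest 0.025-wide histogram bin (the dataset's
  characteristic IQR); genes with IQR < q are eliminated;
* **networks** — all-pairs Pearson correlation with a permutation-FDR
  threshold, and B-spline mutual information (rank-scaled, order-3 splines,
  in nats) with a pooled permutation null and data-processing-inequality
  pruning; per-class networks are combined as set unions of vertices and
  edges, duplicate edges keeping the maximum score.

A seeded synthetic-compendium generator (`generate_compendium()`) plants
category-specific genes, duplicates, outlier arrays, spike-in failures and
linear/quadratic/sinusoidal gene–gene dependencies, so every stage has
ground truth at desk scale.

## Worked example

```r
library(netprep)

comp <- generate_compendium(synth_config(seed = 1))
run  <- run_partitioned(comp, filter_method = "histogram",
                        control_ids = comp$truth$control_probe_sets,
                        pcc = pcc_config(seed = 11),
                        mi  = mi_config(seed = 12))

run$ledger[1:3, c("dataset", "arrays_collected", "duplicates_removed",
                  "qc_failed", "arrays_remaining", "genes_after_filter", "q")]
#>               dataset arrays_collected duplicates_removed qc_failed
#> 1            complete              508                  8         3
#> 2         tissue/Root              100                  0         0
#> 3 process/Development              124                  0         0
#>   arrays_remaining genes_after_filter      q
#> 1              497                155 0.0375
#> 2              100                232 0.0125
#> 3              124                159 0.0375

gain_report_from_run(run)
#>   method union_vertices complete_vertices complete_input_genes gain_vs_network
#> 1    pcc            137                84                  155              53
#> 2     mi            240               155                  155              85
```

Reading the ledger: of 508 collected arrays, 8 were duplicates (2 exact, 6
from near-duplicate submissions) and 3 failed QC (2 planted outlier arrays
caught by the RLE centre rule, 1 spike-in failure), leaving 497. On the
complete dataset the histogram-mode threshold q = 0.0375 keeps 155 of 240
genes — the ~80 category-specific genes are near-silent in four of five
categories and fail. Each per-class run selects its own threshold and keeps
its own active genes, so the union networks cover more genes than the
complete-dataset networks for both construction methods (`gain_vs_network`
of +53 PCC, +85 MI): the pipeline's central result, here reproduced on data
where the gained genes are planted and known.

`autoplot()` methods draw the IQR profile and histogram (the threshold
plots), network score histograms, and `tidy()`/`glance()` turn every result
into tibbles.

A thin command-line wrapper over the same functions is in
`exec/netprep-cli.R` (`synth`, `filter`, `network`, `union`, `stats`
subcommands).

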