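# dnbtip

Tipping-point detection in replicated time-course gene-expression data
via dynamic network biomarkers (DNB), with module-gene prioritization
and focal-gene correlation subnets.

## The problem

Disease progression is often nonlinear: a long, quasi-stable pre-disease
phase ends in an abrupt qualitative transition (the motivating system is
monthly liver expression profiles from a carcinogen-induced mouse model,
four animals per month over eight months, where cirrhotic tissue tips
into carcinoma). Static differential expression cannot locate the
transition in advance. DNB theory predicts that just before the tipping
point a specific group of genes — the *dominant group* — shows rising
fluctuations (SD_i), rising mutual correlation (PCC_i), and falling
correlation to everything else (PCC_o). The package scores these with
the criticality index

    CI(t) = SD_i(t) * PCC_i(t) / (PCC_o(t) + eps)

computed per time point across replicates; the CI peak marks the tipping
point. Around that core the package provides the full analysis pipeline:

* `expression_series()` + TSV/edge-list/GMT readers and writers;
* `simulate_dataset()` — a generator that plants a known transition
  (block-covariance multivariate normal), plus a consistent network,
  pathway annotation, and ground truth for recovery tests;
* `test_deg_across_time()`, `deg_sets_vs_baseline()` — FDR-controlled
  DEG screening (empirical-Bayes moderated by default) with UpSet-style
  intersection summaries; `fuzzy_cmeans()` — temporal pattern clustering;
* `scan_time_points()`, `permutation_test()` — dominant-group search,
  CI series, tipping detection, permutation significance;
* `build_priority_table()` + `rank_dnb_genes()` — the four-criteria
  prioritization of module genes (DEG-neighbour ratio, pathway count,
  DEG flag, cluster membership);
* `subnet_dynamics()` — per-month focal-gene correlation rankings and
  correlation-weight shares around the tipping months;
* `ihc_score()`, `fold_change_ddct()`, `roc_auc()` — the exactly
  specified clinical scoring rules;
* `run_pipeline()` — one-config orchestration with a JSON report.

## Worked example

Simulate the standard study design (500 genes, a 10-gene module tipping
at month 6, 8 months x 4 replicates), scan it, and rank the module:

```r
library(dnbtip)
ds  <- simulate_dataset(simulation_config(), seed = 7)
res <- scan_time_points(ds$series)
res
#> dnb_result: CI series over 8 time points
#>     1     2     3     4     5     6     7     8
#> 0.000 2.146 2.349 2.320 2.998 4.634 2.519 2.422
#> tipping point: 6
```

The CI series is flat (~2.1–3.0, the noise floor of a 4-replicate
design) everywhere except month 6, where the planted module nearly
doubles it: the detected tipping point matches the planted `t* = 6`.
The per-time table shows why — at month 6 the winning group's mean SD
jumps to 2.8 (baseline ~1) while its outside correlation stays at the
background level:

```r
res$ci_table
#>   t n sd_in pcc_in pcc_out    ci
#>   ...
#>   6 7 2.835  0.817   0.499 4.634
#>   ...
permutation_test(ds$series, n_perm = 99, seed = 8)$p_value
#> [1] 0.05
```

Rank the planted module genes by the four priority criteria, using the
analysed DEG results and the simulated network/pathways:

```r
deg <- test_deg_across_time(ds$series)
tab <- build_priority_table(ds$truth$dnb_genes, ds$network, deg,
                            NULL, ds$pathways)
head(rank_dnb_genes(tab), 3)
#>   gene_id criterion1 criterion2 criterion3 criterion4 rank
#> 1   G0298  0.4166667          3          0          0    1
#> 2   G0476  0.2000000          2          0          0    2
#> 3   G0194  0.1818182          0          0          0    3
ds$truth$top_gene
#> [1] "G0298"
```

The planted top gene wins on criterion 1 (42% of its network neighbours
are detected DEGs, versus ~20% background) with criterion 2 (pathway
count) as tie-breaker. `subnet_dynamics(ds$series, "G0298", res$tipping)`
then reports which genes co-vary with it month by month and their
correlation-weight shares around months 5–6.

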