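# ionstim

Glioma transcriptomics through a metal-ion-stimulation gene signature:
subtype discovery, prognosis, and a Shapley-guided hybrid grade classifier.

Gliomas respond heterogeneously to environmental metal-ion exposure, and the
genes annotated to metal-ion-stimulation response carry clinically relevant
signal: they separate tumors from normal tissue, split tumors into two
response states (M1/M2) associated with grade and IDH status, and a small
panel of them predicts overall survival. ionstim packages that entire
analysis as reusable, tested R functions for anyone working with
gene-by-sample expression matrices and clinical annotations — together with
a seeded synthetic-data generator that reproduces the statistical structure
every stage assumes, so the pipeline can be exercised and validated end to
end without downloading any cohort.

## What is inside

* **Differential expression + signature intersection** — per-gene Welch t
  with Benjamini–Hochberg FDR, significance at |log₂FC| ≥ 2 and q < 0.05;
  intersection with the signature set yields the DEMISGs (differentially
  expressed metal-ion-stimulation genes).
* **Consensus clustering** (from scratch, Monti-style) — for rep
  r = 1..R, draw 80% of samples, run k-means; consensus
  M(i,j) = #co-clustered / #co-sampled; assignments by average-linkage
  hierarchical clustering of 1 − M; automated choice of k from the CDF
  delta-area and per-cluster consensus, with the full per-k report for
  human override.
* **Response score** — per-sample sum of the two tSNE coordinates of the
  DEMISG matrix; the higher-scoring cluster is named M2.
* **Prognostic model** — univariate Cox screen → multivariate Cox →
  risk score `Σᵢ βᵢ·xᵢ` → median split → Kaplan–Meier + log-rank,
  IPCW cumulative/dynamic time-dependent ROC at 1/3/5 years, and an
  independence analysis against age, grade and IDH.
* **Dual feature selection** — recursive feature elimination over a
  boosted-tree model, and ranking by mean |TreeSHAP attribution|; per-gene
  logistic diagnostic AUC with a 0.90 flagging bar.
* **Hybrid grade classifier** — tune a boosted-tree classifier (grid or
  Bayesian-style search), explain the external cohort with TreeSHAP,
  cluster the per-sample attribution matrix with K-means (k = 2), map
  clusters to grades by accuracy-maximizing assignment, and benchmark
  base vs hybrid over repeated splitting schemes with paired t-tests on
  accuracy, sensitivity, specificity, precision, FDR and F1.

The methods vignette (`vignettes/methods.Rmd`) documents the model
assumptions, every tunable parameter, the numerical choices, and what
passing tests on synthetic data do and do not show.

## Worked example

```r
library(ionstim)

cfg <- synth_config(n_genes = 500, n_signature_genes = 80, n_tumor = 150,
                    n_normal = 60, n_demisg = 40, n_subtype_genes = 30, seed = 7)
d <- generate_dataset(cfg)

deg <- run_deg(d$expr, d$ann$group, group1 = "tumor", group2 = "normal")
deg
#> Differential expression: tumor vs normal
#>   500 genes tested, 40 significant (|logFC| >= 2, q < 0.05)
#>   14 up, 26 down
demisg <- intersect_signature(deg, d$signature)   # 40 DEMISGs

tumor <- d$ann$sample_id[d$ann$group == "tumor"]
cons  <- consensus_cluster(d$expr[demisg, tumor],
                           consensus_config(max_k = 4, reps = 200, seed = 7))
select_k(cons)$report
#>   k  area delta_area min_cluster_consensus mean_cluster_consensus qualifies
#> 1 2 0.503      0.503                 1.000                  1.000      TRUE
#> 2 3 0.629      0.249                 0.743                  0.802     FALSE
#> 3 4 0.742      0.180                 0.637                  0.682     FALSE
```

k = 2 is the only qualifying choice: both clusters are perfectly stable
(consensus 1.0), while k = 3 and 4 would create clusters whose members
co-cluster in barely two-thirds of resamples. Scoring and naming the
subtypes, then the prognostic model:

```r
emb <- response_score(tsne_embed(d$expr[demisg, tumor], perplexity = 30, seed = 7))
subtype <- label_subtypes(cons$k[["2"]]$assignments, emb$score)
compare_scores(emb$score, subtype)
#> mean M1 = -3.1, mean M2 = 3.2, Welch p = 2.1e-43

annT <- d$ann[d$ann$group == "tumor", ]
uni  <- univariate_screen(d$expr[, tumor], annT, demisg)  # 23/40 selected
mv   <- multivariate_fit(d$expr[, tumor], annT, uni$term[uni$selected])
panel <- mv$table[mv$table$selected, ]
#>  term   beta    hr        p
#> g0003  0.617 1.853 4.57e-07
#> g0025 -0.237 0.789 4.05e-02

risk <- risk_scores(d$expr[, tumor], panel$term, panel$beta)
km_logrank(annT$os_time, annT$os_event, risk$group)
#> log-rank chi2 = 27.0, p = 2e-07
time_dependent_roc(risk$scores, annT$os_time, annT$os_event, c(1, 3, 5))
#>    t1    t3    t5
#> 0.712 0.712 0.754
```

The high/low median split separates survival sharply (log-rank p = 2e-07)
and the score discriminates 1-, 3- and 5-year outcomes with AUC above 0.7 —
the behaviour expected when the generator's planted hazard drivers sit
inside the recovered panel. `run_pipeline()` chains all of the above plus
feature selection and the hybrid-classifier benchmark under one master seed.

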