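#' Run the full metal-ion-stimulation analysis pipeline on synthetic data
#'
#' Chains every stage end to end: synthetic data generation, tumor-vs-normal
#' differential expression and signature intersection (DEMISGs), consensus
#' clustering of tumor samples over the DEMISGs with automated k selection,
#' tSNE response scores and M1/M2 labelling, univariate-to-multivariate Cox
#' screening with risk score / median split / Kaplan-Meier / log-rank /
#' time-dependent ROC and independent-prognostic-factor analysis, dual
#' feature selection (RFE + Shapley ranking) with per-gene diagnostic AUC,
#' and the base-vs-hybrid grade-classifier benchmark.
#'
#' Everything is deterministic given `config$seed`: stage seeds are derived
#' from it.
#'
#' @param config a [synth_config()]; its seed drives the whole run.
#' @param reps consensus-clustering repetitions (default 200; the reference
#'   call uses 1000, scaled here to desk size).
#' @param max_k largest k evaluated by consensus clustering.
#' @param perplexity tSNE perplexity; default adapts to the tumor sample
#'   count (at most 30).
#' @param horizons time-dependent ROC horizons; horizons beyond follow-up are
#'   dropped.
#' @param n_schemes benchmark splitting schemes.
#' @param algorithms benchmark tuning strategies.
#' @param budget Bayesian tuning budget.
#' @param run_rfe run the (slower) recursive-feature-elimination arm
#'   (default TRUE).
#' @param external_fraction fraction of tumor samples held out as the
#'   benchmark's external validation set.
#' @return A list with every stage's outputs (see Details in the vignette).
#' @export
run_pipeline <- function(config = synth_config(),
                         reps = 200L, max_k = 4L, perplexity = NULL,
                         horizons = c(1, 3, 5), n_schemes = 10L,
                         algorithms = c("xgb_grid", "xgb_bayes"),
                         budget = 10L, run_rfe = TRUE,
                         external_fraction = 0.4) {
  seed <- config$seed
  data <- generate_dataset(config)
  tumor_ids <- data$ann$sample_id[data$ann$group == "tumor"]
  ann_tumor <- data$ann[data$ann$group == "tumor", , drop = FALSE]

  deg <- run_deg(data$expr, data$ann$group, group1 = "tumor",
                 group2 = "normal")
  demisg <- intersect_signature(deg, data$signature)
  if (length(demisg) < 2) stop("too few DEMISGs recovered to continue")

  expr_dem <- data$expr[demisg, tumor_ids, drop = FALSE]
  cons <- consensus_cluster(expr_dem,
                            consensus_config(max_k = max_k, reps = reps,
                                             seed = sub_seed(seed, 31L)))
  ksel <- select_k(cons)

  n_t <- length(tumor_ids)
  if (is.null(perplexity)) perplexity <- min(30, floor((n_t - 2) / 3))
  emb <- tsne_embed(expr_dem, perplexity = perplexity,
                    seed = sub_seed(seed, 41L))
  emb <- response_score(emb)
  assign2 <- cons$k[["2"]]$assignments
  subtype <- label_subtypes(assign2, emb$score)
  score_cmp <- compare_scores(emb$score, subtype)

  uni <- univariate_screen(data$expr[, tumor_ids, drop = FALSE], ann_tumor,
                           candidates = demisg)
  screened <- uni$term[uni$selected]
  if (!length(screened)) screened <- uni$term[order(uni$p)][1:min(5, nrow(uni))]
  multi <- multivariate_fit(data$expr[, tumor_ids, drop = FALSE], ann_tumor,
                            screened)
  panel <- multi$table$term[multi$table$selected]
  if (length(panel) < 2) {
    panel <- multi$table$term[order(multi$table$p)][seq_len(min(5, nrow(multi$table)))]
  }
  panel_fit <- multivariate_fit(data$expr[, tumor_ids, drop = FALSE],
                                ann_tumor, panel)
  risk <- risk_scores(data$expr[, tumor_ids, drop = FALSE], panel,
                      panel_fit$table$beta)
  km <- km_logrank(ann_tumor$os_time, ann_tumor$os_event, risk$group)
  horizons <- horizons[horizons <= max(ann_tumor$os_time)]
  tdroc <- if (length(horizons)) {
    time_dependent_roc(risk$scores, ann_tumor$os_time, ann_tumor$os_event,
                       horizons)
  } else NULL
  indep <- independence_analysis(ann_tumor, risk$scores)

  # grade classification over the DEMISGs (tumor samples, high grade positive)
  x_grade <- t(expr_dem)
  y_grade <- ann_tumor$grade
  shap_model <- fit_boosted(x_grade, as_binary(y_grade, "high"),
                            seed = sub_seed(seed, 51L))
  shap_rank <- shap_select(shap_model, x_grade,
                           top_n = min(15L, ncol(x_grade)))
  rfe_rank <- if (run_rfe) {
    rfe_select(x_grade, as_binary(y_grade, "high"),
               seed = sub_seed(seed, 52L))
  } else NULL
  feat_overlap <- if (run_rfe) consensus_features(rfe_rank, shap_rank) else
    shap_rank$selected
  diag_auc <- diagnostic_auc(x_grade, as_binary(y_grade, "high"),
                             genes = utils::head(shap_rank$ranking, 6),
                             seed = sub_seed(seed, 53L))

  ext_idx <- stratified_subsample(y_grade, external_fraction,
                                  seed = sub_seed(seed, 61L))
  bench <- run_benchmark(x_grade[-ext_idx, , drop = FALSE],
                         y_grade[-ext_idx],
                         x_grade[ext_idx, , drop = FALSE],
                         y_grade[ext_idx],
                         n_schemes = n_schemes, algorithms = algorithms,
                         positive = "high", budget = budget,
                         seed = sub_seed(seed, 62L))
  stability <- lapply(bench$shap, shap_stability)

  list(data = data, deg = deg, demisg = demisg,
       consensus = cons, k_selection = ksel,
       embedding = emb, subtype = subtype, score_comparison = score_cmp,
       cox_univariate = uni, cox_multivariate = multi, panel = panel,
       panel_fit = panel_fit$table, risk = risk, km = km,
       time_roc = tdroc, independence = indep,
       shap_rank = shap_rank, rfe_rank = rfe_rank,
       feature_overlap = feat_overlap, diagnostic_auc = diag_auc,
       benchmark = bench, shap_stability = stability)
}
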