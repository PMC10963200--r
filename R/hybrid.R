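#' Tune and fit a boosted-tree grade classifier
#'
#' Two tuning strategies over xgboost's binary-logistic objective:
#' `"xgb_grid"` - exhaustive grid search (desk-scale default grid: depth
#' 2/3/4 x learning rate 0.1/0.3, 150 rounds) with stratified k-fold
#' cross-validated accuracy, ties broken toward smaller tree depth then fewer
#' trees; `"xgb_bayes"` - Bayesian-style optimization implemented as seeded
#' random search guided by a random-forest surrogate over the declared space
#' (`nrounds`, `max_depth`, `eta` on a log scale, `min_child_weight`) with a
#' fixed evaluation budget. Grid tuning is deterministic given the folds;
#' folds are fixed by the seed.
#'
#' @param x samples x features matrix (column names required).
#' @param y binary labels (0/1, logical, or two-level factor/character).
#' @param algorithm `"xgb_grid"` or `"xgb_bayes"`.
#' @param folds stratified CV folds (default 5).
#' @param grid data.frame of hyperparameter combinations for grid tuning
#'   (columns among `max_depth`, `eta`, `gamma`, `min_child_weight`,
#'   `subsample`, `colsample_bytree`, `nrounds`).
#' @param space named list of `c(lo, hi)` bounds for Bayesian tuning.
#' @param budget evaluation budget for Bayesian tuning (default 25).
#' @param seed integer seed.
#' @return An object of class `tuned_model`: `algorithm`, `tuning`,
#'   `hyperparameters`, `nrounds`, `cv_folds`, `cv_accuracy`, `model` (the
#'   fitted booster, refit on the full training data), `feature_ids`.
#' @export
tune_and_fit <- function(x, y, algorithm = c("xgb_grid", "xgb_bayes"),
                         folds = 5L, grid = NULL, space = NULL, budget = 25L,
                         seed = 1L) {
  algorithm <- match.arg(algorithm)
  y <- as_binary(y)
  if (is.null(colnames(x))) stop("feature matrix needs column names")
  folds_id <- stratified_folds(y, folds, seed = sub_seed(seed, 7L))
  eval_cfg <- function(cfg, s) {
    nr <- if (!is.null(cfg$nrounds)) cfg$nrounds else 60
    cv_accuracy(x, y, folds_id, params = cfg[setdiff(names(cfg), "nrounds")],
                nrounds = nr, seed = s)
  }

  if (algorithm == "xgb_grid") {
    if (is.null(grid)) {
      grid <- expand.grid(max_depth = c(2L, 3L, 4L), eta = c(0.1, 0.3),
                          nrounds = 150L)
    }
    if (nrow(grid) == 0) stop("empty search space")
    accs <- vapply(seq_len(nrow(grid)), function(i) {
      eval_cfg(as.list(grid[i, , drop = FALSE]), sub_seed(seed, 100L + i))
    }, numeric(1))
    nr_col <- if ("nrounds" %in% names(grid)) grid$nrounds else rep(60L, nrow(grid))
    dep <- if ("max_depth" %in% names(grid)) grid$max_depth else rep(0L, nrow(grid))
    best <- order(-accs, dep, nr_col)[1]
    cfg <- as.list(grid[best, , drop = FALSE])
    best_acc <- accs[best]
    tuning <- "grid"
  } else {
    if (is.null(space)) {
      space <- list(nrounds = c(50, 200), max_depth = c(2, 6),
                    eta = c(0.03, 0.3), min_child_weight = c(1, 10))
    }
    if (budget < 1) stop("empty search space")
    draw_cfg <- function(n) {
      data.frame(
        nrounds = round(stats::runif(n, space$nrounds[1], space$nrounds[2])),
        max_depth = round(stats::runif(n, space$max_depth[1],
                                       space$max_depth[2])),
        eta = exp(stats::runif(n, log(space$eta[1]), log(space$eta[2]))),
        min_child_weight = round(stats::runif(n, space$min_child_weight[1],
                                              space$min_child_weight[2]))
      )
    }
    n0 <- min(max(4L, budget %/% 3L), budget)
    evaluated <- with_seed(sub_seed(seed, 11L), draw_cfg(n0))
    evaluated$acc <- vapply(seq_len(n0), function(i) {
      eval_cfg(as.list(evaluated[i, setdiff(names(evaluated), "acc")]),
               sub_seed(seed, 200L + i))
    }, numeric(1))
    i <- n0
    while (i < budget) {
      i <- i + 1L
      cand <- with_seed(sub_seed(seed, 300L + i), draw_cfg(50L))
      pred <- if (requireNamespace("randomForest", quietly = TRUE)) {
        # few unique CV accuracies at small budgets are expected; the
        # surrogate only needs a rough ordering of candidates
        sur <- with_seed(sub_seed(seed, 400L + i), suppressWarnings({
          randomForest::randomForest(
            acc ~ ., data = evaluated, ntree = 200)
        }))
        stats::predict(sur, cand)
      } else {
        # fallback surrogate: linear model on the tuning coordinates
        sur <- stats::lm(acc ~ ., data = evaluated)
        stats::predict(sur, cand)
      }
      nxt <- cand[which.max(pred), , drop = FALSE]
      nxt$acc <- eval_cfg(as.list(nxt), sub_seed(seed, 200L + i))
      evaluated <- rbind(evaluated, nxt)
    }
    best <- order(-evaluated$acc, evaluated$max_depth, evaluated$nrounds)[1]
    cfg <- as.list(evaluated[best, setdiff(names(evaluated), "acc")])
    best_acc <- evaluated$acc[best]
    tuning <- "bayesian"
  }

  nrounds <- if (!is.null(cfg$nrounds)) cfg$nrounds else 60L
  params <- cfg[setdiff(names(cfg), "nrounds")]
  model <- fit_boosted(x, y, params, nrounds, seed = sub_seed(seed, 5L))
  structure(list(algorithm = algorithm, tuning = tuning,
                 hyperparameters = params, nrounds = nrounds,
                 cv_folds = folds, cv_accuracy = best_acc, model = model,
                 feature_ids = colnames(x)),
            class = "tuned_model")
}

#' @export
predict.tuned_model <- function(object, newdata, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  miss <- setdiff(object$feature_ids, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$feature_ids)
  if (length(miss) || length(extra)) {
    stop("feature mismatch; missing: ", paste(miss, collapse = ", "),
         "; unexpected: ", paste(extra, collapse = ", "))
  }
  p <- predict_prob(object$model, newdata[, object$feature_ids, drop = FALSE])
  if (type == "prob") p else as.integer(p > 0.5)
}

#' Shapley attributions of a boosted-tree model
#'
#' Per-sample, per-feature additive attributions from the tree-path-dependent
#' TreeSHAP algorithm, on the model's margin (log-odds) scale. For every
#' sample, `base_value + sum(attributions)` equals the model's margin output
#' (additivity).
#'
#' @param model a `tuned_model` or a raw xgboost booster.
#' @param x samples x features matrix matching the model's features.
#' @return An object of class `shap_matrix`: `values` (samples x features),
#'   `base_value`, `sample_ids`, `feature_ids`, `margin` (reconstructed
#'   model output).
#' @export
explain <- function(model, x) {
  if (inherits(model, "tuned_model")) {
    miss <- setdiff(model$feature_ids, colnames(x))
    extra <- setdiff(colnames(x), model$feature_ids)
    if (length(miss) || length(extra)) {
      stop("feature mismatch; missing: ", paste(miss, collapse = ", "),
           "; unexpected: ", paste(extra, collapse = ", "))
    }
    x <- x[, model$feature_ids, drop = FALSE]
    booster <- model$model
  } else {
    booster <- model
  }
  contrib <- stats::predict(booster, xgboost::xgb.DMatrix(x),
                            predcontrib = TRUE)
  bias_col <- which(colnames(contrib) %in% c("BIAS", "(Intercept)"))
  if (!length(bias_col)) bias_col <- ncol(contrib)
  base <- contrib[, bias_col]
  values <- contrib[, -bias_col, drop = FALSE]
  rownames(values) <- rownames(x)
  structure(list(values = values, base_value = base[1],
                 sample_ids = if (!is.null(rownames(x))) rownames(x) else
                   as.character(seq_len(nrow(x))),
                 feature_ids = colnames(values),
                 margin = rowSums(values) + base),
            class = "shap_matrix")
}

#' K-means clustering of a Shapley attribution matrix
#'
#' Clusters the raw attribution matrix (no scaling, base value excluded -
#' raw margin-scale attributions preserve the additive geometry) with
#' k-means, 10 random restarts, 300 iteration cap.
#'
#' @param shap a [explain()] result (or a plain numeric matrix).
#' @param k number of clusters (default 2, matching the two grade classes).
#' @param seed integer seed.
#' @return integer cluster label per sample.
#' @export
shap_kmeans <- function(shap, k = 2L, seed = 1L) {
  m <- if (inherits(shap, "shap_matrix")) shap$values else as.matrix(shap)
  if (sum(!duplicated(m)) < k) {
    stop("fewer distinct attribution rows (", sum(!duplicated(m)),
         ") than clusters (", k, ")")
  }
  with_seed(seed, stats::kmeans(m, centers = k, nstart = 10,
                                iter.max = 300)$cluster)
}

#' Map clusters to class labels and score the induced classifier
#'
#' For two clusters and two classes, the cluster-to-label bijection that
#' maximizes accuracy is chosen (for k = 2 this is the Hungarian assignment),
#' and the six confusion metrics are computed under that mapping. Any fixed
#' arbitrary mapping would make the metrics coin-flip dependent on cluster
#' numbering.
#'
#' @param clusters integer cluster label per sample.
#' @param truth true class label per sample.
#' @param positive the positive-class label (high grade in the grade model).
#' @return list with `mapping` (named character: cluster -> label),
#'   `predicted` labels, and `metrics` ([confusion_metrics()] output).
#' @export
map_clusters_to_labels <- function(clusters, truth, positive) {
  truth <- as.character(truth)
  classes <- sort(unique(truth))
  if (length(classes) != 2) stop("exactly two truth classes required")
  cl <- sort(unique(clusters))
  if (length(cl) > 2) stop("unsupported: more clusters than classes")
  negative <- setdiff(classes, positive)
  maps <- list(stats::setNames(c(positive, negative), cl[c(1, min(2, length(cl)))]),
               stats::setNames(c(negative, positive), cl[c(1, min(2, length(cl)))]))
  accs <- vapply(maps, function(m) mean(m[as.character(clusters)] == truth),
                 numeric(1))
  best <- maps[[which.max(accs)]]
  pred <- unname(best[as.character(clusters)])
  list(mapping = best, predicted = pred,
       metrics = confusion_metrics(pred, truth, positive))
}

metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                  "fdr", "f1")

#' Benchmark base vs SHAP-K-means hybrid classifiers over repeated splits
#'
#' For each of `n_schemes` splitting schemes, a distinct seeded stratified
#' 80% subsample of the training data is drawn and, per algorithm, a model is
#' tuned and fit ([tune_and_fit()]). The base classifier predicts the fixed
#' external validation set directly (probability threshold 0.5); the hybrid
#' classifier explains the external set ([explain()]), clusters the
#' attribution matrix with K-means (k = 2, [shap_kmeans()]) and maps clusters
#' to grades ([map_clusters_to_labels()]). Six metrics are computed for each,
#' paired t-tests compare base and hybrid per metric across schemes, and the
#' mean table (the four-model comparison layout) averages the per-scheme
#' values.
#'
#' @param train_x,train_y training expression (samples x features) and binary
#'   grade labels.
#' @param ext_x,ext_y fixed external validation set.
#' @param n_schemes number of splitting schemes (default 10).
#' @param algorithms tuning strategies to benchmark (see [tune_and_fit()]).
#' @param positive positive-class label (high grade).
#' @param train_fraction per-scheme training subsample fraction (default 0.8).
#' @param folds CV folds inside tuning.
#' @param retune re-tune hyperparameters in every scheme (default TRUE);
#'   when FALSE, hyperparameters are tuned once on the full training set and
#'   frozen across schemes.
#' @param budget Bayesian tuning budget.
#' @param grid optional grid for grid tuning.
#' @param seed integer master seed; the full benchmark is deterministic
#'   given it.
#' @param keep_shap keep per-scheme attribution matrices (for
#'   [shap_stability()]).
#' @return An object of class `benchmark_result`: `per_scheme` (long
#'   data.frame of metrics), `paired` (per algorithm x metric paired-t
#'   p-values; `NaN` when undefined, e.g. a single scheme), `mean_table`
#'   (metrics x model columns), `shap` (optional list of attribution
#'   matrices).
#' @export
run_benchmark <- function(train_x, train_y, ext_x, ext_y, n_schemes = 10L,
                          algorithms = c("xgb_grid", "xgb_bayes"),
                          positive = NULL, train_fraction = 0.8, folds = 5L,
                          retune = TRUE, budget = 15L, grid = NULL, seed = 1L,
                          keep_shap = TRUE) {
  ytr <- as_binary(train_y, positive)
  yev <- as_binary(ext_y, positive)
  miss <- setdiff(colnames(train_x), colnames(ext_x))
  if (length(miss)) {
    stop("external set lacks training features: ", paste(miss, collapse = ", "))
  }
  ext_x <- ext_x[, colnames(train_x), drop = FALSE]

  frozen <- NULL
  if (!retune) {
    frozen <- lapply(algorithms, function(alg) {
      tune_and_fit(train_x, ytr, alg, folds = folds, budget = budget,
                   grid = grid, seed = sub_seed(seed, 1L))
    })
    names(frozen) <- algorithms
  }

  rows <- list()
  shap_store <- stats::setNames(
    lapply(algorithms, function(a) vector("list", n_schemes)), algorithms)
  for (s in seq_len(n_schemes)) {
    idx <- stratified_subsample(ytr, train_fraction,
                                seed = sub_seed(seed, 1000L + s))
    xs <- train_x[idx, , drop = FALSE]
    ys <- ytr[idx]
    for (ai in seq_along(algorithms)) {
      alg <- algorithms[ai]
      sseed <- sub_seed(seed, 10000L + 97L * s + ai)
      model <- tryCatch({
        if (retune) {
          tune_and_fit(xs, ys, alg, folds = folds, budget = budget,
                       grid = grid, seed = sseed)
        } else {
          f <- frozen[[alg]]
          m <- fit_boosted(xs, ys, f$hyperparameters, f$nrounds,
                           seed = sseed)
          structure(list(algorithm = alg, tuning = f$tuning,
                         hyperparameters = f$hyperparameters,
                         nrounds = f$nrounds, cv_folds = folds,
                         cv_accuracy = NA_real_, model = m,
                         feature_ids = colnames(xs)),
                    class = "tuned_model")
        }
      }, error = function(e) stop("scheme ", s, " failed: ",
                                  conditionMessage(e)))
      base_pred <- as.integer(predict(model, ext_x) > 0.5)
      base_m <- confusion_metrics(base_pred, yev, positive = 1)
      sm <- explain(model, ext_x)
      cl <- shap_kmeans(sm, k = 2L, seed = sub_seed(seed, 20000L + s))
      hyb <- map_clusters_to_labels(cl, yev, positive = 1)
      if (keep_shap) shap_store[[alg]][[s]] <- sm
      for (kind in c("base", "hybrid")) {
        m <- if (kind == "base") base_m else hyb$metrics
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = s, algorithm = alg, model = kind,
          as.data.frame(m[metric_names]), stringsAsFactors = FALSE)
      }
    }
  }
  per_scheme <- do.call(rbind, rows)

  paired <- list()
  for (alg in algorithms) {
    ps <- stats::setNames(vapply(metric_names, function(mt) {
      b <- per_scheme[per_scheme$algorithm == alg &
                        per_scheme$model == "base", mt]
      h <- per_scheme[per_scheme$algorithm == alg &
                        per_scheme$model == "hybrid", mt]
      if (length(b) < 2 || !all(is.finite(b)) || !all(is.finite(h))) {
        return(NaN)
      }
      tryCatch(paired_t(h, b)$p, error = function(e) NaN)
    }, numeric(1)), metric_names)
    paired[[alg]] <- ps
  }

  cols <- list()
  for (alg in algorithms) {
    for (kind in c("base", "hybrid")) {
      sub <- per_scheme[per_scheme$algorithm == alg & per_scheme$model == kind,
                        metric_names, drop = FALSE]
      cols[[paste(alg, kind, sep = "_")]] <- colMeans(sub)
    }
  }
  mean_table <- as.data.frame(cols, row.names = metric_names)

  structure(list(per_scheme = per_scheme, paired = paired,
                 mean_table = mean_table,
                 shap = if (keep_shap) shap_store else NULL,
                 n_schemes = n_schemes, algorithms = algorithms),
            class = "benchmark_result")
}

#' Across-scheme stability of per-sample Shapley attributions
#'
#' Standard deviation, across splitting schemes, of each external sample's
#' per-feature attribution, summarized per sample and overall.
#'
#' @param shap_list list of `shap_matrix` objects over the same samples and
#'   features (one per scheme).
#' @return list with `per_sample` (data.frame: `sample_id`, `mean_sd`,
#'   `max_sd`) and `quantiles` of all per-sample-per-feature SDs.
#' @export
shap_stability <- function(shap_list) {
  stopifnot(length(shap_list) >= 1)
  vals <- lapply(shap_list, function(s) {
    if (inherits(s, "shap_matrix")) s$values else as.matrix(s)
  })
  d <- dim(vals[[1]])
  if (!all(vapply(vals, function(v) identical(dim(v), d), logical(1)))) {
    stop("attribution matrices differ in shape across schemes")
  }
  arr <- array(unlist(vals), dim = c(d[1], d[2], length(vals)))
  sds <- apply(arr, c(1, 2), stats::sd)
  ids <- if (inherits(shap_list[[1]], "shap_matrix")) {
    shap_list[[1]]$sample_ids
  } else as.character(seq_len(d[1]))
  list(
    per_sample = data.frame(sample_id = ids,
                            mean_sd = rowMeans(sds),
                            max_sd = apply(sds, 1, max),
                            stringsAsFactors = FALSE),
    quantiles = stats::quantile(sds, c(0, 0.25, 0.5, 0.75, 1))
  )
}
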