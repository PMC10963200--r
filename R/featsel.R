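#' @importFrom xgboost xgb.DMatrix xgb.train xgb.importance
NULL

as_binary <- function(y, positive = NULL) {
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(y))
  }
  y <- as.character(y)
  levs <- sort(unique(y))
  if (length(levs) != 2) stop("binary labels required, got: ",
                              paste(levs, collapse = ", "))
  if (is.null(positive)) positive <- levs[2]
  as.integer(y == positive)
}

# Fit a boosted-tree binary classifier (single thread, seeded).
fit_boosted <- function(x, y, params = list(), nrounds = 50, seed = 1L) {
  defaults <- list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                   gamma = 0, min_child_weight = 1, subsample = 1,
                   colsample_bytree = 1, nthread = 1, tree_method = "exact")
  params <- utils::modifyList(defaults, params)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  with_seed(seed, {
    xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                       verbose = 0)
  })
}

predict_prob <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(x))
}

# Cross-validated accuracy of a boosted-tree model over fixed folds.
cv_accuracy <- function(x, y, folds_id, params = list(), nrounds = 50,
                        seed = 1L) {
  accs <- vapply(sort(unique(folds_id)), function(f) {
    tr <- folds_id != f
    m <- fit_boosted(x[tr, , drop = FALSE], y[tr], params, nrounds,
                     seed = sub_seed(seed, f))
    pred <- as.integer(predict_prob(m, x[!tr, , drop = FALSE]) > 0.5)
    mean(pred == y[!tr])
  }, numeric(1))
  mean(accs)
}

#' Recursive feature elimination over a boosted-tree model
#'
#' Backward elimination: at each step the model is fit on the current feature
#' set, cross-validated accuracy is recorded, and the feature with the lowest
#' gain importance is dropped (features the model never splits on have gain
#' 0; ties break on gene id). The elimination order defines the ranking
#' (survivors rank best). The selected set is the feature set with the best
#' cross-validated accuracy (ties towards fewer features), or the top `keep`
#' of the ranking when `keep` is given.
#'
#' @param x samples x features numeric matrix with column names.
#' @param y binary labels (0/1, logical, or two-level character/factor).
#' @param folds number of stratified CV folds (default 5).
#' @param keep `"auto"` (best CV accuracy) or an integer number of features.
#' @param params,nrounds boosted-tree hyperparameters for the elimination
#'   fits (fixed small model: depth 3, eta 0.3, 50 rounds by default).
#' @param seed integer seed for folds and fits.
#' @return An object of class `ranked_features`: `method = "rfe"`, `ranking`
#'   (best first), `scores` (gain importance from the full-feature model),
#'   `selected`, and `cv` (data.frame of feature-set size vs CV accuracy).
#' @export
rfe_select <- function(x, y, folds = 5L, keep = "auto", params = list(),
                       nrounds = 50, seed = 1L) {
  y <- as_binary(y)
  if (min(table(y)) < folds) {
    stop("stratified folding impossible: a class has fewer than ", folds,
         " samples")
  }
  folds_id <- stratified_folds(y, folds, seed = sub_seed(seed, 99L))
  current <- colnames(x)
  if (is.null(current)) stop("feature matrix needs column names")
  elim <- character(0)
  cv <- data.frame(size = integer(0), accuracy = numeric(0))
  full_imp <- NULL
  step <- 0L
  while (TRUE) {
    step <- step + 1L
    xs <- x[, current, drop = FALSE]
    acc <- cv_accuracy(xs, y, folds_id, params, nrounds,
                       seed = sub_seed(seed, step))
    cv <- rbind(cv, data.frame(size = length(current), accuracy = acc))
    if (length(current) == 1L) break
    m <- fit_boosted(xs, y, params, nrounds, seed = sub_seed(seed, step))
    imp <- xgboost::xgb.importance(model = m)
    gain <- stats::setNames(rep(0, length(current)), current)
    gain[imp$Feature] <- imp$Gain
    if (is.null(full_imp)) full_imp <- gain
    o <- order(gain, names(gain)) # min gain first, gene id tiebreak
    drop <- names(gain)[o][1]
    elim <- c(elim, drop)
    current <- setdiff(current, drop)
  }
  ranking <- c(current, rev(elim))
  selected <- if (identical(keep, "auto")) {
    best <- cv[order(-cv$accuracy, cv$size), ][1, ]
    ranking[seq_len(best$size)]
  } else {
    ranking[seq_len(min(as.integer(keep), length(ranking)))]
  }
  structure(list(method = "rfe", ranking = ranking,
                 scores = full_imp[ranking], selected = sort(selected),
                 cv = cv),
            class = "ranked_features")
}

#' Shapley-attribution feature ranking
#'
#' Scores each feature by the mean absolute Shapley attribution (tree-path
#' dependent TreeSHAP, on the model's margin scale) over the supplied
#' samples, ranks descending (gene id as tiebreak), and selects the top
#' `top_n`.
#'
#' @param model a fitted boosted-tree model (e.g. from [rfe_select()]'s
#'   internals or [tune_and_fit()]).
#' @param x samples x features matrix; columns must match the model's
#'   features.
#' @param top_n number of features to select (default 15).
#' @return A `ranked_features` object with `method = "shap"`.
#' @export
shap_select <- function(model, x, top_n = 15L) {
  sm <- explain(model, x)
  score <- colMeans(abs(sm$values))
  o <- order(-score, names(score))
  ranking <- names(score)[o]
  structure(list(method = "shap", ranking = ranking, scores = score[o],
                 selected = sort(utils::head(ranking, max(0L, top_n)))),
            class = "ranked_features")
}

#' Intersection of two feature selections
#'
#' @param a,b `ranked_features` objects (or lists with a `selected` field).
#' @return Sorted character vector of features selected by both methods.
#' @export
consensus_features <- function(a, b) {
  sort(intersect(a$selected, b$selected))
}

#' Per-gene logistic diagnostic AUC
#'
#' Fits a single-covariate logistic model per gene on a stratified training
#' fraction and reports the AUC on the held-out fraction (or on an external
#' validation set when supplied). Genes exceeding `auc_threshold` are
#' flagged.
#'
#' @param x samples x features matrix.
#' @param y binary labels.
#' @param genes gene ids to evaluate (columns of `x`).
#' @param train_fraction stratified training fraction (default 0.7).
#' @param validation optional list `(x, y)` of an external evaluation set.
#' @param auc_threshold flagging bar (default 0.90).
#' @param seed integer seed for the split.
#' @return data.frame `gene`, `auc`, `flagged`.
#' @export
diagnostic_auc <- function(x, y, genes, train_fraction = 0.7,
                           validation = NULL, auc_threshold = 0.90,
                           seed = 1L) {
  y <- as_binary(y)
  idx <- stratified_subsample(y, train_fraction, seed = seed)
  xtr <- x[idx, , drop = FALSE]; ytr <- y[idx]
  if (is.null(validation)) {
    xev <- x[-idx, , drop = FALSE]; yev <- y[-idx]
  } else {
    xev <- validation$x; yev <- as_binary(validation$y)
  }
  if (length(unique(yev)) < 2) {
    stop("degenerate evaluation set: a single class present")
  }
  if (length(unique(ytr)) < 2) stop("degenerate training set")
  aucs <- vapply(genes, function(g) {
    df <- data.frame(y = ytr, x = xtr[, g])
    fit <- suppressWarnings(stats::glm(y ~ x, data = df, family = "binomial"))
    pred <- stats::predict(fit, newdata = data.frame(x = xev[, g]),
                           type = "response")
    auc_rank(pred, yev == 1)
  }, numeric(1))
  data.frame(gene = genes, auc = unname(aucs),
             flagged = unname(aucs) > auc_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
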