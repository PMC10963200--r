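#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided test with Satterthwaite degrees of freedom. Welch's form is the
#' default two-sample comparison throughout the pipeline: expression groups
#' rarely share a variance, and the cost relative to the pooled test is nil.
#'
#' @param x,y numeric vectors, each with at least 2 finite values.
#' @return list with `t` and two-sided `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("insufficient data: each group needs at least 2 observations")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in input")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # degenerate: no within-group variance; identical means => no evidence
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    stop("degenerate input: both groups have zero variance but differ in mean")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y equal-length numeric vectors (n >= 3), each with nonzero
#'   variance.
#' @return list with `r` in \[-1, 1\] and `p` from the t transform on n - 2
#'   degrees of freedom.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate input: zero variance")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' Chi-square test of independence with Cramer's V
#'
#' Cramer's V is defined on the uncorrected statistic,
#' `V = sqrt(chi2 / (N * (min(r, c) - 1)))`, so the Yates continuity
#' correction is off by default; enable it with `correct = TRUE` if a
#' corrected chi-square is wanted (V is then computed from that statistic).
#'
#' @param counts non-negative integer matrix of at least 2 rows and 2 columns.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return list with `chi2`, `p`, and `v` in \[0, 1\].
#' @export
chisq_cramers_v <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("contingency table needs at least 2 rows and 2 columns")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) stop("grand total must be positive")
  zr <- which(rowSums(counts) == 0)
  zc <- which(colSums(counts) == 0)
  if (length(zr)) stop("empty row margin at row ", paste(zr, collapse = ", "))
  if (length(zc)) {
    stop("empty column margin at column ", paste(zc, collapse = ", "))
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  chi2 <- unname(ht$statistic)
  v <- sqrt(chi2 / (n * (min(dim(counts)) - 1)))
  list(chi2 = chi2, p = ht$p.value, v = min(1, v))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Paired two-sided t-test
#'
#' @param a,b equal-length numeric vectors (n >= 2). All-identical
#'   differences are degenerate (zero variance) and raise an error rather
#'   than returning an arbitrary p-value.
#' @return list with `t` and two-sided `p`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (stats::var(d) == 0) {
    stop("degenerate input: all paired differences are identical")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Binary-classification confusion metrics
#'
#' Computes the six benchmark metrics (accuracy, sensitivity, specificity,
#' precision, FDR, F1) from predicted and true labels, with `positive` naming
#' the positive class (high-grade tumors in the grade classifier). Ratios
#' with a zero denominator are reported as `NaN` with `degenerate = TRUE`,
#' never silently as 0 — silent zeros would corrupt averaged benchmark
#' tables.
#'
#' @param pred,truth equal-length label vectors over exactly two classes.
#' @param positive the positive-class label.
#' @return list with counts `tp`, `fp`, `tn`, `fn`, the six metrics, and a
#'   `degenerate` flag.
#' @export
confusion_metrics <- function(pred, truth, positive) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(pred) < 1) stop("empty input")
  pred <- as.character(pred); truth <- as.character(truth)
  other <- setdiff(unique(c(pred, truth)), positive)
  if (length(other) > 1) {
    stop("labels outside {positive, negative}: ",
         paste(other, collapse = ", "))
  }
  p <- pred == positive
  t <- truth == positive
  tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
  ratio <- function(num, den) if (den > 0) num / den else NaN
  acc <- ratio(tp + tn, tp + fp + tn + fn)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  fdr <- if (tp + fp > 0) 1 - prec else NaN
  f1 <- if (is.finite(prec) && is.finite(sens) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else NaN
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = acc, sensitivity = sens, specificity = spec,
       precision = prec, fdr = fdr, f1 = f1,
       degenerate = !all(is.finite(c(acc, sens, spec, prec, fdr, f1))))
}

# Rank-based (Mann-Whitney) AUC of a score against binary labels; ties get
# half weight. Equals trapezoidal ROC integration.
auc_rank <- function(score, label) {
  label <- as.logical(label)
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: evaluation set has a single class")
  }
  r <- rank(score)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
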