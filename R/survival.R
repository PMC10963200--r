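#' @importFrom survival coxph Surv survfit survdiff
NULL

# Tidy a coxph fit into term/beta/HR/se/p/CI rows.
cox_fit_table <- function(fit) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  data.frame(
    term = rownames(co),
    beta = co[, "coef"],
    hr = exp(co[, "coef"]),
    se = co[, "se(coef)"],
    p = co[, "Pr(>|z|)"],
    ci_low = ci[, "lower .95"],
    ci_high = ci[, "upper .95"],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

make_surv_data <- function(expr, ann, genes) {
  expr <- as_expression_matrix(expr)
  check_genes_present(expr, genes)
  keep <- !is.na(ann$os_time) & !is.na(ann$os_event)
  ann <- ann[keep, , drop = FALSE]
  if (!nrow(ann)) stop("no samples with survival data")
  if (any(ann$os_time <= 0)) stop("os_time must be positive")
  x <- t(expr[genes, ann$sample_id, drop = FALSE])
  list(ann = ann, x = x)
}

#' Univariate Cox screening of candidate genes
#'
#' One single-covariate proportional-hazards fit per gene (Breslow tie
#' handling by default); genes with p below `alpha` are flagged as selected.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param ann annotation data.frame with `sample_id`, `os_time`, `os_event`
#'   (samples without survival data are dropped).
#' @param candidates gene ids to screen; all must be present in `expr`.
#' @param alpha selection threshold on the Wald p-value (default 0.05).
#' @param ties tie handling, `"breslow"` (default) or `"efron"`.
#' @return data.frame of per-gene Cox fits with a logical `selected` column.
#' @export
univariate_screen <- function(expr, ann, candidates, alpha = 0.05,
                              ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  d <- make_surv_data(expr, ann, candidates)
  if (sum(d$ann$os_event) == 0) stop("no events in the data")
  rows <- lapply(candidates, function(g) {
    df <- data.frame(time = d$ann$os_time, event = d$ann$os_event,
                     x = d$x[, g])
    fit <- survival::coxph(survival::Surv(time, event) ~ x, data = df,
                           ties = ties)
    tab <- cox_fit_table(fit)
    tab$term <- g
    tab
  })
  out <- do.call(rbind, rows)
  out$selected <- out$p < alpha
  out
}

#' Multivariate Cox fit of a gene panel
#'
#' Joint proportional-hazards fit of all genes. Warns when the number of
#' events falls below 10 per covariate or when the covariate matrix is
#' near-collinear (the most correlated gene pair is named). The full fit is
#' always reported; terms with p < 0.05 are flagged `selected` for use in
#' panel reduction.
#'
#' @inheritParams univariate_screen
#' @param genes gene ids entering the joint fit.
#' @return list with `table` (per-term fits plus `selected`) and `fit` (the
#'   underlying `coxph` object).
#' @export
multivariate_fit <- function(expr, ann, genes, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (length(genes) < 1) stop("need at least one gene")
  d <- make_surv_data(expr, ann, genes)
  if (sum(d$ann$os_event) == 0) stop("no events in the data")
  if (sum(d$ann$os_event) < 10 * length(genes)) {
    warning("fewer than 10 events per covariate; estimates may be unstable")
  }
  if (length(genes) > 1) {
    cc <- stats::cor(d$x)
    diag(cc) <- 0
    if (kappa(cbind(1, d$x)) > 1e8 || max(abs(cc)) > 0.999) {
      worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
      warning("near-collinear covariates: ", genes[worst[1]], " and ",
              genes[worst[2]])
    }
  }
  df <- data.frame(time = d$ann$os_time, event = d$ann$os_event, d$x,
                   check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", genes), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = ties)
  tab <- cox_fit_table(fit)
  tab$term <- gsub("`", "", tab$term)
  tab$selected <- tab$p < 0.05
  list(table = tab, fit = fit)
}

#' Gene-expression risk score with median split
#'
#' The per-sample risk score is the linear combination
#' `sum_i beta_i * x[gene_i, sample]`. Samples are split at the median score;
#' ties at the median go to the low-risk group (deterministic and
#' conservative).
#'
#' @param expr genes x samples log2 expression matrix.
#' @param genes model gene ids.
#' @param betas Cox coefficients, one per gene.
#' @return An object of class `risk_model`: list with `genes`, `betas`,
#'   `scores` (named per sample), `cutpoint`, `group` ("high"/"low" per
#'   sample).
#' @export
risk_scores <- function(expr, genes, betas) {
  expr <- as_expression_matrix(expr)
  check_genes_present(expr, genes)
  if (length(genes) != length(betas)) stop("genes and betas lengths differ")
  scores <- as.numeric(crossprod(expr[genes, , drop = FALSE], betas))
  names(scores) <- colnames(expr)
  cut <- stats::median(scores)
  group <- ifelse(scores > cut, "high", "low")
  structure(list(genes = genes, betas = betas, scores = scores,
                 cutpoint = cut, group = group),
            class = "risk_model")
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param time,event survival times and event indicators (1 = event).
#' @param group two-level grouping per sample (e.g. "high"/"low" risk).
#' @return list with `curves` (data.frame: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `chi2`, `p` (NA with `flag` when the log-rank
#'   statistic is undefined, e.g. zero events).
#' @export
km_logrank <- function(time, event, group) {
  if (length(unique(group)) != 2) stop("exactly two non-empty groups required")
  df <- data.frame(time = time, event = event, group = as.factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(
    group = sub("^group=", "", strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv, stringsAsFactors = FALSE
  )
  if (sum(event) == 0) {
    return(list(curves = curves, chi2 = NA_real_, p = NA_real_,
                flag = "no events: log-rank undefined"))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, chi2 = unname(sd$chisq), p = p, flag = NULL)
}

#' Time-dependent ROC AUC under IPCW
#'
#' Cumulative-case / dynamic-control AUC at each horizon `t`: cases are
#' samples with an observed event by `t`, controls are samples still at risk
#' beyond `t`. Both sides are weighted by inverse probability of censoring
#' (Kaplan-Meier of the censoring distribution): cases by `1/G(T_i-)`,
#' controls by `1/G(t)`. Tied risk values count one half.
#'
#' @param risk per-sample risk score (higher = worse).
#' @param time,event survival data, same order as `risk`.
#' @param horizons evaluation times (default 1, 3, 5 years).
#' @return named numeric vector of AUCs, one per horizon.
#' @export
time_dependent_roc <- function(risk, time, event, horizons = c(1, 3, 5)) {
  if (any(horizons > max(time))) {
    stop("horizon beyond the last observed time (", max(time), ")")
  }
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  gstep <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  g_at <- function(t) {
    s <- gstep(t)
    ifelse(s > 0, s, NA_real_)
  }
  aucs <- vapply(horizons, function(t) {
    case <- which(time <= t & event == 1)
    ctrl <- which(time > t)
    if (!length(case) || !length(ctrl)) return(NA_real_)
    w_case <- 1 / g_at(time[case] - 1e-10)
    w_ctrl <- rep(1 / g_at(t), length(ctrl))
    ok <- is.finite(w_case)
    case <- case[ok]; w_case <- w_case[ok]
    num <- 0; den <- 0
    for (i in seq_along(case)) {
      gt <- risk[case[i]] > risk[ctrl]
      eq <- risk[case[i]] == risk[ctrl]
      num <- num + w_case[i] * sum(w_ctrl * (gt + 0.5 * eq))
      den <- den + w_case[i] * sum(w_ctrl)
    }
    num / den
  }, numeric(1), USE.NAMES = FALSE)
  stats::setNames(aucs, paste0("t", horizons))
}

#' Independent-prognostic-factor analysis of the risk score
#'
#' Multivariate Cox fit of survival on the risk score together with age,
#' grade and IDH status. Rows with missing covariates are dropped (count
#' reported via message); constant covariates are dropped with a warning.
#'
#' @param ann annotation data.frame with `os_time`, `os_event`, `age`,
#'   `grade`, `idh` (tumor samples; `"none"` levels are treated as missing).
#' @param risk per-sample risk score aligned with `ann` rows.
#' @param ties tie handling for the partial likelihood.
#' @return data.frame of per-term Cox fits (term, beta, hr, se, p, CI).
#' @export
independence_analysis <- function(ann, risk, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  df <- data.frame(
    time = ann$os_time, event = ann$os_event, risk_score = risk,
    age = ann$age,
    grade = ifelse(ann$grade == "none", NA, ann$grade),
    idh = ifelse(ann$idh == "none", NA, ann$idh),
    stringsAsFactors = FALSE
  )
  keep <- stats::complete.cases(df)
  if (sum(!keep)) {
    message(sum(!keep), " samples dropped for missing covariates")
  }
  df <- df[keep, , drop = FALSE]
  covs <- c("risk_score", "age", "grade", "idh")
  const <- covs[vapply(covs, function(v) length(unique(df[[v]])) < 2,
                       logical(1))]
  if (length(const)) {
    warning("constant covariates dropped: ", paste(const, collapse = ", "))
    covs <- setdiff(covs, const)
  }
  if (!length(covs)) stop("no usable covariates")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covs, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  cox_fit_table(fit)
}
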