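#' Configuration for the synthetic glioma expression generator
#'
#' Builds and validates the parameter set that drives [generate_expression()]
#' and [generate_survival()]. The generator plants, on a log2 expression
#' scale, (i) a tumor-vs-normal differential block inside a named signature
#' gene set (the "DEMISG" genes), (ii) a two-subtype (M1/M2) differential
#' block within tumor samples, (iii) grade and IDH labels coupled to subtype
#' through logistic models with configurable odds ratios, and (iv) exponential
#' proportional-hazards survival driven by a small gene panel.
#'
#' Defaults encode the study conditions the rest of the pipeline is exercised
#' under: `tumor_effect = 3` so planted differential genes clear a
#' |logFC| >= 2 cutoff at `noise_sd = 1`; `grade_subtype_odds = (0.85/0.15)^2`
#' so grade equals subtype with a 15% flip probability under the symmetric
#' logistic link; `cox_betas` defaults to the five-gene risk-model
#' coefficients (0.2695063, 0.0924100, 0.4679576, 0.34006645, -0.2472611).
#'
#' @param n_genes total number of genes.
#' @param n_signature_genes size of the named signature set (<= `n_genes`).
#' @param n_tumor,n_normal sample counts per group.
#' @param n_demisg signature genes differential between tumor and normal.
#' @param n_subtype_genes signature genes differential between subtypes M1/M2.
#' @param tumor_effect,subtype_effect planted log2 fold-change magnitudes.
#' @param noise_sd standard deviation of Gaussian expression noise (log2 units).
#' @param grade_subtype_odds odds ratio linking subtype M2 to high grade.
#' @param idh_subtype_odds odds ratio linking subtype M1 to IDH-mutant.
#' @param cox_genes gene identifiers driving survival (default: first five
#'   signature genes).
#' @param cox_betas log-hazard coefficients, same length as `cox_genes`.
#' @param baseline_hazard baseline event rate (events per time unit, years).
#' @param censor_rate independent exponential censoring rate.
#' @param seed integer master seed; identical config + seed gives
#'   byte-identical output.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_genes = 1000L,
                         n_signature_genes = 100L,
                         n_tumor = 150L,
                         n_normal = 80L,
                         n_demisg = 40L,
                         n_subtype_genes = 30L,
                         tumor_effect = 3,
                         subtype_effect = 2,
                         noise_sd = 1,
                         grade_subtype_odds = (0.85 / 0.15)^2,
                         idh_subtype_odds = 9,
                         cox_genes = NULL,
                         cox_betas = c(0.2695063, 0.0924100, 0.4679576,
                                       0.34006645, -0.2472611),
                         baseline_hazard = 0.2,
                         censor_rate = 0.1,
                         seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_signature_genes = as.integer(n_signature_genes),
    n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
    n_demisg = as.integer(n_demisg),
    n_subtype_genes = as.integer(n_subtype_genes),
    tumor_effect = tumor_effect, subtype_effect = subtype_effect,
    noise_sd = noise_sd,
    grade_subtype_odds = grade_subtype_odds,
    idh_subtype_odds = idh_subtype_odds,
    cox_genes = cox_genes, cox_betas = cox_betas,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    seed = as.integer(seed)
  )
  pos <- c("n_genes", "n_signature_genes", "n_tumor", "n_normal",
           "n_demisg", "n_subtype_genes")
  for (f in pos) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("configuration error: '", f, "' must be a positive integer")
    }
  }
  if (cfg$n_signature_genes > cfg$n_genes) {
    stop("configuration error: n_signature_genes exceeds n_genes")
  }
  if (cfg$n_demisg > cfg$n_signature_genes) {
    stop("configuration error: n_demisg exceeds n_signature_genes")
  }
  if (cfg$n_subtype_genes > cfg$n_signature_genes) {
    stop("configuration error: n_subtype_genes exceeds n_signature_genes")
  }
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  if (cfg$baseline_hazard <= 0) {
    stop("configuration error: baseline_hazard must be positive")
  }
  if (cfg$censor_rate < 0) stop("configuration error: censor_rate must be >= 0")
  if (cfg$grade_subtype_odds <= 0 || cfg$idh_subtype_odds <= 0) {
    stop("configuration error: odds ratios must be positive")
  }
  if (is.null(cfg$cox_genes)) {
    cfg$cox_genes <- gene_ids(cfg)[seq_len(min(length(cfg$cox_betas),
                                                cfg$n_signature_genes))]
  }
  if (length(cfg$cox_genes) != length(cfg$cox_betas)) {
    stop("configuration error: cox_genes and cox_betas lengths differ")
  }
  if (!all(cfg$cox_genes %in% gene_ids(cfg))) {
    stop("configuration error: cox_genes contains identifiers outside the ",
         "generated gene set")
  }
  class(cfg) <- "synth_config"
  cfg
}

gene_ids <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))

#' Generate a synthetic log2 expression matrix with planted structure
#'
#' Draws gene-wise baseline means uniform on \[4, 10\], adds the configured
#' tumor-vs-normal shift (random sign per gene) on the first `n_demisg`
#' signature genes and the configured M1-vs-M2 shift on the first
#' `n_subtype_genes` signature genes (so the subtype structure is
#' discoverable from the differential signature genes, as the downstream
#' clustering assumes), then adds i.i.d. Gaussian noise. Tumor subtype is
#' Bernoulli(0.5); grade and IDH status are drawn from symmetric logistic
#' models whose odds ratios against subtype are configured. Normal samples
#' carry `"none"` for subtype, grade and IDH.
#'
#' @param config a [synth_config()].
#' @return A list with `expr` (genes x samples log2 matrix), `ann` (a
#'   data.frame of per-sample annotations: `sample_id`, `group`,
#'   `subtype_truth`, `grade`, `idh`, `age`, plus `os_time`/`os_event` filled
#'   by [generate_survival()]), `signature` (character vector of signature
#'   gene ids), and `truth` (the planted gene sets and effect signs).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  genes <- gene_ids(config)
  sig <- genes[seq_len(config$n_signature_genes)]
  demisg <- sig[seq_len(config$n_demisg)]
  subtype_genes <- sig[seq_len(config$n_subtype_genes)]
  samples <- c(sprintf("T%03d", seq_len(config$n_tumor)),
               sprintf("N%03d", seq_len(config$n_normal)))
  group <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))

  out <- with_seed(sub_seed(config$seed, 1L), {
    base_mean <- stats::runif(config$n_genes, 4, 10)
    tumor_sign <- sample(c(-1, 1), config$n_demisg, replace = TRUE)
    subtype_sign <- sample(c(-1, 1), config$n_subtype_genes, replace = TRUE)
    subtype <- ifelse(stats::rbinom(config$n_tumor, 1, 0.5) == 1, "M2", "M1")

    # symmetric logistic couplings: log-odds +/- log(OR)/2 by subtype
    half_g <- log(config$grade_subtype_odds) / 2
    half_i <- log(config$idh_subtype_odds) / 2
    p_high <- stats::plogis(ifelse(subtype == "M2", half_g, -half_g))
    grade <- ifelse(stats::runif(config$n_tumor) < p_high, "high", "low")
    p_mut <- stats::plogis(ifelse(subtype == "M1", half_i, -half_i))
    idh <- ifelse(stats::runif(config$n_tumor) < p_mut, "mutant", "wildtype")
    age <- pmax(18, stats::rnorm(config$n_tumor + config$n_normal, 55, 12))

    mu <- matrix(base_mean, config$n_genes, length(samples))
    tum <- group == "tumor"
    mu[match(demisg, genes), tum] <- mu[match(demisg, genes), tum] +
      tumor_sign * config$tumor_effect
    # centre the subtype shift on the empirical M2 proportion: M1 vs M2 mean
    # difference is exactly +/- subtype_effect while the overall tumor mean
    # (hence the tumor-vs-normal contrast) is untouched
    m2 <- which(tum)[subtype == "M2"]
    m1 <- which(tum)[subtype == "M1"]
    p2 <- length(m2) / (length(m1) + length(m2))
    sg <- match(subtype_genes, genes)
    mu[sg, m2] <- mu[sg, m2] + subtype_sign * config$subtype_effect * (1 - p2)
    mu[sg, m1] <- mu[sg, m1] - subtype_sign * config$subtype_effect * p2

    values <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                          nrow(mu), ncol(mu))
    list(values = values, subtype = subtype, grade = grade, idh = idh,
         age = age, tumor_sign = tumor_sign, subtype_sign = subtype_sign)
  })

  expr <- out$values
  dimnames(expr) <- list(genes, samples)
  ann <- data.frame(
    sample_id = samples,
    group = group,
    subtype_truth = c(out$subtype, rep("none", config$n_normal)),
    grade = c(out$grade, rep("none", config$n_normal)),
    idh = c(out$idh, rep("none", config$n_normal)),
    age = round(out$age, 1),
    os_time = NA_real_,
    os_event = NA_integer_,
    stringsAsFactors = FALSE
  )
  list(expr = expr, ann = ann, signature = sig,
       truth = list(demisg = demisg, subtype_genes = subtype_genes,
                    tumor_sign = out$tumor_sign,
                    subtype_sign = out$subtype_sign))
}

#' Attach proportional-hazards survival outcomes to synthetic tumor samples
#'
#' Event times for tumor samples are exponential with rate
#' `baseline_hazard * exp(sum(beta_i * x_i))`, where each driver gene's
#' expression is centered across tumor samples so the baseline hazard keeps
#' its interpretation regardless of expression location. Censoring times are
#' independent exponential(`censor_rate`); `os_time` is the minimum and
#' `os_event` indicates an observed event.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param ann annotation data.frame from [generate_expression()].
#' @param config the same [synth_config()].
#' @return `ann` with `os_time` and `os_event` filled for tumor samples.
#' @export
generate_survival <- function(expr, ann, config) {
  stopifnot(inherits(config, "synth_config"))
  expr <- as_expression_matrix(expr)
  check_genes_present(expr, config$cox_genes)
  tum <- which(ann$group == "tumor")
  x <- expr[config$cox_genes, ann$sample_id[tum], drop = FALSE]
  x <- x - rowMeans(x)
  lp <- as.numeric(crossprod(x, config$cox_betas))

  surv <- with_seed(sub_seed(config$seed, 2L), {
    event_t <- stats::rexp(length(tum), rate = config$baseline_hazard * exp(lp))
    censor_t <- if (config$censor_rate > 0) {
      stats::rexp(length(tum), rate = config$censor_rate)
    } else rep(Inf, length(tum))
    list(time = pmin(event_t, censor_t),
         event = as.integer(event_t <= censor_t))
  })
  ann$os_time[tum] <- surv$time
  ann$os_event[tum] <- surv$event
  ann
}

#' Generate a full synthetic dataset (expression, annotations, signature)
#'
#' Convenience wrapper chaining [generate_expression()] and
#' [generate_survival()].
#'
#' @inheritParams generate_expression
#' @return As [generate_expression()], with survival columns filled.
#' @export
generate_dataset <- function(config) {
  d <- generate_expression(config)
  d$ann <- generate_survival(d$expr, d$ann, config)
  d
}
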