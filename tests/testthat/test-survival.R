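# Coefficients printed for the five-gene prognostic model, kept verbatim.
panel_betas <- c(0.2695063, 0.0924100, 0.4679576, 0.34006645, -0.2472611)

surv_fixture <- function(n = 120, betas = c(0.8, -0.5), seed = 1,
                         censor = 0.1) {
  cfg <- synth_config(n_genes = 30, n_signature_genes = 10, n_tumor = n,
                      n_normal = 5, n_demisg = 5, n_subtype_genes = 5,
                      cox_genes = sprintf("g%04d", seq_along(betas)),
                      cox_betas = betas, censor_rate = censor, seed = seed)
  d <- generate_dataset(cfg)
  tum <- d$ann$group == "tumor"
  list(expr = d$expr[, tum], ann = d$ann[tum, ], cfg = cfg)
}

test_that("coxph-based fits agree with direct partial-likelihood maximization", {
  set.seed(101)
  for (i in 1:20) {
    n <- 40
    x <- matrix(rnorm(n * 2), n, 2)
    beta_true <- runif(2, -1, 1)
    time <- rexp(n, exp(x %*% beta_true))
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 5) event[1:5] <- 1
    em <- matrix(t(x), nrow = 2,
                 dimnames = list(c("gA", "gB"), sprintf("s%02d", 1:n)))
    ann <- data.frame(sample_id = colnames(em), os_time = time,
                      os_event = event)
    fit <- suppressWarnings(multivariate_fit(em, ann, c("gA", "gB")))
    oracle <- cox_oracle(time, event, x)
    expect_equal(fit$table$beta, oracle, tolerance = 1e-6)
    expect_equal(fit$table$hr, exp(fit$table$beta), tolerance = 1e-12)
  }
})

test_that("univariate screen: power on planted effects, type-I near alpha on nulls", {
  d <- surv_fixture(n = 500, betas = c(0.5, 0), seed = 3)
  res <- univariate_screen(d$expr, d$ann, c("g0001", "g0002", "g0010"))
  expect_true(res$selected[res$term == "g0001"]) # planted beta 0.5
  expect_error(univariate_screen(d$expr, d$ann, "not_a_gene"), "not_a_gene")

  # null selection rate across seeds approximates alpha
  sel <- vapply(1:30, function(s) {
    dd <- surv_fixture(n = 80, betas = c(0.8, 0), seed = 100 + s)
    univariate_screen(dd$expr, dd$ann, "g0010")$selected
  }, logical(1))
  expect_lte(mean(sel), 0.2)
})

test_that("multivariate fit recovers the printed five-gene coefficients", {
  errs <- sapply(1:5, function(s) {
    d <- surv_fixture(n = 1000, betas = panel_betas, seed = 200 + s)
    fit <- multivariate_fit(d$expr, d$ann, d$cfg$cox_genes)
    abs(fit$table$beta - panel_betas)
  })
  expect_true(all(apply(errs, 1, median) < 0.15))
})

test_that("collinear covariates trigger a warning naming the pair", {
  d <- surv_fixture(n = 60, seed = 7)
  expr <- rbind(d$expr, dup = d$expr["g0001", ])
  expect_warning(multivariate_fit(expr, d$ann, c("g0001", "dup")),
                 "collinear")
})

test_that("risk score arithmetic, linearity and median-split rule", {
  genes <- c("CDK1", "MMP9", "CASP8", "SLC30A3", "SYT13")
  unit <- matrix(1, 5, 4, dimnames = list(genes, paste0("s", 1:4)))
  rm_unit <- risk_scores(unit, genes, panel_betas)
  expect_equal(unname(rm_unit$scores), rep(sum(panel_betas), 4))

  zero <- matrix(0, 5, 3, dimnames = list(genes, paste0("s", 1:3)))
  expect_equal(unname(risk_scores(zero, genes, panel_betas)$scores),
               rep(0, 3))

  # doubling one gene changes the score by exactly beta * increment
  bumped <- unit
  bumped["CASP8", 2] <- 2
  rm_b <- risk_scores(bumped, genes, panel_betas)
  expect_equal(unname(rm_b$scores[2] - rm_unit$scores[2]), panel_betas[3],
               tolerance = 1e-12)

  # distinct scores split into equal halves; ties at the median go low
  sc <- matrix(c(1, 2, 3, 4), 1, 4,
               dimnames = list("CDK1", paste0("s", 1:4)))
  rm2 <- risk_scores(sc, "CDK1", 1)
  expect_equal(sum(rm2$group == "high"), 2)
  expect_equal(unname(rm2$group[2]), "low") # score 2 < median 2.5
  expect_error(risk_scores(sc, "missing", 1), "missing")
})

test_that("Kaplan-Meier steps match the hand-computed product limit", {
  # times 1, 2, 3, 4 with one censor at 2: S = 3/4 at t=1, stays 3/4 at
  # censoring, 3/4 * 1/2 at t=3, 0 at t=4
  time <- c(1, 2, 3, 4)
  event <- c(1, 0, 1, 1)
  res <- km_logrank(c(time, time), c(event, event),
                    rep(c("a", "b"), each = 4))
  a <- res$curves[res$curves$group == "a", ]
  expect_equal(a$surv, c(3 / 4, 3 / 4, 3 / 8, 0))
  # identical groups: log-rank p close to 1
  expect_gt(res$p, 0.95)
})

test_that("log-rank detects a planted hazard ratio", {
  set.seed(31)
  t1 <- rexp(200, 1)
  t2 <- rexp(200, 3)
  cens <- rexp(400, 0.2)
  time <- pmin(c(t1, t2), cens)
  event <- as.integer(c(t1, t2) <= cens)
  res <- km_logrank(time, event, rep(c("lo", "hi"), each = 200))
  expect_lt(res$p, 0.001)
})

test_that("time-dependent ROC: perfect ranking, null risk, planted signal", {
  # no censoring, binary risk perfectly ordering event times
  time <- c(0.5, 0.8, 1.2, 3, 4, 5)
  event <- rep(1, 6)
  risk <- c(9, 8, 7, 1, 2, 3)
  expect_equal(unname(time_dependent_roc(risk, time, event, horizons = 2)), 1)
  expect_error(time_dependent_roc(risk, time, event, horizons = 10),
               "beyond")

  set.seed(33)
  aucs <- replicate(20, {
    n <- 150
    tt <- rexp(n, 0.5); cc <- rexp(n, 0.2)
    time <- pmin(tt, cc); event <- as.integer(tt <= cc)
    mean(time_dependent_roc(rnorm(n), time, event, horizons = c(1, 2)))
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)

  d <- surv_fixture(n = 400, betas = c(1, -0.8), seed = 35)
  lp <- as.numeric(crossprod(d$expr[c("g0001", "g0002"), ], c(1, -0.8)))
  auc <- time_dependent_roc(lp, d$ann$os_time, d$ann$os_event,
                            horizons = c(1, 3, 5))
  expect_true(all(auc > 0.7))
})

test_that("independence analysis isolates the risk-score effect", {
  d <- surv_fixture(n = 400, betas = c(1, -0.8), seed = 37)
  lp <- as.numeric(crossprod(d$expr[c("g0001", "g0002"), ], c(1, -0.8)))
  tab <- independence_analysis(d$ann, lp)
  expect_lt(tab$p[tab$term == "risk_score"], 0.001)
  expect_true("age" %in% tab$term)
  # survival depends only on the risk genes: age stays null-distributed
  expect_gt(tab$p[tab$term == "age"], 0.01)

  # constant covariate is dropped with a warning
  d$ann$idh <- "wildtype"
  expect_warning(independence_analysis(d$ann, lp), "constant")
})
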