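test_that("grid tuning is deterministic and a size-1 grid is returned as-is", {
  d <- hybrid_fixture(n = 80, seed = 2)
  g1 <- data.frame(max_depth = 2, eta = 0.3, nrounds = 20)
  m <- tune_and_fit(d$x, d$y == "high", grid = g1, seed = 5)
  expect_equal(m$hyperparameters$max_depth, 2)
  expect_equal(m$nrounds, 20)

  grid <- expand.grid(max_depth = c(2, 3), eta = c(0.1, 0.3), nrounds = 30)
  m1 <- tune_and_fit(d$x, d$y == "high", grid = grid, seed = 7)
  m2 <- tune_and_fit(d$x, d$y == "high", grid = grid, seed = 7)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(predict(m1, d$x), predict(m2, d$x))
  expect_error(tune_and_fit(d$x, d$y == "high", grid = grid[0, ]), "empty")
})

test_that("perfectly separable data reaches CV accuracy 1", {
  set.seed(11)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(x[, 1] > 0)
  x[, 1] <- x[, 1] + 5 * y # wide margin
  m <- tune_and_fit(x, y, grid = data.frame(max_depth = 2, eta = 0.3,
                                            nrounds = 30), seed = 13)
  expect_equal(m$cv_accuracy, 1)
})

test_that("Bayesian tuning is seeded, bounded and deterministic", {
  d <- hybrid_fixture(n = 80, seed = 3)
  m1 <- tune_and_fit(d$x, d$y == "high", algorithm = "xgb_bayes",
                     budget = 6, seed = 9)
  m2 <- tune_and_fit(d$x, d$y == "high", algorithm = "xgb_bayes",
                     budget = 6, seed = 9)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_true(m1$hyperparameters$max_depth >= 2 &&
                m1$hyperparameters$max_depth <= 6)
  expect_equal(m1$tuning, "bayesian")
})

test_that("attribution additivity holds and unused features get exactly zero", {
  d <- hybrid_fixture(n = 100, seed = 4)
  m <- tune_and_fit(d$x, d$y == "high",
                    grid = data.frame(max_depth = 3, eta = 0.3, nrounds = 40),
                    seed = 15)
  sm <- explain(m, d$x)
  margin <- log(predict(m, d$x) / (1 - predict(m, d$x)))
  expect_lt(max(abs(sm$margin - margin)), 1e-4)
  expect_lt(max(abs(rowSums(sm$values) + sm$base_value - margin)), 1e-4)

  # a feature of pure noise appended after fitting cannot be explained;
  # instead check that a feature the model never splits on attributes 0
  x2 <- cbind(d$x, dead = 0)
  m2 <- tune_and_fit(x2, d$y == "high",
                     grid = data.frame(max_depth = 2, eta = 0.3,
                                       nrounds = 20), seed = 17)
  sm2 <- explain(m2, x2)
  expect_true(all(sm2$values[, "dead"] == 0))

  expect_error(explain(m, d$x[, -1]), "feature mismatch")
})

test_that("a depth-1 stump yields exactly two attribution values", {
  set.seed(19)
  x <- matrix(rnorm(300), 150, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- as.integer(x[, 1] > 0.2)
  m <- ionstim:::fit_boosted(x, y, params = list(max_depth = 1, eta = 1),
                             nrounds = 1, seed = 19)
  sm <- explain(m, x)
  vals <- sort(unique(round(sm$values[, "f1"], 8)))
  expect_length(vals, 2)
  split_side <- sm$values[, "f1"] == max(sm$values[, "f1"])
  expect_equal(unname(split_side), unname(x[, 1] > 0.2) == (vals[2] > 0))
})

test_that("shap_kmeans matches the exhaustive 2-partition SSE minimizer", {
  set.seed(21)
  for (i in 1:5) {
    rows <- matrix(rnorm(12 * 3), 12, 3)
    labels <- shap_kmeans(rows, k = 2, seed = 22 + i)
    expect_equal(kmeans_sse(rows, labels), best_bipartition_sse(rows),
                 tolerance = 1e-9)
  }
  # duplicate rows always co-cluster
  dup <- rbind(matrix(rnorm(10 * 2), 10, 2))
  dup[2, ] <- dup[1, ]
  lab <- shap_kmeans(dup, k = 2, seed = 29)
  expect_equal(lab[1], lab[2])
  expect_error(shap_kmeans(matrix(1, 5, 2), k = 2), "distinct")
})

test_that("cluster-to-label mapping maximizes accuracy and is swap-invariant", {
  truth <- rep(c("high", "low"), each = 50)
  clusters <- c(rep(1, 45), rep(2, 5), rep(1, 8), rep(2, 42))
  res <- map_clusters_to_labels(clusters, truth, positive = "high")
  expect_equal(unname(res$mapping["1"]), "high")
  expect_equal(res$metrics$accuracy, 0.87)

  swapped <- map_clusters_to_labels(3 - clusters, truth, positive = "high")
  expect_equal(swapped$metrics$accuracy, res$metrics$accuracy)

  ident <- map_clusters_to_labels(as.integer(truth == "low") + 1, truth,
                                  positive = "high")
  expect_equal(ident$metrics$accuracy, 1)

  # maximizing map never drops below 0.5 on balanced truth
  set.seed(31)
  rand <- map_clusters_to_labels(sample(1:2, 100, TRUE), truth,
                                 positive = "high")
  expect_gte(rand$metrics$accuracy, 0.5)

  expect_error(map_clusters_to_labels(c(1, 2, 3), c("a", "b", "a"), "a"),
               "unsupported")
})

test_that("run_benchmark produces coherent tables and flagged edge cases", {
  d <- hybrid_fixture(n = 140, seed = 6)
  ext <- ionstim:::stratified_subsample(d$y, 0.4, seed = 33)
  g1 <- data.frame(max_depth = 2, eta = 0.3, nrounds = 40)
  b <- run_benchmark(d$x[-ext, ], d$y[-ext], d$x[ext, ], d$y[ext],
                     n_schemes = 3, algorithms = "xgb_grid",
                     positive = "high", grid = g1, seed = 35)
  expect_equal(nrow(b$per_scheme), 3 * 2)
  # mean table averages the per-scheme rows exactly
  base_rows <- b$per_scheme[b$per_scheme$model == "base", "sensitivity"]
  expect_equal(b$mean_table["sensitivity", "xgb_grid_base"], mean(base_rows))
  expect_true(all(names(b$paired$xgb_grid) ==
                    c("accuracy", "sensitivity", "specificity", "precision",
                      "fdr", "f1")))

  # single scheme: paired tests undefined, flagged NaN, metrics intact
  b1 <- run_benchmark(d$x[-ext, ], d$y[-ext], d$x[ext, ], d$y[ext],
                      n_schemes = 1, algorithms = "xgb_grid",
                      positive = "high", grid = g1, seed = 37)
  expect_true(all(is.nan(b1$paired$xgb_grid)))
  expect_equal(nrow(b1$per_scheme), 2)

  # external set identical to training on separable data: near-perfect both
  set.seed(39)
  xs <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  ys <- as.integer(xs[, 1] > 0)
  xs[, 1] <- xs[, 1] + 6 * ys
  bb <- run_benchmark(xs, ys, xs, ys, n_schemes = 2, algorithms = "xgb_grid",
                      positive = 1, grid = g1, seed = 41)
  expect_gt(min(bb$per_scheme$accuracy), 0.95)

  expect_error(
    run_benchmark(d$x[-ext, ], d$y[-ext], d$x[ext, -1], d$y[ext],
                  n_schemes = 1, algorithms = "xgb_grid", positive = "high",
                  grid = g1, seed = 1),
    "lacks training features")
})

test_that("benchmark is byte-identical under a fixed master seed", {
  d <- hybrid_fixture(n = 120, seed = 8)
  ext <- ionstim:::stratified_subsample(d$y, 0.4, seed = 43)
  g1 <- data.frame(max_depth = 2, eta = 0.3, nrounds = 30)
  args <- list(d$x[-ext, ], d$y[-ext], d$x[ext, ], d$y[ext], n_schemes = 2,
               algorithms = "xgb_grid", positive = "high", grid = g1,
               seed = 45, keep_shap = FALSE)
  b1 <- do.call(run_benchmark, args)
  b2 <- do.call(run_benchmark, args)
  expect_identical(b1$per_scheme, b2$per_scheme)
  expect_identical(b1$mean_table, b2$mean_table)
})

test_that("shap_stability: zero dispersion for identical schemes, order-invariant", {
  d <- hybrid_fixture(n = 100, seed = 9)
  m <- tune_and_fit(d$x, d$y == "high",
                    grid = data.frame(max_depth = 2, eta = 0.3, nrounds = 20),
                    seed = 47)
  sm <- explain(m, d$x)
  st0 <- shap_stability(list(sm, sm, sm))
  expect_equal(max(st0$per_sample$max_sd), 0)

  m2 <- tune_and_fit(d$x[1:80, ], d$y[1:80] == "high",
                     grid = data.frame(max_depth = 2, eta = 0.3,
                                       nrounds = 20), seed = 49)
  sm2 <- explain(m2, d$x)
  st_a <- shap_stability(list(sm, sm2))
  st_b <- shap_stability(list(sm2, sm))
  expect_equal(st_a$per_sample, st_b$per_sample)
  expect_gt(max(st_a$per_sample$max_sd), 0)
})
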