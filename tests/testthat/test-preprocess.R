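test_that("normexp correction matches a quadrature oracle and its limits", {
  g <- rep(c("normal", "tumor"), each = 2)
  d <- tiny_dataset(matrix(c(12, 30, 25, 18), 1), g)
  out <- normexp_correct(d, params = list(mu = 10, sigma = 2, alpha = 50))
  for (j in 1:4)
    expect_equal(out$values[1, j],
                 oracle_normexp_posterior(d$values[1, j], 10, 2, 50),
                 tolerance = 1e-6)

  # vanishing background: correction returns the input
  d2 <- tiny_dataset(matrix(c(100, 55, 70, 41), 1), g)
  out2 <- normexp_correct(d2, params = list(mu = 0, sigma = 1e-8,
                                            alpha = 30))
  expect_equal(out2$values, d2$values, tolerance = 1e-6)

  # deep-background value still maps to a strictly positive signal
  d3 <- tiny_dataset(matrix(c(0, 12, 15, 20), 1), g)
  out3 <- normexp_correct(d3, params = list(mu = 10, sigma = 2, alpha = 50))
  expect_true(all(out3$values > 0))

  # monotone increasing in x for fixed parameters
  xs <- seq(-5, 60, length.out = 40)
  d4 <- tiny_dataset(matrix(rep(xs, 4), ncol = 4),
                     g)
  out4 <- normexp_correct(d4, params = list(mu = 10, sigma = 3, alpha = 20))
  expect_true(all(diff(out4$values[, 1]) > 0))

  expect_error(normexp_correct(d, params = list(mu = 1, sigma = 0,
                                                alpha = 1)), "sigma")
  dinf <- tiny_dataset(matrix(c(Inf, 1, 2, 3), 1), g)
  expect_error(normexp_correct(dinf,
                               params = list(mu = 0, sigma = 1, alpha = 1)),
               "non-finite")
})

test_that("normexp parameters are recoverable from simulated convolutions", {
  set.seed(31)
  n <- 5000
  x <- rnorm(n, 100, 15) + rexp(n, rate = 1 / 200)
  fit <- estimate_normexp_params(x)
  expect_equal(fit$mu, 100, tolerance = 0.1 * 100)
  expect_equal(fit$sigma, 15, tolerance = 0.1 * 15)
  expect_equal(fit$alpha, 200, tolerance = 0.1 * 200)
  expect_error(estimate_normexp_params(rnorm(10)), "at least 50")
})

test_that("quantile normalization equalizes column distributions", {
  g <- c("normal", "tumor")
  d <- tiny_dataset(matrix(c(2, 4, 6, 1, 3, 5), ncol = 2), g)
  out <- quantile_normalize(d)
  expect_equal(unname(out$values[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(out$values[, 2]), c(1.5, 3.5, 5.5))

  # identical columns are a fixed point; the operation is idempotent
  di <- tiny_dataset(matrix(c(5, 1, 9, 5, 1, 9), ncol = 2), g)
  expect_equal(quantile_normalize(di)$values, di$values)
  dr <- random_dataset(n_feat = 30, n_norm = 3, n_tum = 3, seed = 2)
  q1 <- quantile_normalize(dr)
  expect_equal(quantile_normalize(q1)$values, q1$values,
               tolerance = 1e-12)

  # postcondition: every column's sorted values equal the reference
  ref <- rowMeans(apply(dr$values, 2, sort))
  for (j in 1:6)
    expect_equal(unname(sort(q1$values[, j])), unname(ref),
                 tolerance = 1e-12)

  # agrees with limma on complete data
  expect_equal(unname(q1$values),
               unname(limma::normalizeQuantiles(dr$values)),
               tolerance = 1e-9)

  # rank order within columns is preserved with missing entries present
  dm <- random_dataset(n_feat = 40, n_norm = 4, n_tum = 4, seed = 3,
                       missing = 0.1)
  qm <- quantile_normalize(dm)
  for (j in 1:8) {
    obs <- !is.na(dm$values[, j])
    expect_identical(is.na(qm$values[, j]), !obs)
    expect_identical(order(qm$values[obs, j]), order(dm$values[obs, j]))
  }

  dbad <- tiny_dataset(matrix(c(1, 2, 3, 4, NA, NA, 5, NA), ncol = 2),
                       g)
  expect_error(quantile_normalize(dbad), "fewer than 2 observed")
  expect_error(quantile_normalize(tiny_dataset(matrix(1:3, 3), "normal")),
               ">= 2 samples")
})

test_that("probe averaging takes per-sample means over observed probes", {
  g <- rep(c("normal", "tumor"), each = 2)
  v <- matrix(c(3, 5, 7,
                3, 5, 7,
                3, NA, 7,
                3, 5, NA), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), paste0("s", 1:4)))
  pm <- data.frame(probe_id = c("p1", "p2", "p3"),
                   feature_id = c("fX", "fX", "fY"))
  out <- average_probes(expression_dataset(v, g, "d"), pm)
  expect_identical(rownames(out$values), c("fX", "fY"))
  expect_equal(unname(out$values["fX", ]), c(4, 4, 3, 4))
  expect_equal(unname(out$values["fY", ]), c(7, 7, 7, NA))

  # unmapped probes are dropped with a message
  pm2 <- data.frame(probe_id = c("p1", "p2"),
                    feature_id = c("fX", "fX"))
  expect_message(out2 <- average_probes(expression_dataset(v, g, "d"), pm2),
                 "unmapped")
  expect_identical(rownames(out2$values), "fX")
  expect_error(average_probes(expression_dataset(v, g, "d"),
                              pm[0, ]), "empty probe map")
})

test_that("kNN imputation fills from nearest co-observed features only", {
  g <- rep(c("normal", "tumor"), each = 2)
  v <- matrix(c(1, 2, 3, 4,
                1, 2, NA, 4,
                10, 20, 30, 40), nrow = 3, byrow = TRUE,
              dimnames = list(c("f1", "f2", "f3"), paste0("s", 1:4)))
  out <- knn_impute(expression_dataset(v, g, "d"), k = 1)
  expect_equal(out$values["f2", "s3"], 3)  # nearest neighbour is f1
  # observed entries are untouched
  expect_identical(out$values[!is.na(v)], v[!is.na(v)])

  # no missing data: identity
  dd <- random_dataset(n_feat = 10, n_norm = 3, n_tum = 3, seed = 5)
  expect_identical(knn_impute(dd, 5)$values, dd$values)

  # k larger than the candidate pool falls back to all candidates
  out2 <- knn_impute(expression_dataset(v, g, "d"), k = 50)
  expect_equal(out2$values["f2", "s3"], mean(c(3, 30)))

  vfull <- v; vfull["f2", ] <- NA
  expect_error(knn_impute(expression_dataset(vfull, g, "d"), 2),
               "no observed values")
})

test_that("multi-probe genes are removed, single-probe genes renamed", {
  g <- rep(c("normal", "tumor"), each = 2)
  v <- matrix(seq_len(12), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), paste0("s", 1:4)))
  pm <- data.frame(probe_id = c("p1", "p2", "p3"),
                   feature_id = c("geneB", "geneB", "geneA"))
  expect_message(out <- collapse_multiprobe_genes(
    expression_dataset(v, g, "d"), pm), "removed")
  expect_identical(rownames(out$values), "geneA")
  expect_equal(unname(out$values[1, ]), unname(v["p3", ]))

  pm_all_single <- data.frame(probe_id = c("p1", "p2", "p3"),
                              feature_id = c("gA", "gB", "gC"))
  out2 <- collapse_multiprobe_genes(expression_dataset(v, g, "d"),
                                    pm_all_single)
  expect_identical(rownames(out2$values), c("gA", "gB", "gC"))

  pm_all_multi <- data.frame(probe_id = c("p1", "p2", "p3"),
                             feature_id = c("gA", "gA", "gA"))
  expect_warning(out3 <- collapse_multiprobe_genes(
    expression_dataset(v, g, "d"), pm_all_multi), "no single-probe")
  expect_equal(nrow(out3$values), 0L)
})

test_that("the preprocessing chain runs in the documented order", {
  d <- random_dataset(n_feat = 80, n_norm = 5, n_tum = 5, seed = 6,
                      missing = 0.05)
  d$values <- abs(d$values) * 20  # intensity-like scale
  out <- preprocess_dataset(d, steps = c("quantile", "impute"))
  expect_false(anyNA(out$values))
  ref <- sort(out$values[!is.na(d$values[, 1]), 1])
  # after imputation columns keep the normalized distribution approximately
  expect_equal(dim(out$values), dim(d$values))
})
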