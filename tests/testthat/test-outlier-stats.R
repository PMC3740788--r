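test_that("pooled t-statistic matches the hand formula and degenerates safely", {
  g <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(stat_t(c(0, 1, 2, 3, 4, 5), g), 3 / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(stat_t(c(1, 2, 3, 1, 2, 3), g), 0)
  expect_true(is.na(stat_t(c(2, 2, 2, 2, 2, 2), g)))
  # Welch form agrees with stats::t.test
  set.seed(4)
  x <- rnorm(12)
  g2 <- rep(c(FALSE, TRUE), each = 6)
  expect_equal(stat_t(x, g2, welch = TRUE),
               unname(t.test(x[g2], x[!g2])$statistic), tolerance = 1e-10)
})

test_that("COPA percentile statistic behaves at its boundaries", {
  g <- rep(c(FALSE, TRUE), each = 5)
  x <- c(1, 2, 4, 5, 6, 3, 3, 3, 3, 3)  # tumor all at the overall median
  expect_equal(stat_copa(x, g, r = 90), 0)
  set.seed(7)
  y <- rnorm(10)
  med <- median(y)
  scale <- mad(y)
  expect_equal(stat_copa(y, g, r = 100), max((y[g] - med) / scale),
               tolerance = 1e-12)
  expect_true(is.na(stat_copa(rep(1, 10), g)))
})

test_that("outlier-sum statistic sums only tumor values above the cutoff", {
  g <- rep(c(FALSE, TRUE), each = 6)
  # symmetric data, no extreme tumor values: empty outlier set
  x <- c(-3, -2, -1, 1, 2, 3, -3, -2, -1, 1, 2, 3)
  expect_equal(stat_os(x, g), 0)
  # one planted extreme tumor value: statistic equals its standardized value
  set.seed(11); y <- c(rnorm(6, 0, 0.5), rnorm(5, 0, 0.5), 40)
  med <- median(y); scale <- mad(y)
  z <- (y - med) / scale
  q <- quantile(z, c(.25, .75), names = FALSE)
  expect_gt(z[12], q[2] + diff(q))
  expect_equal(stat_os(y, g), z[12], tolerance = 1e-12)
})

test_that("outlier-robust t matches a direct hand computation", {
  g <- c(rep(FALSE, 5), rep(TRUE, 3))
  x <- c(1, 2, 3, 4, 5, 2.5, 3.0, 9.0)
  # cutoff = q75_n + IQR_n = 4 + 2 = 6; only 9.0 exceeds it
  med_n <- 3
  scale <- 1.4826 * median(c(abs(1:5 - 3), abs(c(2.5, 3, 9) - 3)))
  expect_equal(stat_ort(x, g), (9 - med_n) / scale, tolerance = 1e-12)
  # all tumor values below cutoff
  expect_equal(stat_ort(c(1, 2, 3, 4, 5, 2, 3, 4), g), 0)
})

test_that("MOST null moments match theory and are cached deterministically", {
  tab <- most_null_moments(2, B = 50000, seed = 99)
  expect_lt(abs(tab$mu[1] - 1 / sqrt(pi)), 0.01)
  expect_lt(abs(tab$mu[2]), 0.02)
  expect_true(all(tab$sigma > 0))
  tab2 <- most_null_moments(2, B = 50000, seed = 99)
  expect_identical(tab, tab2)
  tab15 <- most_null_moments(15, B = 5000, seed = 1)
  # mu_k increases while added order statistics have positive expectation,
  # and returns to ~0 at k = n by symmetry
  expect_true(all(diff(tab15$mu[1:7]) > 0))
  expect_equal(tab15$mu[15], 0, tolerance = 0.15)
})

test_that("MOST statistic follows its defining formula", {
  g <- rep(c(FALSE, TRUE), each = 6)
  tab <- most_null_moments(6, B = 2000, seed = 3)
  # tumor values all at the normal median: M_k = 0 for all k
  x <- c(1, 2, 3, 4, 5, 6, rep(3.5, 6))
  expect_equal(stat_most(x, g, tab), max(-tab$mu / tab$sigma),
               tolerance = 1e-12)
  # a single strongly shifted tumor sample is picked up at small k
  set.seed(21)
  y <- c(rnorm(6), rnorm(5), 25)
  z <- sort((y[g] - median(y[!g])) / mad(y[!g]), decreasing = TRUE)
  ks <- (cumsum(z) - tab$mu) / tab$sigma
  expect_equal(stat_most(y, g, tab), max(ks), tolerance = 1e-12)
  expect_equal(which.max(ks), 1L)
  expect_error(stat_most(y, g, most_null_moments(4, B = 2000, seed = 3)),
               "does not match")
})

test_that("all five statistics agree with independent loop-based oracles", {
  set.seed(42)
  g <- rep(c(FALSE, TRUE), each = 10)
  tab <- most_null_moments(10, B = 5000, seed = 5)
  for (i in 1:50) {
    x <- rnorm(20, sd = runif(1, 0.5, 2))
    if (i %% 3 == 0) x[sample(20, 2)] <- x[sample(20, 2)] + 5
    expect_equal(stat_t(x, g), oracle_t(x, g), tolerance = 1e-10)
    expect_equal(stat_copa(x, g, 90), oracle_copa(x, g, 90),
                 tolerance = 1e-10)
    expect_equal(stat_os(x, g), oracle_os(x, g), tolerance = 1e-10)
    expect_equal(stat_ort(x, g), oracle_ort(x, g), tolerance = 1e-10)
    expect_equal(stat_most(x, g, tab), oracle_most(x, g, tab),
                 tolerance = 1e-10)
  }
})

test_that("robust statistics are invariant under positive affine transforms", {
  set.seed(13)
  g <- rep(c(FALSE, TRUE), each = 8)
  tab <- most_null_moments(8, B = 2000, seed = 2)
  for (i in 1:10) {
    x <- rnorm(16)
    a <- runif(1, 0.1, 10); b <- runif(1, -50, 50)
    y <- a * x + b
    expect_equal(stat_copa(y, g), stat_copa(x, g), tolerance = 1e-9)
    expect_equal(stat_os(y, g), stat_os(x, g), tolerance = 1e-9)
    expect_equal(stat_ort(y, g), stat_ort(x, g), tolerance = 1e-9)
    expect_equal(stat_most(y, g, tab), stat_most(x, g, tab),
                 tolerance = 1e-9)
  }
})

test_that("score_dataset selects the top fraction with documented tie-breaks", {
  d <- random_dataset(n_feat = 40, n_norm = 6, n_tum = 6, seed = 8)
  sc <- score_dataset(d, "COPA", selection_fraction = 0.05)
  expect_equal(sum(sc$selected), 2L)  # ceiling(0.05 * 40)
  expect_identical(sort(sc$rank), 1:40)
  expect_true(all(diff(sc$statistic[!is.na(sc$statistic)]) <= 1e-12))

  # a down-shifted feature is detected with direction "down"
  v <- d$values
  v["f001", d$groups == "tumor"][1:3] <- v["f001",
                                           d$groups == "tumor"][1:3] - 10
  d2 <- expression_dataset(v, d$groups, "toy")
  sc2 <- score_dataset(d2, "MOST", null_B = 2000)
  row <- sc2[sc2$feature_id == "f001", ]
  expect_equal(row$direction, "down")
  expect_true(row$selected)

  # an undefined (constant) feature ranks last and is never selected
  v2 <- d$values
  v2["f002", ] <- 5
  d3 <- expression_dataset(v2, d$groups, "toy")
  sc3 <- score_dataset(d3, "OS", selection_fraction = 0.5)
  row3 <- sc3[sc3$feature_id == "f002", ]
  expect_true(is.na(row3$statistic))
  expect_equal(row3$rank, 40L)
  expect_false(row3$selected)

  # exact ties at the selection boundary resolve lexicographically
  vt <- matrix(rep(c(1, 2, 3, 4, 10, 4), each = 4), nrow = 4, byrow = FALSE,
               dimnames = list(c("fb", "fa", "fd", "fc"), paste0("s", 1:6)))
  dt <- expression_dataset(vt, rep(c("normal", "tumor"), each = 3), "tie")
  st <- score_dataset(dt, "t", selection_fraction = 0.5)
  expect_identical(st$feature_id, c("fa", "fb", "fc", "fd"))
  expect_identical(selected_features(st), c("fa", "fb"))
})

test_that("consensus putative set requires the method quorum", {
  mk <- function(sel, universe = paste0("f", 1:6)) {
    df <- data.frame(feature_id = universe, statistic = 1,
                     direction = "up", rank = seq_along(universe),
                     selected = universe %in% sel)
    class(df) <- c("outlier_scores", "data.frame")
    df
  }
  tables <- list(mk(c("f1", "f2")), mk(c("f1", "f2")), mk(c("f1", "f3")),
                 mk(c("f4")), mk(c("f4")))
  expect_identical(consensus_putative(tables, 3), "f1")
  expect_identical(consensus_putative(tables, 2), c("f1", "f2", "f4"))
  expect_identical(consensus_putative(tables, 1), paste0("f", 1:4))
  bad <- c(tables[1:4], list(mk("f1", universe = paste0("g", 1:6))))
  expect_error(consensus_putative(bad), "universes")
})

test_that("benchmark accuracy is the median proportion across datasets", {
  ds <- lapply(1:3, function(s)
    random_dataset(n_feat = 60, n_norm = 8, n_tum = 8, seed = s,
                   planted = 1:6, shift = 4))
  ds <- lapply(seq_along(ds), function(i) {
    d <- ds[[i]]; d$dataset_id <- paste0("d", i); d
  })
  b <- method_accuracy(ds, null_B = 2000)
  expect_equal(dim(b$proportions), c(3L, 5L))
  expect_true(all(b$proportions >= 0 & b$proportions <= 1, na.rm = TRUE))
  expect_equal(b$accuracy, apply(b$proportions, 2, median, na.rm = TRUE))
  b1 <- method_accuracy(ds[1], null_B = 2000)
  expect_equal(unname(b1$accuracy), unname(b1$proportions[1, ]))
})
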