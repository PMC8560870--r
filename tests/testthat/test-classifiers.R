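test_that("standardization uses training statistics and survives constants", {
  X <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2)
  Z <- standardize(X)
  expect_equal(colMeans(Z), c(0, 0))
  expect_equal(apply(Z, 2, sd), c(1, 1))
  # hand-computed on a 3x2 toy matrix
  expect_equal(Z[, 1], (X[, 1] - 2) / 1)
  expect_equal(Z[, 2], (X[, 2] - 20) / 10)
  # constant column maps to zeros without errors
  Xc <- cbind(X, 5)
  expect_equal(standardize(Xc)[, 3], c(0, 0, 0))
  # train/apply separation
  A <- matrix(c(4, 5, 6, 40, 50, 60), 3, 2)
  expect_equal(standardize(X, A)[, 1], (A[, 1] - 2) / 1)
})

test_that("3-NN scores are neighbour vote fractions with training-order ties", {
  train <- matrix(c(0, 0, 10, 10, 20, 20), 3, 2, byrow = TRUE)
  labels <- c("AD", "MCI", "HC")
  # query equal to a training point, k = 1
  s1 <- knn_scores(train, labels, matrix(c(10, 10), 1), k = 1)
  expect_equal(unname(s1[1, ]), c(0, 1, 0))
  # nearest three of classes (AD, AD, MCI) -> (2/3, 1/3, 0)
  tr2 <- matrix(c(0, 0, 1, 0, 5, 0, 50, 0), 4, 2, byrow = TRUE)
  s2 <- knn_scores(tr2, c("AD", "AD", "MCI", "HC"), matrix(c(0.2, 0), 1), k = 3)
  expect_equal(unname(s2[1, ]), c(2 / 3, 1 / 3, 0))
  # tie in distance: first training row wins a slot
  tr3 <- matrix(c(1, 0, -1, 0), 2, 2, byrow = TRUE)
  s3 <- knn_scores(tr3, c("AD", "HC"), matrix(c(0, 0), 1), k = 1)
  expect_equal(unname(s3[1, ]), c(1, 0, 0))
  expect_error(knn_scores(train, labels, train, k = 5), "exceeds")
})

test_that("3-NN agrees with brute-force neighbour enumeration", {
  set.seed(21)
  train <- matrix(rnorm(50 * 4), 50, 4)
  labels <- sample(c("AD", "MCI", "HC"), 50, replace = TRUE)
  queries <- matrix(rnorm(20 * 4), 20, 4)
  got <- knn_scores(train, labels, queries, k = 3)
  lv <- factor(labels, c("AD", "MCI", "HC"))
  for (i in seq_len(20)) {
    d <- sqrt(colSums((t(train) - queries[i, ])^2))
    nn <- order(d)[1:3]
    expect_equal(unname(got[i, ]), as.vector(tabulate(lv[nn], 3) / 3))
  }
})

test_that("QBNC recovers well-separated Gaussian classes", {
  set.seed(22)
  train <- rbind(matrix(rnorm(200, 0), ncol = 1),
                 matrix(rnorm(200, 10), ncol = 1),
                 matrix(rnorm(200, 30), ncol = 1))
  labels <- rep(c("AD", "MCI", "HC"), each = 200)
  model <- qbnc_fit(train, labels)
  expect_lt(abs(model$classes$AD$mu - 0), 0.3)
  expect_lt(abs(model$classes$MCI$mu - 10), 0.3)
  # query at a class mean: posterior > 0.99
  sc <- qbnc_scores(model, matrix(c(0, 10), 2, 1))
  expect_gt(sc[1, "AD"], 0.99)
  expect_gt(sc[2, "MCI"], 0.99)
  expect_equal(rowSums(sc), c(1, 1), tolerance = 1e-12)
})

test_that("QBNC is symmetric on identical classes and robust in 21 dimensions", {
  set.seed(23)
  base <- matrix(rnorm(40 * 3), 40, 3)
  train <- rbind(base, base, base)
  labels <- rep(c("AD", "MCI", "HC"), each = 40)
  model <- qbnc_fit(train, labels)
  sc <- qbnc_scores(model, matrix(rnorm(15), 5, 3))
  expect_equal(unname(sc), matrix(1 / 3, 5, 3), tolerance = 1e-9)
  # 21-dimensional features, 108 training rows: finite PD covariances
  X <- matrix(rnorm(108 * 21), 108, 21)
  lab <- rep(c("AD", "MCI", "HC"), each = 36)
  m21 <- qbnc_fit(X, lab)
  for (cl in c("AD", "MCI", "HC")) {
    ev <- eigen(m21$classes[[cl]]$cov, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(is.finite(ev)) && all(ev > 0))
  }
  sc21 <- qbnc_scores(m21, X[1:7, ])
  expect_true(all(is.finite(sc21)))
  expect_equal(rowSums(sc21), rep(1, 7), tolerance = 1e-12)
  expect_error(qbnc_fit(X[1:37, ], lab[1:37]), "at least 2")
})

test_that("QBNC posteriors match an independent QDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(24)
  n <- 120
  train <- rbind(matrix(rnorm(n * 2, 0), ncol = 2),
                 matrix(rnorm(n * 2, 2), ncol = 2),
                 matrix(rnorm(n * 2, 5, 2), ncol = 2))
  labels <- rep(c("AD", "MCI", "HC"), each = n)
  queries <- matrix(rnorm(40, 1.5, 2), 20, 2)
  # vanishing shrinkage: should match plain class-wise Gaussian QDA
  sc <- qbnc_scores(qbnc_fit(train, labels, shrinkage = 0), queries)
  qda <- MASS::qda(train, grouping = factor(labels, c("AD", "MCI", "HC")))
  ref <- predict(qda, queries)$posterior
  expect_equal(unname(sc), unname(ref[, c("AD", "MCI", "HC")]), tolerance = 1e-5)
})

test_that("posteriors are stable far from all classes (log-sum-exp)", {
  set.seed(25)
  train <- rbind(matrix(rnorm(100), ncol = 2), matrix(rnorm(100, 3), ncol = 2),
                 matrix(rnorm(100, 6), ncol = 2))
  labels <- rep(c("AD", "MCI", "HC"), each = 25)
  model <- qbnc_fit(train, labels)
  far <- matrix(c(1e3, 1e3, -1e3, -1e3), 2, 2, byrow = TRUE)
  sc <- qbnc_scores(model, far)
  expect_true(all(is.finite(sc)))
  expect_equal(rowSums(sc), c(1, 1), tolerance = 1e-12)
})

test_that("score normalisation is idempotent and handles zero rows", {
  raw <- rbind(c(2, 3, 5), c(0, 0, 0), c(0.2, 0.3, 0.5))
  norm <- normalize_scores(raw)
  expect_equal(unname(norm[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(norm[2, ]), rep(1 / 3, 3))
  expect_equal(unname(norm[3, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(normalize_scores(norm)), unname(norm))
  expect_error(normalize_scores(rbind(c(-1, 2, 3))), "non-negative")
})

test_that("QBNC models survive a JSON round-trip", {
  set.seed(26)
  train <- matrix(rnorm(60 * 4), 60, 4)
  labels <- rep(c("AD", "MCI", "HC"), each = 20)
  model <- qbnc_fit(train, labels)
  path <- withr::local_tempfile(fileext = ".json")
  qbnc_to_json(model, path)
  back <- qbnc_from_json(path)
  q <- matrix(rnorm(12), 3, 4)
  expect_equal(qbnc_scores(back, q), qbnc_scores(model, q), tolerance = 1e-12)
})
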