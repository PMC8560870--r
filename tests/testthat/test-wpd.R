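test_that("quad-tree structure: 4^l nodes per level, 84 in a level-3 tree", {
  set.seed(1)
  tree <- wpd_decompose(matrix(rnorm(128 * 16), 128, 16), "db4", 3)
  expect_length(tree$nodes, 4 + 16 + 64)
  for (l in 1:3) {
    paths <- names(tree$nodes)[nchar(names(tree$nodes)) == l]
    expect_length(paths, 4^l)
  }
  # subband sizes halve per level
  expect_equal(dim(tree$nodes[["A"]]), c(64L, 8L))
  expect_equal(dim(tree$nodes[["AAA"]]), c(16L, 2L))
  # a level-3 tree needs every filtering input at least 2 wide
  expect_error(wpd_decompose(matrix(0, 4, 4), "db4", 3), "too small")
  expect_error(wpd_decompose(matrix(0, 64, 1), "db4", 1), "too small")
})

test_that("Haar analytic case: constant image has zero details, scaled approximation", {
  tree <- wpd_decompose(matrix(7, 64, 16), "haar", 3)
  for (p in names(tree$nodes)) {
    if (grepl("[HVD]", p)) {
      expect_lt(max(abs(tree$nodes[[p]])), 1e-12)
    }
  }
  expect_equal(tree$nodes[["A"]][1, 1], 7 * 2)
  expect_equal(tree$nodes[["AA"]][1, 1], 7 * 4)
  expect_equal(tree$nodes[["AAA"]][1, 1], 7 * 8)
})

test_that("level-1 energy is conserved on even-sized images", {
  set.seed(7)
  for (w in c("haar", "db2", "db4")) {
    x <- matrix(rnorm(64 * 16), 64, 16)
    tree <- wpd_decompose(x, w, 1)
    e <- sum(vapply(tree$nodes, function(m) sum(m^2), numeric(1)))
    expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-9)
  }
})

test_that("decompose/reconstruct round-trips below 1e-8, including odd sizes", {
  set.seed(8)
  cases <- list(c(2000, 22), c(64, 16), c(50, 9), c(37, 21))
  for (dims in cases) {
    for (w in c("haar", "db4")) {
      x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
      tree <- wpd_decompose(x, w, 3)
      expect_lt(max(abs(wpd_reconstruct(tree) - x)), 1e-8)
    }
  }
  # all-zero tree reconstructs to all zeros
  z <- wpd_decompose(matrix(0, 64, 8), "db4", 2)
  expect_equal(wpd_reconstruct(z), matrix(0, 64, 8))
  # incomplete tree is rejected
  broken <- wpd_decompose(matrix(rnorm(64 * 8), 64, 8), "db4", 2)
  broken$nodes[["AH"]] <- NULL
  expect_error(wpd_reconstruct(broken), "incomplete")
})

test_that("the transform is linear", {
  set.seed(9)
  x1 <- matrix(rnorm(64 * 12), 64, 12)
  x2 <- matrix(rnorm(64 * 12), 64, 12)
  a <- 2.5
  t_sum <- wpd_decompose(a * x1 + x2, "db4", 2)
  t1 <- wpd_decompose(x1, "db4", 2)
  t2 <- wpd_decompose(x2, "db4", 2)
  for (p in names(t_sum$nodes)) {
    expect_equal(t_sum$nodes[[p]], a * t1$nodes[[p]] + t2$nodes[[p]],
                 tolerance = 1e-9)
  }
  expect_lt(max(abs(wpd_reconstruct(t_sum) - (a * x1 + x2))), 1e-8)
})

test_that("terminal-H selection yields 1, 5, 21 nodes for levels 1..3, in order", {
  set.seed(10)
  x <- matrix(rnorm(128 * 16), 128, 16)
  expect_equal(names(wpd_terminal_nodes(wpd_decompose(x, "db4", 1))), "H")
  expect_equal(names(wpd_terminal_nodes(wpd_decompose(x, "db4", 2))),
               c("H", "AH", "HH", "VH", "DH"))
  sel3 <- wpd_terminal_nodes(wpd_decompose(x, "db4", 3))
  expect_length(sel3, 21L)
  expect_true(all(substr(names(sel3), nchar(names(sel3)), nchar(names(sel3))) == "H"))
  # ordered by level then natural child order
  expect_equal(names(sel3)[1:5], c("H", "AH", "HH", "VH", "DH"))
  expect_equal(names(sel3)[6:9], c("AAH", "AHH", "AVH", "ADH"))
})

test_that("coefficient gradients match hand-computed finite differences", {
  expect_equal(wpd_gradient(matrix(3, 5, 4), "time"), matrix(0, 5, 4))
  ramp <- matrix(rep(1:6, 4), 6, 4) # entries = row index
  expect_equal(wpd_gradient(ramp, "time"), matrix(1, 6, 4))
  expect_equal(wpd_gradient(ramp, "sensor"), matrix(0, 6, 4))
  m <- matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3, 3) # columns 0,1,2
  expect_equal(wpd_gradient(m, "magnitude"), matrix(1, 3, 3))
  expect_error(wpd_gradient(matrix(1, 1, 5), "magnitude"), "at least 2")
  expect_error(wpd_gradient(matrix(1, 5, 1), "magnitude"), "at least 2")
})

test_that("node statistics use the population definition", {
  expect_equal(node_statistic(matrix(1:4, 2, 2), "mean"), 2.5)
  expect_equal(node_statistic(matrix(5, 3, 3), "sd"), 0)
  expect_equal(node_statistic(matrix(c(0, 0, 0, 2), 2, 2), "sd"), 0.8660254,
               tolerance = 1e-7)
  expect_error(node_statistic(matrix(numeric(0), 0, 0), "mean"), "empty")
})

test_that("feature vectors compose decompose -> select -> gradient -> statistic", {
  set.seed(11)
  x <- matrix(rnorm(256 * 22), 256, 22)
  cfg <- feature_config("gradiometer")
  fv <- extract_feature_vector(x, cfg)
  expect_length(fv, 21L)
  # manual composition oracle
  tree <- wpd_decompose(x, cfg$wavelet, cfg$levels)
  manual <- vapply(wpd_terminal_nodes(tree, "H"), function(m) {
    node_statistic(wpd_gradient(m, "time"), "sd")
  }, numeric(1))
  expect_equal(fv, manual)
  # magnetometer default: mean of raw coefficients
  fm <- extract_feature_vector(x, feature_config("magnetometer"))
  manual_m <- vapply(wpd_terminal_nodes(tree, "H"), node_statistic,
                     numeric(1), stat = "mean")
  expect_equal(fm, manual_m)
  # constant image: SD-of-gradient features are all zero
  expect_equal(unname(extract_feature_vector(matrix(4, 64, 8), cfg)),
               rep(0, 21))
})

test_that("features are scale-covariant", {
  set.seed(12)
  x <- matrix(rnorm(128 * 16), 128, 16)
  c0 <- -3.7
  f_mean <- extract_feature_vector(x, feature_config("magnetometer"))
  f_mean_c <- extract_feature_vector(c0 * x, feature_config("magnetometer"))
  expect_equal(f_mean_c, c0 * f_mean, tolerance = 1e-9)
  f_sd <- extract_feature_vector(x, feature_config("gradiometer"))
  f_sd_c <- extract_feature_vector(c0 * x, feature_config("gradiometer"))
  expect_equal(f_sd_c, abs(c0) * f_sd, tolerance = 1e-9)
})

test_that("level-3 nominal bands tile 0-80 Hz in 10 Hz steps", {
  paths3 <- names(wpd_terminal_nodes(wpd_decompose(matrix(rnorm(64 * 16), 64, 16),
                                                   "haar", 3)))
  paths3 <- paths3[nchar(paths3) == 3]
  # extend to all 64 level-3 paths via the tree itself
  tree <- wpd_decompose(matrix(rnorm(64 * 16), 64, 16), "haar", 3)
  all3 <- names(tree$nodes)[nchar(names(tree$nodes)) == 3]
  bands <- node_bands(all3, band_top = 80)
  expect_true(all(bands$band_high - bands$band_low == 10))
  # the 8 distinct time-frequency bands tile [0, 80]
  distinct <- sort(unique(bands$band_low))
  expect_equal(distinct, seq(0, 70, by = 10))
  # every band is hit by the same number of nodes (8 sensor-axis variants)
  expect_true(all(table(bands$band_low) == 8))
})
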