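test_that("LOOCV builds one leakage-free fold per participant index", {
  feats <- fake_features(n_per_class = 7, n_epochs = 18, separation = 2)
  cv <- loocv_run(feats)
  expect_equal(nrow(cv$reps), 7L)
  expect_true(all(cv$reps$n_test == 54L)) # 18 epochs x 3 classes
  # every observation tested exactly once across folds
  keys <- paste(cv$predictions$participant, cv$predictions$epoch)
  expect_equal(sort(keys), sort(unique(paste(feats$participant, feats$epoch))))
  # one participant per class per fold, never in its own training set
  for (r in seq_len(7)) {
    test_p <- cv$folds$test_participants[[r]]
    train_p <- cv$folds$train_participants[[r]]
    expect_length(test_p, 3L)
    expect_length(intersect(test_p, train_p), 0L)
    expect_equal(sort(substr(test_p, 1, 2)), c("AD", "HC", "MC"))
  }
  # two participants per class -> two folds
  cv2 <- loocv_run(fake_features(n_per_class = 2, n_epochs = 4))
  expect_equal(nrow(cv2$reps), 2L)
  # unequal class sizes rejected
  bad <- dplyr::filter(fake_features(n_per_class = 3, n_epochs = 4),
                       !(class == "AD" & participant == "AD03"))
  expect_error(loocv_run(bad), "unequal")
})

test_that("LOOCV separates well-separated classes and is near chance on noise", {
  strong <- loocv_run(fake_features(n_per_class = 4, n_epochs = 6,
                                    separation = 4, seed = 5))
  expect_gt(mean(strong$reps$acc_grad), 0.9)
  null <- loocv_run(fake_features(n_per_class = 4, n_epochs = 6,
                                  separation = 0, seed = 5))
  expect_lt(mean(null$reps$acc_grad), 0.62)
})

test_that("MCRS splits epochs at the stated fractions, reproducibly", {
  feats <- fake_features(n_per_class = 7, n_epochs = 18)
  cv <- mcrs_run(feats, n_reps = 3, train_frac = 2 / 3, seed = 9)
  # 378 epochs -> 252 train / 126 test
  expect_true(all(cv$reps$n_test == 126L))
  cv_again <- mcrs_run(feats, n_reps = 3, train_frac = 2 / 3, seed = 9)
  expect_identical(cv$predictions, cv_again$predictions)
  expect_identical(cv$reps, cv_again$reps)
  expect_error(mcrs_run(feats, n_reps = 1, train_frac = 1.0), "train")
})

test_that("epoch-level MCRS inflates accuracy relative to LOOCV under confounds", {
  # participant-level intercepts, weak class structure: epoch leakage helps
  accs <- purrr::map_dfr(1:20, function(s) {
    feats <- fake_features(n_per_class = 3, n_epochs = 6, separation = 0.3,
                           participant_sd = 1.5, seed = s)
    tibble::tibble(
      mcrs = mean(mcrs_run(feats, n_reps = 4, train_frac = 0.8,
                           seed = s)$reps$acc_grad),
      loocv = mean(loocv_run(feats)$reps$acc_grad)
    )
  })
  expect_gt(mean(accs$mcrs), mean(accs$loocv))
})

test_that("hybrid LOO-MCRS tests half of one held-out participant per class", {
  feats <- fake_features(n_per_class = 7, n_epochs = 18)
  cv <- hybrid_loo_mcrs_run(feats, repetitions = 25, seed = 4)
  # 9 epochs x 3 held-out participants tested; 6 x 18 x 3 trained on
  expect_true(all(cv$reps$n_test == 27L))
  for (r in seq_len(25)) {
    expect_length(intersect(cv$folds$test_participants[[r]],
                            cv$folds$train_participants[[r]]), 0L)
    expect_length(cv$folds$train_participants[[r]], 18L)
  }
  # reproducible under the same seed
  cv_b <- hybrid_loo_mcrs_run(feats, repetitions = 25, seed = 4)
  expect_identical(cv$predictions, cv_b$predictions)
  # 100 repetitions give every participant a test chance (7 per class)
  cv100 <- hybrid_loo_mcrs_run(fake_features(n_per_class = 7, n_epochs = 2),
                               repetitions = 100, seed = 1)
  tested <- unique(unlist(cv100$folds$test_participants))
  expect_length(tested, 21L)
  expect_error(hybrid_loo_mcrs_run(feats, repetitions = 1, test_frac = 0.01),
               "0 evaluation epochs")
  expect_error(hybrid_loo_mcrs_run(fake_features(n_per_class = 1, n_epochs = 4)),
               "at least 2 participants")
})

test_that("exhaustive hybrid selection at full test fraction degenerates to LOOCV", {
  feats <- fake_features(n_per_class = 5, n_epochs = 6, separation = 1.2,
                         seed = 8)
  loo <- loocv_run(feats)
  hyb <- hybrid_loo_mcrs_run(feats, repetitions = 5, test_frac = 1,
                             participant_selection = "exhaustive", seed = 3)
  # same folds in the same order -> identical predictions
  p1 <- dplyr::arrange(loo$predictions, participant, epoch)
  p2 <- dplyr::arrange(hyb$predictions, participant, epoch)
  expect_equal(p1$pred_grad, p2$pred_grad)
  expect_equal(p1$pred_magn, p2$pred_magn)
  expect_equal(p1$pred_fused, p2$pred_fused)
  expect_equal(mean(loo$reps$acc_fused), mean(hyb$reps$acc_fused))
})

test_that("confusion matrices count actual x predicted, averaging over reps", {
  truth <- rep(c("AD", "MCI", "HC"), each = 18)
  perfect <- confusion_and_accuracy(truth, truth)
  expect_equal(perfect$confusion, diag(18, 3) |>
                 `dimnames<-`(list(actual = c("AD", "MCI", "HC"),
                                   predicted = c("AD", "MCI", "HC"))))
  expect_equal(perfect$accuracy, 1)
  # all AD predicted as MCI
  pred <- truth
  pred[truth == "AD"] <- "MCI"
  m <- confusion_and_accuracy(truth, pred)
  expect_equal(unname(m$confusion["AD", ]), c(0, 18, 0))
  expect_equal(m$accuracy, 36 / 54)
  # entry-wise averaging of two repetitions
  avg <- confusion_and_accuracy(c(truth, truth), c(truth, pred),
                                rep = rep(1:2, each = 54))
  expect_equal(unname(avg$confusion["AD", ]), c(9, 9, 0))
  expect_error(confusion_and_accuracy("XX", "AD"), "unknown")
})

test_that("Kruskal-Wallis H and Holm adjustment match hand-computed oracles", {
  # three groups with non-overlapping ranks: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
  res <- kruskal_wallis_holm(list(x = list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))))
  expect_equal(res$H, 7.2, tolerance = 1e-12)
  expect_equal(res$df, 2L)
  # identical groups: H = 0, p = 1 by convention
  same <- kruskal_wallis_holm(list(x = list(c(1, 1), c(1, 1), c(1, 1))))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  # Holm step-down: sort raw p, multiply by (m, m-1, ...), enforce monotone
  set.seed(41)
  groups <- purrr::map(1:3, function(i) {
    list(rnorm(8, 0), rnorm(8, i * 0.6))
  })
  names(groups) <- c("a", "b", "c")
  res3 <- kruskal_wallis_holm(groups)
  ord <- order(res3$p)
  manual <- res3$p
  manual[ord] <- pmin(1, cummax(res3$p[ord] * (3:1)))
  expect_equal(res3$p_adj, manual)
})
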