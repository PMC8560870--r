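#' Pipeline configuration for classification and fusion
#'
#' Binds each modality to its classifier (magnetometer to 3-NN, gradiometer
#' to the quadratic Bayes normal classifier, both overridable), and fixes
#' the classifier and fusion settings used inside every cross-validation
#' fold. Standardisation and classifier fitting always happen on the
#' training side of a split only.
#'
#' @param modality_classifier Named character vector mapping modality to
#'   `"knn"` or `"qbnc"`.
#' @param k Neighbourhood size for 3-NN (default 3).
#' @param shrinkage QBNC covariance shrinkage (default 1e-3).
#' @param fusion_level `"participant"` (default) or `"epoch"`.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(modality_classifier = c(magnetometer = "knn",
                                                    gradiometer = "qbnc"),
                            k = 3L, shrinkage = 1e-3,
                            fusion_level = c("participant", "epoch")) {
  stopifnot(all(modality_classifier %in% c("knn", "qbnc")))
  structure(list(modality_classifier = modality_classifier, k = as.integer(k),
                 shrinkage = shrinkage,
                 fusion_level = match.arg(fusion_level)),
            class = "pipeline_config")
}

.feature_cols <- function(features) {
  setdiff(names(features), c("participant", "class", "epoch", "modality", "roi"))
}

.epoch_key <- function(tbl) paste(tbl$participant, tbl$epoch, sep = "#")

# Classify one train/test split of a two-modality feature table and fuse.
# train_keys / test_keys are participant#epoch keys; a key may appear on one
# side only per modality. Returns per-epoch predictions (per modality and
# fused) plus accuracies.
.evaluate_split <- function(features, train_keys, test_keys, config) {
  feat_cols <- .feature_cols(features)
  modalities <- intersect(c("magnetometer", "gradiometer"),
                          unique(features$modality))
  scores <- list()
  meta <- NULL
  for (mod in modalities) {
    fm <- features[features$modality == mod, , drop = FALSE]
    fm <- fm[order(fm$participant, fm$epoch), , drop = FALSE]
    key <- .epoch_key(fm)
    tr <- fm[key %in% train_keys, , drop = FALSE]
    te <- fm[key %in% test_keys, , drop = FALSE]
    if (!nrow(te)) stop("empty test set")
    if (length(unique(tr$class)) < 3L)
      stop("degenerate split: training set lost a class")
    Xtr <- as.matrix(tr[feat_cols])
    Xte <- as.matrix(te[feat_cols])
    Xte_s <- standardize(Xtr, Xte)
    Xtr_s <- standardize(Xtr)
    sc <- switch(config$modality_classifier[[mod]],
      knn = knn_scores(Xtr_s, tr$class, Xte_s, k = config$k),
      qbnc = qbnc_scores(qbnc_fit(Xtr_s, tr$class, config$shrinkage), Xte_s)
    )
    scores[[mod]] <- sc
    m <- te[c("participant", "class", "epoch")]
    if (is.null(meta)) meta <- m
    else stopifnot(identical(meta$participant, m$participant),
                   identical(meta$epoch, m$epoch))
  }

  preds <- meta
  for (mod in modalities) {
    preds[[paste0("pred_", substr(mod, 1, 4))]] <-
      apply(scores[[mod]], 1, function(r) decide(r))
  }

  if (length(modalities) == 2L) {
    fused <- purrr::map_dfr(unique(preds$participant), function(pid) {
      rows <- which(preds$participant == pid)
      if (config$fusion_level == "participant") {
        d <- fuse_decision(scores$magnetometer[rows, , drop = FALSE],
                           scores$gradiometer[rows, , drop = FALSE],
                           true_label = preds$class[rows][1], participant = pid)
        tibble::tibble(participant = pid, pred_fused = d$predicted)
      } else {
        ep <- fuse_decision(scores$magnetometer[rows, , drop = FALSE],
                            scores$gradiometer[rows, , drop = FALSE],
                            true_label = preds$class[rows][1], participant = pid,
                            level = "epoch")
        # majority over the participant's per-epoch fused decisions
        tibble::tibble(participant = pid,
                       pred_fused = names(sort(table(factor(ep$predicted,
                                                            CLASS_LEVELS)),
                                               decreasing = TRUE))[1])
      }
    })
    preds <- dplyr::left_join(preds, fused, by = "participant")
  }
  preds
}

.accuracy <- function(truth, predicted) mean(truth == predicted)

.new_cv_result <- function(scheme, predictions, folds) {
  acc_cols <- c(acc_mag = "pred_magn", acc_grad = "pred_grad",
                acc_fused = "pred_fused")
  acc_cols <- acc_cols[acc_cols %in% names(predictions)]
  reps <- purrr::map_dfr(split(predictions, predictions$rep), function(p) {
    row <- tibble::tibble(rep = p$rep[1], n_test = nrow(p))
    for (nm in names(acc_cols))
      row[[nm]] <- .accuracy(p$class, p[[acc_cols[[nm]]]])
    row
  })
  reps <- reps[order(reps$rep), ]
  structure(list(scheme = scheme, predictions = predictions, reps = reps,
                 folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> scheme: ", x$scheme, ", ", nrow(x$reps),
      " repetition(s)\n", sep = "")
  for (nm in intersect(c("acc_mag", "acc_grad", "acc_fused"), names(x$reps)))
    cat(sprintf("  mean %s: %.3f (sd %.3f)\n", nm, mean(x$reps[[nm]]),
                stats::sd(x$reps[[nm]])))
  invisible(x)
}

#' Leave-one-participant-out cross-validation
#'
#' One fold per participant index: fold i holds out the i-th participant of
#' every class (all of their epochs) and trains on the rest, so no
#' participant contributes to both sides of any fold. With 7 participants
#' per class and 18 epochs each, every fold tests 54 epochs (18 per class).
#'
#' @param features Two-modality feature table from [extract_features()].
#' @param config A [pipeline_config()].
#' @return A `cv_result`.
#' @export
loocv_run <- function(features, config = pipeline_config()) {
  info <- dplyr::distinct(features, .data$participant, .data$class)
  split_by_class <- split(sort(info$participant), info$class[order(info$participant)])
  sizes <- lengths(split_by_class)
  if (length(unique(sizes)) != 1L)
    stop("unequal participant counts per class: ",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))
  n_fold <- unname(sizes[1])
  all_keys <- unique(.epoch_key(features))
  preds <- purrr::map_dfr(seq_len(n_fold), function(i) {
    test_pids <- vapply(split_by_class, `[`, character(1), i)
    test_keys <- all_keys[sub("#.*", "", all_keys) %in% test_pids]
    out <- .evaluate_split(features, setdiff(all_keys, test_keys), test_keys,
                           config)
    out$rep <- i
    out
  })
  folds <- dplyr::summarise(
    dplyr::group_by(preds, .data$rep),
    test_participants = list(unique(.data$participant)),
    .groups = "drop"
  )
  folds$train_participants <- purrr::map(folds$test_participants,
                                         ~setdiff(info$participant, .x))
  .new_cv_result("loocv", preds, folds)
}

#' Monte Carlo random-subsampling cross-validation
#'
#' Epoch-level random splits that deliberately ignore participant identity:
#' the same participant's epochs can land on both sides of a split, so
#' accuracy estimates absorb participant-level leakage and tend to be
#' optimistic relative to participant-held-out schemes. Provided as the
#' baseline that the leakage-free schemes are compared against.
#'
#' @param features Two-modality feature table.
#' @param config A [pipeline_config()].
#' @param n_reps Number of random splits (default 100).
#' @param train_frac Fraction of epochs used for training (default 2/3).
#' @param seed RNG seed; per-repetition seeds derive from it and are logged
#'   in the result's `folds`.
#' @return A `cv_result`.
#' @export
mcrs_run <- function(features, config = pipeline_config(), n_reps = 100L,
                     train_frac = 2 / 3, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  all_keys <- unique(.epoch_key(features))
  n_train <- floor(train_frac * length(all_keys))
  if (n_train < 3L || n_train >= length(all_keys))
    stop("degenerate train fraction")
  res <- purrr::map(seq_len(n_reps), function(r) {
    rep_seed <- .child_seed(seed, r)
    train_keys <- .with_seed(rep_seed, sample(all_keys, n_train))
    out <- .evaluate_split(features, train_keys,
                           setdiff(all_keys, train_keys), config)
    out$rep <- r
    list(preds = out,
         fold = tibble::tibble(rep = r, seed = rep_seed,
                               test_participants = list(unique(out$participant)),
                               train_participants = list(unique(sub("#.*", "", train_keys)))))
  })
  .new_cv_result("mcrs", purrr::map_dfr(res, "preds"),
                 purrr::map_dfr(res, "fold"))
}

#' Hybrid LOO-MCRS cross-validation
#'
#' The leakage-free randomised scheme: per repetition and per class, one
#' participant is held out (chosen uniformly at random), the remaining
#' participants form the training set, and a random 50% of the held-out
#' participant's epochs (without replacement, floor) form the evaluation
#' set. Repeating many times gives every participant a test chance while no
#' repetition ever shares a participant between training and evaluation.
#'
#' @param features Two-modality feature table.
#' @param config A [pipeline_config()].
#' @param repetitions Number of repetitions (default 100).
#' @param test_frac Fraction of the held-out participant's epochs evaluated
#'   per repetition (default 0.5).
#' @param seed RNG seed; per-repetition seeds are logged.
#' @param participant_selection `"random"` (default) or `"exhaustive"`,
#'   which cycles the held-out participant index deterministically —
#'   combined with `test_frac = 1` this reproduces leave-one-participant-out
#'   exactly.
#' @return A `cv_result`.
#' @export
hybrid_loo_mcrs_run <- function(features, config = pipeline_config(),
                                repetitions = 100L, test_frac = 0.5,
                                seed = 1L,
                                participant_selection = c("random", "exhaustive")) {
  participant_selection <- match.arg(participant_selection)
  stopifnot(test_frac > 0, test_frac <= 1)
  info <- dplyr::distinct(features, .data$participant, .data$class)
  split_by_class <- split(sort(info$participant), info$class[order(info$participant)])
  if (any(lengths(split_by_class) < 2L))
    stop("need at least 2 participants per class")
  keys <- unique(.epoch_key(features))
  keys_by_pid <- split(keys, sub("#.*", "", keys))
  n_test_per <- vapply(keys_by_pid, function(k) floor(test_frac * length(k)),
                       numeric(1))
  if (any(n_test_per < 1))
    stop("test_frac yields 0 evaluation epochs for some participant")

  res <- purrr::map(seq_len(repetitions), function(r) {
    rep_seed <- .child_seed(seed, r)
    .with_seed(rep_seed, {
      held <- vapply(split_by_class, function(pids) {
        if (participant_selection == "random") sample(pids, 1L)
        else pids[(r - 1L) %% length(pids) + 1L]
      }, character(1))
      test_keys <- unlist(lapply(held, function(pid) {
        k <- keys_by_pid[[pid]]
        sample(k, floor(test_frac * length(k)))
      }), use.names = FALSE)
      train_keys <- keys[!sub("#.*", "", keys) %in% held]
      out <- .evaluate_split(features, train_keys, test_keys, config)
      out$rep <- r
      list(preds = out,
           fold = tibble::tibble(rep = r, seed = rep_seed,
                                 test_participants = list(unname(held)),
                                 train_participants = list(setdiff(info$participant, held))))
    })
  })
  .new_cv_result("hybrid_loo_mcrs", purrr::map_dfr(res, "preds"),
                 purrr::map_dfr(res, "fold"))
}

#' Confusion matrix and accuracy
#'
#' Rows are actual classes, columns predicted. With a `rep` grouping the
#' per-repetition matrices are averaged entry-wise (which is why reported
#' confusion counts can be fractional); accuracy is trace over total of the
#' averaged matrix, equal to the mean per-repetition accuracy for balanced
#' repetition sizes.
#'
#' @param truth Actual class labels.
#' @param predicted Predicted class labels.
#' @param rep Optional repetition index for entry-wise averaging.
#' @return List with `confusion` (3 x 3 matrix) and `accuracy`.
#' @export
confusion_and_accuracy <- function(truth, predicted, rep = NULL) {
  if (!length(truth)) stop("no predictions")
  truth <- factor(as.character(truth), levels = CLASS_LEVELS)
  predicted <- factor(as.character(predicted), levels = CLASS_LEVELS)
  if (anyNA(truth) || anyNA(predicted)) stop("unknown class labels")
  if (is.null(rep)) rep <- rep(1L, length(truth))
  mats <- lapply(split(seq_along(truth), rep), function(ix) {
    table(actual = truth[ix], predicted = predicted[ix])
  })
  avg <- Reduce(`+`, mats) / length(mats)
  conf <- matrix(as.numeric(avg), 3, 3,
                 dimnames = list(actual = CLASS_LEVELS,
                                 predicted = CLASS_LEVELS))
  list(confusion = conf, accuracy = sum(diag(conf)) / sum(conf))
}

#' Kruskal-Wallis tests with Holm step-down adjustment
#'
#' Runs one Kruskal-Wallis H test (chi-square approximation with tie
#' correction) per named comparison and adjusts the p-values across
#' comparisons with the Holm-Bonferroni step-down procedure (monotonicity
#' enforced). A comparison whose pooled values are all identical gets
#' H = 0 and p = 1 by convention.
#'
#' @param samples Named list of comparisons; each element is a list of two
#'   or more numeric vectors (the accuracy samples being compared).
#' @return Tibble with `comparison`, `H`, `df`, `p`, `p_adj`.
#' @export
kruskal_wallis_holm <- function(samples) {
  stopifnot(length(samples) >= 1L)
  rows <- purrr::imap_dfr(samples, function(groups, name) {
    stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
    pooled <- unlist(groups)
    if (length(unique(pooled)) == 1L) {
      tibble::tibble(comparison = name, H = 0, df = length(groups) - 1L, p = 1)
    } else {
      kt <- stats::kruskal.test(groups)
      tibble::tibble(comparison = name, H = unname(kt$statistic),
                     df = unname(kt$parameter), p = kt$p.value)
    }
  })
  rows$p_adj <- stats::p.adjust(rows$p, method = "holm")
  rows
}
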