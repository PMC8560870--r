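#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' One row per repetition and accuracy type.
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with `scheme`, `rep`, `metric`, `accuracy`.
#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) {
  long <- tidyr::pivot_longer(x$reps, dplyr::starts_with("acc_"),
                              names_to = "metric", values_to = "accuracy")
  long$scheme <- x$scheme
  long[c("scheme", "rep", "metric", "accuracy")]
}

#' Summarise a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble: scheme, repetitions, mean and SD of each
#'   accuracy type.
#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  out <- tibble::tibble(scheme = x$scheme, n_reps = nrow(x$reps))
  for (nm in intersect(c("acc_mag", "acc_grad", "acc_fused"), names(x$reps))) {
    out[[paste0("mean_", nm)]] <- mean(x$reps[[nm]])
    out[[paste0("sd_", nm)]] <- stats::sd(x$reps[[nm]])
  }
  out
}

#' Tidy a fitted quadratic Bayes normal classifier
#'
#' @param x A `qbnc_model`.
#' @param ... Unused.
#' @return Tibble with one row per class and feature: class, feature index,
#'   mean, marginal variance.
#' @exportS3Method generics::tidy
tidy.qbnc_model <- function(x, ...) {
  purrr::imap_dfr(x$classes, function(f, cl) {
    tibble::tibble(class = cl, feature = seq_along(f$mu), mean = f$mu,
                   variance = diag(f$cov), prior = x$priors[[cl]])
  })
}
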