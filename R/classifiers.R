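#' Z-score features with training-set statistics
#'
#' Per-feature standardisation fitted on the training rows only (means and
#' SDs of `train`), applied to `apply_to`. Zero-variance features map to 0,
#' so degenerate columns never produce divisions by zero.
#'
#' @param train Numeric matrix (rows = observations) whose column statistics
#'   define the transform.
#' @param apply_to Matrix to transform (defaults to `train`).
#' @return Matrix of the same shape as `apply_to`.
#' @export
standardize <- function(train, apply_to = train) {
  train <- as.matrix(train)
  apply_to <- as.matrix(apply_to)
  if (!nrow(train)) stop("empty training matrix")
  mu <- colMeans(train)
  sdev <- apply(train, 2, stats::sd)
  out <- sweep(apply_to, 2, mu, "-")
  keep <- sdev > 0
  out[, keep] <- sweep(out[, keep, drop = FALSE], 2, sdev[keep], "/")
  out[, !keep] <- 0
  out
}

.score_matrix <- function(scores, meta = NULL) {
  colnames(scores) <- CLASS_LEVELS
  attr(scores, "meta") <- meta
  class(scores) <- c("score_matrix", class(scores))
  scores
}

#' k-nearest-neighbour class scores
#'
#' Euclidean 3-NN (by default) vote fractions: the score of class J for a
#' query is the number of class-J training points among its k nearest
#' neighbours, divided by k, so each score row sums to 1. Distance ties are
#' broken by training-sample order.
#'
#' @param train Numeric training matrix (rows = observations).
#' @param labels Class labels of the training rows (AD/MCI/HC).
#' @param queries Numeric query matrix with matching columns.
#' @param k Neighbourhood size (default 3); at most `nrow(train)`.
#' @return A `score_matrix`: queries x 3 matrix of vote fractions.
#' @export
knn_scores <- function(train, labels, queries, k = 3L) {
  train <- as.matrix(train)
  queries <- as.matrix(queries)
  if (!nrow(train)) stop("empty training set")
  if (k > nrow(train)) stop("k (", k, ") exceeds training size (", nrow(train), ")")
  labels <- factor(as.character(labels), levels = CLASS_LEVELS)
  # squared Euclidean distances, queries x train
  qq <- rowSums(queries^2)
  tt <- rowSums(train^2)
  d2 <- outer(qq, tt, "+") - 2 * queries %*% t(train)
  scores <- t(apply(d2, 1, function(dr) {
    nn <- order(dr)[seq_len(k)] # order() breaks ties by index = training order
    tabulate(labels[nn], nbins = 3L) / k
  }))
  .score_matrix(scores)
}

#' Fit a quadratic Bayes normal classifier
#'
#' Class-conditional Gaussian densities with shrinkage-regularised
#' covariances: each class covariance is replaced by
#' `(1 - lambda) * S + lambda * diag(S) + eps * I`, which keeps the model
#' well defined when the feature dimension approaches the per-class sample
#' count. Priors are uniform (the study design is class-balanced).
#'
#' @param train Numeric training matrix.
#' @param labels Class labels (AD/MCI/HC); at least 2 samples per class.
#' @param shrinkage Diagonal shrinkage weight lambda (default 1e-3).
#' @return A `qbnc_model` with per-class means, covariances and priors.
#' @export
qbnc_fit <- function(train, labels, shrinkage = 1e-3) {
  train <- as.matrix(train)
  labels <- factor(as.character(labels), levels = CLASS_LEVELS)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("each class needs at least 2 training samples; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  p <- ncol(train)
  fits <- lapply(CLASS_LEVELS, function(cl) {
    X <- train[labels == cl, , drop = FALSE]
    mu <- colMeans(X)
    S <- stats::cov(X)
    S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), p)
    eps <- 1e-8 * max(mean(diag(S)), 1e-12)
    S <- S + eps * diag(p)
    ch <- chol(S)
    list(mu = mu, cov = S, chol = ch,
         logdet = 2 * sum(log(diag(ch))))
  })
  names(fits) <- CLASS_LEVELS
  structure(list(classes = fits, priors = stats::setNames(rep(1 / 3, 3), CLASS_LEVELS),
                 p = p, shrinkage = shrinkage),
            class = "qbnc_model")
}

#' Posterior class scores from a fitted QBNC
#'
#' Gaussian log-densities plus log-priors, normalised with the
#' log-sum-exp trick; each output row is a posterior distribution over the
#' three classes and sums to 1.
#'
#' @param model A `qbnc_model`.
#' @param queries Numeric matrix with `model$p` columns.
#' @return A `score_matrix` of posteriors.
#' @export
qbnc_scores <- function(model, queries) {
  queries <- as.matrix(queries)
  if (ncol(queries) != model$p)
    stop("query dimension (", ncol(queries), ") does not match model (", model$p, ")")
  loglik <- sapply(CLASS_LEVELS, function(cl) {
    f <- model$classes[[cl]]
    xc <- sweep(queries, 2, f$mu, "-")
    z <- backsolve(f$chol, t(xc), transpose = TRUE) # chol' z = xc'
    maha <- colSums(z^2)
    -0.5 * (maha + f$logdet + model$p * log(2 * pi)) + log(model$priors[[cl]])
  })
  loglik <- matrix(loglik, ncol = 3)
  mx <- apply(loglik, 1, max)
  w <- exp(loglik - mx)
  .score_matrix(w / rowSums(w))
}

#' Normalise non-negative score rows to sum to 1
#'
#' Rows that are all zero become the uniform distribution (1/3, 1/3, 1/3).
#' Idempotent on already-normalised input.
#'
#' @param raw Non-negative numeric matrix with 3 columns.
#' @return A `score_matrix`.
#' @export
normalize_scores <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("scores must be non-negative")
  s <- rowSums(raw)
  out <- raw
  out[s > 0, ] <- raw[s > 0, , drop = FALSE] / s[s > 0]
  out[s == 0, ] <- 1 / 3
  .score_matrix(out)
}

#' Serialise / restore a QBNC model as JSON
#'
#' @param model A `qbnc_model`.
#' @param path File path.
#' @return `path` invisibly; `qbnc_from_json()` returns the model.
#' @export
qbnc_to_json <- function(model, path) {
  obj <- list(p = model$p, shrinkage = model$shrinkage,
              priors = as.list(model$priors),
              classes = purrr::map(model$classes, function(f) {
                list(mu = f$mu, cov = as.vector(f$cov))
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname qbnc_to_json
#' @export
qbnc_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$p
  fits <- purrr::map(obj$classes, function(f) {
    S <- matrix(f$cov, p, p)
    ch <- chol(S)
    list(mu = f$mu, cov = S, chol = ch, logdet = 2 * sum(log(diag(ch))))
  })
  structure(list(classes = fits[CLASS_LEVELS],
                 priors = stats::setNames(unlist(obj$priors[CLASS_LEVELS]), CLASS_LEVELS),
                 p = p, shrinkage = obj$shrinkage),
            class = "qbnc_model")
}
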