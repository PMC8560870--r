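#' Mean class scores over a participant's observations
#'
#' Column-wise arithmetic mean of an observations x 3 score matrix: the mean
#' probability of each class across a participant's test epochs. Because
#' every input row sums to 1, the result does too.
#'
#' @param scores Numeric matrix with 3 columns (rows = epochs), rows summing
#'   to 1.
#' @return Length-3 named numeric vector.
#' @export
mean_class_scores <- function(scores) {
  scores <- as.matrix(scores)
  if (!nrow(scores)) stop("empty score matrix")
  stats::setNames(colMeans(scores), CLASS_LEVELS)
}

#' Product-rule fusion of two modality score vectors
#'
#' Element-wise product of the two class-mean score vectors (magnetometer
#' and gradiometer). The raw product determines the decision; a renormalised
#' version (summing to 1) is returned alongside for reporting.
#'
#' @param u,v Length-3 score vectors with entries in `[0, 1]`.
#' @return List with `raw` (element-wise product) and `normalized`.
#' @export
product_fuse <- function(u, v) {
  stopifnot(length(u) == 3L, length(v) == 3L)
  if (any(u < 0 | u > 1) || any(v < 0 | v > 1))
    stop("score entries must lie in [0, 1]")
  w <- stats::setNames(as.numeric(u) * as.numeric(v), CLASS_LEVELS)
  s <- sum(w)
  norm <- if (s > 0) w / s else stats::setNames(rep(1 / 3, 3), CLASS_LEVELS)
  list(raw = w, normalized = norm)
}

#' Decide a class from a fused score vector
#'
#' Argmax over the three classes; exact ties are broken by the fixed class
#' order AD < MCI < HC (the first maximal entry wins).
#'
#' @param w Length-3 numeric vector of finite scores.
#' @return A class label.
#' @export
decide <- function(w) {
  stopifnot(length(w) == 3L)
  if (any(!is.finite(w))) stop("non-finite score entries")
  CLASS_LEVELS[which.max(w)]
}

#' Fuse per-epoch modality scores into a participant decision
#'
#' The participant-level bimodal rule: average each modality's epoch scores
#' into a class-mean vector, multiply the two vectors element-wise, and take
#' the argmax. Per-epoch fusion (`level = "epoch"`) multiplies the two
#' modality scores epoch by epoch instead and is provided for comparison.
#'
#' @param u_scores Magnetometer epoch scores (n x 3, rows sum to 1).
#' @param v_scores Gradiometer epoch scores (same shape).
#' @param true_label Optional true class, carried through.
#' @param participant Optional participant id, carried through.
#' @param level `"participant"` (default) or `"epoch"`.
#' @return For participant level: a `fused_decision` list with `p_u`, `p_v`,
#'   `w` (raw product), `w_norm`, `predicted`, `true`, `participant`. For
#'   epoch level: a tibble of per-epoch decisions.
#' @export
fuse_decision <- function(u_scores, v_scores, true_label = NA_character_,
                          participant = NA_character_,
                          level = c("participant", "epoch")) {
  level <- match.arg(level)
  if (level == "participant") {
    p_u <- mean_class_scores(u_scores)
    p_v <- mean_class_scores(v_scores)
    f <- product_fuse(p_u, p_v)
    structure(list(participant = participant, p_u = p_u, p_v = p_v,
                   w = f$raw, w_norm = f$normalized,
                   predicted = decide(f$raw), true = true_label),
              class = "fused_decision")
  } else {
    stopifnot(nrow(u_scores) == nrow(v_scores))
    purrr::map_dfr(seq_len(nrow(u_scores)), function(i) {
      f <- product_fuse(u_scores[i, ], v_scores[i, ])
      tibble::tibble(participant = participant, epoch = i,
                     predicted = decide(f$raw), true = true_label)
    })
  }
}

#' @export
print.fused_decision <- function(x, ...) {
  cat("<fused_decision> ", x$participant, ": predicted ", x$predicted,
      " (true ", x$true, ")\n", sep = "")
  cat("  W =", paste(sprintf("%s %.4f", CLASS_LEVELS, x$w), collapse = ", "), "\n")
  invisible(x)
}
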