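#' Fuse the two classifier streams
#'
#' The interval prediction of the pipeline is the component-wise arithmetic
#' mean of the single-frame stream and the multiframe stream. Works on
#' single vectors or on matrices (one interval per row); both inputs must
#' be normalized and of equal dimension.
#'
#' @param p1,p2 probability vectors, or matrices of row-wise probability
#'   vectors, over the same states (3 or 4).
#' @return normalized vector/matrix of the same shape.
#' @export
fuse_streams <- function(p1, p2) {
  m1 <- if (is.matrix(p1)) p1 else matrix(p1, nrow = 1)
  m2 <- if (is.matrix(p2)) p2 else matrix(p2, nrow = 1)
  if (!identical(dim(m1), dim(m2))) {
    stop("stream shapes differ: ", paste(dim(m1), collapse = "x"), " vs ",
         paste(dim(m2), collapse = "x"))
  }
  check_prob_matrix(m1); check_prob_matrix(m2)
  out <- (m1 + m2) / 2
  if (is.matrix(p1)) out else out[1, ]
}

#' Centered rolling average over consecutive intervals
#'
#' Smooths a sequence of per-interval probability vectors with a centered
#' moving mean of odd width. At the sequence boundaries the window is
#' truncated (not padded), so the first element with window 3 is the mean of
#' elements 1 and 2 only. Averaging normalized vectors keeps them
#' normalized; output length equals input length.
#'
#' @param probs matrix of row-wise probability vectors.
#' @param window odd window width >= 1 (default 3).
#' @return matrix of the same shape.
#' @export
rolling_average <- function(probs, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  stopifnot(is.matrix(probs))
  n <- nrow(probs)
  if (n == 0 || window == 1) return(probs)
  half <- (window - 1) / 2
  cs <- rbind(0, apply(probs, 2, cumsum))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  out <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  dimnames(out) <- dimnames(probs)
  out
}

#' Inject the absent state into a behavior probability vector
#'
#' The detector decides presence: the probability of the absent state is
#' one minus the fraction of the interval's frames with a surviving
#' detection, and the three behavior probabilities are scaled by that
#' fraction, yielding a normalized 4-state vector.
#'
#' @param behavior_probs length-3 probability vector over (standing, lhu,
#'   lhd), or `NULL` when no frame was detected.
#' @param detected_fraction fraction in [0, 1]; must be > 0 exactly when
#'   `behavior_probs` is present.
#' @return length-4 probability vector over (standing, lhu, lhd, absent).
#' @export
inject_absence <- function(behavior_probs, detected_fraction) {
  stopifnot(detected_fraction >= 0, detected_fraction <= 1)
  if (detected_fraction == 0) {
    if (!is.null(behavior_probs)) {
      stop("behavior_probs given although nothing was detected")
    }
    return(stats::setNames(c(0, 0, 0, 1), behavior_levels()))
  }
  if (is.null(behavior_probs)) {
    stop("behavior_probs required when detected_fraction > 0")
  }
  stopifnot(length(behavior_probs) == 3)
  if (abs(sum(behavior_probs) - 1) > 1e-9) {
    stop("behavior_probs must sum to 1")
  }
  stats::setNames(c(behavior_probs * detected_fraction,
                    1 - detected_fraction), behavior_levels())
}

#' Decide a label from a probability vector
#'
#' Argmax with deterministic tie-breaking by the fixed label order
#' standing < lhu < lhd < absent (ties go to the earlier state).
#'
#' @param probs normalized probability vector over 3 or 4 states, or a
#'   matrix of row-wise vectors.
#' @param levels label vocabulary matching the columns (defaults to the
#'   first 3 or all 4 of [behavior_levels()]).
#' @return factor of decided labels (length 1 for a single vector).
#' @export
decide <- function(probs, levels = NULL) {
  m <- if (is.matrix(probs)) probs else matrix(probs, nrow = 1)
  if (is.null(levels)) levels <- behavior_levels()[seq_len(ncol(m))]
  stopifnot(ncol(m) == length(levels))
  check_prob_matrix(m)
  idx <- apply(m, 1, which.max)  # which.max: first maximum wins
  factor(levels[idx], levels = behavior_levels())
}
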