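# Frame records are kept as a plain data.frame with one row per frame:
#   frame_index (0-based), detected (logical), conf, x0, y0, x1, y1,
#   p_standing, p_lhu, p_lhd
# Probability columns are NA on frames without a detection: no animal means
# no classifier output.

#' Group a night of 1-fps frames into fixed intervals
#'
#' Partitions `n_frames` consecutive frames into half-open index ranges of
#' `fps * interval_s` frames each (7 at the defaults: 1 fps, 7 s). An
#' incomplete trailing group is dropped, keeping the fixed-length interval
#' contract.
#'
#' @param n_frames number of frames in the night.
#' @param fps frame rate (default 1).
#' @param interval_s interval length in seconds (default 7).
#' @return data.frame with columns `interval_index` (0-based), `start`,
#'   `end` (0-based, half-open frame indices); zero rows if no complete
#'   interval fits.
#' @export
group_frames <- function(n_frames, fps = 1, interval_s = 7) {
  fpi <- fps * interval_s
  if (fpi <= 0 || fpi != round(fpi)) {
    stop("fps * interval_s must be a positive integer, got ", fpi)
  }
  fpi <- as.integer(round(fpi))
  k <- n_frames %/% fpi
  if (k == 0) {
    return(data.frame(interval_index = integer(), start = integer(),
                      end = integer()))
  }
  start <- (seq_len(k) - 1L) * fpi
  data.frame(interval_index = seq_len(k) - 1L, start = start,
             end = start + fpi)
}

#' Accumulate single-frame predictions over one interval (stream 1)
#'
#' The single-frame classifier emits one 3-state probability vector per
#' detected frame; the interval-level stream-1 prediction is their
#' unweighted arithmetic mean. The fraction of frames with a detection is
#' returned alongside and later drives absence injection
#' ([inject_absence()]).
#'
#' @param frames data.frame of frame records for exactly one interval
#'   (columns `detected`, `p_standing`, `p_lhu`, `p_lhd`).
#' @return list with `probs` (length-3 named numeric, or `NULL` when no
#'   frame was detected) and `detected_fraction` in [0, 1].
#' @export
accumulate_stream1 <- function(frames) {
  stopifnot(is.data.frame(frames), nrow(frames) >= 1)
  det <- which(frames$detected)
  frac <- length(det) / nrow(frames)
  if (length(det) == 0) {
    return(list(probs = NULL, detected_fraction = 0))
  }
  p <- colMeans(frames[det, c("p_standing", "p_lhu", "p_lhd"), drop = FALSE])
  if (anyNA(p)) stop("detected frames with missing probability vectors")
  list(probs = stats::setNames(as.numeric(p), c("standing", "lhu", "lhd")),
       detected_fraction = frac)
}

#' Choose the frames entering the multiframe encoding (stream 2)
#'
#' Four of the seven frames of an interval form the 2 x 2 mosaic input.
#' Which four is a free choice; the default offsets {0, 2, 4, 6} are evenly
#' spaced over the interval with both endpoints included, maximizing
#' temporal coverage. The choice is configurable so that inputs stay
#' compatible with a given trained model.
#'
#' @param interval_range integer vector of the interval's frame indices
#'   (length `fps * interval_s`, 7 by default).
#' @param offsets 0-based offsets into the interval (default c(0, 2, 4, 6)).
#' @return integer vector of selected absolute frame indices.
#' @export
select_encoding_frames <- function(interval_range, offsets = c(0L, 2L, 4L, 6L)) {
  if (any(offsets < 0) || any(offsets >= length(interval_range))) {
    stop("offsets must lie within the interval")
  }
  interval_range[offsets + 1L]
}

#' Read and write per-frame prediction CSVs
#'
#' Dialect: `frame_index,detected,conf,x0,y0,x1,y1,p_standing,p_lhu,p_lhd`,
#' header mandatory; box and probability fields are empty on undetected
#' frames.
#'
#' @param path CSV file path.
#' @param frames frame-record data.frame.
#' @return `read_frame_records()` returns the frame-record data.frame.
#' @export
read_frame_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "detected", "conf", "x0", "y0", "x1", "y1",
            "p_standing", "p_lhu", "p_lhd")
  if (!all(need %in% names(df))) {
    stop("frame CSV ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  df$detected <- as.logical(df$detected)
  pr <- as.matrix(df[, c("p_standing", "p_lhu", "p_lhd")])
  ok <- df$detected
  if (any(ok) && any(abs(rowSums(pr[ok, , drop = FALSE]) - 1) > 1e-9)) {
    stop("probability rows of detected frames must sum to 1 in ", path)
  }
  df[need]
}

#' @rdname read_frame_records
#' @export
write_frame_records <- function(frames, path) {
  utils::write.csv(frames, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Aggregate a night of frame records into interval predictions
#'
#' Convenience wrapper running [group_frames()] and [accumulate_stream1()]
#' over a whole night: the stream-1 interval probabilities plus detected
#' fractions that feed fusion and absence injection.
#'
#' @param frames frame-record data.frame for one night, `frame_index`
#'   starting at 0 and consecutive.
#' @inheritParams group_frames
#' @return list with `probs` (n x 3 matrix, NA rows where nothing was
#'   detected), `detected_fraction` (length-n numeric) and `intervals`
#'   (the [group_frames()] table).
#' @export
aggregate_stream1 <- function(frames, fps = 1, interval_s = 7) {
  stopifnot(identical(as.integer(frames$frame_index),
                      seq_len(nrow(frames)) - 1L))
  grp <- group_frames(nrow(frames), fps = fps, interval_s = interval_s)
  n <- nrow(grp)
  probs <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, c("standing", "lhu", "lhd")))
  frac <- numeric(n)
  for (i in seq_len(n)) {
    acc <- accumulate_stream1(frames[(grp$start[i] + 1):grp$end[i], ])
    frac[i] <- acc$detected_fraction
    if (!is.null(acc$probs)) probs[i, ] <- acc$probs
  }
  list(probs = probs, detected_fraction = frac, intervals = grp)
}
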