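#' Interval timeline of behavior states
#'
#' A `timeline` holds one night's sequence of behavior labels, one per
#' fixed-length interval (7 s by default, i.e. 7 frames at 1 fps), and
#' optionally the per-interval probability vectors the labels were decided
#' from. Probabilities may live on the three behavior states
#' (standing, lhu, lhd) or on all four states including absent.
#'
#' @param labels character or factor vector of behavior labels (may be
#'   length 0); see [behavior_levels()].
#' @param probs optional numeric matrix, one row per interval, 3 or 4
#'   columns; every row must be non-negative and sum to 1 (tolerance 1e-9).
#' @param interval_s interval length in seconds (default 7).
#' @param night_id free-text identifier for the night.
#' @param levels label vocabulary (the binary task uses
#'   [binary_levels()]).
#' @return object of class `timeline`: a list with elements `labels`
#'   (factor), `probs` (matrix or NULL), `interval_s`, `night_id`.
#' @examples
#' tl <- timeline(c("standing", "standing", "lhu"))
#' length(tl)
#' segment_phases(tl)
#' @export
timeline <- function(labels = character(), probs = NULL, interval_s = 7,
                     night_id = "night", levels = behavior_levels()) {
  labels <- as_behavior(labels, levels = levels)
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    storage.mode(probs) <- "double"
    if (nrow(probs) != length(labels)) {
      stop("probs has ", nrow(probs), " rows but there are ",
           length(labels), " labels")
    }
    check_prob_matrix(probs)
  }
  stopifnot(is.numeric(interval_s), length(interval_s) == 1, interval_s > 0)
  structure(
    list(labels = labels, probs = probs, interval_s = interval_s,
         night_id = as.character(night_id)),
    class = "timeline"
  )
}

check_prob_matrix <- function(p, tol = 1e-9) {
  if (!ncol(p) %in% c(3L, 4L)) {
    stop("probability matrix must have 3 or 4 columns, got ", ncol(p))
  }
  if (nrow(p) == 0) return(invisible(p))
  if (any(p < -tol)) stop("negative probability entries")
  s <- rowSums(p)
  if (any(abs(s - 1) > tol)) {
    stop("probability rows must sum to 1 (max deviation ",
         format(max(abs(s - 1))), ")")
  }
  invisible(p)
}

#' @export
length.timeline <- function(x) length(x$labels)

#' @export
print.timeline <- function(x, ...) {
  cat("<timeline> night ", x$night_id, ": ", length(x$labels),
      " intervals of ", x$interval_s, " s (",
      format(length(x$labels) * x$interval_s / 60, digits = 4),
      " min)\n", sep = "")
  if (length(x$labels)) {
    print(table(x$labels))
  }
  invisible(x)
}

#' Run-length segmentation of a timeline into behavior phases
#'
#' A *phase* is a maximal run of consecutive intervals carrying the same
#' label; phase counts and durations are the behavioral key figures reported
#' per night. Indices are 0-based and half-open: a phase covers intervals
#' `[start, end)`.
#'
#' @param timeline a [timeline()] (or a bare label vector).
#' @return data.frame with columns `label` (factor), `start`, `end`
#'   (0-based, half-open) and `length` (= end - start); zero rows for an
#'   empty timeline. Adjacent rows always differ in label and the rows tile
#'   `[0, n)` exactly.
#' @seealso [rebuild_timeline()], [key_figures()]
#' @export
segment_phases <- function(timeline) {
  labels <- if (inherits(timeline, "timeline")) timeline$labels else timeline
  levs <- levels(as_behavior(labels, levels = levels(labels) %||% behavior_levels()))
  if (length(labels) == 0) {
    return(data.frame(label = factor(character(), levels = levs),
                      start = integer(), end = integer(),
                      length = integer()))
  }
  r <- rle(as.character(labels))
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  data.frame(label = factor(r$values, levels = levs),
             start = as.integer(start), end = as.integer(end),
             length = as.integer(r$lengths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rebuild a timeline from phase segments
#'
#' Inverse of [segment_phases()]. Segments must tile `[0, n)` contiguously
#' (in order, no gaps, no overlaps); adjacent segments with equal labels are
#' legal and simply merge on re-segmentation.
#'
#' @param segments data.frame with columns `label`, `start`, `end` as
#'   produced by [segment_phases()].
#' @param interval_s interval length in seconds.
#' @param night_id night identifier for the rebuilt timeline.
#' @return a [timeline()].
#' @export
rebuild_timeline <- function(segments, interval_s = 7, night_id = "night") {
  stopifnot(all(c("label", "start", "end") %in% names(segments)))
  if (nrow(segments) == 0) {
    return(timeline(character(), interval_s = interval_s, night_id = night_id))
  }
  len <- segments$end - segments$start
  if (any(len < 1)) stop("segment with non-positive length")
  if (segments$start[1] != 0) stop("segments must start at interval 0")
  if (nrow(segments) > 1) {
    gaps <- segments$start[-1] != segments$end[-nrow(segments)]
    if (any(gaps)) stop("segments have gaps or overlaps")
  }
  labels <- rep(as.character(segments$label), times = len)
  timeline(labels, interval_s = interval_s, night_id = night_id,
           levels = levels(segments$label) %||% behavior_levels())
}

#' Read and write timeline CSV files
#'
#' The on-disk dialect has mandatory header
#' `interval_index,start_s,label` plus optional probability columns
#' `p_standing,p_lhu,p_lhd[,p_absent]`. Labels are serialized as
#' `standing|lhu|lhd|absent`.
#'
#' @param x a [timeline()].
#' @param path file path.
#' @return `read_timeline()` returns a [timeline()]; `write_timeline()`
#'   returns `path` invisibly.
#' @export
write_timeline <- function(x, path) {
  stopifnot(inherits(x, "timeline"))
  n <- length(x$labels)
  df <- data.frame(interval_index = seq_len(n) - 1L,
                   start_s = (seq_len(n) - 1L) * x$interval_s,
                   label = as.character(x$labels))
  if (!is.null(x$probs)) {
    pcols <- c("p_standing", "p_lhu", "p_lhd", "p_absent")[seq_len(ncol(x$probs))]
    pr <- as.data.frame(x$probs)
    names(pr) <- pcols
    df <- cbind(df, pr)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeline
#' @param interval_s interval length in seconds assumed for the file (the
#'   dialect stores `start_s`, from which it is cross-checked when n > 1).
#' @param night_id night identifier to attach.
#' @export
read_timeline <- function(path, interval_s = 7, night_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("interval_index", "start_s", "label")
  if (!all(need %in% names(df))) {
    stop("timeline CSV ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(df) > 1) {
    step <- diff(df$start_s)
    if (any(step != step[1])) stop("non-uniform start_s spacing in ", path)
    interval_s <- step[1]
  }
  pcols <- intersect(c("p_standing", "p_lhu", "p_lhd", "p_absent"), names(df))
  probs <- NULL
  if (length(pcols) >= 3) {
    probs <- as.matrix(df[, pcols, drop = FALSE])
    dimnames(probs) <- NULL
  }
  timeline(df$label, probs = probs, interval_s = interval_s,
           night_id = night_id)
}
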