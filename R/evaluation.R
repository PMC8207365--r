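check_pair <- function(truth, pred) {
  stopifnot(inherits(truth, "timeline"), inherits(pred, "timeline"))
  if (length(truth) != length(pred)) {
    stop("truth has ", length(truth), " intervals, prediction has ",
         length(pred))
  }
  invisible(length(truth))
}

#' Classification accuracy of an interval timeline
#'
#' Proportion of intervals whose predicted label equals the ground-truth
#' label. The absent state counts like any other label; use
#' `include_absent = FALSE` to restrict the comparison to intervals whose
#' ground truth is one of the three behavior states.
#'
#' @param truth,pred [timeline()] objects of equal length (n >= 1).
#' @param include_absent include intervals with true label absent
#'   (default TRUE).
#' @return fraction in [0, 1].
#' @export
accuracy <- function(truth, pred, include_absent = TRUE) {
  n <- check_pair(truth, pred)
  if (n == 0) stop("accuracy undefined for empty timelines")
  y <- as.character(truth$labels)
  yhat <- as.character(pred$labels)
  if (!include_absent) {
    keep <- y != "absent"
    if (!any(keep)) stop("no non-absent intervals to score")
    y <- y[keep]; yhat <- yhat[keep]
  }
  mean(y == yhat)
}

#' Per-class recall, precision and f-score
#'
#' For each class c, recall is the fraction of true-c intervals predicted
#' as c, precision the fraction of predicted-c intervals that are truly c,
#' and the f-score their harmonic mean. A class never predicted has
#' undefined precision, a class never true has undefined recall; such
#' entries are returned as NA with `defined = FALSE` rather than silently
#' zeroed, so macro-averages can exclude them explicitly.
#'
#' @inheritParams accuracy
#' @return list with `metrics` (data.frame: label, support, predicted, tp,
#'   recall, precision, f_score, defined) and `confusion` (4 x 4 matrix,
#'   truth in rows, prediction in columns).
#' @export
per_class_metrics <- function(truth, pred) {
  check_pair(truth, pred)
  levs <- levels(truth$labels)
  y <- factor(truth$labels, levels = levs)
  yhat <- factor(pred$labels, levels = levs)
  confusion <- table(truth = y, prediction = yhat)
  tp <- diag(confusion)
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  precision <- ifelse(predicted > 0, tp / predicted, NA_real_)
  f_score <- ifelse(!is.na(recall) & !is.na(precision),
                    ifelse(recall + precision > 0,
                           2 * recall * precision / (recall + precision), 0),
                    NA_real_)
  list(
    metrics = data.frame(
      label = factor(levs, levels = levs),
      support = as.integer(support),
      predicted = as.integer(predicted),
      tp = as.integer(tp),
      recall = as.numeric(recall),
      precision = as.numeric(precision),
      f_score = as.numeric(f_score),
      defined = !is.na(recall) & !is.na(precision),
      row.names = NULL
    ),
    confusion = unclass(confusion)
  )
}

#' Collapse the ethogram to the binary standing/lying task
#'
#' Maps lhu and lhd to a single lying state; standing and absent pass
#' through. Because the collapse can only turn lhu/lhd confusions into
#' agreements, binary accuracy is never below the multiclass accuracy for
#' the same prediction.
#'
#' @param timeline a [timeline()] over the 4-state vocabulary.
#' @return [timeline()] over `c("standing", "lying", "absent")`.
#' @export
binary_collapse <- function(timeline) {
  stopifnot(inherits(timeline, "timeline"))
  map <- c(standing = "standing", lhu = "lying", lhd = "lying",
           absent = "absent")
  timeline(unname(map[as.character(timeline$labels)]),
           interval_s = timeline$interval_s, night_id = timeline$night_id,
           levels = binary_levels())
}

#' Binary-task accuracy
#'
#' Accuracy after [binary_collapse()] of both timelines. Intervals where
#' either sequence says absent can optionally be excluded so the score
#' reflects the pure standing-vs-lying decision.
#'
#' @inheritParams accuracy
#' @param drop_absent exclude intervals absent in either timeline
#'   (default FALSE).
#' @return fraction in [0, 1].
#' @export
binary_accuracy <- function(truth, pred, drop_absent = FALSE) {
  check_pair(truth, pred)
  y <- binary_collapse(truth)$labels
  yhat <- binary_collapse(pred)$labels
  if (drop_absent) {
    keep <- y != "absent" & yhat != "absent"
    if (!any(keep)) stop("no intervals left after dropping absent")
    y <- y[keep]; yhat <- yhat[keep]
  }
  if (length(y) == 0) stop("accuracy undefined for empty timelines")
  mean(as.character(y) == as.character(yhat))
}

#' Behavioral key figures of one night
#'
#' The two quantities behavioral studies read off a night: the number of
#' phases (maximal runs) of each state and its total duration in minutes.
#' Durations over all states always sum to the night length.
#'
#' @param timeline a [timeline()].
#' @param night_id identifier recorded in the summary (defaults to the
#'   timeline's).
#' @return object of class `night_summary`: data.frame with columns
#'   `label`, `phase_count`, `duration_min` (one row per vocabulary state)
#'   and attributes `night_id`, `n_intervals`, `interval_s`.
#' @export
key_figures <- function(timeline, night_id = timeline$night_id) {
  stopifnot(inherits(timeline, "timeline"))
  levs <- levels(timeline$labels)
  segs <- segment_phases(timeline)
  phase_count <- table(factor(segs$label, levels = levs))
  n_by_label <- table(factor(timeline$labels, levels = levs))
  out <- data.frame(
    label = factor(levs, levels = levs),
    phase_count = as.integer(phase_count),
    duration_min = as.numeric(n_by_label) * timeline$interval_s / 60,
    row.names = NULL
  )
  structure(out, class = c("night_summary", "data.frame"),
            night_id = night_id, n_intervals = length(timeline),
            interval_s = timeline$interval_s)
}

#' Across-night summary of key figures
#'
#' Per-state mean and standard error of the mean (SEM = sample sd / sqrt(n),
#' 0 for a single night) of phase counts and durations over a set of
#' nights, the form in which nightly activity budgets are reported.
#'
#' @param summaries non-empty list of `night_summary` objects
#'   ([key_figures()]).
#' @return data.frame with columns `label`, `n_nights`, `phase_count_mean`,
#'   `phase_count_sem`, `duration_min_mean`, `duration_min_sem`.
#' @export
summarize_nights <- function(summaries) {
  if (length(summaries) == 0) stop("need at least one night")
  stopifnot(all(vapply(summaries, inherits, logical(1), "night_summary")))
  labs <- as.character(summaries[[1]]$label)
  same <- vapply(summaries, function(s) identical(as.character(s$label), labs),
                 logical(1))
  if (!all(same)) stop("night summaries use different vocabularies")
  n <- length(summaries)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  pc <- sapply(summaries, function(s) s$phase_count)
  du <- sapply(summaries, function(s) s$duration_min)
  pc <- matrix(pc, nrow = length(labs))
  du <- matrix(du, nrow = length(labs))
  data.frame(
    label = factor(labs, levels = labs),
    n_nights = n,
    phase_count_mean = rowMeans(pc),
    phase_count_sem = apply(pc, 1, sem),
    duration_min_mean = rowMeans(du),
    duration_min_sem = apply(du, 1, sem),
    row.names = NULL
  )
}

#' Write an evaluation report
#'
#' Per-class metrics go to CSV; night summaries and their across-night
#' means with SEMs go to JSON.
#'
#' @param metrics result of [per_class_metrics()].
#' @param summaries list of [key_figures()] results (may be empty).
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(metrics, summaries, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "per_class_metrics.csv")
  utils::write.csv(metrics$metrics, csv, row.names = FALSE)
  js <- file.path(dir, "night_summaries.json")
  payload <- list(
    nights = lapply(summaries, function(s) {
      list(night_id = attr(s, "night_id"),
           n_intervals = attr(s, "n_intervals"),
           figures = as.data.frame(s))
    }),
    summary = if (length(summaries)) summarize_nights(summaries) else NULL
  )
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(metrics = csv, summaries = js))
}
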