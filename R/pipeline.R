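#' Smooth one night of interval predictions
#'
#' The temporal half of the prediction pipeline: fuse the two classifier
#' streams, apply the centered rolling average, inject the absent state
#' (when working on 3-state behavior probabilities plus detected fractions),
#' decide a label per interval, and run the transition-rule postprocessor.
#'
#' Streams may be n x 4 matrices (absence already included, as produced by
#' the synthetic noise model) or n x 3 behavior matrices with NA rows on
#' intervals where nothing was detected; in the latter case
#' `detected_fraction` is required and absence is injected after the
#' rolling average. Fusion averages the streams where both are defined and
#' falls back to the defined one otherwise; the rolling window likewise
#' averages over the defined rows it covers.
#'
#' @param stream1 n x 3 or n x 4 probability matrix (rows may be NA for
#'   3-state input).
#' @param stream2 optional second stream, same shape as `stream1`.
#' @param detected_fraction length-n vector of per-interval detected-frame
#'   fractions; required iff the streams have 3 columns.
#' @param window rolling-average window (odd, default 3).
#' @param rules transition rules (default [default_rules()]).
#' @param max_passes rule-engine pass limit (default 50).
#' @param interval_s,night_id timeline metadata.
#' @return list with `raw` (decided [timeline()] before rules, probabilities
#'   attached) and `smoothed` (after [apply_rules()]).
#' @export
smooth_night <- function(stream1, stream2 = NULL, detected_fraction = NULL,
                         window = 3, rules = default_rules(),
                         max_passes = 50, interval_s = 7,
                         night_id = "night") {
  stopifnot(is.matrix(stream1))
  n <- nrow(stream1)
  d <- ncol(stream1)
  stopifnot(d %in% c(3L, 4L))
  if (!is.null(stream2)) {
    stopifnot(is.matrix(stream2), identical(dim(stream2), dim(stream1)))
  }
  fused <- fuse_streams_na(stream1, stream2)
  rolled <- rolling_average_na(fused, window)
  if (d == 3L) {
    if (is.null(detected_fraction) || length(detected_fraction) != n) {
      stop("detected_fraction (length n) required for 3-state streams")
    }
    probs4 <- matrix(0, n, 4,
                     dimnames = list(NULL, behavior_levels()))
    for (i in seq_len(n)) {
      bp <- if (detected_fraction[i] > 0) rolled[i, ] else NULL
      probs4[i, ] <- inject_absence(bp, detected_fraction[i])
    }
  } else {
    if (!is.null(detected_fraction)) {
      stop("detected_fraction only applies to 3-state streams")
    }
    if (anyNA(rolled)) stop("4-state streams may not contain NA rows")
    probs4 <- rolled
  }
  raw_labels <- decide(probs4)
  raw <- timeline(as.character(raw_labels), probs = probs4,
                  interval_s = interval_s, night_id = night_id)
  list(raw = raw,
       smoothed = apply_rules(raw, rules = rules, max_passes = max_passes))
}

# Fusion tolerating NA rows: mean where both defined, fallback otherwise.
fuse_streams_na <- function(p1, p2) {
  if (is.null(p2)) return(p1)
  ok1 <- !apply(p1, 1, anyNA)
  ok2 <- !apply(p2, 1, anyNA)
  out <- matrix(NA_real_, nrow(p1), ncol(p1), dimnames = dimnames(p1))
  both <- ok1 & ok2
  if (any(both)) {
    out[both, ] <- fuse_streams(p1[both, , drop = FALSE],
                                p2[both, , drop = FALSE])
  }
  out[ok1 & !ok2, ] <- p1[ok1 & !ok2, ]
  out[ok2 & !ok1, ] <- p2[ok2 & !ok1, ]
  out
}

# Rolling average skipping NA rows inside the (truncated) window; a row
# whose whole window is undefined stays NA.
rolling_average_na <- function(probs, window) {
  if (!anyNA(probs)) return(rolling_average(probs, window))
  stopifnot(window >= 1, window %% 2 == 1)
  n <- nrow(probs)
  ok <- !apply(probs, 1, anyNA)
  z <- probs
  z[!ok, ] <- 0
  half <- (window - 1) / 2
  cs <- rbind(0, apply(z, 2, cumsum))
  ck <- c(0, cumsum(ok))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- ck[hi + 1] - ck[lo]
  out <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / cnt
  out[cnt == 0, ] <- NA_real_
  dimnames(out) <- dimnames(probs)
  out
}

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with its standard default:
#' 7-second intervals at 1 fps, 300 px cut-outs and 150 px mosaic tiles,
#' 97% detection confidence, stream fusion with a width-3 rolling average,
#' and the default transition-rule set. Unknown keys in a YAML config file
#' are rejected.
#'
#' @param fps frame rate of the source video (default 1).
#' @param interval_seconds interval length (default 7).
#' @param encoding_frame_offsets offsets of the multiframe-encoding frames
#'   within an interval (default 0, 2, 4, 6).
#' @param mosaic_layout tile order of the 2 x 2 mosaic; only "row-major" is
#'   implemented (recorded so trained models stay compatible).
#' @param cutout_px,tile_px stream-1 input side and mosaic tile side.
#' @param conf_threshold detection confidence threshold (default 0.97).
#' @param window rolling-average window (odd; default 3).
#' @param rules_file optional YAML rule file; `NULL` = default rule set.
#' @param max_passes rule-engine pass limit (default 50).
#' @param seed integer seed recorded in the run manifest.
#' @param frames_csv,stream1_csv,stream2_csv,truth_csv,out_dir input/output
#'   paths (see [run_pipeline()]).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(fps = 1, interval_seconds = 7,
                            encoding_frame_offsets = c(0, 2, 4, 6),
                            mosaic_layout = "row-major",
                            cutout_px = 300, tile_px = 150,
                            conf_threshold = 0.97, window = 3,
                            rules_file = NULL, max_passes = 50, seed = 1,
                            frames_csv = NULL, stream1_csv = NULL,
                            stream2_csv = NULL, truth_csv = NULL,
                            out_dir = NULL) {
  stopifnot(fps > 0, interval_seconds > 0,
            all(encoding_frame_offsets >= 0),
            all(encoding_frame_offsets < fps * interval_seconds),
            identical(mosaic_layout, "row-major"),
            cutout_px > 0, tile_px > 0,
            conf_threshold >= 0, conf_threshold <= 1,
            window >= 1, window %% 2 == 1, max_passes >= 1)
  structure(list(fps = fps, interval_seconds = interval_seconds,
                 encoding_frame_offsets = as.integer(encoding_frame_offsets),
                 mosaic_layout = mosaic_layout, cutout_px = cutout_px,
                 tile_px = tile_px, conf_threshold = conf_threshold,
                 window = window, rules_file = rules_file,
                 max_passes = max_passes, seed = as.integer(seed),
                 frames_csv = frames_csv, stream1_csv = stream1_csv,
                 stream2_csv = stream2_csv, truth_csv = truth_csv,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys mirror the arguments of
#'   `pipeline_config()`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Run the full prediction pipeline on one night
#'
#' Executes detection filtering / interval aggregation (when per-frame
#' records are supplied), stream fusion, rolling average, absence
#' injection, label decision and rule-based postprocessing, and writes the
#' artifacts: `raw.csv` and `smoothed.csv` (timeline CSVs), an evaluation
#' report against the ground truth when `truth_csv` is given, and a
#' `manifest.json` recording config, seed and package version.
#'
#' Inputs: either `frames_csv` (per-frame detection/probability records,
#' stream 1) optionally plus `stream2_csv` (3-state interval timeline CSV),
#' or `stream1_csv` (+ optional `stream2_csv`) as interval timeline CSVs
#' with probability columns.
#'
#' @param config a [pipeline_config()] with paths set.
#' @return invisibly, a list with the `raw` and `smoothed` timelines and
#'   the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rules <- if (is.null(config$rules_file)) default_rules() else
    read_rules_yaml(config$rules_file)

  frac <- NULL
  if (!is.null(config$frames_csv)) {
    frames <- read_frame_records(config$frames_csv)
    agg <- aggregate_stream1(frames, fps = config$fps,
                             interval_s = config$interval_seconds)
    s1 <- agg$probs
    frac <- agg$detected_fraction
    night_id <- basename(config$frames_csv)
  } else if (!is.null(config$stream1_csv)) {
    tl1 <- read_timeline(config$stream1_csv,
                         interval_s = config$interval_seconds)
    if (is.null(tl1$probs)) stop("stream1 CSV has no probability columns")
    s1 <- tl1$probs
    night_id <- tl1$night_id
  } else {
    stop("config must set frames_csv or stream1_csv")
  }
  s2 <- NULL
  if (!is.null(config$stream2_csv)) {
    tl2 <- read_timeline(config$stream2_csv,
                         interval_s = config$interval_seconds)
    if (is.null(tl2$probs)) stop("stream2 CSV has no probability columns")
    s2 <- tl2$probs
    if (ncol(s2) != ncol(s1)) {
      stop("stream1 and stream2 must carry the same number of states")
    }
    if (nrow(s2) != nrow(s1)) stop("stream lengths differ")
  }

  res <- smooth_night(s1, s2, detected_fraction = frac,
                      window = config$window, rules = rules,
                      max_passes = config$max_passes,
                      interval_s = config$interval_seconds,
                      night_id = night_id)

  raw_path <- file.path(config$out_dir, "raw.csv")
  smooth_path <- file.path(config$out_dir, "smoothed.csv")
  write_timeline(res$raw, raw_path)
  write_timeline(res$smoothed, smooth_path)

  report <- NULL
  if (!is.null(config$truth_csv)) {
    truth <- read_timeline(config$truth_csv,
                           interval_s = config$interval_seconds)
    m <- per_class_metrics(truth, res$smoothed)
    write_report(m, list(key_figures(res$smoothed), key_figures(truth)),
                 file.path(config$out_dir, "report"))
    report <- list(
      accuracy = accuracy(truth, res$smoothed),
      accuracy_raw = accuracy(truth, res$raw),
      binary_accuracy = binary_accuracy(truth, res$smoothed)
    )
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report", "accuracy.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "ethosmooth",
    version = as.character(utils::packageVersion("ethosmooth")),
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(raw = res$raw, smoothed = res$smoothed, report = report,
                 paths = c(raw = raw_path, smoothed = smooth_path)))
}
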