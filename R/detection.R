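#' Bounding boxes and detections
#'
#' Boxes use 0-based, half-open pixel coordinates: the box covers the pixel
#' set `[x0, x1) x [y0, y1)`, so `area = (x1 - x0) * (y1 - y0)`. COCO-style
#' `[x, y, width, height]` boxes are converted on read (see
#' [read_detections_coco()]).
#'
#' @param x0,y0,x1,y1 pixel coordinates with `x1 > x0`, `y1 > y0`.
#' @return `bbox()` returns an object of class `bbox` (named numeric
#'   vector); `detection()` wraps a box with a confidence score and frame id.
#' @export
bbox <- function(x0, y0, x1, y1) {
  v <- c(x0 = as.numeric(x0), y0 = as.numeric(y0),
         x1 = as.numeric(x1), y1 = as.numeric(y1))
  if (anyNA(v)) stop("bbox coordinates must be numeric")
  if (v["x1"] <= v["x0"] || v["y1"] <= v["y0"]) {
    stop("degenerate bbox: need x1 > x0 and y1 > y0")
  }
  structure(v, class = "bbox")
}

#' @rdname bbox
#' @param box a [bbox()].
#' @param confidence detector confidence in [0, 1].
#' @param frame_id free-text frame identifier.
#' @export
detection <- function(box, confidence, frame_id = "") {
  stopifnot(inherits(box, "bbox"))
  confidence <- as.numeric(confidence)
  if (is.na(confidence) || confidence < 0 || confidence > 1) {
    stop("confidence must be in [0, 1]")
  }
  structure(list(box = box, confidence = confidence,
                 frame_id = as.character(frame_id)),
            class = "detection")
}

box_area <- function(b) unname((b["x1"] - b["x0"]) * (b["y1"] - b["y0"]))

#' Keep at most one confident detection per frame
#'
#' Detector postfilter: candidate boxes with confidence below the threshold
#' (default 97%) are discarded, and of the survivors only the single
#' highest-confidence box is kept -- at most one animal per frame. A frame
#' with no surviving box is a candidate for the absent state.
#'
#' @param candidates list of [detection()] objects for one frame.
#' @param conf_threshold minimum confidence to keep a box (default 0.97).
#' @return the winning [detection()], or `NULL` if no candidate survives.
#'   Ties in confidence are broken by candidate order (first wins).
#' @export
filter_detections <- function(candidates, conf_threshold = 0.97) {
  if (length(candidates) == 0) return(NULL)
  conf <- vapply(candidates, function(d) {
    stopifnot(inherits(d, "detection"))
    d$confidence
  }, numeric(1))
  keep <- conf >= conf_threshold
  if (!any(keep)) return(NULL)
  candidates[keep][[which.max(conf[keep])]]
}

#' Intersection over union of two boxes
#'
#' @param a,b [bbox()] objects.
#' @return IoU in [0, 1]: ratio of intersection area to union area.
#' @export
iou <- function(a, b) {
  stopifnot(inherits(a, "bbox"), inherits(b, "bbox"))
  iw <- min(a["x1"], b["x1"]) - max(a["x0"], b["x0"])
  ih <- min(a["y1"], b["y1"]) - max(a["y0"], b["y0"])
  inter <- max(0, iw) * max(0, ih)
  un <- box_area(a) + box_area(b) - inter
  unname(inter / un)
}

#' Average precision of a detector at an IoU threshold
#'
#' `AP@t` is the percentage of predicted boxes whose IoU with the
#' ground-truth box of their frame is at least `t`%. The denominator counts
#' predicted boxes only; a prediction on a frame without a ground-truth box
#' scores IoU 0 and therefore fails every threshold. Frames where the animal
#' is truly absent and nothing was predicted (correct rejections) do not
#' enter the ratio; their count is returned as an attribute.
#'
#' @param predictions named list, one entry per frame id: a [detection()]
#'   (or [bbox()]) or `NULL` for "nothing predicted".
#' @param truths named list keyed by frame id: a [bbox()] or `NULL` for
#'   "animal absent".
#' @param t IoU threshold as a percentage in (0, 100].
#' @return AP as a percentage in [0, 100], with attribute
#'   `correct_rejections` = number of frames absent in both inputs.
#'   Errors if there are zero predicted boxes (metric undefined).
#' @export
average_precision_at <- function(predictions, truths, t) {
  stopifnot(is.numeric(t), length(t) == 1, t > 0, t <= 100)
  frames <- union(names(predictions), names(truths))
  get_box <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "detection")) return(x$box)
    if (inherits(x, "bbox")) return(x)
    stop("expected detection, bbox or NULL")
  }
  hits <- 0L
  n_pred <- 0L
  rejections <- 0L
  for (f in frames) {
    p <- get_box(predictions[[f]])
    g <- get_box(truths[[f]])
    if (is.null(p)) {
      if (is.null(g)) rejections <- rejections + 1L
      next
    }
    n_pred <- n_pred + 1L
    if (!is.null(g) && iou(p, g) >= t / 100) hits <- hits + 1L
  }
  if (n_pred == 0L) stop("AP undefined: no predicted boxes")
  structure(100 * hits / n_pred, correct_rejections = rejections)
}

#' Read and write detections as COCO-style JSON
#'
#' The JSON carries an `images` array (`id`, `file_name`, `width`,
#' `height`) and an `annotations` array (`image_id`, `bbox` as
#' `[x, y, width, height]`, optional `score`). On read, COCO boxes are
#' converted to the half-open `(x0, y0, x1, y1)` convention.
#'
#' @param path JSON file path.
#' @return `read_detections_coco()` returns a named list keyed by
#'   `file_name` (falling back to image id); each element is a
#'   [detection()] (score defaults to 1) or `NULL` for images without
#'   annotation.
#' @export
read_detections_coco <- function(path) {
  j <- jsonlite::read_json(path)
  imgs <- j$images %||% list()
  anns <- j$annotations %||% list()
  key_of <- function(img) as.character(img$file_name %||% img$id)
  keys <- vapply(imgs, key_of, character(1))
  ids <- vapply(imgs, function(im) as.character(im$id), character(1))
  out <- stats::setNames(vector("list", length(keys)), keys)
  for (a in anns) {
    id <- as.character(a$image_id)
    k <- keys[match(id, ids)]
    if (is.na(k)) stop("annotation references unknown image_id ", id)
    bb <- as.numeric(unlist(a$bbox))
    if (length(bb) != 4) stop("bbox must have 4 entries [x, y, w, h]")
    out[[k]] <- detection(
      bbox(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4]),
      confidence = as.numeric(a$score %||% 1),
      frame_id = k
    )
  }
  out
}

#' @rdname read_detections_coco
#' @param detections named list of [detection()] / `NULL` as returned by
#'   [read_detections_coco()].
#' @param width,height nominal image size recorded in the `images` array.
#' @export
write_detections_coco <- function(detections, path, width = NA, height = NA) {
  keys <- names(detections)
  stopifnot(!is.null(keys))
  images <- lapply(seq_along(keys), function(i) {
    list(id = i, file_name = keys[i], width = width, height = height)
  })
  annotations <- list()
  aid <- 0L
  for (i in seq_along(keys)) {
    d <- detections[[i]]
    if (is.null(d)) next
    aid <- aid + 1L
    b <- d$box
    annotations[[aid]] <- list(
      id = aid, image_id = i, category_id = 1,
      bbox = c(b[["x0"]], b[["y0"]],
               b[["x1"]] - b[["x0"]], b[["y1"]] - b[["y0"]]),
      score = d$confidence
    )
  }
  jsonlite::write_json(
    list(images = images, annotations = annotations,
         categories = list(list(id = 1, name = "individual"))),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
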