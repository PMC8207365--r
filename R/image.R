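# Grayscale images are numeric matrices with values in [0, 1], indexed
# [row = y, col = x]; 3-D arrays (h x w x channels) are processed per
# channel. Frame files are plain-text PGM (P2) so fixtures stay text-only;
# PNG is supported when the png package is installed.

#' Read and write plain PGM (P2) images
#'
#' @param path file path.
#' @param img numeric matrix in [0, 1].
#' @param maxval integer gray-level ceiling used on disk (default 255).
#' @return `read_pgm()` returns a numeric matrix in [0, 1].
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("not a plain PGM (P2) file: ", path)
  v <- as.numeric(tok[-1])
  w <- v[1]; h <- v[2]; maxval <- v[3]
  px <- v[-(1:3)]
  if (length(px) != w * h) stop("PGM pixel count mismatch in ", path)
  matrix(px / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  stopifnot(is.matrix(img))
  px <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  writeLines(apply(px, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read/write PNG frames (requires the png package)
#' @noRd
read_frame_image <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading ", path, " requires the png package; use PGM otherwise")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

apply_channels <- function(img, f) {
  if (is.matrix(img)) return(f(img))
  if (length(dim(img)) == 3) {
    out <- vapply(seq_len(dim(img)[3]), function(k) f(img[, , k]),
                  f(img[, , 1]))
    return(out)
  }
  stop("expected a 2-D matrix or 3-D array")
}

#' Bilinear resize of an image
#'
#' Resamples with bilinear interpolation, treating pixels as cell centers
#' (the mapping used by common image libraries). Resizing to the input size
#' returns the input unchanged.
#'
#' @param img numeric matrix or 3-D array.
#' @param height,width output size in pixels.
#' @return resized image of the same kind as the input.
#' @export
resize_bilinear <- function(img, height, width) {
  apply_channels(img, function(m) resize_bilinear_2d(m, height, width))
}

resize_bilinear_2d <- function(m, height, width) {
  h0 <- nrow(m); w0 <- ncol(m)
  if (h0 == height && w0 == width) return(m)
  # source coordinates of output pixel centers
  sy <- (seq_len(height) - 0.5) * h0 / height - 0.5
  sx <- (seq_len(width) - 0.5) * w0 / width - 0.5
  sample_bilinear(m, outer(sy, rep(1, width)), outer(rep(1, height), sx))
}

# Bilinear lookup at fractional (y, x) matrices; coordinates clamped to the
# image so border pixels replicate.
sample_bilinear <- function(m, ym, xm) {
  h <- nrow(m); w <- ncol(m)
  ym <- pmin(pmax(ym, 0), h - 1)
  xm <- pmin(pmax(xm, 0), w - 1)
  y0 <- floor(ym); x0 <- floor(xm)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- ym - y0; fx <- xm - x0
  idx <- function(y, x) m[cbind(as.vector(y) + 1, as.vector(x) + 1)]
  v <- (1 - fy) * (1 - fx) * idx(y0, x0) +
       (1 - fy) * fx       * idx(y0, x1) +
       fy       * (1 - fx) * idx(y1, x0) +
       fy       * fx       * idx(y1, x1)
  matrix(v, nrow = nrow(ym), ncol = ncol(ym))
}

#' Cut out a detection box and resize it to a square
#'
#' Extracts the box region from a frame (clipping the box to the frame
#' bounds first) and resizes it to `side` x `side` pixels with bilinear
#' interpolation. Aspect ratio is not preserved: the network input is a
#' fixed square.
#'
#' @param frame numeric matrix or 3-D array.
#' @param box a [bbox()] in pixel coordinates of `frame`.
#' @param side output side length in pixels (default 300).
#' @return `side` x `side` image.
#' @export
cutout <- function(frame, box, side = 300) {
  stopifnot(inherits(box, "bbox"))
  h <- dim(frame)[1]; w <- dim(frame)[2]
  x0 <- max(0, floor(box[["x0"]])); y0 <- max(0, floor(box[["y0"]]))
  x1 <- min(w, ceiling(box[["x1"]])); y1 <- min(h, ceiling(box[["y1"]]))
  if (x1 <= x0 || y1 <= y0) stop("box does not intersect the frame")
  region <- if (is.matrix(frame)) {
    frame[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  } else {
    frame[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  }
  resize_bilinear(region, side, side)
}

#' Combine four interval frames into one mosaic input
#'
#' The multiframe encoding of an interval: four cut-outs, each
#' `tile_side` x `tile_side` (default 150), placed on a 2 x 2 grid in
#' row-major temporal order (t0 top-left, t1 top-right, t2 bottom-left,
#' t3 bottom-right), giving a single `2 * tile_side` square input with the
#' same size as the single-frame stream.
#'
#' @param cutouts list of exactly 4 square matrices of identical size.
#' @param tile_side required tile side length (default 150).
#' @return `2 * tile_side` square matrix.
#' @export
mosaic_multiframe <- function(cutouts, tile_side = 150) {
  if (length(cutouts) != 4) stop("need exactly 4 cut-outs, got ",
                                 length(cutouts))
  ok <- vapply(cutouts, function(t) {
    is.matrix(t) && all(dim(t) == c(tile_side, tile_side))
  }, logical(1))
  if (!all(ok)) stop("every tile must be a ", tile_side, "x", tile_side,
                     " matrix")
  rbind(cbind(cutouts[[1]], cutouts[[2]]),
        cbind(cutouts[[3]], cutouts[[4]]))
}

#' Extract the four quadrants of a mosaic
#'
#' Inverse of [mosaic_multiframe()]; mainly used to verify round-tripping.
#' @param mosaic square matrix with even side length.
#' @return list of 4 tiles in row-major order.
#' @export
mosaic_quadrants <- function(mosaic) {
  s <- nrow(mosaic) / 2
  stopifnot(s == floor(s), ncol(mosaic) == nrow(mosaic))
  list(mosaic[1:s, 1:s], mosaic[1:s, (s + 1):(2 * s)],
       mosaic[(s + 1):(2 * s), 1:s], mosaic[(s + 1):(2 * s), (s + 1):(2 * s)])
}

#' Training-time augmentation
#'
#' Applies, in order: random center cropping by 0--16 px, random horizontal
#' flipping, random Gaussian blurring, brightness and contrast jitter, and
#' random rotation by -25 to +25 degrees. Parameters are drawn from a
#' seeded generator, so the same seed gives byte-identical output. The
#' deterministic worker [augment_transform()] is exported so individual
#' transforms can be forced (e.g. identity, flip-only) in tests.
#'
#' @param img square numeric matrix in [0, 1].
#' @param seed integer seed for the parameter draws.
#' @param params list of ranges as produced by [augment_params()].
#' @return augmented image with the same dimensions as the input.
#' @export
augment <- function(img, seed, params = augment_params()) {
  draws <- with_local_seed(seed, list(
    crop_px = sample.int(params$crop_px_max + 1L, 1L) - 1L,
    flip = stats::runif(1) < params$flip_prob,
    blur_sigma = stats::runif(1, params$blur_sigma[1], params$blur_sigma[2]),
    brightness = stats::runif(1, params$brightness[1], params$brightness[2]),
    contrast = stats::runif(1, params$contrast[1], params$contrast[2]),
    rotation_deg = stats::runif(1, params$rotation_deg[1],
                                params$rotation_deg[2])
  ))
  do.call(augment_transform, c(list(img = img), draws))
}

#' @rdname augment
#' @param crop_px_max maximum center-crop margin in pixels (default 16).
#' @param flip_prob probability of a horizontal flip (default 0.5).
#' @param blur_sigma,brightness,contrast,rotation_deg numeric ranges for the
#'   respective draws. Brightness/contrast default to +/-20% and blur sigma
#'   to [0, 1.5]; the crop, flip and rotation ranges are fixed by the
#'   training recipe.
#' @export
augment_params <- function(crop_px_max = 16L, flip_prob = 0.5,
                           blur_sigma = c(0, 1.5),
                           brightness = c(0.8, 1.2),
                           contrast = c(0.8, 1.2),
                           rotation_deg = c(-25, 25)) {
  list(crop_px_max = as.integer(crop_px_max), flip_prob = flip_prob,
       blur_sigma = blur_sigma, brightness = brightness,
       contrast = contrast, rotation_deg = rotation_deg)
}

#' @rdname augment
#' @param crop_px center-crop margin actually applied (0 = no crop).
#' @param flip logical; mirror columns.
#' @export
augment_transform <- function(img, crop_px = 0L, flip = FALSE,
                              blur_sigma = 0, brightness = 1, contrast = 1,
                              rotation_deg = 0) {
  stopifnot(is.matrix(img), nrow(img) == ncol(img))
  side <- nrow(img)
  if (crop_px > 0) {
    if (2 * crop_px >= side) stop("crop margin too large for image")
    img <- img[(crop_px + 1):(side - crop_px),
               (crop_px + 1):(side - crop_px)]
    img <- resize_bilinear(img, side, side)
  }
  if (isTRUE(flip)) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  if (blur_sigma > 0) img <- gaussian_blur(img, blur_sigma)
  if (brightness != 1 || contrast != 1) {
    img <- pmin(pmax((img - 0.5) * contrast + 0.5, 0), 1) * brightness
    img <- pmin(pmax(img, 0), 1)
  }
  if (rotation_deg != 0) img <- rotate_bilinear(img, rotation_deg)
  img
}

#' Separable Gaussian blur (kernel radius 3 sigma, edge-replicated)
#' @noRd
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) {
    # convolve along rows (y) with edge replication
    h <- nrow(m)
    out <- matrix(0, h, ncol(m))
    for (j in -r:r) {
      rows <- pmin(pmax(seq_len(h) + j, 1L), h)
      out <- out + k[j + r + 1] * m[rows, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

#' Rotate about the image center with bilinear resampling, zero fill
#' @noRd
rotate_bilinear <- function(img, degrees) {
  h <- nrow(img); w <- ncol(img)
  th <- degrees * pi / 180
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  yy <- matrix(seq_len(h) - 1, h, w) - cy
  xx <- matrix(seq_len(w) - 1, h, w, byrow = TRUE) - cx
  # inverse mapping: output pixel pulls from source rotated by -theta
  sy <- cy - xx * sin(th) + yy * cos(th)
  sx <- cx + xx * cos(th) + yy * sin(th)
  inside <- sy >= 0 & sy <= h - 1 & sx >= 0 & sx <= w - 1
  out <- sample_bilinear(img, pmin(pmax(sy, 0), h - 1),
                         pmin(pmax(sx, 0), w - 1))
  out[!inside] <- 0
  out
}

# Run expr with a private RNG state; the caller's .Random.seed is restored.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
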