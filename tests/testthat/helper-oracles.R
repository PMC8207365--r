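# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: the rule engine below walks the raw label
# array with explicit index loops (no rle), the IoU oracle rasterizes boxes
# onto a pixel grid, and the metric oracle counts with nested loops.

LEVS <- c("standing", "lhu", "lhd", "absent")

# --- naive transition-rule engine on the raw label array -------------------
# Pass semantics: walk runs left to right; a matching interior run is
# overwritten with the previous label and the walk resumes after the merged
# block; passes repeat until one changes nothing or max_passes is hit.
naive_apply_rules <- function(labels, rules, max_passes = 50) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n == 0) return(labels)
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    s <- 1L
    # advance past the first run (never replaced: no previous phase)
    while (s < n && labels[s + 1L] == labels[s]) s <- s + 1L
    s <- s + 1L
    while (s <= n) {
      e <- s
      while (e < n && labels[e + 1L] == labels[e]) e <- e + 1L
      if (e == n) break  # last run: no next phase
      len <- e - s + 1L
      prev <- labels[s - 1L]
      nxt <- labels[e + 1L]
      cur <- labels[s]
      replaced <- FALSE
      for (r in rules) {
        if (cur == r$current && len < r$min_intervals &&
            prev %in% r$prev && nxt %in% r$next_) {
          labels[s:e] <- prev
          changed <- TRUE
          replaced <- TRUE
          break
        }
      }
      if (replaced) {
        # skip the merged block: next examined run starts at the first
        # position after e whose label differs from prev
        s <- e + 1L
        while (s <= n && labels[s] == prev) s <- s + 1L
      } else {
        s <- e + 1L
      }
    }
    if (!changed) break
  }
  labels
}

# --- pixel-rasterization IoU oracle ----------------------------------------
# Boxes with integer coordinates on a small grid: paint each box onto a
# logical raster and count cells.
raster_iou <- function(a, b) {
  xmax <- max(a[["x1"]], b[["x1"]])
  ymax <- max(a[["y1"]], b[["y1"]])
  paint <- function(bx) {
    g <- matrix(FALSE, ymax, xmax)
    g[(bx[["y0"]] + 1):bx[["y1"]], (bx[["x0"]] + 1):bx[["x1"]]] <- TRUE
    g
  }
  ga <- paint(a); gb <- paint(b)
  sum(ga & gb) / sum(ga | gb)
}

random_int_box <- function(max_coord = 20) {
  repeat {
    x <- sort(sample.int(max_coord + 1, 2) - 1)
    y <- sort(sample.int(max_coord + 1, 2) - 1)
    if (x[2] > x[1] && y[2] > y[1]) return(bbox(x[1], y[1], x[2], y[2]))
  }
}

# --- brute-force counting metrics ------------------------------------------
brute_metrics <- function(y, yhat, levs = LEVS) {
  y <- as.character(y); yhat <- as.character(yhat)
  acc <- sum(y == yhat) / length(y)
  out <- list(accuracy = acc, recall = c(), precision = c(), tp = c())
  conf <- matrix(0L, length(levs), length(levs),
                 dimnames = list(levs, levs))
  for (i in seq_along(y)) conf[y[i], yhat[i]] <- conf[y[i], yhat[i]] + 1L
  for (c in levs) {
    tp <- 0L; nt <- 0L; np <- 0L
    for (i in seq_along(y)) {
      if (y[i] == c && yhat[i] == c) tp <- tp + 1L
      if (y[i] == c) nt <- nt + 1L
      if (yhat[i] == c) np <- np + 1L
    }
    out$tp[c] <- tp
    out$recall[c] <- if (nt > 0) tp / nt else NA_real_
    out$precision[c] <- if (np > 0) tp / np else NA_real_
  }
  out$confusion <- conf
  out
}

# brute-force phase counter: scan for run starts
brute_phase_count <- function(labels, c) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n == 0) return(0L)
  sum(labels == c & c(TRUE, labels[-n] != labels[-1]))
}

random_labels <- function(n, levs = LEVS) sample(levs, n, replace = TRUE)
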