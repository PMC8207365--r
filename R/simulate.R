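#' Night model for the semi-Markov behavior simulator
#'
#' Ground-truth nights are generated as alternating behavior phases: the
#' label sequence is a Markov chain without self-transitions and phase
#' lengths are gamma-distributed with a per-state mean. The defaults are
#' calibrated to a typical common-eland night (14 h, 5 p.m. to 7 a.m.):
#' roughly 8 standing phases totalling ~195 min, 17 lying-head-up phases
#' totalling ~590 min, 9 lying-head-down phases totalling ~50 min, and a
#' couple of short absences. With transition weights proportional to the
#' target phase frequencies the embedded chain's stationary distribution
#' equals those frequencies.
#'
#' @param night_length_h night length in hours (default 14).
#' @param interval_s interval length in seconds (default 7).
#' @param mean_duration_min named numeric: mean phase duration in minutes
#'   per state.
#' @param phase_freq named numeric: relative frequency of phases per state
#'   (normalized internally); also used as the initial-state distribution.
#' @param shape gamma shape parameter for phase durations (default 2:
#'   right-skewed, mode below the mean, as resting bouts typically are).
#' @param transition_weights optional 4 x 4 matrix of transition weights
#'   with zero diagonal; defaults to `phase_freq` replicated per row.
#' @return object of class `night_model`.
#' @export
night_model <- function(night_length_h = 14, interval_s = 7,
                        mean_duration_min = c(standing = 23.8, lhu = 34.3,
                                              lhd = 5.7, absent = 2),
                        phase_freq = c(standing = 8.2, lhu = 17.2,
                                       lhd = 9.0, absent = 2.0),
                        shape = 2,
                        transition_weights = NULL) {
  levs <- behavior_levels()
  stopifnot(all(levs %in% names(mean_duration_min)),
            all(levs %in% names(phase_freq)),
            all(mean_duration_min[levs] > 0), all(phase_freq[levs] >= 0),
            shape > 0, night_length_h > 0, interval_s > 0)
  f <- phase_freq[levs] / sum(phase_freq[levs])
  if (is.null(transition_weights)) {
    transition_weights <- matrix(rep(f, each = 4), 4, 4,
                                 dimnames = list(levs, levs))
    diag(transition_weights) <- 0
  }
  transition_weights <- as.matrix(transition_weights)
  stopifnot(all(dim(transition_weights) == c(4, 4)),
            all(diag(transition_weights) == 0),
            all(transition_weights >= 0),
            all(rowSums(transition_weights) > 0))
  dimnames(transition_weights) <- list(levs, levs)
  structure(list(night_length_h = night_length_h, interval_s = interval_s,
                 mean_duration_min = mean_duration_min[levs],
                 phase_freq = f, shape = shape,
                 transition_weights = transition_weights),
            class = "night_model")
}

#' Simulate a ground-truth night
#'
#' Draws alternating phases until the night is full: labels from the
#' model's transition weights (first phase from the phase frequencies),
#' lengths from a gamma distribution with the state's mean duration and the
#' model's shape, rounded to at least one interval; the last phase is
#' truncated so the total equals the night length exactly (7,200 intervals
#' at the defaults). Deterministic given the seed; the caller's RNG state
#' is left untouched.
#'
#' @param model a [night_model()].
#' @param seed integer seed.
#' @param night_id identifier for the generated timeline.
#' @return ground-truth [timeline()].
#' @export
simulate_night <- function(model, seed, night_id = paste0("sim", seed)) {
  stopifnot(inherits(model, "night_model"))
  levs <- behavior_levels()
  n_total <- round(model$night_length_h * 3600 / model$interval_s)
  mean_int <- model$mean_duration_min * 60 / model$interval_s
  with_local_seed(seed, {
    labels <- character(0)
    lens <- integer(0)
    cur <- sample(levs, 1, prob = model$phase_freq)
    total <- 0L
    while (total < n_total) {
      len <- max(1L, as.integer(round(stats::rgamma(
        1, shape = model$shape,
        scale = mean_int[[cur]] / model$shape))))
      len <- min(len, n_total - total)
      labels <- c(labels, cur)
      lens <- c(lens, len)
      total <- total + len
      cur <- sample(levs, 1, prob = model$transition_weights[cur, ])
    }
    timeline(rep.int(labels, lens), interval_s = model$interval_s,
             night_id = night_id)
  })
}

#' Noise model emulating the classifier ensemble
#'
#' Two corruption mechanisms sit on top of a ground-truth night. First,
#' independent per-interval confusion: each label is resampled from its
#' confusion-matrix row (small misclassifications that make raw predictions
#' flicker). Second, contiguous *bursts*: with a small per-interval start
#' probability, a short run of intervals is overwritten with one wrong
#' label, emulating stretches of occlusion or truncation where the
#' classifier is consistently wrong. Probability vectors are drawn from a
#' Dirichlet concentrated on the (possibly corrupted) label.
#'
#' @param confusion 4 x 4 row-stochastic matrix (truth in rows); default
#'   [symmetric_confusion()] with 5% error.
#' @param burst_rate per-interval probability that a burst starts
#'   (default 0.01).
#' @param burst_mean mean burst length in intervals (geometric, >= 1;
#'   default 3).
#' @param concentration Dirichlet concentration added on the drawn label
#'   (default 20; larger = more confident vectors).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(confusion = symmetric_confusion(0.05),
                        burst_rate = 0.01, burst_mean = 3,
                        concentration = 20) {
  levs <- behavior_levels()
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == c(4, 4)), all(confusion >= 0),
            all(abs(rowSums(confusion) - 1) < 1e-9),
            burst_rate >= 0, burst_rate <= 1, burst_mean >= 1,
            concentration > 0)
  dimnames(confusion) <- list(levs, levs)
  structure(list(confusion = confusion, burst_rate = burst_rate,
                 burst_mean = burst_mean, concentration = concentration),
            class = "noise_model")
}

#' @rdname noise_model
#' @param error total probability of flipping to some other state; spread
#'   uniformly over the three wrong states.
#' @export
symmetric_confusion <- function(error = 0.05) {
  stopifnot(error >= 0, error <= 1)
  m <- matrix(error / 3, 4, 4,
              dimnames = list(behavior_levels(), behavior_levels()))
  diag(m) <- 1 - error
  m
}

#' Corrupt a ground-truth night into classifier-like predictions
#'
#' Produces `n_streams` conditionally independent corruptions of the same
#' truth (independence is the conservative setting for testing fusion: real
#' stream errors are correlated, which fusion helps less with).
#' Deterministic given the seed.
#'
#' @param truth ground-truth [timeline()].
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param n_streams number of prediction streams (default 2).
#' @return list of length `n_streams`; each element has `labels` (factor)
#'   and `probs` (n x 4 matrix, rows normalized, argmax = label).
#' @export
corrupt_predictions <- function(truth, noise, seed, n_streams = 2) {
  stopifnot(inherits(truth, "timeline"), inherits(noise, "noise_model"))
  levs <- behavior_levels()
  n <- length(truth)
  y <- as.integer(truth$labels)
  with_local_seed(seed, {
    lapply(seq_len(n_streams), function(s) {
      lab <- y
      if (n > 0) {
        # per-interval confusion flips
        for (c in 1:4) {
          idx <- which(y == c)
          if (length(idx)) {
            lab[idx] <- sample.int(4, length(idx), replace = TRUE,
                                   prob = noise$confusion[c, ])
          }
        }
        # contiguous flicker bursts with a constant wrong label
        starts <- which(stats::runif(n) < noise$burst_rate)
        for (st in starts) {
          len <- 1L + stats::rgeom(1, prob = 1 / noise$burst_mean)
          en <- min(n, st + len - 1L)
          wrong <- sample(setdiff(1:4, y[st]), 1)
          lab[st:en] <- wrong
        }
        # concentrated Dirichlet probability vectors
        alpha <- matrix(1, n, 4)
        alpha[cbind(seq_len(n), lab)] <- 1 + noise$concentration
        g <- matrix(stats::rgamma(n * 4, shape = alpha), n, 4)
        # keep argmax consistent with the drawn label
        top <- g[cbind(seq_len(n), lab)]
        rowmax <- apply(g, 1, max)
        fix <- which(top < rowmax)
        if (length(fix)) {
          g[cbind(fix, lab[fix])] <- rowmax[fix] * 1.0001
        }
        probs <- g / rowSums(g)
      } else {
        probs <- matrix(numeric(0), 0, 4)
      }
      colnames(probs) <- levs
      list(labels = factor(levs[lab], levels = levs), probs = probs)
    })
  })
}

#' Scene configuration for the toy frame renderer
#'
#' @param width,height frame size in pixels (defaults 128 x 96; real frames
#'   are 720p/1080p, scaled down here so fixtures stay tiny).
#' @param fps frame rate (default 1).
#' @param bg_level,bg_texture background gray level and texture amplitude.
#' @param blob_level gray level of the animal silhouette.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(width = 128, height = 96, fps = 1,
                         bg_level = 0.35, bg_texture = 0.08,
                         blob_level = 0.85) {
  structure(list(width = width, height = height, fps = fps,
                 bg_level = bg_level, bg_texture = bg_texture,
                 blob_level = blob_level),
            class = "scene_config")
}

#' Render toy night-vision frames with ground-truth boxes
#'
#' Produces grayscale frames (one per frame of each interval) showing a
#' textured background and a simple articulated silhouette whose shape
#' depends on the behavior state: upright body on legs (standing),
#' horizontal body with a raised head (lying head up), horizontal body only
#' (lying head down), or nothing (absent). The emitted bounding box is the
#' tight box of the silhouette. Deterministic given the seed.
#'
#' @param truth ground-truth [timeline()]; rendering n_intervals * fps *
#'   interval_s frames can be large, so `max_intervals` caps it.
#' @param scene a [scene_config()].
#' @param seed integer seed.
#' @param max_intervals render at most this many leading intervals
#'   (default 20).
#' @return list with `frames` (list of matrices), `boxes` (list of
#'   [bbox()] or `NULL`), `state` (character per frame), `frame_id`
#'   (character per frame).
#' @export
render_frames <- function(truth, scene = scene_config(), seed = 1,
                          max_intervals = 20) {
  stopifnot(inherits(truth, "timeline"), inherits(scene, "scene_config"))
  fpi <- round(scene$fps * truth$interval_s)
  k <- min(length(truth), max_intervals)
  labels <- as.character(truth$labels[seq_len(k)])
  h <- scene$height; w <- scene$width
  with_local_seed(seed, {
    # slowly drifting animal position
    cx <- w / 2; cy <- h * 0.6
    frames <- vector("list", k * fpi)
    boxes <- vector("list", k * fpi)
    state <- character(k * fpi)
    ids <- character(k * fpi)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(k)) {
      for (f in seq_len(fpi)) {
        idx <- (i - 1L) * fpi + f
        cx <- min(w - 25, max(25, cx + stats::rnorm(1, 0, 0.8)))
        cy <- min(h - 18, max(18, cy + stats::rnorm(1, 0, 0.4)))
        bg <- scene$bg_level +
          scene$bg_texture * sin(xx / 9 + yy / 13) +
          matrix(stats::runif(h * w, -0.02, 0.02), h, w)
        mask <- silhouette_mask(labels[i], cx, cy, xx, yy)
        img <- bg
        img[mask] <- scene$blob_level
        img <- pmin(pmax(img, 0), 1)
        frames[[idx]] <- img
        state[idx] <- labels[i]
        ids[idx] <- sprintf("frame_%05d", idx - 1L)
        if (any(mask)) {
          rows <- range(which(rowSums(mask) > 0))
          cols <- range(which(colSums(mask) > 0))
          boxes[[idx]] <- bbox(cols[1] - 1, rows[1] - 1, cols[2], rows[2])
        }
      }
    }
    list(frames = frames, boxes = boxes, state = state, frame_id = ids)
  })
}

# State-dependent silhouette on the pixel grid (1-based xx, yy matrices).
silhouette_mask <- function(label, cx, cy, xx, yy) {
  ell <- function(x0, y0, rx, ry) {
    ((xx - x0) / rx)^2 + ((yy - y0) / ry)^2 <= 1
  }
  switch(label,
    standing = {
      body <- ell(cx, cy - 6, 12, 6)
      legs <- (abs(xx - (cx - 8)) <= 1.2 | abs(xx - (cx + 8)) <= 1.2) &
        yy > cy - 4 & yy <= cy + 8
      body | legs
    },
    lhu = ell(cx, cy + 4, 14, 5) | ell(cx + 11, cy - 5, 4, 6),
    lhd = ell(cx, cy + 4, 14, 5) | ell(cx + 13, cy + 5, 4, 3),
    absent = matrix(FALSE, nrow(xx), ncol(xx)),
    stop("unknown state ", label)
  )
}
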