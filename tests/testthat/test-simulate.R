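test_that("simulate_night is deterministic and fills the night exactly", {
  m <- night_model()
  a <- simulate_night(m, seed = 21)
  b <- simulate_night(m, seed = 21)
  expect_identical(as.character(a$labels), as.character(b$labels))
  expect_false(identical(as.character(a$labels),
                         as.character(simulate_night(m, seed = 22)$labels)))
  expect_length(a, 7200)  # 14 h * 3600 / 7
  segs <- segment_phases(a)
  expect_true(all(segs$label[-1] != segs$label[-nrow(segs)]))
  # RNG state of the caller is untouched
  set.seed(5); r1 <- runif(1)
  set.seed(5); invisible(simulate_night(m, 1)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("shorter nights and custom models are honored", {
  m <- night_model(night_length_h = 1,
                   mean_duration_min = c(standing = 5, lhu = 5, lhd = 5,
                                         absent = 5),
                   phase_freq = c(standing = 1, lhu = 1, lhd = 1, absent = 1))
  tl <- simulate_night(m, seed = 3)
  expect_length(tl, round(3600 / 7))
  expect_error(night_model(mean_duration_min = c(standing = -1, lhu = 1,
                                                 lhd = 1, absent = 1)))
  w <- matrix(1, 4, 4); diag(w) <- 0
  expect_silent(night_model(transition_weights = w))
  diag(w) <- 1
  expect_error(night_model(transition_weights = w))
})

test_that("corrupt_predictions respects the confusion matrix", {
  m <- night_model()
  truth <- simulate_night(m, seed = 31)
  # identity confusion, no bursts: labels unchanged, probs argmax consistent
  clean <- corrupt_predictions(truth, noise_model(symmetric_confusion(0),
                                                  burst_rate = 0),
                               seed = 1)
  expect_identical(as.character(clean[[1]]$labels),
                   as.character(truth$labels))
  expect_equal(rowSums(clean[[1]]$probs), rep(1, length(truth)),
               tolerance = 1e-12)
  am <- apply(clean[[1]]$probs, 1, which.max)
  expect_identical(behavior_levels()[am], as.character(clean[[1]]$labels))

  # always-wrong confusion: no interval keeps its true label
  wrong <- matrix(1 / 3, 4, 4); diag(wrong) <- 0
  allwrong <- corrupt_predictions(truth,
                                  noise_model(wrong, burst_rate = 0),
                                  seed = 2)
  expect_false(any(as.character(allwrong[[1]]$labels) ==
                     as.character(truth$labels)))

  # symmetric 10%: empirical flip fraction within 3 sd of 0.10
  ten <- corrupt_predictions(truth, noise_model(symmetric_confusion(0.10),
                                                burst_rate = 0),
                             seed = 3)
  flip <- mean(as.character(ten[[1]]$labels) != as.character(truth$labels))
  sd3 <- 3 * sqrt(0.1 * 0.9 / length(truth))
  expect_lt(abs(flip - 0.10), sd3)

  # determinism and stream decorrelation
  again <- corrupt_predictions(truth, noise_model(), seed = 5)
  again2 <- corrupt_predictions(truth, noise_model(), seed = 5)
  expect_identical(again[[1]]$probs, again2[[1]]$probs)
  expect_false(identical(as.character(again[[1]]$labels),
                         as.character(again[[2]]$labels)))
})

test_that("bursts overwrite contiguous runs", {
  truth <- timeline(rep("standing", 2000))
  noisy <- corrupt_predictions(truth,
                               noise_model(symmetric_confusion(0),
                                           burst_rate = 0.01,
                                           burst_mean = 4),
                               seed = 8)[[1]]
  segs <- segment_phases(timeline(as.character(noisy$labels)))
  burst_segs <- segs[segs$label != "standing", ]
  expect_gt(nrow(burst_segs), 0)       # some bursts happened
  expect_gt(max(burst_segs$length), 1) # and they are runs, not single flips
})

test_that("render_frames emits tight boxes and is deterministic", {
  truth <- timeline(c(rep("standing", 1), rep("lhu", 1), rep("lhd", 1),
                      rep("absent", 1)), interval_s = 7)
  sc <- scene_config()
  r1 <- render_frames(truth, sc, seed = 41, max_intervals = 4)
  r2 <- render_frames(truth, sc, seed = 41, max_intervals = 4)
  expect_identical(r1$frames, r2$frames)
  expect_length(r1$frames, 4 * 7)
  # absent intervals have no box
  expect_true(all(vapply(which(r1$state == "absent"),
                         function(i) is.null(r1$boxes[[i]]), logical(1))))
  # emitted box equals the recomputed tight box of the bright silhouette
  for (i in which(r1$state != "absent")[1:5]) {
    img <- r1$frames[[i]]
    mask <- img >= sc$blob_level - 1e-9
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    recomputed <- bbox(cols[1] - 1, rows[1] - 1, cols[2], rows[2])
    expect_equal(iou(r1$boxes[[i]], recomputed), 1)
  }
  # frames can be cut out and mosaicked end to end
  sel <- select_encoding_frames(0:6)
  tiles <- lapply(sel + 1, function(i) {
    cutout(r1$frames[[i]], r1$boxes[[i]], side = 150)
  })
  expect_equal(dim(mosaic_multiframe(tiles)), c(300, 300))
})
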