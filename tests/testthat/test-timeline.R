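test_that("label parsing accepts exactly the four states", {
  expect_equal(levels(as_behavior("LHU")), behavior_levels())
  expect_equal(as.character(as_behavior(c("Standing", "absent"))),
               c("standing", "absent"))
  expect_error(as_behavior("sitting"), "unknown behavior label")
  expect_error(timeline(c("standing", "lhx")), "unknown behavior label")
})

test_that("timeline validates probability rows", {
  p <- matrix(c(0.5, 0.3, 0.2), 1, 3)
  expect_silent(timeline("lhu", probs = p))
  expect_error(timeline("lhu", probs = matrix(c(0.5, 0.3, 0.3), 1, 3)),
               "sum to 1")
  expect_error(timeline("lhu", probs = matrix(c(1.2, -0.1, -0.1), 1, 3)),
               "negative")
  expect_error(timeline(c("lhu", "lhd"), probs = p), "rows")
  expect_error(timeline("lhu", probs = matrix(0.5, 1, 2)), "3 or 4 columns")
})

test_that("segment_phases matches the worked examples", {
  expect_equal(nrow(segment_phases(timeline())), 0)
  s1 <- segment_phases(timeline(rep("standing", 3)))
  expect_equal(as.character(s1$label), "standing")
  expect_equal(c(s1$start, s1$end), c(0L, 3L))
  s2 <- segment_phases(timeline(c("standing", "standing", "lhu", "lhd", "lhd")))
  expect_equal(as.character(s2$label), c("standing", "lhu", "lhd"))
  expect_equal(s2$start, c(0L, 2L, 3L))
  expect_equal(s2$end, c(2L, 3L, 5L))
  expect_equal(s2$length, c(2L, 1L, 2L))
})

test_that("rebuild_timeline inverts segmentation and merges equal neighbors", {
  expect_length(rebuild_timeline(segment_phases(timeline())), 0)
  one <- data.frame(label = factor("standing", levels = behavior_levels()),
                    start = 0L, end = 3L)
  expect_equal(as.character(rebuild_timeline(one)$labels), rep("standing", 3))
  split <- data.frame(
    label = factor(c("standing", "standing"), levels = behavior_levels()),
    start = c(0L, 2L), end = c(2L, 4L))
  merged <- rebuild_timeline(split)
  expect_equal(as.character(merged$labels), rep("standing", 4))
  expect_equal(nrow(segment_phases(merged)), 1)
})

test_that("rebuild_timeline rejects gaps and overlaps", {
  bad <- data.frame(label = factor(c("standing", "lhu"),
                                   levels = behavior_levels()),
                    start = c(0L, 3L), end = c(2L, 5L))
  expect_error(rebuild_timeline(bad), "gaps or overlaps")
  bad$start <- c(0L, 1L)
  expect_error(rebuild_timeline(bad), "gaps or overlaps")
  bad2 <- data.frame(label = factor("standing", levels = behavior_levels()),
                     start = 1L, end = 3L)
  expect_error(rebuild_timeline(bad2), "start at interval 0")
})

test_that("round trip and phase counts hold on random sequences", {
  set.seed(42)
  for (rep in 1:1000) {
    n <- sample.int(200, 1)
    labs <- random_labels(n)
    tl <- timeline(labs)
    segs <- segment_phases(tl)
    expect_identical(as.character(rebuild_timeline(segs)$labels), labs)
    expect_true(all(segs$length >= 1))
    expect_true(all(diff(segs$start) > 0))
    # adjacent segments differ
    if (nrow(segs) > 1) {
      expect_true(all(segs$label[-1] != segs$label[-nrow(segs)]))
    }
    # phase count per label vs brute-force run-start scan
    for (c in sample(LEVS, 2)) {
      expect_equal(sum(segs$label == c), brute_phase_count(labs, c))
    }
  }
})

test_that("timeline CSV round-trips labels and probabilities", {
  set.seed(7)
  n <- 25
  p <- matrix(rgamma(n * 4, 1), n, 4)
  p <- p / rowSums(p)
  tl <- timeline(random_labels(n), probs = p, interval_s = 7,
                 night_id = "n1")
  f <- withr::local_tempfile(fileext = ".csv")
  write_timeline(tl, f)
  back <- read_timeline(f, night_id = "n1")
  expect_equal(as.character(back$labels), as.character(tl$labels))
  expect_equal(back$probs, tl$probs, tolerance = 1e-12)
  expect_equal(back$interval_s, 7)
  header <- readLines(f, n = 1)
  expect_equal(header,
               "interval_index,start_s,label,p_standing,p_lhu,p_lhd,p_absent")
  expect_error(read_timeline(withr::local_tempfile(lines = "a,b\n1,2")),
               "must have columns")
})
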