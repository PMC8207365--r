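tl <- function(...) timeline(c(...))

test_that("accuracy counts matching intervals", {
  a <- tl("standing", "lhu", "lhd")
  expect_equal(accuracy(a, a), 1)
  expect_equal(accuracy(a, tl("standing", "lhu", "lhu")), 2 / 3)
  expect_equal(accuracy(a, tl("lhu", "lhd", "standing")), 0)
  expect_error(accuracy(a, tl("standing")), "intervals")
  expect_error(accuracy(timeline(), timeline()), "empty")
  # absent exclusion mode
  t2 <- tl("standing", "absent", "lhu")
  p2 <- tl("standing", "lhd", "lhd")
  expect_equal(accuracy(t2, p2), 1 / 3)
  expect_equal(accuracy(t2, p2, include_absent = FALSE), 1 / 2)
})

test_that("per_class_metrics matches the hand-counted contingency", {
  truth <- tl("standing", "standing", "lhu", "lhu")
  pred <- tl("standing", "lhu", "lhu", "lhu")
  m <- per_class_metrics(truth, pred)$metrics
  s <- m[m$label == "standing", ]
  u <- m[m$label == "lhu", ]
  expect_equal(s$recall, 1 / 2)
  expect_equal(s$precision, 1)
  expect_equal(u$recall, 1)
  expect_equal(u$precision, 2 / 3)
  expect_equal(u$f_score, 4 / 5)
  # class never true and never predicted: undefined, support 0
  d <- m[m$label == "lhd", ]
  expect_equal(d$support, 0L)
  expect_false(d$defined)
  expect_true(is.na(d$recall))
  # perfect prediction: everything 1 for present classes
  mp <- per_class_metrics(truth, truth)$metrics
  expect_true(all(mp$recall[mp$support > 0] == 1))
  expect_true(all(mp$f_score[mp$support > 0] == 1))
})

test_that("metrics agree with the brute-force counting oracle", {
  set.seed(14)
  for (rep in 1:60) {
    n <- sample.int(120, 1)
    y <- random_labels(n); yhat <- random_labels(n)
    ty <- timeline(y); tp <- timeline(yhat)
    o <- brute_metrics(y, yhat)
    expect_equal(accuracy(ty, tp), o$accuracy)
    m <- per_class_metrics(ty, tp)
    expect_equal(unname(m$metrics$tp), unname(as.integer(o$tp)))
    expect_equal(m$metrics$recall, unname(o$recall))
    expect_equal(m$metrics$precision, unname(o$precision))
    expect_equal(unclass(m$confusion), unclass(o$confusion),
                 ignore_attr = TRUE)
    # micro-consistency: sum of true positives / n = accuracy
    expect_equal(sum(m$metrics$tp) / n, o$accuracy)
  }
})

test_that("binary_collapse merges the lying states and never hurts accuracy", {
  expect_equal(as.character(binary_collapse(tl("lhu", "lhd"))$labels),
               c("lying", "lying"))
  expect_equal(as.character(binary_collapse(tl("standing"))$labels),
               "standing")
  expect_equal(levels(binary_collapse(tl("absent"))$labels), binary_levels())
  set.seed(15)
  for (rep in 1:50) {
    n <- sample.int(80, 1)
    ty <- timeline(random_labels(n)); tp <- timeline(random_labels(n))
    expect_gte(binary_accuracy(ty, tp), accuracy(ty, tp))
  }
  # drop_absent mode scores only the standing/lying decision
  t2 <- tl("standing", "absent", "lhu")
  p2 <- tl("lhd", "absent", "lhu")
  expect_equal(binary_accuracy(t2, p2, drop_absent = TRUE), 1 / 2)
})

test_that("key_figures reports phase counts and durations in minutes", {
  full <- timeline(rep("standing", 7200))  # a 14-h night of 7-s intervals
  kf <- key_figures(full)
  expect_equal(kf$phase_count[kf$label == "standing"], 1L)
  expect_equal(kf$duration_min[kf$label == "standing"], 840)
  expect_equal(sum(kf$duration_min), 840)

  mixed <- timeline(c(rep("standing", 100), rep("lhu", 100),
                      rep("standing", 100)))
  km <- key_figures(mixed)
  expect_equal(km$phase_count[km$label == "standing"], 2L)
  expect_equal(km$duration_min[km$label == "standing"], 1400 / 60)
  expect_equal(sum(km$duration_min), 300 * 7 / 60)

  k0 <- key_figures(timeline())
  expect_true(all(k0$phase_count == 0))
  expect_true(all(k0$duration_min == 0))
})

test_that("duration conservation holds on random nights", {
  set.seed(16)
  for (rep in 1:25) {
    n <- sample.int(500, 1)
    x <- timeline(random_labels(n))
    expect_equal(sum(key_figures(x)$duration_min), n * 7 / 60,
                 tolerance = 1e-6)
  }
})

test_that("summarize_nights reports mean and SEM", {
  n1 <- key_figures(timeline(c(rep("standing", 10), rep("lhu", 5))),
                    night_id = "n1")
  single <- summarize_nights(list(n1))
  expect_equal(single$phase_count_mean,
               as.numeric(n1$phase_count))
  expect_true(all(single$phase_count_sem == 0))

  # two nights with 6 and 8 standing phases -> 7 +/- 1
  mk <- function(k) {
    labs <- rep(c("standing", "lhu"), k)
    key_figures(timeline(rep(labs, each = 3)))
  }
  two <- summarize_nights(list(mk(6), mk(8)))
  st <- two[two$label == "standing", ]
  expect_equal(st$phase_count_mean, 7)
  expect_equal(st$phase_count_sem, 1)
  ident <- summarize_nights(list(mk(5), mk(5), mk(5)))
  expect_true(all(ident$phase_count_sem == 0))
  expect_error(summarize_nights(list()), "at least one")
})

test_that("write_report emits the CSV and JSON artifacts", {
  set.seed(17)
  ty <- timeline(random_labels(50)); tp <- timeline(random_labels(50))
  dir <- withr::local_tempdir()
  write_report(per_class_metrics(ty, tp),
               list(key_figures(tp), key_figures(ty)), dir)
  csv <- utils::read.csv(file.path(dir, "per_class_metrics.csv"))
  expect_equal(csv$label, behavior_levels())
  js <- jsonlite::read_json(file.path(dir, "night_summaries.json"))
  expect_length(js$nights, 2)
  expect_length(js$summary, 4)
})
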