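test_that("transition_rule validates its fields", {
  r <- transition_rule(c("standing", "lhu"), "lhd", c("standing", "lhu"), 3)
  expect_s3_class(r, "transition_rule")
  expect_equal(r$min_intervals, 3L)
  expect_error(transition_rule("standing", "naps", "standing", 3),
               "unknown behavior label")
  expect_error(transition_rule("standing", "lhu", "standing", 0),
               "count >= 1")
})

test_that("the default rule set encodes the six antelope rows in order", {
  rules <- default_rules()
  expect_length(rules, 6)
  expect_equal(vapply(rules, `[[`, integer(1), "min_intervals"),
               c(3L, 6L, 6L, 25L, 25L, 50L))
  expect_equal(vapply(rules, `[[`, character(1), "current"),
               c("lhd", "lhu", "lhu", "lhu", "standing", "absent"))
  # the shipped YAML matches the in-code defaults
  shipped <- read_rules_yaml(system.file("extdata", "default_rules.yaml",
                                         package = "ethosmooth"))
  expect_equal(lapply(shipped, unclass), lapply(rules, unclass))
})

test_that("rules YAML round-trips", {
  rules <- default_rules()[c(2, 6)]
  f <- withr::local_tempfile(fileext = ".yaml")
  write_rules_yaml(rules, f)
  expect_equal(lapply(read_rules_yaml(f), unclass), lapply(rules, unclass))
})

test_that("apply_rules reproduces the worked replacements", {
  tl <- timeline(c(rep("standing", 10), rep("lhd", 2), rep("lhu", 10)))
  out <- apply_rules(tl)
  expect_equal(as.character(out$labels),
               c(rep("standing", 12), rep("lhu", 10)))

  tl2 <- timeline(c(rep("standing", 100), rep("absent", 30),
                    rep("standing", 100)))
  out2 <- apply_rules(tl2)
  expect_equal(as.character(out2$labels), rep("standing", 230))
  expect_length(out2, length(tl2))
})

test_that("compliant and boundary phases are never replaced", {
  # every interior phase meets all applicable minima -> identity
  tl <- timeline(c(rep("standing", 30), rep("lhd", 3), rep("lhu", 25),
                   rep("standing", 25), rep("lhu", 6), rep("lhd", 40)))
  expect_equal(as.character(apply_rules(tl)$labels),
               as.character(tl$labels))
  # short phases at the night boundary stay: no previous/next neighbor
  edge <- timeline(c("lhd", rep("standing", 50), "lhu"))
  expect_equal(as.character(apply_rules(edge)$labels),
               as.character(edge$labels))
})

test_that("cascading merges need several passes; max_passes = 1 is single-pass", {
  # lhd(2) between standing and lhu collapses first, then the lhu block
  # (now 24 < 25 between standing and standing) collapses too
  labs <- c(rep("standing", 30), rep("lhu", 10), rep("lhd", 2),
            rep("lhu", 12), rep("standing", 30))
  tl <- timeline(labs)
  full <- apply_rules(tl)
  expect_equal(as.character(full$labels), rep("standing", 84))
  one <- suppressWarnings(apply_rules(tl, max_passes = 1))
  expect_equal(nrow(segment_phases(one)), 3)  # lhd removed, lhu(24) remains
  expect_warning(apply_rules(tl, max_passes = 1), "max_passes")
})

test_that("apply_rules is idempotent and matches the naive oracle", {
  rules <- default_rules()
  set.seed(13)
  for (rep in 1:400) {
    n <- sample.int(60, 1)
    labs <- random_labels(n)
    tl <- timeline(labs)
    out <- apply_rules(tl)
    expect_length(out, n)
    expect_identical(as.character(apply_rules(out)$labels),
                     as.character(out$labels))
    expect_identical(as.character(out$labels),
                     naive_apply_rules(labs, rules))
    expect_equal(count_rule_violations(out), 0L)
  }
})

test_that("custom rule sets and orderings are honored", {
  # single rule: short absent between standing phases
  r <- list(transition_rule("standing", "absent", "standing", 10))
  tl <- timeline(c(rep("standing", 5), rep("absent", 9), rep("standing", 5)))
  expect_equal(as.character(apply_rules(tl, rules = r)$labels),
               rep("standing", 19))
  # with an empty rule list nothing changes
  expect_equal(as.character(apply_rules(tl, rules = list())$labels),
               as.character(tl$labels))
})
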