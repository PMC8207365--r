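#' Transition rules for ethogram postprocessing
#'
#' A transition rule encodes one row of the species' postprocessing table:
#' whenever a phase of `current` is shorter than `min_intervals` and is
#' flanked by a previous phase whose label is in `prev` and a next phase
#' whose label is in `next`, the phase is implausibly short (e.g. a brief
#' burst of standing between two lying-head-down phases) and is replaced by
#' the *previous* phase's label.
#'
#' @param prev non-empty character vector of admissible previous-phase
#'   labels.
#' @param current the label of the (too short) phase the rule removes.
#' @param next_ non-empty character vector of admissible next-phase labels.
#' @param min_intervals phases of `current` shorter than this many intervals
#'   are replaced (>= 1).
#' @return object of class `transition_rule`.
#' @seealso [default_rules()], [apply_rules()]
#' @export
transition_rule <- function(prev, current, next_, min_intervals) {
  prev <- as.character(as_behavior(prev))
  current <- as.character(as_behavior(current))
  next_ <- as.character(as_behavior(next_))
  stopifnot(length(prev) >= 1, length(current) == 1, length(next_) >= 1)
  min_intervals <- as.integer(min_intervals)
  if (is.na(min_intervals) || min_intervals < 1) {
    stop("min_intervals must be a count >= 1")
  }
  structure(list(prev = unique(prev), current = current,
                 next_ = unique(next_), min_intervals = min_intervals),
            class = "transition_rule")
}

#' @export
print.transition_rule <- function(x, ...) {
  cat(sprintf("{%s} -> %s -> {%s}: min %d intervals\n",
              paste(x$prev, collapse = ","), x$current,
              paste(x$next_, collapse = ","), x$min_intervals))
  invisible(x)
}

#' Default rule set for elands, bongos and wildebeest
#'
#' The six rules used for the antelope species the pipeline was developed
#' on. Minimum lengths are in 7-s intervals (3 intervals = 21 s, 50
#' intervals = 350 s). Rules are evaluated in this order; species-specific
#' sets can be loaded from YAML ([read_rules_yaml()]).
#'
#' @return ordered list of [transition_rule()] objects.
#' @export
default_rules <- function() {
  list(
    transition_rule(c("standing", "lhu"), "lhd", c("standing", "lhu"), 3),
    transition_rule("lhd", "lhu", c("lhd", "standing"), 6),
    transition_rule("standing", "lhu", "lhd", 6),
    transition_rule("standing", "lhu", "standing", 25),
    transition_rule(c("lhd", "lhu"), "standing", c("lhd", "lhu"), 25),
    transition_rule(c("lhd", "lhu", "standing"), "absent",
                    c("lhd", "lhu", "standing"), 50)
  )
}

#' Read and write rule sets as YAML
#'
#' Format: a YAML list of mappings
#' `{prev: [..], current: .., next: [..], min_intervals: N}`. The shipped
#' file `system.file("extdata", "default_rules.yaml", package =
#' "ethosmooth")` holds the default set.
#'
#' @param path YAML file path.
#' @param rules list of [transition_rule()] objects.
#' @return `read_rules_yaml()` returns a list of [transition_rule()].
#' @export
read_rules_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    need <- c("prev", "current", "next", "min_intervals")
    if (!all(need %in% names(r))) {
      stop("rule entry must have keys ", paste(need, collapse = ", "))
    }
    transition_rule(unlist(r$prev), r$current, unlist(r$`next`),
                    r$min_intervals)
  })
}

#' @rdname read_rules_yaml
#' @export
write_rules_yaml <- function(rules, path) {
  yaml::write_yaml(lapply(rules, function(r) {
    list(prev = as.list(r$prev), current = r$current,
         `next` = as.list(r$next_), min_intervals = r$min_intervals)
  }), path)
  invisible(path)
}

# Compile rules to integer codes against the 4-level vocabulary for the
# hot path.
compile_rules <- function(rules) {
  levs <- behavior_levels()
  lapply(rules, function(r) {
    stopifnot(inherits(r, "transition_rule"))
    list(prev = levs %in% r$prev,
         current = match(r$current, levs),
         next_ = levs %in% r$next_,
         min = r$min_intervals)
  })
}

# Is any (prev, current, next) pattern with a too-short current phase still
# present? Used for the fixpoint warning and by the pattern scanner.
first_violation <- function(vals, lens, crules) {
  k <- length(vals)
  if (k < 3) return(0L)
  for (i in 2:(k - 1)) {
    for (r in crules) {
      if (vals[i] == r$current && lens[i] < r$min &&
          r$prev[vals[i - 1]] && r$next_[vals[i + 1]]) {
        return(i)
      }
    }
  }
  0L
}

#' Apply transition rules to a timeline
#'
#' Removes implausibly short behavior phases. Each *pass* scans the phase
#' segmentation left to right; a phase matching any rule (rules tried in
#' list order) is relabeled to the previous phase's label, the segmentation
#' is re-merged immediately, and scanning continues after the merged phase.
#' Because a replacement can merge phases and expose new short phases,
#' passes repeat until a full pass changes nothing (a fixpoint, also
#' reached by construction at most after the number of phases halves to 1)
#' or `max_passes` is reached; in the latter case a warning is issued if
#' matching patterns remain. The single detect-and-replace sweep is
#' available via `max_passes = 1`. Phases at the night boundary (no
#' previous or next phase) are never replaced. Output length always equals
#' input length.
#'
#' @param timeline a [timeline()] over the 4-state vocabulary.
#' @param rules ordered list of [transition_rule()]; default
#'   [default_rules()].
#' @param max_passes maximum number of passes (default 50).
#' @return smoothed [timeline()] (probabilities, if any, are dropped: they
#'   no longer correspond to the labels).
#' @export
apply_rules <- function(timeline, rules = default_rules(), max_passes = 50) {
  stopifnot(inherits(timeline, "timeline"))
  codes <- as.integer(timeline$labels)
  out <- apply_rules_codes(codes, compile_rules(rules), max_passes)
  timeline(behavior_levels()[out], interval_s = timeline$interval_s,
           night_id = timeline$night_id)
}

# Hot path on integer codes 1..4; returns the smoothed codes.
apply_rules_codes <- function(codes, crules, max_passes) {
  n <- length(codes)
  if (n == 0) return(codes)
  r <- rle(codes)
  vals <- r$values
  lens <- r$lengths
  pass <- 0L
  repeat {
    pass <- pass + 1L
    changed <- FALSE
    i <- 2L
    while (i <= length(vals) - 1L) {
      v <- vals[i]
      len <- lens[i]
      hit <- FALSE
      for (rl in crules) {
        if (v == rl$current && len < rl$min &&
            rl$prev[vals[i - 1L]] && rl$next_[vals[i + 1L]]) {
          hit <- TRUE
          break
        }
      }
      if (hit) {
        changed <- TRUE
        # replace by previous label, merge with previous phase
        lens[i - 1L] <- lens[i - 1L] + len
        drop <- i
        # next phase merges too if it carries the previous label
        if (vals[i + 1L] == vals[i - 1L]) {
          lens[i - 1L] <- lens[i - 1L] + lens[i + 1L]
          drop <- c(i, i + 1L)
        }
        vals <- vals[-drop]
        lens <- lens[-drop]
        # continue at the phase after the merged block (now at index i)
      } else {
        i <- i + 1L
      }
    }
    if (!changed || pass >= max_passes) {
      if (changed && first_violation(vals, lens, crules) > 0L) {
        warning("apply_rules: max_passes = ", max_passes,
                " reached before fixpoint; returning current state")
      }
      break
    }
  }
  rep.int(vals, lens)
}

#' Scan a timeline for remaining rule violations
#'
#' Diagnostic used to verify the postprocessing guarantee: after
#' [apply_rules()] has reached a fixpoint, no interior phase may match any
#' rule's (prev, current, next) pattern with a length below that rule's
#' minimum.
#'
#' @inheritParams apply_rules
#' @return number of interior phases still matching some rule pattern.
#' @export
count_rule_violations <- function(timeline, rules = default_rules()) {
  codes <- as.integer(timeline$labels)
  if (length(codes) == 0) return(0L)
  r <- rle(codes)
  crules <- compile_rules(rules)
  k <- length(r$values)
  if (k < 3) return(0L)
  hits <- 0L
  for (i in 2:(k - 1)) {
    for (rl in crules) {
      if (r$values[i] == rl$current && r$lengths[i] < rl$min &&
          rl$prev[r$values[i - 1]] && rl$next_[r$values[i + 1]]) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits
}
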