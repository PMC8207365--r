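#' Behavior label vocabulary
#'
#' The ethogram used throughout the package distinguishes four mutually
#' exclusive states per 7-second interval of a recording night:
#' \describe{
#'   \item{standing}{animal upright on all four hooves (feeding, walking,
#'     ruminating, ... all count)}
#'   \item{lhu}{lying with the head lifted ("lying -- head up")}
#'   \item{lhd}{lying with the head rested on the ground ("lying -- head
#'     down"); the postural proxy for REM sleep}
#'   \item{absent}{animal not visible in the frame}
#' }
#' The order \code{standing < lhu < lhd < absent} is fixed and is used for
#' serialization and for deterministic tie-breaking in [decide()].
#'
#' @return `behavior_levels()` returns the four label strings in their fixed
#'   order. `binary_levels()` returns the collapsed vocabulary
#'   `c("standing", "lying", "absent")` used by the binary task.
#' @seealso [as_behavior()], [binary_collapse()]
#' @export
behavior_levels <- function() c("standing", "lhu", "lhd", "absent")

#' @rdname behavior_levels
#' @export
binary_levels <- function() c("standing", "lying", "absent")

#' Parse behavior labels
#'
#' Coerces a character (or factor) vector to the canonical behavior factor.
#' Parsing is case-insensitive; any token outside the four-state vocabulary
#' is an error.
#'
#' @param x character or factor vector of label tokens.
#' @param levels label vocabulary; defaults to [behavior_levels()].
#' @return factor with levels `levels`.
#' @export
as_behavior <- function(x, levels = behavior_levels()) {
  if (is.factor(x)) x <- as.character(x)
  x <- tolower(trimws(x))
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop("unknown behavior label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected one of ", paste(levels, collapse = ", "), ")")
  }
  if (anyNA(x)) stop("missing behavior label")
  factor(x, levels = levels)
}
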