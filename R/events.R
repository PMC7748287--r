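# Unit layout shared by the input and output layers:
#   units 1-3  colour stimuli
#   units 4-8  actions (finger presses)
#   units 9-10 feedback (correct / incorrect)

.event_kinds <- c("colour", "action", "feedback")
.event_counts <- c(colour = 3L, action = 5L, feedback = 2L)
.event_offset <- c(colour = 0L, action = 3L, feedback = 8L)

#' Observable task events and their input/output unit indices
#'
#' The task alphabet consists of ten observable events: three colour
#' stimuli, five actions and two feedback outcomes.  Each event maps to a
#' fixed unit of both the input and the output layer (the two layers share
#' an identical layout).  `event_code()` is the general constructor;
#' `event_colour()`, `event_action()` and `event_feedback()` are
#' convenience wrappers.  `event_from_unit()` inverts the unit mapping.
#'
#' @param kind one of `"colour"`, `"action"`, `"feedback"`.
#' @param index event index within its kind: colours 1-3, actions 1-5,
#'   feedback 1 (`"correct"`) or 2 (`"incorrect"`).
#' @return an object of class `event_code` with fields `kind`, `index` and
#'   `unit` (the shared input/output unit, 1-10).
#' @examples
#' event_action(3)$unit      # 6
#' event_feedback("correct") # unit 9
#' @export
event_code <- function(kind, index) {
  kind <- match.arg(kind, .event_kinds)
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) ||
      index < 1L || index > .event_counts[[kind]])
    stop("invalid ", kind, " index: must be in 1..", .event_counts[[kind]])
  structure(list(kind = kind, index = index,
                 unit = .event_offset[[kind]] + index),
            class = "event_code")
}

#' @rdname event_code
#' @export
event_colour <- function(index) event_code("colour", index)

#' @rdname event_code
#' @export
event_action <- function(index) event_code("action", index)

#' @rdname event_code
#' @param outcome `"correct"`, `"incorrect"`, or the corresponding index
#'   (1 or 2).
#' @export
event_feedback <- function(outcome) {
  if (is.character(outcome))
    outcome <- match(match.arg(outcome, c("correct", "incorrect")),
                     c("correct", "incorrect"))
  event_code("feedback", outcome)
}

#' @rdname event_code
#' @param unit a unit index, 1-10.
#' @export
event_from_unit <- function(unit) {
  unit <- as.integer(unit)
  if (length(unit) != 1L || is.na(unit) || unit < 1L || unit > 10L)
    stop("'unit' must be in 1..10")
  if (unit <= 3L) event_code("colour", unit)
  else if (unit <= 8L) event_code("action", unit - 3L)
  else event_code("feedback", unit - 8L)
}

#' @rdname event_code
#' @param x an object.
#' @export
is_event_code <- function(x) inherits(x, "event_code")

#' @rdname event_code
#' @param e an `event_code`.
#' @export
event_unit <- function(e) {
  stopifnot(is_event_code(e))
  e$unit
}

#' @export
print.event_code <- function(x, ...) {
  lab <- if (x$kind == "feedback")
    c("correct", "incorrect")[x$index] else x$index
  cat(sprintf("<event: %s %s (unit %d)>\n", x$kind, lab, x$unit))
  invisible(x)
}

# coerce an integer colour index or event_code to a colour event
as_colour_event <- function(colour) {
  if (is_event_code(colour)) {
    if (colour$kind != "colour") stop("event must be a colour")
    colour
  } else event_colour(colour)
}

as_action_event <- function(action) {
  if (is_event_code(action)) {
    if (action$kind != "action") stop("event must be an action")
    action
  } else event_action(action)
}

as_feedback_event <- function(outcome) {
  if (is_event_code(outcome)) {
    if (outcome$kind != "feedback") stop("event must be a feedback outcome")
    outcome
  } else event_feedback(outcome)
}

one_hot <- function(unit, n) {
  v <- integer(n)
  v[unit] <- 1L
  v
}
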