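# The staircased visuomotor association task.  Three colours are shown in
# pseudo-random triplets (each triplet a permutation of the colours).  The
# correct action for each colour is not fixed a priori: it is established
# dynamically so every participant makes the same number of errors before
# the first success — the colour first responded to (among those without a
# correct action) inside triplet 2 becomes S1 and that very response is
# declared correct (its 2nd response overall); likewise triplet 4 -> S2
# (4th response) and triplet 5 -> S3 (5th response).  Once set, a colour's
# correct action never changes.

#' Generate a pseudo-random stimulus schedule
#'
#' @param n_triplets number of triplets; each triplet is an independent
#'   uniformly-random permutation of the three colours.
#' @return integer vector of colour indices of length `3 * n_triplets`.
#' @export
generate_schedule <- function(n_triplets = 20L) {
  n_triplets <- as.integer(n_triplets)
  stopifnot(n_triplets >= 1L)
  as.integer(unlist(lapply(seq_len(n_triplets),
                           function(i) sample.int(3L))))
}

#' Staircase task state
#'
#' @param schedule stimulus schedule from [generate_schedule()].
#' @return an object of class `task_state` holding the schedule, the
#'   per-colour response counts, the per-colour designation (1 = S1, 2 =
#'   S2, 3 = S3, `NA` = none yet), the per-colour established correct
#'   action (`NA` = none yet) and the 0-based count of completed trials.
#' @export
task_state <- function(schedule = generate_schedule()) {
  schedule <- as.integer(schedule)
  if (length(schedule) %% 3L != 0L || !all(schedule %in% 1:3))
    stop("'schedule' must be colour indices in whole triplets")
  blocks <- matrix(schedule, nrow = 3L)
  if (!all(apply(blocks, 2L, function(b) setequal(b, 1:3))))
    stop("each length-3 block must be a permutation of the colours")
  structure(list(schedule = schedule,
                 response_count = integer(3L),
                 designation = rep(NA_integer_, 3L),
                 correct_action = rep(NA_integer_, 3L),
                 trial_index = 0L),
            class = "task_state")
}

#' @export
print.task_state <- function(x, ...) {
  lab <- ifelse(is.na(x$designation), "-", paste0("S", x$designation))
  cat(sprintf("<task_state: trial %d/%d; designations: %s; actions: %s>\n",
              x$trial_index, length(x$schedule),
              paste(lab, collapse = " "),
              paste(ifelse(is.na(x$correct_action), "-",
                           x$correct_action), collapse = " ")))
  invisible(x)
}

#' Append a fresh block of triplets to a task's schedule
#'
#' Used for the second goal phase: the stimulus stream continues with new
#' pseudo-random triplets while the established colour-action
#' contingencies persist.
#'
#' @param state a `task_state`.
#' @param n_triplets number of triplets to append.
#' @return the updated `task_state`.
#' @export
extend_schedule <- function(state, n_triplets = 20L) {
  state$schedule <- c(state$schedule, generate_schedule(n_triplets))
  state
}

# which designation (1=S1, 2=S2, 3=S3) can be assigned in a given triplet
.designation_for_triplet <- function(triplet) {
  switch(as.character(triplet), `2` = 1L, `4` = 2L, `5` = 3L, NA_integer_)
}

#' Respond to the current stimulus and receive staircased feedback
#'
#' Checks the response against the protocol: if the colour has no
#' established correct action and the current triplet is one of the
#' designating triplets (2, 4, 5) whose label is still unassigned, the
#' colour receives that label and the response itself is declared its
#' correct action (so the designating response is fed back as correct).
#' Otherwise feedback is correct iff the colour's established action was
#' pressed.  The trial pointer then advances.
#'
#' @param state a `task_state`.
#' @param colour the responded colour; must equal the scheduled stimulus.
#' @param action the pressed action (index 1-5 or an action
#'   `event_code`).
#' @return a list with `feedback` (a feedback `event_code`), `state` (the
#'   updated `task_state`) and `designated` (the label just assigned, or
#'   `NA`).
#' @export
respond <- function(state, colour, action) {
  stopifnot(inherits(state, "task_state"))
  colour <- if (is_event_code(colour)) colour$index else as.integer(colour)
  action <- as_action_event(action)$index
  pos <- state$trial_index + 1L
  if (pos > length(state$schedule)) stop("schedule exhausted")
  if (colour != state$schedule[pos])
    stop("out-of-order response: trial ", pos, " presents colour ",
         state$schedule[pos], ", not ", colour)
  state$response_count[colour] <- state$response_count[colour] + 1L
  designated <- NA_integer_
  if (is.na(state$correct_action[colour])) {
    lab <- .designation_for_triplet((pos - 1L) %/% 3L + 1L)
    if (!is.na(lab) && !lab %in% state$designation) {
      state$designation[colour] <- lab
      state$correct_action[colour] <- action
      designated <- lab
    }
  }
  fb <- !is.na(state$correct_action[colour]) &&
    action == state$correct_action[colour]
  state$trial_index <- pos
  list(feedback = event_feedback(if (fb) 1L else 2L), state = state,
       designated = designated)
}

#' Does a feedback outcome satisfy a goal?
#'
#' @param feedback a feedback `event_code` (or index 1/2).
#' @param goal goal unit: 1 seeks correct feedback, 2 seeks incorrect.
#' @return logical.
#' @export
goal_achieved <- function(feedback, goal) {
  fb <- as_feedback_event(feedback)
  fb$index == as.integer(goal)
}

#' Simulate an idealised participant through the staircase
#'
#' The ideal agent never repeats an action already found wrong for a
#' colour and always repeats a discovered correct action.  Under the
#' protocol its first correct feedback therefore arrives at the 2nd, 4th
#' and 5th response for S1, S2 and S3 respectively.  Used as a protocol
#' oracle in tests and to build the synthetic reference curves.
#'
#' @param state a `task_state` (its whole remaining schedule is played).
#' @return a list with `records` (data.frame: trial, triplet, colour,
#'   action, feedback, response_number) and `state` (the final
#'   `task_state`).
#' @export
run_ideal_agent <- function(state = task_state()) {
  n <- length(state$schedule) - state$trial_index
  tried_wrong <- list(integer(0), integer(0), integer(0))
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- state$trial_index + 1L
    colour <- state$schedule[pos]
    action <- if (!is.na(state$correct_action[colour]))
      state$correct_action[colour]
    else setdiff(1:5, tried_wrong[[colour]])[1L]
    r <- respond(state, colour, action)
    state <- r$state
    correct <- r$feedback$index == 1L
    if (!correct)
      tried_wrong[[colour]] <- union(tried_wrong[[colour]], action)
    rec[[i]] <- data.frame(trial = pos, triplet = (pos - 1L) %/% 3L + 1L,
                           colour = colour, action = action,
                           feedback = if (correct) "correct" else
                             "incorrect",
                           response_number = state$response_count[colour])
  }
  list(records = do.call(rbind, rec), state = state)
}
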