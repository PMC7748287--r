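# Two-layer stochastic action selector used when the world model is too
# uncertain to plan: 6 input units (colour x goal combinations) project to
# the 5 action units; actions are drawn from a temperature-scaled softmax
# of the active input unit's weight row, and failed actions are punished
# (never rewarded), implementing inhibition of return over actions.

#' @rdname select_exploration_action
#' @export
exploration_input_unit <- function(colour, goal) {
  colour <- as.integer(colour)
  goal <- as.integer(goal)
  if (!colour %in% 1:3) stop("'colour' must be in 1..3")
  if (!goal %in% 1:2) stop("'goal' must be 1 or 2")
  2L * (colour - 1L) + goal
}

#' @rdname select_exploration_action
#' @export
exploration_probs <- function(W_explore, colour, goal, temperature) {
  if (temperature <= 0) stop("'temperature' must be > 0")
  u <- W_explore[exploration_input_unit(colour, goal), ]
  competitive_distribution(u / temperature)
}

#' Stochastic exploration over actions with inhibition of return
#'
#' `select_exploration_action()` activates the single input unit coding
#' the current (colour, goal) combination and samples one of the five
#' actions from a softmax of that unit's weight row scaled by the
#' temperature.  `punish_exploration()` is called only when the executed
#' action failed the goal: it decrements the single active-input ->
#' chosen-action weight with the bounded reinforcement rule (pseudo-reward
#' -1) and clips to the bound, lowering the probability that the same
#' action is tried again for that combination.  Successful actions are
#' deliberately not reinforced.
#'
#' @param W_explore the 6 x 5 exploration weight matrix (rows: colour x
#'   goal input units; columns: actions).
#' @param colour colour index, 1-3.
#' @param goal goal unit, 1 or 2.
#' @param temperature softmax temperature (> 0); lower values sharpen the
#'   choice.
#' @param action the punished action (index 1-5 or an action
#'   `event_code`).
#' @param eta learning rate of the reinforcement rule.
#' @param w_max weight bound.
#' @return `select_exploration_action()`: an action `event_code`;
#'   `exploration_probs()`: the length-5 selection distribution;
#'   `punish_exploration()`: the updated `W_explore`;
#'   `exploration_input_unit()`: the input unit index for a (colour,
#'   goal) pair.
#' @export
select_exploration_action <- function(W_explore, colour, goal,
                                      temperature) {
  p <- exploration_probs(W_explore, colour, goal, temperature)
  event_action(sample.int(5L, 1L, prob = p))
}

#' @rdname select_exploration_action
#' @export
punish_exploration <- function(W_explore, colour, goal, action, eta,
                               w_max) {
  act_ev <- as_action_event(action)
  i <- exploration_input_unit(colour, goal)
  j <- act_ev$index
  w <- W_explore[i, j]
  w <- w + eta * (-1) * ((w_max - abs(w)) / w_max)
  W_explore[i, j] <- min(max(w, -w_max), w_max)
  W_explore
}
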