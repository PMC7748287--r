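# The per-trial loop and multi-participant session harness: plan until
# confident or too uncertain, explore otherwise, act, learn, reinforce.

#' Model parameters
#'
#' Bundles the seven searchable parameters (defaults are the fitted
#' values) together with the fixed architecture constants.  The seven
#' searchable parameters and their admissible ranges are: STDP learning
#' rate `zeta` (0.1-1, fitted 0.96), STDP threshold `stdp_c` (0.1-1,
#' fitted 0.67), reinforcement learning rate `eta` (0.001-1, fitted
#' 0.008), exploration softmax `temperature` (0.01-0.1, fitted 0.02),
#' membrane-potential noise `noise_sd` (0.01-0.1, fitted 0.02), initial
#' entropy threshold `epsilon` (0.3-1, fitted 0.74) and per-failure
#' threshold decrement `delta` (0.01-0.2, fitted 0.12).
#'
#' @param zeta STDP learning rate.
#' @param stdp_c STDP depression constant, in (0,1).
#' @param eta learning rate of the goal/exploration reinforcement rule.
#' @param temperature exploration softmax temperature.
#' @param noise_sd sd of the Gaussian potential noise (associative and
#'   output layers).
#' @param epsilon initial entropy threshold of each trial.
#' @param delta threshold decrement per failed planning cycle.
#' @param n_assoc associative layer size.
#' @param n_steps steps per trial / planning cycle (divisible by 3).
#' @param clamp_steps steps during which the colour is clamped in a
#'   planning cycle.
#' @param r0,tau_r refractory amplitude and decay constant.
#' @param w_max bound on goal and exploration weights.
#' @param n_triplets triplets per goal phase.
#' @param max_cycles safety cap on planning cycles per trial.
#' @param init_sd sd of the initial weight jitter.
#' @param goal_in_learning clamp the goal unit on during the learning
#'   replay?
#' @param noise_in_planning,noise_in_learning apply potential noise in
#'   the respective phase?
#' @return an object of class `model_params`.
#' @export
model_params <- function(zeta = 0.96, stdp_c = 0.67, eta = 0.008,
                         temperature = 0.02, noise_sd = 0.02,
                         epsilon = 0.74, delta = 0.12,
                         n_assoc = 400L, n_steps = 15L, clamp_steps = 5L,
                         r0 = 1.1, tau_r = 9.5, w_max = 0.5,
                         n_triplets = 20L, max_cycles = 50L,
                         init_sd = 0.01, goal_in_learning = TRUE,
                         noise_in_planning = TRUE,
                         noise_in_learning = TRUE) {
  p <- list(zeta = zeta, stdp_c = stdp_c, eta = eta,
            temperature = temperature, noise_sd = noise_sd,
            epsilon = epsilon, delta = delta,
            n_assoc = as.integer(n_assoc), n_steps = as.integer(n_steps),
            clamp_steps = as.integer(clamp_steps), r0 = r0, tau_r = tau_r,
            w_max = w_max, n_triplets = as.integer(n_triplets),
            max_cycles = as.integer(max_cycles), init_sd = init_sd,
            goal_in_learning = isTRUE(goal_in_learning),
            noise_in_planning = isTRUE(noise_in_planning),
            noise_in_learning = isTRUE(noise_in_learning))
  stopifnot(p$zeta > 0, p$stdp_c > 0, p$stdp_c < 1, p$eta > 0,
            p$temperature > 0, p$noise_sd >= 0, p$epsilon > 0,
            p$epsilon <= 1, p$delta > 0, p$n_assoc >= 2L,
            p$n_steps >= 3L, p$clamp_steps >= 1L,
            p$clamp_steps <= p$n_steps, p$r0 >= 0, p$tau_r > 0,
            p$w_max > 0, p$n_triplets >= 1L, p$max_cycles >= 1L,
            p$init_sd >= 0)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<model_params: zeta=%g c=%g eta=%g temp=%g noise=%g ",
    "epsilon=%g delta=%g | K=%d T=%d>\n"),
    x$zeta, x$stdp_c, x$eta, x$temperature, x$noise_sd, x$epsilon,
    x$delta, x$n_assoc, x$n_steps))
  invisible(x)
}

# build a weight set from a parameter bundle
init_weights <- function(params) {
  weight_set(n_assoc = params$n_assoc, zeta = params$zeta,
             stdp_c = params$stdp_c, eta = params$eta,
             w_max = params$w_max, init_sd = params$init_sd)
}

#' Run one task trial of the full architecture
#'
#' The trial loop: a planning cycle is always executed first; the
#' arbitration component then either accepts the simulated action
#' (confident and goal-matching), requests another cycle after punishing
#' the failed sequence's goal weights and lowering the threshold, or
#' hands control to the exploration component.  The chosen action is
#' executed in the environment, the world model learns from the observed
#' (colour, action, feedback) episode, and finally either the goal
#' weights are reinforced (goal achieved; eligibility from the successful
#' cycle, or from the learning replay when the action came from
#' exploration) or the exploration weight of the failed action is
#' punished.  The reaction time is the number of planning cycles
#' executed.
#'
#' @param weights a [weight_set()].
#' @param task a `task_state`.
#' @param colour the trial's stimulus (index or colour `event_code`).
#' @param goal pursued goal unit (1 or 2).
#' @param params a [model_params()].
#' @return a list with `record` (one-row data.frame: stimulus, goal,
#'   action, feedback, goal_met, rt, mode, entropy, threshold),
#'   `weights` and `task` (both updated).
#' @export
run_trial <- function(weights, task, colour, goal,
                      params = model_params()) {
  col_ev <- as_colour_event(colour)
  goal <- as.integer(goal)
  f <- 0L
  planned <- NULL
  repeat {
    cyc <- planning_cycle(weights, col_ev, goal, params)
    dec <- arbitrate(cyc$mean_entropy, f, cyc$readout_outcome, goal,
                     params, has_action = !is.null(cyc$readout_action))
    if (dec$mode == "act_planned") {
      planned <- cyc
      break
    }
    if (dec$mode == "explore") break
    weights <- update_goal_weights(weights, cyc, m = -1, goal)
    f <- f + 1L
  }
  rt <- f + 1L
  mode <- if (is.null(planned)) "explored" else "planned"
  action <- if (mode == "planned") planned$readout_action
            else select_exploration_action(weights$W_explore,
                                           col_ev$index, goal,
                                           params$temperature)
  resp <- respond(task, col_ev$index, action)
  task <- resp$state
  fb <- resp$feedback
  lt <- learn_trial(weights, col_ev, action, fb, goal, params)
  weights <- lt$weights
  met <- goal_achieved(fb, goal)
  if (met) {
    eligible <- if (mode == "planned") planned$fired_units
                else lt$fired_units
    weights <- update_goal_weights(weights, eligible, m = 1, goal)
  } else {
    weights$W_explore <- punish_exploration(weights$W_explore,
                                            col_ev$index, goal, action,
                                            weights$eta, weights$w_max)
  }
  record <- data.frame(stimulus = col_ev$index, goal = goal,
                       action = action$index,
                       feedback = c("correct", "incorrect")[fb$index],
                       goal_met = met, rt = rt, mode = mode,
                       entropy = dec$entropy, threshold = dec$threshold)
  list(record = record, weights = weights, task = task)
}

#' Simulate one participant through both goal phases
#'
#' Phase 1 presents `params$n_triplets` triplets under the goal "achieve
#' a correct feedback"; with `goal_switch = TRUE` a second phase of fresh
#' triplets follows under the goal "achieve an incorrect feedback", with
#' the same persistent colour-action contingencies and the same learned
#' weights.  Fully reproducible from `(params, seed)`.
#'
#' @param params a [model_params()].
#' @param seed integer seed for this participant.
#' @param goal_switch run the second goal phase?
#' @return a data.frame with one row per trial: `trial`, `phase`,
#'   `triplet` (within phase), `trial_in_stim` (the stimulus's running
#'   trial count within the phase), `label` (`"S1"`/`"S2"`/`"S3"`), plus
#'   the [run_trial()] record columns.  The final `task_state` is
#'   attached as attribute `"task"`.
#' @export
run_participant <- function(params = model_params(), seed = 1L,
                            goal_switch = TRUE) {
  set.seed(as.integer(seed))
  weights <- init_weights(params)
  task <- task_state(generate_schedule(params$n_triplets))
  n_phase <- 3L * params$n_triplets
  phases <- if (goal_switch) 1:2 else 1L
  rows <- vector("list", n_phase * length(phases))
  for (phase in phases) {
    if (phase == 2L) task <- extend_schedule(task, params$n_triplets)
    goal <- phase  # phase 1 seeks correct feedback, phase 2 incorrect
    seen <- integer(3L)
    for (i in seq_len(n_phase)) {
      pos <- task$trial_index + 1L
      colour <- task$schedule[pos]
      seen[colour] <- seen[colour] + 1L
      tr <- run_trial(weights, task, colour, goal, params)
      weights <- tr$weights
      task <- tr$task
      rows[[(phase - 1L) * n_phase + i]] <- cbind(
        data.frame(trial = pos, phase = phase,
                   triplet = (i - 1L) %/% 3L + 1L,
                   trial_in_stim = seen[colour]),
        tr$record)
    }
  }
  out <- do.call(rbind, rows)
  out$label <- paste0("S", task$designation[out$stimulus])
  attr(out, "task") <- task
  attr(out, "weights") <- weights
  out
}

#' Simulate a cohort of participants
#'
#' @param params a [model_params()].
#' @param n_participants cohort size.
#' @param seed master seed; participant `i` runs with seed
#'   `seed * 1000 + i` (kept below 2^31).
#' @param goal_switch run the second goal phase for every participant?
#' @return the row-bound participant data.frames with a `participant`
#'   column.
#' @export
run_experiment <- function(params = model_params(), n_participants = 20L,
                           seed = 1L, goal_switch = TRUE) {
  seeds <- participant_seeds(seed, n_participants)
  res <- lapply(seq_len(n_participants), function(i) {
    df <- run_participant(params, seeds[i], goal_switch)
    attr(df, "task") <- NULL
    attr(df, "weights") <- NULL
    cbind(participant = i, df)
  })
  do.call(rbind, res)
}

# derive per-participant seeds from a master seed, within 32-bit range
participant_seeds <- function(seed, n) {
  (as.double(seed) * 1000 + seq_len(n)) %% 2147483647
}
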