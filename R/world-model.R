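# The four-layer generative network: input (10) -> associative (K,
# recurrent) -> output (10), conditioned by a two-unit goal layer.  The
# associative layer learns hidden causes of the observed events and their
# temporal dependencies by STDP; the goal weights are shaped by a bounded
# reinforcement rule so a goal can bias which learnt sequence is sampled.

#' Connection weights of the planning and exploration networks
#'
#' All trainable matrices are stored presynaptic-rows x postsynaptic-cols
#' and start at zero plus a small Gaussian jitter (symmetry breaking; a
#' zero-mean start keeps \eqn{e^{-w} > c} so potentiation is possible from
#' the first trial).  The recurrent matrix has a structurally zero
#' diagonal (no self-connections).  Uses the current RNG stream; seed
#' before calling for reproducibility.
#'
#' @param n_assoc number of associative (hidden-cause) units.
#' @param zeta STDP learning rate.
#' @param stdp_c STDP depression constant, in (0,1); persistent pre->post
#'   co-firing drives a weight to the fixed point \eqn{-\ln c}.
#' @param eta learning rate of the goal/exploration reinforcement rule.
#' @param w_max bound on goal and exploration weights.
#' @param init_sd standard deviation of the initial weight jitter.
#' @return an object of class `weight_set` with matrices `W_in` (10 x
#'   n_assoc), `W_goal` (2 x n_assoc), `W_rec` (n_assoc x n_assoc, zero
#'   diagonal), `W_out` (n_assoc x 10), `W_explore` (6 x 5), and the
#'   learning constants.
#' @export
weight_set <- function(n_assoc = 400, zeta = 0.96, stdp_c = 0.67,
                       eta = 0.008, w_max = 0.5, init_sd = 0.01) {
  n_assoc <- as.integer(n_assoc)
  stopifnot(n_assoc >= 2L, zeta > 0, stdp_c > 0, stdp_c < 1,
            eta > 0, w_max > 0, init_sd >= 0)
  jitter <- function(nr, nc)
    matrix(if (init_sd > 0) rnorm(nr * nc, 0, init_sd) else 0, nr, nc)
  W_rec <- jitter(n_assoc, n_assoc)
  diag(W_rec) <- 0
  ws <- structure(list(
    W_in = jitter(10L, n_assoc),
    W_goal = pmin(pmax(jitter(2L, n_assoc), -w_max), w_max),
    W_rec = W_rec,
    W_out = jitter(n_assoc, 10L),
    W_explore = pmin(pmax(jitter(6L, 5L), -w_max), w_max),
    zeta = zeta, stdp_c = stdp_c, eta = eta, w_max = w_max),
    class = "weight_set")
  validate_weight_set(ws)
}

#' @rdname weight_set
#' @param ws a `weight_set`.
#' @export
validate_weight_set <- function(ws) {
  stopifnot(inherits(ws, "weight_set"))
  K <- ncol(ws$W_in)
  if (!identical(dim(ws$W_rec), c(K, K)) || nrow(ws$W_out) != K ||
      ncol(ws$W_goal) != K || nrow(ws$W_in) != 10L ||
      ncol(ws$W_out) != 10L || !identical(dim(ws$W_explore), c(6L, 5L)))
    stop("inconsistent weight matrix dimensions")
  if (any(diag(ws$W_rec) != 0))
    stop("the recurrent matrix must have a zero diagonal")
  if (any(abs(ws$W_goal) > ws$w_max + 1e-12))
    stop("goal weights exceed w_max")
  if (any(abs(ws$W_explore) > ws$w_max + 1e-12))
    stop("exploration weights exceed w_max")
  if (ws$stdp_c <= 0 || ws$stdp_c >= 1) stop("'stdp_c' must be in (0,1)")
  if (ws$zeta <= 0) stop("'zeta' must be > 0")
  invisible(ws)
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf(
    "<weight_set: %d associative units; zeta=%g, c=%g, eta=%g, w_max=%g>\n",
    ncol(x$W_in), x$zeta, x$stdp_c, x$eta, x$w_max))
  invisible(x)
}

#' One forward-sampling planning cycle
#'
#' Runs the network for `params$n_steps` discrete steps: the input layer is
#' clamped to the observed colour for the first `params$clamp_steps` steps
#' and silent afterwards, the active goal unit (if any) is clamped on
#' throughout, and at each step the associative layer samples one spike
#' under input + goal + recurrent drive while the output layer samples one
#' spike under the drive of the previous associative spike.  No weights
#' are modified.  The simulated action and predicted feedback are read out
#' as the most frequently firing output unit of each category, and the
#' mean normalized entropy of the associative sampling distributions is
#' the world model's uncertainty for this cycle.
#'
#' @param weights a [weight_set()].
#' @param colour the observed colour (index 1-3 or a colour `event_code`).
#' @param goal active goal unit: 1 (seek correct feedback), 2 (seek
#'   incorrect feedback), or 0/`NULL` for goal layer off.
#' @param params a [model_params()].
#' @return an object of class `planning_cycle` with fields `assoc_spikes`
#'   and `out_spikes` (unit indices per step), `distributions` (steps x
#'   n_assoc matrix of pre-sampling probabilities), `readout_action`,
#'   `readout_outcome` (event codes or `NULL`), `mean_entropy` and
#'   `fired_units` (associative units that spiked at least once).
#' @export
planning_cycle <- function(weights, colour, goal, params = model_params()) {
  col_ev <- as_colour_event(colour)
  if (is.null(goal)) goal <- 0L
  goal <- as.integer(goal)
  if (length(goal) != 1L || is.na(goal) || !goal %in% 0:2)
    stop("'goal' must be 1, 2, or 0/NULL for goal layer off")
  K <- ncol(weights$W_in)
  n_out <- ncol(weights$W_out)
  n_steps <- params$n_steps
  nu <- if (isTRUE(params$noise_in_planning)) params$noise_sd else 0
  decay <- exp(-1 / params$tau_r)
  col_drive <- weights$W_in[event_unit(col_ev), ]
  goal_drive <- if (goal > 0L) weights$W_goal[goal, ] else numeric(K)
  sub_a <- numeric(K)
  sub_o <- numeric(n_out)
  dists <- matrix(0, n_steps, K)
  assoc <- integer(n_steps)
  out <- integer(n_steps)
  kprev <- 0L
  for (t in seq_len(n_steps)) {
    u <- goal_drive
    if (t <= params$clamp_steps) u <- u + col_drive
    if (kprev > 0L) u <- u + weights$W_rec[kprev, ]
    u <- u - sub_a
    if (nu > 0) u <- u + rnorm(K, 0, nu)
    p <- competitive_distribution(u / params$temperature)
    k <- sample.int(K, 1L, prob = p)
    uo <- if (kprev > 0L) weights$W_out[kprev, ] else numeric(n_out)
    uo <- uo - sub_o
    if (nu > 0) uo <- uo + rnorm(n_out, 0, nu)
    o <- sample.int(n_out, 1L,
                    prob = competitive_distribution(uo /
                                                    params$temperature))
    dists[t, ] <- p
    assoc[t] <- k
    out[t] <- o
    sub_a <- sub_a * decay
    sub_a[k] <- params$r0
    sub_o <- sub_o * decay
    sub_o[o] <- params$r0
    kprev <- k
  }
  structure(list(assoc_spikes = assoc, out_spikes = out,
                 distributions = dists,
                 readout_action = readout(out, "action"),
                 readout_outcome = readout(out, "feedback"),
                 mean_entropy = normalized_entropy(dists),
                 fired_units = sort(unique(assoc))),
            class = "planning_cycle")
}

#' @export
print.planning_cycle <- function(x, ...) {
  act <- if (is.null(x$readout_action)) "none" else x$readout_action$index
  fb <- if (is.null(x$readout_outcome)) "none"
        else c("correct", "incorrect")[x$readout_outcome$index]
  cat(sprintf(
    "<planning_cycle: %d steps, action=%s, outcome=%s, entropy=%.3f>\n",
    length(x$assoc_spikes), act, fb, x$mean_entropy))
  invisible(x)
}

#' Read an event out of an output spike train
#'
#' The event generated by a planning cycle is the output unit of the
#' requested category that fired the most during the cycle.  Ties are
#' broken uniformly at random; if no spike fell in the category the
#' readout is `NULL`.
#'
#' @param out_spikes integer vector of output unit indices (1-10), one per
#'   step.
#' @param category `"action"`, `"feedback"` or `"colour"`.
#' @return an `event_code`, or `NULL`.
#' @export
readout <- function(out_spikes, category = c("action", "feedback",
                                             "colour")) {
  category <- match.arg(category)
  rng <- switch(category, colour = 1:3, action = 4:8, feedback = 9:10)
  counts <- tabulate(as.integer(out_spikes), nbins = 10L)[rng]
  if (all(counts == 0L)) return(NULL)
  winners <- which(counts == max(counts))
  w <- if (length(winners) > 1L)
    winners[sample.int(length(winners), 1L)] else winners
  event_code(category, w)
}

#' STDP weight increment
#'
#' The post-gated spike-timing-dependent rule
#' \eqn{\Delta w = \zeta \, s_{post} (e^{-w} s_{pre} - c)}: nothing
#' changes unless the postsynaptic unit fires; a presynaptic spike one
#' step earlier drives the weight towards the fixed point \eqn{-\ln c},
#' and a silent presynaptic unit depresses it by \eqn{\zeta c}.
#' Vectorised over `w` and `s_pre`.
#'
#' @param w current weight(s).
#' @param s_post postsynaptic spike at the current step (0/1 scalar).
#' @param s_pre presynaptic spike(s) at the previous step (0/1).
#' @param zeta learning rate.
#' @param stdp_c depression constant in (0,1).
#' @return weight increment(s).
#' @export
stdp_delta <- function(w, s_post, s_pre, zeta, stdp_c) {
  zeta * s_post * (exp(-w) * s_pre - stdp_c)
}

# input-layer unit schedule of a driven 15-step trial replay:
# colour | action | feedback, in equal thirds
trial_unit_schedule <- function(colour, action, outcome, n_steps) {
  if (n_steps %% 3L != 0L)
    stop("'n_steps' must be divisible by 3 for the trial replay")
  seg <- n_steps %/% 3L
  rep(c(event_unit(colour), event_unit(action), event_unit(outcome)),
      each = seg)
}

#' Unsupervised learning from one experienced trial
#'
#' Replays the trial as a driven episode: the input layer is clamped to
#' the observed colour, executed action and received feedback in equal
#' thirds of the `params$n_steps` steps; the goal unit is clamped on
#' (configurable via `params$goal_in_learning`); the associative layer
#' free-runs under this drive; and the output layer is clamped to the
#' same event schedule (teacher forcing).  The STDP rule is applied per
#' step to the input->associative, recurrent and associative->output
#' weights, with the presynaptic signal equal to the drive that produced
#' each postsynaptic spike.  The recurrent diagonal is forced back to
#' zero after every update and the goal weights are never touched here.
#'
#' @param weights a [weight_set()].
#' @param colour,action,outcome the experienced events (indices or
#'   `event_code`s).
#' @param goal the active goal unit (1 or 2).
#' @param params a [model_params()].
#' @return a list with `weights` (the updated `weight_set`) and
#'   `fired_units` (associative units that spiked during the replay: the
#'   eligibility trace of the executed sequence).
#' @export
learn_trial <- function(weights, colour, action, outcome, goal,
                        params = model_params()) {
  col_ev <- as_colour_event(colour)
  act_ev <- as_action_event(action)
  out_ev <- as_feedback_event(outcome)
  goal <- as.integer(goal)
  if (!goal %in% 1:2) stop("'goal' must be 1 or 2")
  K <- ncol(weights$W_in)
  n_steps <- params$n_steps
  sched <- trial_unit_schedule(col_ev, act_ev, out_ev, n_steps)
  nu <- if (isTRUE(params$noise_in_learning)) params$noise_sd else 0
  decay <- exp(-1 / params$tau_r)
  zeta <- weights$zeta
  cc <- weights$stdp_c
  goal_drive <- if (isTRUE(params$goal_in_learning))
    weights$W_goal[goal, ] else numeric(K)
  sub_a <- numeric(K)
  fired <- logical(K)
  kprev <- 0L
  for (t in seq_len(n_steps)) {
    iu <- sched[t]
    u <- weights$W_in[iu, ] + goal_drive
    if (kprev > 0L) u <- u + weights$W_rec[kprev, ]
    u <- u - sub_a
    if (nu > 0) u <- u + rnorm(K, 0, nu)
    k <- sample.int(K, 1L,
                    prob = competitive_distribution(u /
                                                    params$temperature))
    fired[k] <- TRUE
    # STDP, post = sampled associative spike, pre = the drive pattern
    pre_in <- one_hot(iu, 10L)
    weights$W_in[, k] <- weights$W_in[, k] +
      stdp_delta(weights$W_in[, k], 1L, pre_in, zeta, cc)
    if (kprev > 0L) {
      pre_a <- one_hot(kprev, K)
      weights$W_rec[, k] <- weights$W_rec[, k] +
        stdp_delta(weights$W_rec[, k], 1L, pre_a, zeta, cc)
      weights$W_rec[k, k] <- 0
      # output teacher-forced to the scheduled event
      weights$W_out[, iu] <- weights$W_out[, iu] +
        stdp_delta(weights$W_out[, iu], 1L, pre_a, zeta, cc)
    }
    sub_a <- sub_a * decay
    sub_a[k] <- params$r0
    kprev <- k
  }
  list(weights = weights, fired_units = which(fired))
}

#' Goal-weight reinforcement increment
#'
#' The bounded reinforcement rule
#' \eqn{\Delta w = \eta\, m\, ET_k \frac{w_{max} - |w|}{w_{max}} s_g}:
#' a pseudo-reward `m` of +1 (goal achieved in the environment) or -1
#' (failed planning cycle) moves the weights of eligible associative
#' units towards the corresponding bound, with a step that vanishes as
#' the bound is approached.  Vectorised over `w_kg` and `et`.
#'
#' @param w_kg current goal->associative weight(s); must satisfy
#'   `|w_kg| <= w_max`.
#' @param m pseudo-reward, -1 or +1.
#' @param et eligibility trace (0/1): did the unit fire during the
#'   cycle/trial?
#' @param s_g activity of the goal neuron (0/1).
#' @param eta learning rate.
#' @param w_max weight bound.
#' @return increment(s); the caller clips the updated weight to
#'   `[-w_max, w_max]`.
#' @export
goal_weight_delta <- function(w_kg, m, et, s_g, eta, w_max) {
  if (!m %in% c(-1, 1)) stop("'m' must be -1 or +1")
  if (any(abs(w_kg) > w_max + 1e-9))
    stop("goal weight outside [-w_max, w_max] on entry")
  eta * m * et * ((w_max - abs(w_kg)) / w_max) * s_g
}

#' Apply the goal-weight reinforcement rule to a weight set
#'
#' Updates the active goal's row of the goal->associative matrix using
#' the eligibility trace of a planning cycle (or an explicit set of fired
#' units), then clips to the bound.  The inactive goal's row is never
#' modified.
#'
#' @param weights a [weight_set()].
#' @param cycle a `planning_cycle` (its `fired_units` are used) or an
#'   integer vector of associative units eligible for the update.
#' @param m pseudo-reward: -1 after a failed planning cycle, +1 only
#'   after goal achievement in the environment.
#' @param goal the active goal unit (1 or 2).
#' @return the updated `weight_set`.
#' @export
update_goal_weights <- function(weights, cycle, m, goal) {
  goal <- as.integer(goal)
  if (!goal %in% 1:2) stop("'goal' must be 1 or 2")
  fired <- if (inherits(cycle, "planning_cycle"))
    cycle$fired_units else as.integer(cycle)
  K <- ncol(weights$W_goal)
  et <- numeric(K)
  et[fired] <- 1
  row <- weights$W_goal[goal, ]
  row <- row + goal_weight_delta(row, m, et, 1, weights$eta, weights$w_max)
  weights$W_goal[goal, ] <- pmin(pmax(row, -weights$w_max), weights$w_max)
  weights
}
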