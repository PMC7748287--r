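# Discrete-time stochastic winner-take-all layer mechanics shared by the
# associative and output layers.  At every step a layer turns its membrane
# potentials into a categorical distribution through a softmax (abstracting
# lateral-inhibition competition) and emits exactly one spike.

#' Parameters of a stochastic winner-take-all spiking layer
#'
#' @param n_units number of units in the layer (>= 1).
#' @param noise_sd standard deviation of the i.i.d. Gaussian noise added to
#'   each unit's membrane potential at every step; 0 disables noise.
#' @param r0 refractory amplitude: the potential subtracted from a unit at
#'   the step right after it spiked (dimensionless potential units).
#' @param tau_r refractory decay constant, in time steps.
#' @return an object of class `layer_params`.
#' @export
layer_params <- function(n_units, noise_sd = 0, r0 = 1.1, tau_r = 9.5) {
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1L) stop("'n_units' must be >= 1")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (r0 < 0) stop("'r0' must be >= 0")
  if (tau_r <= 0) stop("'tau_r' must be > 0")
  structure(list(n_units = n_units, noise_sd = noise_sd,
                 r0 = r0, tau_r = tau_r),
            class = "layer_params")
}

#' Fresh state of a spiking layer
#'
#' Units start with zero potential and have never fired (`last_spike_age`
#' is `NA`, which yields a zero refractory subtraction).
#'
#' @param n_units number of units.
#' @return an object of class `layer_state` with fields `potentials`,
#'   `last_spike_age` and `spike`.
#' @export
layer_state <- function(n_units) {
  n_units <- as.integer(n_units)
  structure(list(potentials = numeric(n_units),
                 last_spike_age = rep(NA_real_, n_units),
                 spike = integer(n_units)),
            class = "layer_state")
}

#' Total activation received by a layer
#'
#' Computes the summed synaptic drive \eqn{\hat u_k = \sum_i w_{ki} s_i}
#' for every target unit \eqn{k}, given one or several source layers.
#' Weight matrices are oriented with one row per target unit (columns are
#' presynaptic sources).
#'
#' @param weight_rows a matrix (targets x sources), or a list of such
#'   matrices, one per source layer.
#' @param incoming_spikes a binary spike vector, or a list of vectors
#'   matching `weight_rows`.
#' @return numeric vector of potentials, one per target unit.
#' @export
total_activation <- function(weight_rows, incoming_spikes) {
  if (is.matrix(weight_rows)) {
    weight_rows <- list(weight_rows)
    incoming_spikes <- list(incoming_spikes)
  }
  if (length(weight_rows) != length(incoming_spikes))
    stop("'weight_rows' and 'incoming_spikes' must have the same length")
  u <- NULL
  for (i in seq_along(weight_rows)) {
    W <- weight_rows[[i]]
    s <- incoming_spikes[[i]]
    if (!is.matrix(W)) stop("weight_rows[[", i, "]] is not a matrix")
    if (ncol(W) != length(s))
      stop("dimension mismatch: weight matrix ", i, " has ", ncol(W),
           " columns but received ", length(s), " incoming spikes")
    ui <- drop(W %*% s)
    u <- if (is.null(u)) ui else {
      if (length(ui) != length(u))
        stop("weight matrices disagree on the number of target units")
      u + ui
    }
  }
  u
}

#' Lateral-inhibition competition as a softmax
#'
#' Maps membrane potentials to the categorical spiking distribution
#' \eqn{p_k = e^{\hat u_k} / \sum_l e^{\hat u_l}}, the abstraction of a
#' winner-take-all competition through common inhibition.  Implemented
#' with max-subtraction so it is invariant to adding a constant to all
#' potentials and safe against overflow.
#'
#' @param potentials numeric vector of membrane potentials (finite).
#' @return a probability vector summing to 1.
#' @export
competitive_distribution <- function(potentials) {
  if (length(potentials) == 0L) stop("'potentials' must be non-empty")
  if (anyNA(potentials) || any(!is.finite(potentials)))
    stop("'potentials' must be finite")
  e <- exp(potentials - max(potentials))
  e / sum(e)
}

#' Draw one spike from a categorical spiking distribution
#'
#' @param probs probability vector (non-negative, summing to 1 within
#'   1e-9).
#' @return a one-hot integer vector with a single 1 at the sampled unit.
#' @export
sample_spike <- function(probs) {
  if (any(probs < 0)) stop("negative probability")
  if (abs(sum(probs) - 1) > 1e-9) stop("'probs' must sum to 1")
  one_hot(sample.int(length(probs), 1L, prob = probs), length(probs))
}

#' Refractory potential subtraction
#'
#' A unit that spiked `age` steps ago has \eqn{r_0 e^{-age/\tau}}
#' subtracted from its potential; `age = 0` denotes the step right after
#' the spike.  Units that never fired (`NA` age) get zero subtraction.
#'
#' @param age steps since the unit's own last spike (vectorised; `NA` for
#'   never fired).
#' @param r0 refractory amplitude.
#' @param tau_r decay constant in steps.
#' @return refractory subtraction values, same length as `age`.
#' @export
refractory_term <- function(age, r0 = 1.1, tau_r = 9.5) {
  if (any(age < 0, na.rm = TRUE)) stop("'age' must be >= 0")
  r <- r0 * exp(-age / tau_r)
  r[is.na(age)] <- 0
  r
}

#' Advance a winner-take-all layer by one discrete step
#'
#' Composes the layer mechanics: synaptic drive, refractory subtraction,
#' Gaussian potential noise, softmax competition and categorical spike
#' sampling (or an externally clamped spike).  The pre-sampling
#' distribution is retained in the returned state (`$dist`) because the
#' arbitration mechanism consumes it.
#'
#' @param state a `layer_state`.
#' @param params a `layer_params`.
#' @param weight_rows,incoming_spikes passed to [total_activation()].
#' @param clamp optional one-hot vector forcing the spike (driven layers);
#'   `NULL` for free-running sampling.
#' @return the updated `layer_state`, with elements `potentials` (after
#'   refractory and noise), `dist` (pre-sampling distribution), `spike`
#'   and `last_spike_age`.
#' @export
step_layer <- function(state, params, weight_rows, incoming_spikes,
                       clamp = NULL) {
  u <- total_activation(weight_rows, incoming_spikes)
  if (length(u) != params$n_units)
    stop("weight matrices target ", length(u), " units but the layer has ",
         params$n_units)
  u <- u - refractory_term(state$last_spike_age, params$r0, params$tau_r)
  if (params$noise_sd > 0)
    u <- u + rnorm(length(u), 0, params$noise_sd)
  p <- competitive_distribution(u)
  if (is.null(clamp)) {
    s <- sample_spike(p)
  } else {
    clamp <- as.integer(clamp)
    if (length(clamp) != params$n_units || any(!clamp %in% c(0L, 1L)) ||
        sum(clamp) != 1L)
      stop("'clamp' must be a one-hot vector over the layer's units")
    s <- clamp
  }
  age <- state$last_spike_age + 1
  age[s == 1L] <- 0
  structure(list(potentials = u, last_spike_age = age, spike = s, dist = p),
            class = "layer_state")
}
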