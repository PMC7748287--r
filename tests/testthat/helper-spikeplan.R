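# Shared fixtures, all built in code.

# small network for fast protocol-level tests
quick_params <- function(...) model_params(n_assoc = 100L, ...)

# Deterministic hand-built chain: colour 1 drives associative units 1..15
# in sequence; units 1-5 reconstruct the colour, 6-10 emit action 3
# (output unit 6), 11-15 emit "correct" (output unit 9).  Weights of +2
# are ~100 nats at the default temperature, so the chain is effectively
# deterministic despite noise.
chain_weights <- function(params = model_params()) {
  ws <- weight_set(n_assoc = params$n_assoc, zeta = params$zeta,
                   stdp_c = params$stdp_c, eta = params$eta,
                   w_max = params$w_max, init_sd = 0)
  ws$W_in[1, 1] <- 2
  for (k in 1:14) ws$W_rec[k, k + 1] <- 2
  for (k in 1:15) {
    out_unit <- if (k <= 5) 1L else if (k <= 10) 6L else 9L
    ws$W_out[k, out_unit] <- 2
  }
  ws
}

# train one fixed continuation repeatedly
train_repeated <- function(ws, colour, action, outcome, goal, params,
                           n = 60L) {
  for (i in seq_len(n))
    ws <- learn_trial(ws, colour, action, outcome, goal, params)$weights
  ws
}

# readout-action frequencies over repeated planning cycles
readout_action_freq <- function(ws, colour, goal, params, n_cycles) {
  counts <- integer(5L)
  none <- 0L
  for (i in seq_len(n_cycles)) {
    a <- planning_cycle(ws, colour, goal, params)$readout_action
    if (is.null(a)) none <- none + 1L
    else counts[a$index] <- counts[a$index] + 1L
  }
  list(freq = counts / n_cycles, none = none / n_cycles)
}
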