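test_that("stdp_delta implements the post-gated rule", {
  z <- 0.96
  cc <- 0.67
  expect_equal(stdp_delta(-log(cc), 1, 1, z, cc), 0)
  expect_equal(stdp_delta(0.2, 1, 0, z, cc), -z * cc)
  expect_equal(stdp_delta(0.7, 0, 1, z, cc), 0)
  expect_equal(stdp_delta(0, 1, 1, z, cc), z * (1 - cc))
  # vectorised over weights and pre spikes
  expect_equal(stdp_delta(c(0, -log(cc)), 1, c(1, 1), z, cc),
               c(z * (1 - cc), 0))
})

test_that("persistent co-firing drives weights to the -ln(c) fixed point", {
  set.seed(3)
  for (i in 1:20) {
    z <- runif(1, 0.1, 1)
    cc <- runif(1, 0.1, 0.9)
    w <- runif(1, -1, -log(cc) - 0.05)  # start below the fixed point
    # iterate long enough for the worst-case contraction rate 1 - zeta*c
    for (t in 1:5000) w <- w + stdp_delta(w, 1, 1, z, cc)
    expect_equal(w, -log(cc), tolerance = 1e-3)
  }
})

test_that("weight_set enforces its structural invariants", {
  set.seed(1)
  ws <- weight_set(n_assoc = 50)
  expect_identical(dim(ws$W_rec), c(50L, 50L))
  expect_true(all(diag(ws$W_rec) == 0))
  expect_true(all(abs(ws$W_goal) <= ws$w_max))
  bad <- ws
  bad$W_rec[2, 2] <- 0.1
  expect_error(validate_weight_set(bad), "zero diagonal")
  bad2 <- ws
  bad2$W_goal[1, 1] <- 0.6
  expect_error(validate_weight_set(bad2), "w_max")
})

test_that("planning cycles run 15 steps, one spike per step, purely", {
  set.seed(10)
  pars <- quick_params()
  ws <- init_weights(pars)
  before <- ws
  cyc <- planning_cycle(ws, 2, 1, pars)
  expect_identical(ws, before)  # no weight mutation
  expect_length(cyc$assoc_spikes, 15L)
  expect_length(cyc$out_spikes, 15L)
  expect_identical(dim(cyc$distributions), c(15L, pars$n_assoc))
  expect_true(all(cyc$assoc_spikes %in% seq_len(pars$n_assoc)))
  expect_equal(rowSums(cyc$distributions), rep(1, 15), tolerance = 1e-9)
  expect_true(all(cyc$fired_units %in% cyc$assoc_spikes))
  expect_error(planning_cycle(ws, 2, 5, pars), "goal")
})

test_that("an untrained world model is near-maximally uncertain", {
  pars <- model_params(noise_in_planning = FALSE, init_sd = 0)
  set.seed(2)
  ws <- init_weights(pars)
  H <- replicate(5, planning_cycle(ws, 1, 1, pars)$mean_entropy)
  expect_true(all(H > 0.95))
})

test_that("a hand-built chain plans the embedded action and outcome", {
  pars <- model_params()
  ws <- chain_weights(pars)
  set.seed(4)
  for (i in 1:10) {
    cyc <- planning_cycle(ws, 1, 1, pars)
    expect_equal(cyc$assoc_spikes, 1:15)
    expect_equal(cyc$readout_action$index, 3L)
    expect_equal(cyc$readout_outcome$index, 1L)
    expect_lt(cyc$mean_entropy, 0.1)
  }
})

test_that("readout picks the most active unit of a category", {
  # action units are 4-8: unit 5 fired the most
  expect_equal(readout(c(5, 5, 5, 5, 5, 6, 1, 1), "action")$index, 2L)
  expect_null(readout(c(1, 2, 3, 9), "action"))
  expect_equal(readout(c(9, 9, 10), "feedback")$index, 1L)
  # ties are broken uniformly at random
  set.seed(8)
  picks <- replicate(2000, readout(c(9, 10), "feedback")$index)
  expect_lt(abs(mean(picks == 1L) - 0.5), 4 * sqrt(0.25 / 2000))
})

test_that("learning preserves the zero recurrent diagonal", {
  set.seed(20)
  pars <- quick_params()
  ws <- init_weights(pars)
  for (i in 1:50) {
    ws <- learn_trial(ws, sample(3, 1), sample(5, 1),
                      sample(c("correct", "incorrect"), 1),
                      sample(2, 1), pars)$weights
    expect_true(all(diag(ws$W_rec) == 0))
  }
})

test_that("a repeatedly experienced trial becomes the planned readout", {
  set.seed(7)
  pars <- quick_params()
  ws <- train_repeated(init_weights(pars), 1, 2, "correct", 1, pars, 60)
  # most-reused STDP pairs sit at the fixed point
  expect_equal(max(ws$W_in), -log(pars$stdp_c), tolerance = 0.05)
  res <- readout_action_freq(ws, 1, 1, pars, 100)
  expect_gte(res$freq[2], 0.8)
  # and the trained model is confident
  expect_lt(planning_cycle(ws, 1, 1, pars)$mean_entropy, 0.5)
})

test_that("goal_weight_delta follows the bounded reinforcement rule", {
  expect_equal(goal_weight_delta(0, 1, 1, 1, 0.008, 0.5), 0.008)
  expect_equal(goal_weight_delta(0.5, 1, 1, 1, 0.008, 0.5), 0)
  expect_equal(goal_weight_delta(-0.5, -1, 1, 1, 0.008, 0.5), 0)
  expect_equal(goal_weight_delta(0.2, 1, 0, 1, 0.008, 0.5), 0)
  expect_equal(goal_weight_delta(0.2, 1, 1, 0, 0.008, 0.5), 0)
  expect_error(goal_weight_delta(0.6, 1, 1, 1, 0.008, 0.5),
               "outside")
  expect_error(goal_weight_delta(0, 2, 1, 1, 0.008, 0.5), "-1 or \\+1")
})

test_that("goal-weight updates gate on eligibility and stay bounded", {
  set.seed(5)
  ws <- weight_set(n_assoc = 30, init_sd = 0)
  fired <- c(3L, 7L, 20L)
  ws2 <- update_goal_weights(ws, fired, m = 1, goal = 1)
  expect_true(all(ws2$W_goal[1, fired] > 0))
  expect_equal(ws2$W_goal[1, -fired], rep(0, 27))
  expect_equal(ws2$W_goal[2, ], ws$W_goal[2, ])  # inactive goal untouched

  # unbounded repetition converges to +w_max and never exceeds it
  for (i in 1:5000) ws2 <- update_goal_weights(ws2, fired, 1, 1)
  expect_true(all(abs(ws2$W_goal) <= ws2$w_max))
  expect_equal(ws2$W_goal[1, fired], rep(ws2$w_max, 3),
               tolerance = 1e-6)

  # arbitrary +-1 interleavings respect the bound
  set.seed(6)
  w <- 0
  for (i in 1:10000) {
    w <- w + goal_weight_delta(w, sample(c(-1, 1), 1), 1, 1, 0.4, 0.5)
    w <- min(max(w, -0.5), 0.5)
    expect_lte(abs(w), 0.5)
  }
})

test_that("planning cycles accept an inactive goal layer", {
  set.seed(9)
  pars <- quick_params()
  ws <- init_weights(pars)
  cyc <- planning_cycle(ws, 1, NULL, pars)
  expect_s3_class(cyc, "planning_cycle")
  expect_length(cyc$assoc_spikes, 15L)
})

test_that("two trained continuations of one colour both remain sampled", {
  # goal-off branching: the world model keeps both futures alive
  set.seed(11)
  pars <- model_params()
  ws <- init_weights(pars)
  for (i in 1:30) {
    ws <- learn_trial(ws, 1, 1, "correct", 1, pars)$weights
    ws <- learn_trial(ws, 1, 2, "incorrect", 1, pars)$weights
  }
  res <- readout_action_freq(ws, 1, 0, pars, 200)
  expect_gte(res$freq[1], 0.05)
  expect_gte(res$freq[2], 0.05)
})
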