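test_that("total_activation sums weighted incoming spikes", {
  W <- rbind(c(1, 2), c(3, 4))
  expect_equal(total_activation(W, c(0, 0)), c(0, 0))
  # a single source spike selects the corresponding weight column
  expect_equal(total_activation(W, c(0, 1)), W[, 2])
  expect_equal(total_activation(W, c(1, 1)), c(3, 7))
  # multiple source layers add up
  expect_equal(total_activation(list(W, diag(2)), list(c(1, 1), c(1, 0))),
               c(4, 7))
  expect_error(total_activation(W, c(1, 0, 0)), "dimension mismatch")
})

test_that("competitive_distribution is the shift-invariant softmax", {
  expect_equal(competitive_distribution(rep(0.3, 7)), rep(1 / 7, 7))
  expect_equal(competitive_distribution(c(log(2), 0)), c(2 / 3, 1 / 3))
  set.seed(1)
  for (i in 1:20) {
    u <- rnorm(sample(2:50, 1), sd = 10)
    p <- competitive_distribution(u)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(competitive_distribution(u + 100), p, tolerance = 1e-12)
  }
  # overflow-safe for huge potentials
  expect_equal(competitive_distribution(c(1e4, 1e4)), c(0.5, 0.5))
  expect_error(competitive_distribution(numeric(0)), "non-empty")
  expect_error(competitive_distribution(c(1, NaN)), "finite")
})

test_that("sample_spike draws a reproducible one-hot categorical spike", {
  expect_equal(sample_spike(c(0, 1, 0)), c(0L, 1L, 0L))
  set.seed(42)
  draws <- replicate(10000, sample_spike(c(0.5, 0.5))[1])
  # binomial oracle: within 4 SD of 0.5 (SD = sqrt(0.25/10000) = 0.005)
  expect_lt(abs(mean(draws) - 0.5), 4 * 0.005)
  set.seed(7)
  for (i in 1:10) {
    p <- competitive_distribution(rnorm(5))
    expect_equal(sum(sample_spike(p)), 1L)
  }
  expect_error(sample_spike(c(-0.1, 1.1)), "negative")
  expect_error(sample_spike(c(0.5, 0.4)), "sum to 1")
})

test_that("spike frequencies match the analytic distribution", {
  p <- c(0.5, 0.3, 0.15, 0.05)
  set.seed(99)
  idx <- replicate(10000, which(sample_spike(p) == 1L))
  gof <- chisq.test(tabulate(idx, 4L), p = p)
  expect_gt(gof$p.value, 0.001)
})

test_that("refractory subtraction decays exponentially from r0", {
  expect_equal(refractory_term(0, 1.1, 9.5), 1.1)
  expect_equal(refractory_term(9.5, 1.1, 9.5), 1.1 * exp(-1))
  ages <- 0:50
  r <- refractory_term(ages, 1.1, 9.5)
  expect_true(all(diff(r) < 0))
  expect_lt(r[51], 0.01)
  # never-fired units get no subtraction
  expect_equal(refractory_term(c(NA, 3), 1.1, 9.5),
               c(0, 1.1 * exp(-3 / 9.5)))
  expect_error(refractory_term(-1), ">= 0")
})

test_that("step_layer composes drive, refractory, noise and competition", {
  lp <- layer_params(4, noise_sd = 0)
  st <- layer_state(4)
  W <- matrix(0, 4, 2)
  out <- step_layer(st, lp, W, c(1, 0))
  expect_equal(out$dist, rep(0.25, 4))
  expect_equal(sum(out$spike), 1L)
  expect_equal(out$last_spike_age[out$spike == 1L], 0)

  # with no noise and no refractory history the distribution is exactly
  # the closed-form softmax of the drive
  W2 <- matrix(c(1, 0, 2, 0.5, 0, 1, 0, 0), 4, 2)
  out2 <- step_layer(layer_state(4), lp, W2, c(1, 1))
  expect_equal(out2$dist,
               competitive_distribution(drop(W2 %*% c(1, 1))))

  # clamp overrides sampling regardless of potentials
  out3 <- step_layer(layer_state(4), lp, W2 * 100, c(1, 1),
                     clamp = c(0, 0, 0, 1))
  expect_equal(out3$spike, c(0L, 0L, 0L, 1L))
  expect_error(step_layer(st, lp, W, c(1, 0), clamp = c(1, 1, 0, 0)),
               "one-hot")

  # a unit that just spiked is handicapped by r0*exp(0)
  st4 <- layer_state(4)
  st4$last_spike_age[1] <- 0
  out4 <- step_layer(st4, lp, W, c(1, 0))
  expect_lt(out4$dist[1], 0.25)
  expect_equal(out4$dist,
               competitive_distribution(c(-1.1, 0, 0, 0)))
})
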