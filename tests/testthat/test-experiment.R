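test_that("a session produces 120 reproducible trials, 60 per goal", {
  pars <- quick_params()
  p1 <- run_participant(pars, seed = 123)
  p2 <- run_participant(pars, seed = 123)
  expect_equal(nrow(p1), 120L)
  expect_equal(as.integer(table(p1$goal)), c(60L, 60L))
  attr(p1, "task") <- attr(p1, "weights") <- NULL
  attr(p2, "task") <- attr(p2, "weights") <- NULL
  expect_identical(p1, p2)
  expect_true(all(p1$label %in% c("S1", "S2", "S3")))
  expect_true(all(p1$rt >= 1L))
})

test_that("reaction times respect the threshold-schedule bound", {
  pars <- quick_params()
  p <- run_participant(pars, seed = 31)
  expect_lte(max(p$rt), ceiling(pars$epsilon / pars$delta) + 1L)
})

test_that("a fresh model explores; a goal-matching chain plans at once", {
  pars <- model_params()
  set.seed(17)
  explored <- replicate(12, {
    ws <- init_weights(pars)
    task <- task_state(generate_schedule(20))
    run_trial(ws, task, task$schedule[1], 1, pars)$record$mode
  })
  expect_gte(mean(explored == "explored"), 0.95)

  # deterministic chain predicting the pursued goal: planned, one cycle
  ws <- chain_weights(pars)
  task <- task_state(rep(c(1, 2, 3), 20))  # colour 1 first
  tr <- run_trial(ws, task, 1, 1, pars)
  expect_equal(tr$record$mode, "planned")
  expect_equal(tr$record$rt, 1L)
  expect_equal(tr$record$action, 3L)
})

test_that("pearson matches its closed form and the stats oracle", {
  expect_equal(pearson(c(1, 5, 9), c(1, 5, 9)), 1)
  x <- c(2, 4, 9, 1)
  expect_equal(pearson(x, mean(x) - (x - mean(x))), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 0.98198051,
               tolerance = 1e-7)
  set.seed(2)
  a <- rnorm(15)
  b <- rnorm(15)
  expect_equal(pearson(a, b), cor(a, b))
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1:4, 1:5), "equal length")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("representative steps align the three stimuli", {
  expect_equal(representative_step("S1", 1:4), c(1L, 2L, 6L, 7L))
  expect_equal(representative_step("S2", 1:6), c(1L, 2L, 3L, 4L, 6L, 7L))
  expect_equal(representative_step("S3", 1:6), 1:6)
  # step 5 is reachable by S3 only
  steps <- lapply(c("S1", "S2", "S3"),
                  function(l) representative_step(l, 1:20))
  expect_false(5L %in% steps[[1]])
  expect_false(5L %in% steps[[2]])
  expect_true(5L %in% steps[[3]])
})

test_that("aggregation reproduces the ideal-agent protocol curves", {
  # two identical idealised participants, assembled record-by-record
  make_ideal_records <- function(seed, participant) {
    set.seed(seed)
    ia <- run_ideal_agent(task_state(generate_schedule(20)))
    r <- ia$records
    seen <- stats::ave(r$colour, r$colour, FUN = seq_along)
    data.frame(participant = participant, trial = r$trial, phase = 1L,
               triplet = r$triplet, trial_in_stim = seen,
               stimulus = r$colour, goal = 1L, action = r$action,
               feedback = r$feedback,
               goal_met = r$feedback == "correct", rt = 1L,
               mode = "explored", entropy = 1, threshold = 0.74,
               label = paste0("S", ia$state$designation[r$colour]))
  }
  rec <- rbind(make_ideal_records(42, 1), make_ideal_records(42, 2))
  perf <- aggregate_performance(rec, "correct", phase = 1)
  s1 <- perf[perf$label == "S1", ]
  expect_equal(s1$mean[s1$triplet == 1], 0)
  expect_true(all(s1$mean[s1$triplet >= 2] == 1))
  expect_true(all(perf$mean >= 0 & perf$mean <= 1))
  expect_true(all(perf$se == 0))  # identical participants
  rt <- aggregate_rt(rec, phase = 1)
  expect_true(all(rt$mean == 1))
  expect_true(all(diff(rt$step) > 0))
})

test_that("fitness of a model against its own curves is 1", {
  pars <- quick_params()
  rec <- run_experiment(pars, n_participants = 3, seed = 9,
                        goal_switch = FALSE)
  perf <- aggregate_performance(rec, "correct", 1)
  rt <- aggregate_rt(rec, 1)
  self_ref <- list(
    performance = data.frame(label = perf$label, triplet = perf$triplet,
                             value = perf$mean),
    rt = data.frame(step = rt$step, value = rt$mean))
  fit <- fitness(pars, self_ref, n_participants = 3, seed = 9)
  expect_equal(as.numeric(fit), 1, tolerance = 1e-12)
  expect_length(attr(fit, "correlations"), 4L)
})

test_that("the fitted model correlates positively with a rising synthetic reference", {
  ref <- synthetic_reference(seed = 1)
  fit <- fitness(model_params(), ref, n_participants = 5, seed = 2)
  expect_gt(as.numeric(fit), 0)
})

test_that("parameter_search samples within ranges and ranks by fitness", {
  ranges <- list(zeta = c(0.5, 1), epsilon = c(0.5, 0.9))
  res <- parameter_search(ranges, n_combos = 4, n_participants = 2,
                          reference = synthetic_reference(seed = 3),
                          seed = 5, params_base = quick_params())
  expect_equal(nrow(res), 4L)
  expect_true(all(res$zeta >= 0.5 & res$zeta <= 1))
  expect_true(all(res$epsilon >= 0.5 & res$epsilon <= 0.9))
  expect_true(all(diff(res$fitness) <= 0))
  one <- parameter_search(list(zeta = c(0.9, 1)), n_combos = 1,
                          n_participants = 2,
                          reference = synthetic_reference(seed = 3),
                          seed = 6, params_base = quick_params())
  expect_equal(nrow(one), 1L)
  expect_true(is.finite(one$fitness))
  expect_error(parameter_search(list(bogus = c(0, 1)), 1, 1), "unknown")
})

test_that("weight sets and trial logs round-trip through plain text", {
  set.seed(12)
  ws <- weight_set(n_assoc = 20)
  dir <- withr::local_tempdir()
  write_weight_set(ws, dir)
  ws2 <- read_weight_set(dir)
  for (nm in c("W_in", "W_goal", "W_rec", "W_out", "W_explore"))
    expect_equal(ws2[[nm]], ws[[nm]], tolerance = 1e-12)
  expect_equal(ws2$zeta, ws$zeta)

  pars <- quick_params()
  rec <- run_participant(pars, seed = 2, goal_switch = FALSE)
  f <- file.path(dir, "log.tsv")
  write_trial_log(rec, f)
  rec2 <- read_trial_log(f)
  expect_equal(nrow(rec2), nrow(rec))
  expect_equal(rec2$rt, rec$rt)
  expect_equal(rec2$feedback, rec$feedback)

  cyc <- planning_cycle(chain_weights(model_params()), 1, 1)
  ras <- spike_raster(cyc)
  expect_equal(nrow(ras), 30L)
  expect_equal(unique(ras$layer), c("associative", "output"))
})
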