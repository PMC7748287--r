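# Behavioural aggregation: per-stimulus learning curves over triplets,
# reaction-time curves over representative steps, goal-switch summaries,
# and the Pearson fitting harness with its random parameter search.

se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0

#' Per-stimulus learning curves
#'
#' For each stimulus label (S1/S2/S3, taken per participant from that
#' participant's own staircase designations) and triplet index, the mean
#' and standard error over participants of the chosen success indicator.
#'
#' @param records trial records from [run_experiment()] (or one
#'   participant's records).
#' @param measure `"correct"` for the proportion of correct feedback
#'   (the phase-1 learning curve) or `"goal"` for the proportion of
#'   trials achieving the pursued goal (useful across a goal switch).
#' @param phase which phase to aggregate (1 or 2).
#' @return a data.frame with columns `label`, `triplet`, `mean`, `se`,
#'   `n`.
#' @export
aggregate_performance <- function(records, measure = c("correct", "goal"),
                                  phase = 1L) {
  measure <- match.arg(measure)
  if (is.null(records$participant)) records$participant <- 1L
  d <- records[records$phase == phase, ]
  d$value <- if (measure == "correct") as.numeric(d$feedback == "correct")
             else as.numeric(d$goal_met)
  agg <- stats::aggregate(value ~ label + triplet, data = d,
                          FUN = function(x) c(mean = mean(x), se = se(x),
                                              n = length(x)))
  out <- data.frame(label = agg$label, triplet = agg$triplet,
                    mean = agg$value[, "mean"], se = agg$value[, "se"],
                    n = as.integer(agg$value[, "n"]))
  out[order(out$label, out$triplet), , drop = FALSE]
}

#' Representative step of a stimulus's k-th trial
#'
#' The alignment scheme that puts the three stimuli on a common axis
#' separating exploration (steps 1-5) from exploitation (step 6 onward):
#' S1's successive trials map to steps 1, 2, 6, 7, ...; S2's to 1, 2, 3,
#' 4, 6, 7, ...; S3's to 1, 2, 3, 4, 5, 6, ... (identity).
#'
#' @param label `"S1"`, `"S2"` or `"S3"`.
#' @param k the stimulus's trial rank (vectorised).
#' @return integer representative step(s).
#' @export
representative_step <- function(label, k) {
  k <- as.integer(k)
  switch(match.arg(label, c("S1", "S2", "S3")),
         S1 = ifelse(k <= 2L, k, k + 3L),
         S2 = ifelse(k <= 4L, k, k + 1L),
         S3 = k)
}

#' Reaction-time curve over representative steps
#'
#' Maps each stimulus's successive phase-1 trials to representative steps
#' (see [representative_step()]) and averages the planning-cycle counts
#' per step over stimuli and participants.
#'
#' @param records trial records from [run_experiment()].
#' @param phase which phase to aggregate.
#' @return a data.frame with columns `step`, `mean`, `se`, `n`.
#' @export
aggregate_rt <- function(records, phase = 1L) {
  if (is.null(records$participant)) records$participant <- 1L
  d <- records[records$phase == phase, ]
  d$step <- NA_integer_
  for (lab in c("S1", "S2", "S3")) {
    i <- d$label == lab
    d$step[i] <- representative_step(lab, d$trial_in_stim[i])
  }
  agg <- stats::aggregate(rt ~ step, data = d,
                          FUN = function(x) c(mean = mean(x), se = se(x),
                                              n = length(x)))
  out <- data.frame(step = agg$step, mean = agg$rt[, "mean"],
                    se = agg$rt[, "se"], n = as.integer(agg$rt[, "n"]))
  out[order(out$step), , drop = FALSE]
}

#' Goal achievement and reaction time by triplet across both phases
#'
#' Summarises the session on the global triplet axis (phase-2 triplets
#' continue the count), which is the natural axis for goal-switch
#' analysis.
#'
#' @param records trial records from [run_experiment()].
#' @return a data.frame with columns `phase`, `triplet` (within phase),
#'   `global_triplet`, `goal_rate`, `rt_mean`, `rt_se`.
#' @export
aggregate_by_triplet <- function(records) {
  if (is.null(records$participant)) records$participant <- 1L
  records$global_triplet <- records$triplet +
    (records$phase - 1L) * max(records$triplet)
  agg <- stats::aggregate(cbind(goal_met, rt) ~ phase + triplet +
                            global_triplet, data = records, FUN = mean)
  rtse <- stats::aggregate(rt ~ global_triplet, data = records, FUN = se)
  out <- data.frame(phase = agg$phase, triplet = agg$triplet,
                    global_triplet = agg$global_triplet,
                    goal_rate = agg$goal_met, rt_mean = agg$rt,
                    rt_se = rtse$rt[match(agg$global_triplet,
                                          rtse$global_triplet)])
  out[order(out$global_triplet), , drop = FALSE]
}

#' Pearson correlation between a model curve and a reference curve
#'
#' \eqn{R = C_{d,m} / \sqrt{V_d V_m}}, computed from the raw definition
#' (covariance over the product of the standard deviations).
#'
#' @param model_curve,reference_curve numeric vectors of equal length
#'   (>= 3) with non-zero variance.
#' @return the correlation coefficient.
#' @export
pearson <- function(model_curve, reference_curve) {
  x <- as.numeric(model_curve)
  y <- as.numeric(reference_curve)
  if (length(x) != length(y)) stop("curves must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  cx <- x - mean(x)
  cy <- y - mean(y)
  vx <- mean(cx^2)
  vy <- mean(cy^2)
  if (vx == 0 || vy == 0)
    stop("undefined correlation: a curve has zero variance")
  mean(cx * cy) / sqrt(vx * vy)
}

#' Fit quality of a parameter set against reference curves
#'
#' Runs a cohort, builds the three per-stimulus phase-1 performance
#' curves and the representative-step reaction-time curve, correlates
#' each with the corresponding reference curve and returns the mean of
#' the four correlations.  The reference is user-supplied (see
#' [synthetic_reference()] for the format and a synthetic stand-in).
#'
#' @param params a [model_params()].
#' @param reference a list with `performance` (data.frame: `label`,
#'   `triplet`, `value`) and `rt` (data.frame: `step`, `value`).
#' @param n_participants cohort size per evaluation.
#' @param seed master seed for the cohort.
#' @return the mean correlation, with the four per-dataset correlations
#'   attached as attribute `"correlations"`.
#' @export
fitness <- function(params, reference, n_participants = 20L, seed = 1L) {
  records <- run_experiment(params, n_participants, seed,
                            goal_switch = FALSE)
  perf <- aggregate_performance(records, "correct", phase = 1L)
  rt <- aggregate_rt(records, phase = 1L)
  cors <- numeric(4L)
  names(cors) <- c("S1", "S2", "S3", "rt")
  for (lab in c("S1", "S2", "S3")) {
    ref <- reference$performance[reference$performance$label == lab, ]
    mod <- perf[perf$label == lab, ]
    i <- match(ref$triplet, mod$triplet)
    if (anyNA(i)) stop("model curve missing triplets present in the ",
                       "reference for ", lab)
    cors[lab] <- pearson(mod$mean[i], ref$value)
  }
  common <- intersect(reference$rt$step, rt$step)
  if (length(common) < 3L)
    stop("fewer than 3 common representative steps between model and ",
         "reference reaction times")
  cors["rt"] <- pearson(rt$mean[match(common, rt$step)],
                        reference$rt$value[match(common,
                                                 reference$rt$step)])
  structure(mean(cors), correlations = cors)
}

#' Admissible ranges of the seven searchable parameters
#'
#' @return a named list of `c(min, max)` ranges.
#' @export
default_search_ranges <- function() {
  list(zeta = c(0.1, 1), stdp_c = c(0.1, 1), eta = c(0.001, 1),
       temperature = c(0.01, 0.1), noise_sd = c(0.01, 0.1),
       epsilon = c(0.3, 1), delta = c(0.01, 0.2))
}

#' Random search over the model parameters
#'
#' Samples parameter combinations uniformly within the given ranges,
#' evaluates the [fitness()] of each against the reference curves with a
#' per-combination seed derived deterministically from the master seed
#' and the combination index, and returns the combinations ranked by
#' fitness.
#'
#' @param ranges named list of `c(min, max)` ranges over a subset of the
#'   searchable parameters (defaults to [default_search_ranges()]).
#' @param n_combos number of random combinations to evaluate.
#' @param n_participants cohort size per evaluation.
#' @param reference reference curves, as in [fitness()].
#' @param seed master seed.
#' @param params_base a [model_params()] supplying every value not
#'   searched.
#' @return a data.frame with one row per combination (sampled parameter
#'   values, `fitness`, `combo`, `seed`), sorted by decreasing fitness.
#' @export
parameter_search <- function(ranges = default_search_ranges(),
                             n_combos = 100L, n_participants = 20L,
                             reference = synthetic_reference(),
                             seed = 1L, params_base = model_params()) {
  allowed <- default_search_ranges()
  bad <- setdiff(names(ranges), names(allowed))
  if (length(bad)) stop("unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  draws <- as.data.frame(lapply(ranges, function(r)
    runif(n_combos, r[1], r[2])))
  combo_seeds <- (as.double(seed) * 100000 + seq_len(n_combos)) %%
    2147483647
  fit <- vapply(seq_len(n_combos), function(i) {
    p <- do.call(model_params,
                 modifyList(unclass(params_base),
                            as.list(draws[i, , drop = FALSE])))
    as.numeric(fitness(p, reference, n_participants, combo_seeds[i]))
  }, numeric(1))
  out <- cbind(draws, fitness = fit, combo = seq_len(n_combos),
               seed = combo_seeds)
  out[order(-out$fitness), , drop = FALSE]
}
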