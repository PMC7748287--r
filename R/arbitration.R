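# Entropy-based arbitration between planning and exploration.  The world
# model's uncertainty is the per-cycle mean of the associative layer's
# step entropies, normalized by ln(K); it is compared against a threshold
# that starts at epsilon and drops by delta after every failed planning
# cycle, so that a trial always terminates.

#' Normalized entropy of a planning cycle
#'
#' For `T` step distributions over `K` units,
#' \deqn{H = \frac{1}{T} \sum_t \frac{-\sum_k p_t(k) \ln p_t(k)}{\ln K}}
#' with the convention \eqn{0 \ln 0 = 0}.  Equals 1 iff every step's
#' distribution is uniform and 0 iff every step is degenerate.
#'
#' @param distributions a steps x units probability matrix (each row
#'   summing to 1), or a list of probability vectors.
#' @return the mean normalized entropy, in \[0, 1\].
#' @export
normalized_entropy <- function(distributions) {
  if (is.list(distributions))
    distributions <- do.call(rbind, distributions)
  if (!is.matrix(distributions))
    distributions <- matrix(distributions, nrow = 1L)
  K <- ncol(distributions)
  if (K < 2L) stop("need distributions over at least 2 units")
  if (any(distributions < 0) ||
      any(abs(rowSums(distributions) - 1) > 1e-6))
    stop("each distribution must be non-negative and sum to 1")
  plogp <- distributions * log(distributions)
  plogp[distributions == 0] <- 0
  mean(-rowSums(plogp)) / log(K)
}

#' Within-trial entropy threshold schedule
#'
#' \eqn{H_{Th}(f) = \epsilon - f \delta}: the threshold starts each trial
#' at `epsilon` and decreases linearly with the number of failed planning
#' cycles `f`, so exploration is eventually forced.  The value may go
#' negative, which guarantees termination since the entropy is
#' non-negative.
#'
#' @param f number of failed planning cycles in the current trial
#'   (vectorised).
#' @param params a [model_params()] supplying `epsilon` and `delta`.
#' @return threshold value(s).
#' @export
entropy_threshold <- function(f, params = model_params()) {
  if (any(f < 0)) stop("'f' must be >= 0")
  params$epsilon - f * params$delta
}

#' Select a functioning mode for the current planning cycle
#'
#' Implements the three-way decision taken after each planning cycle:
#' * `"explore"` if the uncertainty is at or above the current threshold
#'   (or the safety cap on cycles is reached) — the exploration component
#'   picks the action;
#' * `"act_planned"` if the cycle is confident, its predicted outcome
#'   matches the pursued goal and an action was read out — the simulated
#'   action is executed;
#' * `"replan"` otherwise — the caller applies the negative goal-weight
#'   update, increments `f` and runs a new cycle.
#'
#' The boundary `H == threshold` counts as too uncertain.
#'
#' @param H mean normalized entropy of the cycle, in \[0, 1\].
#' @param f failed planning cycles so far this trial.
#' @param outcome the cycle's feedback readout (`event_code` or `NULL`).
#' @param goal pursued goal unit (1 = correct feedback, 2 = incorrect).
#' @param params a [model_params()].
#' @param has_action does the cycle have an action readout?  A goal match
#'   without an executable action is treated as a failure.
#' @return an object of class `arbitration_decision` with fields `mode`,
#'   `entropy`, `threshold`.
#' @export
arbitrate <- function(H, f, outcome, goal, params = model_params(),
                      has_action = TRUE) {
  if (is.na(H) || H < 0 || H > 1) stop("'H' must be in [0, 1]")
  th <- entropy_threshold(f, params)
  goal_matched <- !is.null(outcome) && outcome$kind == "feedback" &&
    outcome$index == as.integer(goal)
  mode <- if (H >= th || f >= params$max_cycles) "explore"
          else if (goal_matched && has_action) "act_planned"
          else "replan"
  structure(list(mode = mode, entropy = H, threshold = th),
            class = "arbitration_decision")
}

#' @export
print.arbitration_decision <- function(x, ...) {
  cat(sprintf("<arbitration: %s (H=%.3f, threshold=%.3f)>\n",
              x$mode, x$entropy, x$threshold))
  invisible(x)
}
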