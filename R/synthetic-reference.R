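# SYNTHETIC reference curves for exercising the fitting harness.  These
# are NOT human data: the published human curves exist only as figures,
# so the harness accepts any user-supplied table and this generator
# provides a clearly-labelled stand-in built from the ideal-agent
# protocol plus smooth exploitation noise.

#' Synthetic reference curves (not human data)
#'
#' Builds a reference table in the format consumed by [fitness()] from an
#' idealised participant: per-stimulus performance steps up at the
#' staircase-determined discovery trial (trial 2 for S1, 4 for S2, 5 for
#' S3) with an imperfect plateau, and reaction times follow an
#' inverted-U over representative steps (short during early exploration,
#' a mid-learning peak, short again during exploitation).  Gaussian
#' noise is added and proportions are clipped to \[0, 1\].  The curves
#' are synthetic and serve only to test the fitting machinery; supply
#' your own table to fit real data.
#'
#' @param seed optional seed for the added noise.
#' @param noise_sd standard deviation of the noise.
#' @param plateau asymptotic correct-response proportion.
#' @return a list with `performance` (data.frame: `label`, `triplet`,
#'   `value`) and `rt` (data.frame: `step`, `value`).
#' @export
synthetic_reference <- function(seed = NULL, noise_sd = 0.03,
                                plateau = 0.95) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  discovery <- c(S1 = 2L, S2 = 4L, S3 = 5L)
  perf <- do.call(rbind, lapply(names(discovery), function(lab) {
    base <- ifelse(seq_len(20L) < discovery[[lab]], 0, plateau)
    data.frame(label = lab, triplet = seq_len(20L),
               value = pmin(pmax(base + rnorm(20L, 0, noise_sd), 0), 1))
  }))
  steps <- seq_len(23L)
  # inverted U: low at step 1, peak over the mid representative steps,
  # settling back to a single planning cycle during exploitation
  bump <- 1 + 2.5 * exp(-((steps - 4)^2) / 8)
  tail_decay <- ifelse(steps >= 6, exp(-(steps - 6) / 4), 1)
  rt <- 1 + (bump - 1) * tail_decay
  rt <- pmax(rt + rnorm(length(steps), 0, noise_sd), 0)
  list(performance = perf, rt = data.frame(step = steps, value = rt))
}
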