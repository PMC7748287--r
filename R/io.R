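# Portable plain-text serialization: one TSV per weight matrix plus a
# DCF metadata record; trial logs and spike rasters as tidy tables.

.weight_matrices <- c("W_in", "W_goal", "W_rec", "W_out", "W_explore")

#' Serialize a weight set to a directory of plain-text tables
#'
#' Writes one tab-separated file per connection matrix plus a
#' `metadata.dcf` record carrying the learning constants.
#'
#' @param weights a [weight_set()].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_weight_set <- function(weights, dir) {
  validate_weight_set(weights)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in .weight_matrices)
    write.table(weights[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- data.frame(zeta = weights$zeta, stdp_c = weights$stdp_c,
                     eta = weights$eta, w_max = weights$w_max,
                     n_assoc = ncol(weights$W_in))
  write.dcf(meta, file.path(dir, "metadata.dcf"))
  invisible(dir)
}

#' @rdname write_weight_set
#' @export
read_weight_set <- function(dir) {
  meta <- as.data.frame(read.dcf(file.path(dir, "metadata.dcf")),
                        stringsAsFactors = FALSE)
  ws <- structure(list(), class = "weight_set")
  for (nm in .weight_matrices)
    ws[[nm]] <- as.matrix(read.table(file.path(dir, paste0(nm, ".tsv")),
                                     sep = "\t"))
  for (nm in .weight_matrices) dimnames(ws[[nm]]) <- NULL
  ws$zeta <- as.numeric(meta$zeta)
  ws$stdp_c <- as.numeric(meta$stdp_c)
  ws$eta <- as.numeric(meta$eta)
  ws$w_max <- as.numeric(meta$w_max)
  validate_weight_set(ws)
}

#' Tidy spike raster of a planning cycle
#'
#' @param cycle a `planning_cycle`.
#' @return a data.frame with columns `step`, `layer` (`"associative"` or
#'   `"output"`), `unit` — one row per spike, suitable for plotting or
#'   export with [write_trial_log()].
#' @export
spike_raster <- function(cycle) {
  stopifnot(inherits(cycle, "planning_cycle"))
  n <- length(cycle$assoc_spikes)
  data.frame(step = rep(seq_len(n), 2L),
             layer = rep(c("associative", "output"), each = n),
             unit = c(cycle$assoc_spikes, cycle$out_spikes))
}

#' Write / read a tidy trial log
#'
#' @param records a trial-record data.frame.
#' @param file path of the tab-separated file.
#' @return `file` invisibly; `read_trial_log()` returns the data.frame.
#' @export
write_trial_log <- function(records, file) {
  write.table(records, file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(file)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(file) {
  read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
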