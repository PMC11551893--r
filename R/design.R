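#' Condition labels for a complete 2 x 2 x phase x run design
#'
#' Builds the full factorial label table of a sequence experiment: two serial
#' orders crossed with two timing structures, each measured once per phase
#' (preparation, production) in every imaging run -- eight condition rows per
#' run.
#'
#' @param n_runs number of imaging runs (default 6).
#' @param phases character vector of phase names present in the design.
#' @return a data.frame with columns `run`, `order`, `timing`, `phase` and
#'   `sequence` (a factor pasting order and timing), one row per condition
#'   per run, ordered by run, then phase, then order, then timing.
#' @export
make_design_labels <- function(n_runs = 6,
                               phases = c("preparation", "production")) {
  if (length(n_runs) != 1L || is.na(n_runs) || n_runs < 1)
    stop("n_runs must be a positive integer")
  grid <- expand.grid(timing = 1:2, order = 1:2,
                      phase = phases, run = seq_len(n_runs),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  labels <- grid[, c("run", "order", "timing", "phase")]
  labels$sequence <- sequence_id(labels$order, labels$timing)
  labels
}

sequence_id <- function(order, timing) {
  paste0("O", order, "T", timing)
}

#' @keywords internal
check_complete_design <- function(labels, phase = NULL, n_runs = NULL) {
  if (!is.null(phase)) labels <- labels[labels$phase == phase, , drop = FALSE]
  if (nrow(labels) == 0L) stop("no rows for the requested phase")
  runs <- sort(unique(labels$run))
  if (!is.null(n_runs) && length(runs) != n_runs)
    stop("design error: expected ", n_runs, " runs, found ", length(runs))
  n_phases <- length(unique(labels$phase))
  key <- paste(labels$run, labels$order, labels$timing, labels$phase)
  if (anyDuplicated(key) ||
      nrow(labels) != length(runs) * 4L * n_phases ||
      !all(labels$order %in% 1:2) || !all(labels$timing %in% 1:2))
    stop("design error: each run must contain each order x timing x phase ",
         "cell exactly once")
  invisible(runs)
}
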