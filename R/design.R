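#' Stimulus design for a scanning run
#'
#' Describes the block structure of one run: block onsets and durations in
#' seconds, the repetition time, the number of volumes and the microtime
#' resolution on which the neural and hemodynamic equations are integrated
#' (default 16 bins per TR). Optional event-level onsets support per-stimulus
#' input modelling.
#'
#' @param block_onsets,block_durations Numeric vectors (seconds), equal length.
#' @param TR Repetition time in seconds.
#' @param n_volumes Number of scan volumes.
#' @param microtime_bins_per_TR Integer >= 1.
#' @param event_onsets,event_durations Optional per-stimulus timing (seconds).
#' @return An object of class `stimulus_design`.
#' @export
stimulus_design <- function(block_onsets, block_durations, TR, n_volumes,
                            microtime_bins_per_TR = 16L,
                            event_onsets = NULL, event_durations = NULL) {
  stopifnot(length(block_onsets) == length(block_durations),
            TR > 0, n_volumes >= 1, microtime_bins_per_TR >= 1)
  if (length(block_durations) && any(block_durations <= 0)) {
    stop("all block durations must be positive", call. = FALSE)
  }
  if (length(block_onsets) &&
      max(block_onsets + block_durations) > n_volumes * TR + 1e-9) {
    stop("blocks extend beyond the end of the run", call. = FALSE)
  }
  if (length(block_onsets) > 1) {
    o <- order(block_onsets)
    ends <- (block_onsets + block_durations)[o]
    if (any(ends[-length(ends)] > block_onsets[o][-1] + 1e-9)) {
      stop("stimulation blocks overlap", call. = FALSE)
    }
  }
  structure(
    list(
      block_onsets = as.numeric(block_onsets),
      block_durations = as.numeric(block_durations),
      TR = TR,
      n_volumes = as.integer(n_volumes),
      microtime_bins_per_TR = as.integer(microtime_bins_per_TR),
      event_onsets = event_onsets,
      event_durations = event_durations
    ),
    class = "stimulus_design"
  )
}

#' The study's block design for one task
#'
#' One run presents 40 words or pseudowords in 4 blocks of 10 stimuli (25 s
#' per block, inter-stimulus interval 2.5 s) interspersed with 16 s of rest,
#' acquired over 66 volumes at TR 3.085 s (3.4 min). The first block starts
#' after a 16 s lead-in rest; the tail of the run is rest.
#'
#' @param task `"word"` or `"pseudoword"` (identical timing; the label is
#'   carried through bookkeeping).
#' @param TR Repetition time in seconds.
#' @param microtime_bins_per_TR Microtime resolution.
#' @return A [stimulus_design()] with 40 event onsets available for
#'   event-level input mode.
#' @export
make_design <- function(task = c("word", "pseudoword"), TR = 3.085,
                        microtime_bins_per_TR = 16L) {
  task <- match.arg(task)
  block_on <- 16 + (0:3) * (25 + 16)
  events <- as.vector(outer(seq(0, by = 2.5, length.out = 10), block_on, "+"))
  stimulus_design(
    block_onsets = block_on,
    block_durations = rep(25, 4),
    TR = TR,
    n_volumes = 66L,
    microtime_bins_per_TR = microtime_bins_per_TR,
    event_onsets = sort(events),
    event_durations = rep(0.65, 40)
  )
}

#' Driving input on the microtime grid
#'
#' Box-car input: 1 within stimulation blocks, 0 elsewhere, sampled on the
#' microtime grid of width `TR / microtime_bins_per_TR`. A bin is "on" when
#' its midpoint falls inside a block.
#'
#' @param design A [stimulus_design()].
#' @param mode `"block"` (default box-car) or `"event"` (per-stimulus
#'   box-cars from the design's event onsets/durations).
#' @return Numeric vector of 0/1 of length `n_volumes * microtime_bins_per_TR`,
#'   with attributes `dt` (bin width, s) and `time` (bin midpoints, s).
#' @export
build_input <- function(design, mode = c("block", "event")) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "stimulus_design"))
  dt <- design$TR / design$microtime_bins_per_TR
  n <- design$n_volumes * design$microtime_bins_per_TR
  mid <- (seq_len(n) - 0.5) * dt
  if (mode == "event") {
    if (is.null(design$event_onsets)) {
      stop("design has no event-level timing", call. = FALSE)
    }
    on <- design$event_onsets
    dur <- design$event_durations
  } else {
    on <- design$block_onsets
    dur <- design$block_durations
  }
  u <- numeric(n)
  for (i in seq_along(on)) {
    u[mid >= on[i] & mid < on[i] + dur[i]] <- 1
  }
  attr(u, "dt") <- dt
  attr(u, "time") <- mid
  u
}
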