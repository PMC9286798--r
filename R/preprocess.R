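#' Filter specification
#'
#' Deterministic zero-phase (forward-backward Butterworth) filtering chain
#' applied before discriminant analysis: a broad band-pass (high-pass plus
#' low-pass), a power-line notch, and a final low-pass. All stages are
#' optional (`NULL` disables a stage).
#'
#' @param band_pass_hz Two-element band `c(low, high)` (default
#'   `c(0.1, 95)`), applied as a cascade of a high-pass at `low` and a
#'   low-pass at `high`.
#' @param notch_hz Power-line notch centre frequency (default 50); a
#'   band-stop of `notch_width_hz` around it.
#' @param final_lowpass_hz Final smoothing low-pass (default 30).
#' @param notch_width_hz Full width of the stop band (default 4).
#' @param hp_order,lp_order,notch_order,final_order Butterworth orders
#'   (doubled in effect by the forward-backward pass).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(band_pass_hz = c(0.1, 95), notch_hz = 50,
                        final_lowpass_hz = 30, notch_width_hz = 4,
                        hp_order = 2, lp_order = 4, notch_order = 2,
                        final_order = 4) {
  if (!is.null(band_pass_hz)) {
    assert_that(length(band_pass_hz) == 2 && band_pass_hz[1] > 0 &&
                band_pass_hz[1] < band_pass_hz[2],
                "band_pass_hz must satisfy 0 < low < high")
  }
  structure(list(band_pass_hz = band_pass_hz, notch_hz = notch_hz,
                 final_lowpass_hz = final_lowpass_hz,
                 notch_width_hz = notch_width_hz, hp_order = hp_order,
                 lp_order = lp_order, notch_order = notch_order,
                 final_order = final_order), class = "filter_spec")
}

# zero-phase filter of a [n_series x n_samples] matrix along rows
filtfilt_rows <- function(m, filt) {
  t(apply(m, 1, function(row) signal::filtfilt(filt, row)))
}

#' Apply the zero-phase filter chain
#'
#' Filters an [epoch_set()] (per trial and channel along the sample axis) or
#' a continuous `channels x samples` matrix. Shape is preserved; filtering
#' is forward-backward so no phase delay is introduced.
#'
#' @param x An `epoch_set` or a numeric matrix `channels x samples`.
#' @param spec A [filter_spec()].
#' @param srate_hz Required when `x` is a bare matrix.
#' @return The filtered object, same class and shape as the input.
#' @export
apply_filters <- function(x, spec = filter_spec(), srate_hz = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(x, "epoch_set")) srate_hz <- x$srate_hz
  assert_that(!is.null(srate_hz), "srate_hz required for matrix input")
  nyq <- srate_hz / 2
  cutoffs <- c(spec$band_pass_hz, spec$notch_hz, spec$final_lowpass_hz)
  assert_that(all(cutoffs < nyq),
              "all filter cutoffs must be below the Nyquist frequency")

  filters <- list()
  if (!is.null(spec$band_pass_hz)) {
    filters <- c(filters, list(
      signal::butter(spec$hp_order, spec$band_pass_hz[1] / nyq, "high"),
      signal::butter(spec$lp_order, spec$band_pass_hz[2] / nyq, "low")))
  }
  if (!is.null(spec$notch_hz)) {
    edges <- (spec$notch_hz + c(-0.5, 0.5) * spec$notch_width_hz) / nyq
    filters <- c(filters, list(signal::butter(spec$notch_order, edges, "stop")))
  }
  if (!is.null(spec$final_lowpass_hz)) {
    filters <- c(filters, list(
      signal::butter(spec$final_order, spec$final_lowpass_hz / nyq, "low")))
  }

  run <- function(m) {
    for (f in filters) m <- filtfilt_rows(m, f)
    m
  }
  if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    for (i in seq_len(d[1])) x$data[i, , ] <- run(x$data[i, , , drop = TRUE])
    x
  } else {
    run(x)
  }
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean across all scalp channels; after
#' this the per-sample channel mean is exactly zero. Applying it twice is a
#' no-op (a warning is raised on the second application).
#'
#' @param x An [epoch_set()].
#' @return The re-referenced `epoch_set` with `reference_state = "average"`.
#' @export
average_reference <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  if (x$reference_state == "average") {
    warning("epoch_set is already average-referenced; returning unchanged")
    return(x)
  }
  mean_ts <- apply(x$data, c(1, 3), mean)           # trial x sample
  d <- dim(x$data)
  x$data <- x$data - aperm(array(mean_ts, dim = c(d[1], d[3], d[2])),
                           c(1, 3, 2))
  x$reference_state <- "average"
  x
}

#' Epoch a continuous recording with baseline correction
#'
#' Cuts fixed-length epochs around event samples and subtracts, per channel
#' and epoch, the mean over the baseline window. Events whose epoch would
#' extend beyond the record are dropped with a message.
#'
#' @param x Numeric matrix `channels x samples` (continuous record).
#' @param events Integer vector of event sample indices (1-based; the event
#'   sample maps to time 0).
#' @param srate_hz Sampling rate.
#' @param channels Channel labels.
#' @param span_ms Epoch span around the event (default `c(-500, 2000)`).
#' @param baseline_ms Baseline window (default `c(-200, 0)`); `NULL`
#'   disables baseline correction.
#' @param lock_event Label of the locking event.
#' @return An [epoch_set()].
#' @export
epoch_and_baseline <- function(x, events, srate_hz, channels,
                               span_ms = c(-500, 2000),
                               baseline_ms = c(-200, 0),
                               lock_event = "cue") {
  stopifnot(is.matrix(x))
  step <- 1000 / srate_hz
  offsets <- seq(round(span_ms[1] / step), round(span_ms[2] / step))
  times <- offsets * step
  keep <- events + min(offsets) >= 1 & events + max(offsets) <= ncol(x)
  if (any(!keep)) {
    message(sum(!keep), " event(s) too close to the record edge; dropped")
  }
  events <- events[keep]
  assert_that(length(events) > 0, "no events fully inside the record")
  data <- array(0, dim = c(length(events), nrow(x), length(offsets)))
  for (i in seq_along(events)) data[i, , ] <- x[, events[i] + offsets]
  if (!is.null(baseline_ms)) {
    bl <- which(times >= baseline_ms[1] & times <= baseline_ms[2])
    assert_that(length(bl) > 0, "baseline window contains no samples")
    data <- data - array(apply(data[, , bl, drop = FALSE], c(1, 2), mean),
                         dim = dim(data))
  }
  epoch_set(data, channels, times, srate_hz, lock_event = lock_event,
            reference_state = "raw")
}

#' Amplitude-threshold epoch rejection
#'
#' Drops whole epochs in which any channel exceeds `threshold_uv` in
#' absolute amplitude — a simple deterministic stand-in for automated
#' artifact screening, disabled by default for synthetic data.
#'
#' @param x An [epoch_set()].
#' @param trials Matching trial table (rows dropped in step with epochs).
#' @param threshold_uv Absolute amplitude bound in microvolts.
#' @return List with the pruned `epochs`, `trials`, and the integer vector
#'   `rejected` of dropped trial indices.
#' @export
reject_epochs <- function(x, trials, threshold_uv = 100) {
  stopifnot(inherits(x, "epoch_set"), nrow(trials) == n_trials(x))
  peak <- apply(abs(x$data), 1, max)
  bad <- which(peak > threshold_uv)
  if (length(bad)) {
    x$data <- x$data[-bad, , , drop = FALSE]
    trials <- trials[-bad, , drop = FALSE]
  }
  list(epochs = x, trials = trials, rejected = bad)
}
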