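#' Epoched EEG container
#'
#' Lightweight container for epoched multichannel EEG: a numeric array
#' `[trial, channel, sample]` in microvolts plus channel labels, the sampling
#' rate, a time axis in milliseconds (0 = lock event) and bookkeeping about
#' the reference state.
#'
#' @param data Numeric array `[trial, channel, sample]`, microvolts.
#' @param channels Character vector of channel labels (10-10 names).
#' @param times_ms Numeric vector of sample times in ms, strictly increasing
#'   with uniform spacing `1000 / srate_hz`.
#' @param srate_hz Sampling rate in Hz.
#' @param lock_event Which event the epochs are locked to: `"cue"`,
#'   `"target"` or `"feedback"`.
#' @param reference_state `"raw"` or `"average"`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, channels, times_ms, srate_hz,
                      lock_event = c("cue", "target", "feedback"),
                      reference_state = c("raw", "average")) {
  lock_event <- match.arg(lock_event)
  reference_state <- match.arg(reference_state)
  assert_that(is.array(data) && length(dim(data)) == 3,
              "data must be a [trial, channel, sample] array")
  assert_that(dim(data)[2] == length(channels),
              "channel axis length must match length(channels)")
  assert_that(dim(data)[3] == length(times_ms),
              "sample axis length must match length(times_ms)")
  if (length(times_ms) > 1) {
    dt <- diff(times_ms)
    assert_that(all(dt > 0), "times_ms must be strictly increasing")
    assert_that(max(abs(dt - 1000 / srate_hz)) < 1e-6,
                "times_ms spacing must equal 1000/srate_hz")
  }
  structure(
    list(data = data, channels = as.character(channels),
         times_ms = as.numeric(times_ms), srate_hz = srate_hz,
         lock_event = lock_event, reference_state = reference_state),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$srate_hz))
  cat(sprintf("  time %g..%g ms, locked to %s, reference: %s\n",
              min(x$times_ms), max(x$times_ms), x$lock_event,
              x$reference_state))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]

#' Convert an epoch set to a long tibble
#'
#' One row per (trial, channel, sample); useful for ggplot2-based inspection
#' of small epoch sets. Large sets expand quickly, so consider subsetting.
#'
#' @param x An `epoch_set`.
#' @param ... Unused.
#' @return Tibble with columns `trial`, `channel`, `time_ms`, `amplitude_uv`.
#' @export
as_tibble.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(x$channels, each = d[1]), times = d[3]),
    time_ms = rep(x$times_ms, each = d[1] * d[2]),
    amplitude_uv = as.vector(x$data))
}

#' Read and write epoch sets
#'
#' `write_epoch_set()`/`read_epoch_set()` persist an epoch set. Two formats
#' are supported: `"rds"` (compact, default) and `"tsv"`, a portable
#' plain-text long format with a `#`-prefixed JSON header line carrying the
#' metadata (channels, times, sampling rate, lock event, reference state).
#'
#' @param x An `epoch_set`.
#' @param path Output/input file path.
#' @param format `"rds"` or `"tsv"`.
#' @return `read_epoch_set()` returns an `epoch_set`; `write_epoch_set()`
#'   returns `path` invisibly.
#' @export
write_epoch_set <- function(x, path, format = c("rds", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "epoch_set"))
  if (format == "rds") {
    saveRDS(x, path)
  } else {
    meta <- jsonlite::toJSON(
      list(channels = x$channels, times_ms = x$times_ms,
           srate_hz = x$srate_hz, lock_event = x$lock_event,
           reference_state = x$reference_state, dim = dim(x$data)),
      auto_unbox = TRUE, digits = NA)
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste0("#epoch_set ", meta), con)
    # samples in column-major order of the [trial, channel, sample] array
    write.table(data.frame(value = as.vector(x$data)), con,
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path, format = c("rds", "tsv")) {
  format <- match.arg(format)
  if (format == "rds") {
    x <- readRDS(path)
    stopifnot(inherits(x, "epoch_set"))
    return(x)
  }
  header <- readLines(path, n = 1L)
  assert_that(startsWith(header, "#epoch_set "),
              "not an epoch_set tsv file (missing header)")
  meta <- jsonlite::fromJSON(sub("^#epoch_set ", "", header))
  vals <- read.delim(path, comment.char = "#")$value
  data <- array(vals, dim = meta$dim)
  epoch_set(data, meta$channels, meta$times_ms, meta$srate_hz,
            meta$lock_event, meta$reference_state)
}
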