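#' A sampled CAP recording epoch
#'
#' Container for one recording epoch with the fixed timing layout used by
#' the recording chain: 5 ms pre-stimulus, a 24 ms stimulus and 20 ms
#' post-stimulus (49 ms total). Time zero is stimulus onset; the first
#' sample sits at -5 ms.
#'
#' @param samples Numeric vector of samples in microvolts; its length must
#'   equal `round((pre_ms + stim_ms + post_ms)/1000 * fs)`.
#' @param fs Sampling rate in Hz.
#' @param pre_ms,stim_ms,post_ms Epoch layout in ms.
#' @return An object of class `cap_trace`.
#' @export
#' @examples
#' tr <- cap_trace(numeric(1225), fs = 25000)
#' tr
cap_trace <- function(samples, fs, pre_ms = 5, stim_ms = 24, post_ms = 20) {
  n_expected <- round((pre_ms + stim_ms + post_ms) / 1000 * fs)
  if (length(samples) != n_expected) {
    stop("trace has ", length(samples), " samples but the ",
         pre_ms + stim_ms + post_ms, " ms layout at ", fs,
         " Hz requires ", n_expected, call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), fs = fs,
         pre_ms = pre_ms, stim_ms = stim_ms, post_ms = post_ms),
    class = "cap_trace"
  )
}

#' @export
print.cap_trace <- function(x, ...) {
  cat(sprintf("<cap_trace> %d samples @ %g Hz (%g/%g/%g ms pre/stim/post)\n",
              length(x$samples), x$fs, x$pre_ms, x$stim_ms, x$post_ms))
  invisible(x)
}

# half-open window [a, b) in ms post stimulus onset -> 1-based sample indices
window_indices <- function(trace, window_ms) {
  if (length(window_ms) != 2 || window_ms[2] <= window_ms[1]) {
    stop("window must be an increasing (start, end) pair in ms", call. = FALSE)
  }
  total_ms <- trace$pre_ms + trace$stim_ms + trace$post_ms
  if (window_ms[1] < -trace$pre_ms || window_ms[2] > total_ms - trace$pre_ms) {
    stop("window [", window_ms[1], ", ", window_ms[2],
         ") ms lies outside the epoch", call. = FALSE)
  }
  abs_ms <- window_ms + trace$pre_ms
  start <- floor(abs_ms[1] / 1000 * trace$fs) + 1
  end <- floor(abs_ms[2] / 1000 * trace$fs)
  if (end < start) stop("window is empty after index conversion", call. = FALSE)
  c(start, end)
}

same_layout <- function(a, b) {
  a$fs == b$fs && a$pre_ms == b$pre_ms && a$stim_ms == b$stim_ms &&
    a$post_ms == b$post_ms
}

#' Synthesize a gated tone burst
#'
#' Generates the stimulus waveform: a sinusoidal carrier gated by a
#' raised-cosine (cos^2) rise/fall envelope with unit plateau amplitude.
#' With the defaults this is the 24 ms burst with 2 ms rise/fall and 20 ms
#' plateau used throughout the package. Level scaling is applied downstream.
#'
#' @param frequency Carrier frequency in Hz.
#' @param fs Sampling rate in Hz; must be at least `4 * frequency`.
#' @param duration_ms Total burst duration in ms.
#' @param rise_ms Rise time in ms (the fall time is identical).
#' @param phase Carrier phase offset in radians; `pi` yields the sample-wise
#'   negation of the `phase = 0` burst.
#' @return Numeric vector of `round(duration_ms/1000 * fs)` samples.
#' @export
#' @examples
#' w <- synth_tone_burst(1000, fs = 250000)
#' length(w)  # 6000 samples = 24 ms
synth_tone_burst <- function(frequency, fs, duration_ms = 24, rise_ms = 2,
                             phase = 0) {
  if (frequency <= 0) stop("frequency must be positive", call. = FALSE)
  if (fs < 4 * frequency) {
    stop("sampling rate ", fs, " Hz is below 4x the ", frequency,
         " Hz carrier (aliasing)", call. = FALSE)
  }
  if (2 * rise_ms > duration_ms) {
    stop("rise + fall exceeds the burst duration", call. = FALSE)
  }
  n <- round(duration_ms / 1000 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  env <- rep(1, n)
  rising <- t_ms < rise_ms
  env[rising] <- 0.5 * (1 - cos(pi * t_ms[rising] / rise_ms))
  falling <- t_ms > duration_ms - rise_ms
  env[falling] <- 0.5 * (1 - cos(pi * (duration_ms - t_ms[falling]) / rise_ms))
  env * sin(2 * pi * frequency * t_ms / 1000 + phase)
}

# 2-pole Butterworth band-pass emulating the analog preamplifier
recording_filter <- function(fs, low = 300, high = 3000) {
  nyq <- fs / 2
  if (low <= 0 || high <= low || high >= nyq) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  signal::butter(1, c(low, high) / nyq, type = "pass")
}

#' Band-pass filter a trace through the recording chain
#'
#' Applies the analog-preamplifier emulation: a single causal second-order
#' Butterworth band-pass section (default 300--3000 Hz). The filter is
#' applied once in the forward direction, not zero-phase, so CAP latencies
#' shift the way they would through real hardware.
#'
#' @param trace A [cap_trace()].
#' @param low,high Band edges in Hz; `high` must be below Nyquist.
#' @return A filtered `cap_trace` with the same layout.
#' @export
bandpass_trace <- function(trace, low = 300, high = 3000) {
  flt <- recording_filter(trace$fs, low, high)
  out <- as.numeric(signal::filter(flt, trace$samples))
  cap_trace(out, trace$fs, trace$pre_ms, trace$stim_ms, trace$post_ms)
}

# zero-mean Gaussian noise band-limited to the recording band, scaled so
# the steady-state RMS equals rms_uv
band_limited_noise <- function(n, fs, rms_uv, low = 300, high = 3000) {
  if (rms_uv < 0) stop("noise RMS must be non-negative", call. = FALSE)
  if (rms_uv == 0) return(numeric(n))
  flt <- recording_filter(fs, low, high)
  # white-noise power gain of the filter = sum of squared impulse response
  h <- as.numeric(signal::filter(flt, c(1, numeric(4095))))
  gain <- sqrt(sum(h^2))
  white <- stats::rnorm(n)
  as.numeric(signal::filter(flt, white)) * (rms_uv / gain)
}

#' Average an alternating-phase sequence of traces
#'
#' Sample-wise arithmetic mean of an even-length sequence of epochs whose
#' stimulus phase alternates trial by trial. Components that are locked to
#' the stimulus waveform and flip sign with its phase (the cochlear
#' microphonic artifact) cancel exactly in the mean; the CAP, which does not
#' invert, survives, and uncorrelated noise is reduced by `sqrt(n)`.
#'
#' @param traces A list of [cap_trace()] objects with identical layouts and
#'   an even length.
#' @return The averaged `cap_trace`.
#' @export
average_alternating <- function(traces) {
  if (length(traces) == 0) stop("no traces to average", call. = FALSE)
  if (length(traces) %% 2 != 0) {
    stop("alternating-phase averaging needs an even number of trials",
         call. = FALSE)
  }
  first <- traces[[1]]
  for (tr in traces[-1]) {
    if (!inherits(tr, "cap_trace") || !same_layout(first, tr) ||
        length(tr$samples) != length(first$samples)) {
      stop("all traces must share the same layout and length", call. = FALSE)
    }
  }
  mat <- vapply(traces, function(tr) tr$samples,
                numeric(length(first$samples)))
  cap_trace(rowMeans(mat), first$fs, first$pre_ms, first$stim_ms,
            first$post_ms)
}

#' Write and read a trace as columnar text
#'
#' The container is plain text: `key: value` header lines for the sampling
#' rate and epoch layout followed by one sample per line at full double
#' precision, so a write/read round trip is bit-exact.
#'
#' @param trace A [cap_trace()].
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   the reconstructed `cap_trace`.
#' @export
write_trace <- function(trace, path) {
  header <- c(
    sprintf("# fs: %.17g", trace$fs),
    sprintf("# pre_ms: %.17g", trace$pre_ms),
    sprintf("# stim_ms: %.17g", trace$stim_ms),
    sprintf("# post_ms: %.17g", trace$post_ms)
  )
  writeLines(c(header, sprintf("%.17g", trace$samples)), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "# ")
  header <- lines[is_header]
  get <- function(key) {
    line <- header[startsWith(header, paste0("# ", key, ":"))]
    if (length(line) != 1) stop("trace file missing header '", key, "'",
                                call. = FALSE)
    as.numeric(sub(".*: ", "", line))
  }
  cap_trace(as.numeric(lines[!is_header]), fs = get("fs"),
            pre_ms = get("pre_ms"), stim_ms = get("stim_ms"),
            post_ms = get("post_ms"))
}
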