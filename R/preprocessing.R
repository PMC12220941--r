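#' A set of raw sweeps for one stimulus
#'
#' The unit of acquisition: repeated per-trial voltage traces recorded in
#' response to the same stimulus, with the metadata needed for averaging and
#' mains-phase bookkeeping. The time axis is
#' `t = index / sample_rate - pre_stimulus_ms / 1000`, i.e. stimulus onset at
#' t = 0 with `pre_stimulus_ms` of baseline before it.
#'
#' @param sweeps Numeric matrix, one column per trial (equal lengths), in µV.
#'   A list of equal-length numeric vectors is also accepted.
#' @param sample_rate Sampling rate in Hz.
#' @param pre_stimulus_ms Pre-stimulus baseline duration in ms.
#' @param channel `"ERG"` or `"VEP"`.
#' @param stimulus A [stimulus_spec()] (optional but needed by the pipeline).
#' @param trial_onset_times_s Trial onset times in seconds, one per sweep;
#'   defaults to a regular 987 ms spacing. Used to phase the mains component
#'   in simulations and retained for audit.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, sample_rate = 2000, pre_stimulus_ms = 20,
                      channel = c("ERG", "VEP"), stimulus = NULL,
                      trial_onset_times_s = NULL) {
  channel <- match.arg(channel)
  if (is.list(sweeps)) {
    lens <- lengths(sweeps)
    if (length(unique(lens)) != 1L)
      stop("all sweeps must have the same length", call. = FALSE)
    sweeps <- do.call(cbind, sweeps)
  }
  sweeps <- as.matrix(sweeps)
  if (ncol(sweeps) < 1L) stop("at least one sweep is required", call. = FALSE)
  stopifnot(is.numeric(sample_rate), sample_rate > 0, pre_stimulus_ms >= 0)
  if (!is.null(stimulus)) stopifnot(inherits(stimulus, "stimulus_spec"))
  if (is.null(trial_onset_times_s))
    trial_onset_times_s <- (seq_len(ncol(sweeps)) - 1) * 0.987
  if (length(trial_onset_times_s) != ncol(sweeps))
    stop("need one trial onset time per sweep", call. = FALSE)
  structure(
    list(sweeps = sweeps, sample_rate = sample_rate,
         pre_stimulus_ms = pre_stimulus_ms, channel = channel,
         stimulus = stimulus, trial_onset_times_s = trial_onset_times_s),
    class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples, %g Hz, %s channel\n",
              ncol(x$sweeps), nrow(x$sweeps), x$sample_rate, x$channel))
  if (!is.null(x$stimulus)) print(x$stimulus)
  invisible(x)
}

#' A single (typically trial-averaged) trace
#'
#' @param values Voltage samples in µV.
#' @param sample_rate Sampling rate in Hz.
#' @param pre_stimulus_ms Pre-stimulus baseline duration in ms (may be
#'   negative for traces cropped to start after stimulus onset).
#' @param filter_log Character vector recording every transformation applied,
#'   in order.
#' @param stimulus Optional [stimulus_spec()] carried along for convention
#'   decisions downstream.
#' @param channel `"ERG"` or `"VEP"`.
#' @return An object of class `erg_trace`.
#' @export
new_trace <- function(values, sample_rate = 2000, pre_stimulus_ms = 20,
                      filter_log = character(), stimulus = NULL,
                      channel = "ERG") {
  stopifnot(is.numeric(values), all(is.finite(values)), sample_rate > 0)
  structure(
    list(values = as.numeric(values), sample_rate = sample_rate,
         pre_stimulus_ms = pre_stimulus_ms, filter_log = filter_log,
         stimulus = stimulus, channel = channel),
    class = "erg_trace")
}

#' @export
print.erg_trace <- function(x, ...) {
  cat(sprintf("<erg_trace> %d samples @ %g Hz (%.1f ms pre-stimulus)\n",
              length(x$values), x$sample_rate, x$pre_stimulus_ms))
  if (length(x$filter_log))
    cat("  filters:", paste(x$filter_log, collapse = " -> "), "\n")
  invisible(x)
}

#' Time axis of a trace in milliseconds (stimulus onset at 0)
#' @param trace An `erg_trace`.
#' @return Numeric vector of times in ms.
#' @export
trace_time <- function(trace) {
  stopifnot(inherits(trace, "erg_trace"))
  (seq_along(trace$values) - 1) / trace$sample_rate * 1000 - trace$pre_stimulus_ms
}

# Zero-phase application of a digital filter with constant (edge-value)
# padding. Constant padding continues the quiescent baseline outside the
# epoch; reflection-style padding biases the near-DC content of short epochs
# and distorts sub-1 Hz high-pass stages.
zero_phase <- function(x, filt, pad) {
  n <- length(x)
  pad <- max(1L, as.integer(pad))
  padded <- c(rep(x[1], pad), x, rep(x[n], pad))
  y <- signal::filtfilt(filt, padded)
  y[(pad + 1):(pad + n)]
}

# Padding long enough for the slowest pole to settle, capped at 4 s.
pad_samples <- function(corner_hz, sample_rate) {
  ceiling(sample_rate * min(4, max(0.5, 3 / corner_hz)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' High-pass and low-pass Butterworth sections (order `order` each) applied
#' forward and backward, so the filter has zero group delay: the peak of a
#' symmetric pulse is not displaced (to within one sample). Standard
#' channel settings are 0.125–300 Hz for flash ERG and 3–100 Hz for VEP;
#' oscillatory potentials are isolated with 75–300 Hz.
#'
#' @param trace An `erg_trace`.
#' @param low_hz Lower corner (Hz, >= 0; 0 disables the high-pass section).
#' @param high_hz Upper corner (Hz, must be below Nyquist).
#' @param order Butterworth order of each section (applied twice by the
#'   forward-backward pass).
#' @return The filtered `erg_trace`, with `filter_log` appended.
#' @export
bandpass <- function(trace, low_hz, high_hz, order = 4) {
  stopifnot(inherits(trace, "erg_trace"))
  nyq <- trace$sample_rate / 2
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq))
    stop("need 0 <= low_hz < high_hz < sample_rate/2", call. = FALSE)
  x <- trace$values
  if (low_hz > 0) {
    hp <- signal::butter(order, low_hz / nyq, type = "high")
    x <- zero_phase(x, hp, pad_samples(low_hz, trace$sample_rate))
  }
  if (high_hz < nyq) {
    lp <- signal::butter(order, high_hz / nyq, type = "low")
    x <- zero_phase(x, lp, pad_samples(high_hz, trace$sample_rate))
  }
  trace$values <- x
  trace$filter_log <- c(trace$filter_log,
                        sprintf("bandpass %g-%g Hz (zero-phase butterworth order %d)",
                                low_hz, high_hz, order))
  trace
}

#' Zero-phase 50 Hz mains notch filter
#'
#' A biquad notch centered at 50 Hz applied forward and backward. The
#' default quality factor Q = 30 gives a narrow (~1.7 Hz) stopband:
#' essentially complete rejection of steady mains interference while leaving
#' a 30 Hz component untouched. Note that on very short epochs a windowed
#' 50 Hz burst is spectrally wider than the notch and is only partially
#' removed — trial averaging with intertrial intervals that are not
#' multiples of 20 ms is the primary mains defense; the notch mops up the
#' steady remainder. Reflection padding is used so an ongoing oscillation
#' continues smoothly across the epoch edges.
#'
#' @param trace An `erg_trace` (sample rate must exceed 100 Hz).
#' @param q Notch quality factor (center frequency / bandwidth).
#' @return The filtered `erg_trace`, with `filter_log` appended.
#' @export
notch50 <- function(trace, q = 30) {
  stopifnot(inherits(trace, "erg_trace"))
  if (trace$sample_rate <= 100)
    stop("sample rate must exceed 100 Hz for a 50 Hz notch", call. = FALSE)
  w0 <- 2 * pi * 50 / trace$sample_rate
  al <- sin(w0) / (2 * q)
  filt <- signal::Arma(b = c(1, -2 * cos(w0), 1) / (1 + al),
                       a = c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al)))
  x <- trace$values
  n <- length(x)
  p <- n - 1L
  padded <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filtfilt(filt, padded)
  trace$values <- y[(p + 1):(p + n)]
  trace$filter_log <- c(trace$filter_log,
                        sprintf("notch 50 Hz (zero-phase biquad, Q = %g)", q))
  trace
}

#' Average the trials of a sweep set
#'
#' Pointwise arithmetic mean across sweeps; no artifact rejection. Besides
#' suppressing white noise by 1/sqrt(n), averaging cancels 50 Hz mains
#' interference almost completely when the intertrial interval is not a
#' multiple of 20 ms (e.g. the 987 ms interval spreads trial phases evenly
#' around the circle).
#'
#' @param sweeps A [sweep_set()].
#' @return An `erg_trace` with the same time axis.
#' @export
average_trials <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (ncol(sweeps$sweeps) < 1L) stop("empty sweep set", call. = FALSE)
  new_trace(rowMeans(sweeps$sweeps),
            sample_rate = sweeps$sample_rate,
            pre_stimulus_ms = sweeps$pre_stimulus_ms,
            filter_log = sprintf("average of %d trials", ncol(sweeps$sweeps)),
            stimulus = sweeps$stimulus,
            channel = sweeps$channel)
}

#' Baseline statistics of the pre-stimulus segment
#'
#' Mean and standard deviation over the samples before stimulus onset
#' (t < 0). The mean anchors "measured from baseline" amplitude conventions;
#' the standard deviation feeds the marker presence criterion.
#'
#' @param trace An `erg_trace` whose pre-stimulus segment spans at least 10
#'   samples.
#' @return A list with `mean` and `sd` (µV).
#' @export
baseline_stats <- function(trace) {
  stopifnot(inherits(trace, "erg_trace"))
  idx <- trace_time(trace) < 0
  if (sum(idx) < 10L)
    stop("pre-stimulus segment must span at least 10 samples", call. = FALSE)
  x <- trace$values[idx]
  list(mean = mean(x), sd = stats::sd(x))
}
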