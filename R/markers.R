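#' Default marker search windows
#'
#' Half-open (lo, hi\] windows in ms after stimulus onset for each component.
#' The defaults bracket the reported medians with margin: a_o peaks near
#' 8 ms, the photopic a-wave near 17 ms, the b-wave between roughly 35 and
#' 70 ms; on the cortical side N1_o precedes P1, which precedes N1.
#'
#' @return Named list of length-2 numeric vectors (ms).
#' @export
default_marker_windows <- function() {
  list(a_o = c(0.5, 12), a = c(12, 30), b = c(20, 120),
       N1_o = c(15, 40), P1 = c(30, 50), N1 = c(40, 90))
}

window_indices <- function(trace, win) {
  t <- trace_time(trace)
  if (max(t) < win[2])
    stop(sprintf("trace ends at %.1f ms; detection window extends to %.1f ms",
                 max(t), win[2]), call. = FALSE)
  which(t > win[1] & t <= win[2])
}

# Earliest extremum in a half-open window. Ties on plateaus resolve to the
# earliest sample: implicit time is time-to-peak, so earliest attainment is
# the conservative choice. An extremum sitting on the first or last sample
# of the searched range is not a genuine component peak but the slope of a
# neighbouring wave passing through the window (e.g. the a-wave rise
# crossing the a_o window); `interior` flags this for the presence gate.
window_extremum <- function(trace, win, direction = c("min", "max")) {
  direction <- match.arg(direction)
  idx <- window_indices(trace, win)
  extremum_at(trace, idx, direction)
}

extremum_at <- function(trace, idx, direction) {
  vals <- trace$values[idx]
  i <- if (direction == "min") which.min(vals) else which.max(vals)
  list(index = idx[i], time_ms = trace_time(trace)[idx[i]], value = vals[i],
       interior = i > 1L && i < length(idx))
}

marker_row <- function(name, present, time_ms = NA_real_, amp = NA_real_,
                       reference = NA_character_, confidence = "absent") {
  tibble::tibble(name = name, present = present,
                 implicit_time_ms = if (present) time_ms else NA_real_,
                 amplitude_uV = if (present) amp else NA_real_,
                 reference = reference, confidence = confidence)
}

new_marker_set <- function(markers, conventions, noise_sd, baseline_mean) {
  structure(list(markers = markers, conventions = conventions,
                 noise_sd_uV = noise_sd, baseline_mean_uV = baseline_mean),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> (%s conventions, baseline sd %.2f uV)\n",
              x$conventions$adaptation, x$noise_sd_uV))
  print(x$markers)
  invisible(x)
}

# Presence criterion: a deflection counts as present when its magnitude
# exceeds both 3x the pre-stimulus noise sd and an absolute floor. The floor
# keeps noise-free traces (sd = 0) from declaring every sub-microvolt ripple
# a component.
presence_threshold <- function(noise_sd, min_amplitude_uV) {
  max(3 * noise_sd, min_amplitude_uV)
}

#' Detect the optogenetic a_o-wave
#'
#' Searches the early post-stimulus window for the fast negative deflection
#' produced by direct ReaChR activation of ON-bipolar cells. The a_o trough
#' occurs around 8 ms — well before the photoreceptor-driven a-wave — and
#' its onset is effectively instantaneous (the first post-stimulus sample
#' already deviates from baseline). Amplitude is measured from the baseline
#' mean; the marker is present when the trough magnitude exceeds
#' 3x the baseline noise sd (and the absolute floor).
#'
#' @param trace A filtered, averaged ERG `erg_trace`.
#' @param noise_sd Baseline noise sd in µV; taken from [baseline_stats()]
#'   when `NULL`.
#' @param window Search window (lo, hi\] in ms.
#' @param min_amplitude_uV Absolute presence floor in µV.
#' @return A one-row marker tibble (see [place_erg_markers()]).
#' @export
detect_ao <- function(trace, noise_sd = NULL, window = c(0.5, 12),
                      min_amplitude_uV = 2) {
  stopifnot(inherits(trace, "erg_trace"))
  bl <- baseline_stats(trace)
  if (is.null(noise_sd)) noise_sd <- bl$sd
  ext <- window_extremum(trace, window, "min")
  amp <- bl$mean - ext$value
  thr <- presence_threshold(noise_sd, min_amplitude_uV)
  if (amp >= thr && ext$interior && ext$time_ms <= window[2]) {
    marker_row("a_o", TRUE, ext$time_ms, amp, "baseline", "clear")
  } else {
    marker_row("a_o", FALSE, reference = "baseline")
  }
}

#' Place ERG wave markers under adaptation-specific conventions
#'
#' Detects a_o, a and b on a filtered, trial-averaged ERG trace:
#' \itemize{
#'   \item a_o: most negative sample in the early window (see [detect_ao()]).
#'   \item a-wave: most negative sample in its window, measured from
#'     baseline. When a_o is present the a-wave is still measured but
#'     flagged `confidence = "low"`: the oscillations following a_o
#'     superimpose the incident a-wave and preclude accurate quantification.
#'   \item b-wave: most positive sample in its window. Dark-adapted, the
#'     amplitude is measured from the level of the a-wave trough (standard
#'     clinical convention); light-adapted it is measured from baseline,
#'     because superposition with optogenetic responses makes the true
#'     a-wave level unreliable at bright stimuli.
#' }
#' Presence of each marker is gated at 3x the baseline noise sd.
#'
#' @param trace A filtered, averaged ERG `erg_trace` extending to at least
#'   120 ms post-stimulus.
#' @param stim The [stimulus_spec()]; defaults to the one carried by the
#'   trace. Determines the adaptation convention.
#' @param windows Marker window list, see [default_marker_windows()].
#' @param min_amplitude_uV Absolute presence floor in µV.
#' @return A `marker_set` whose `conventions` record the adaptation state
#'   and b-wave reference actually applied.
#' @export
place_erg_markers <- function(trace, stim = NULL,
                              windows = default_marker_windows(),
                              min_amplitude_uV = 2) {
  stopifnot(inherits(trace, "erg_trace"))
  if (is.null(stim)) stim <- trace$stimulus
  if (is.null(stim)) stop("a stimulus_spec is required", call. = FALSE)
  if (max(trace_time(trace)) < 120)
    stop("trace must extend to at least 120 ms post-stimulus", call. = FALSE)
  bl <- baseline_stats(trace)
  thr <- presence_threshold(bl$sd, min_amplitude_uV)

  ao <- detect_ao(trace, noise_sd = bl$sd, window = windows$a_o,
                  min_amplitude_uV = min_amplitude_uV)

  a_ext <- window_extremum(trace, windows$a, "min")
  a_amp <- bl$mean - a_ext$value
  a_present <- a_amp >= thr && a_ext$interior
  a <- if (a_present) {
    marker_row("a", TRUE, a_ext$time_ms, a_amp, "baseline",
               if (ao$present) "low" else "clear")
  } else marker_row("a", FALSE, reference = "baseline")

  b_ext <- window_extremum(trace, windows$b, "max")
  dark <- stim$adaptation == "dark"
  b_reference <- if (dark && a_present) "a_peak" else "baseline"
  b_ref_level <- if (b_reference == "a_peak") a_ext$value else bl$mean
  b_amp <- b_ext$value - b_ref_level
  b <- if (b_amp >= thr && b_ext$interior) {
    marker_row("b", TRUE, b_ext$time_ms, b_amp, b_reference, "clear")
  } else marker_row("b", FALSE, reference = b_reference)

  new_marker_set(
    rbind(ao, a, b),
    conventions = list(adaptation = stim$adaptation,
                       b_reference = b_reference,
                       channel = "ERG",
                       presence_threshold_uV = thr),
    noise_sd = bl$sd, baseline_mean = bl$mean)
}

#' Place flash-VEP markers
#'
#' Detects the cortical components on a filtered (3–100 Hz, plus 50 Hz
#' notch for light-adapted recordings), trial-averaged VEP trace:
#' \itemize{
#'   \item N1_o: most negative sample in its early window, measured from
#'     baseline — the early cortical deflection attributed to the
#'     optogenetic pathway arriving ahead of the native signal. It is often
#'     just above noise level, so it is accepted from 2x the baseline noise
#'     sd with `confidence = "low"` below 3x.
#'   \item P1: most positive sample in its window, from baseline.
#'   \item N1: most negative sample in its window occurring after P1;
#'     its amplitude is measured from the level of the preceding P1 peak.
#' }
#' If the windows cannot be satisfied (e.g. no sample after P1), the marker
#' is returned absent rather than raising an error.
#'
#' @param trace A filtered, averaged VEP `erg_trace`.
#' @param windows Marker window list, see [default_marker_windows()].
#' @param min_amplitude_uV Absolute presence floor in µV.
#' @return A `marker_set`.
#' @export
place_vep_markers <- function(trace, windows = default_marker_windows(),
                              min_amplitude_uV = 2) {
  stopifnot(inherits(trace, "erg_trace"))
  bl <- baseline_stats(trace)
  thr3 <- presence_threshold(bl$sd, min_amplitude_uV)
  thr2 <- max(2 * bl$sd, min_amplitude_uV)

  n1o_ext <- window_extremum(trace, windows$N1_o, "min")
  n1o_amp <- bl$mean - n1o_ext$value
  n1o <- if (n1o_amp >= thr2 && n1o_ext$interior) {
    marker_row("N1_o", TRUE, n1o_ext$time_ms, n1o_amp, "baseline",
               if (n1o_amp >= thr3) "clear" else "low")
  } else marker_row("N1_o", FALSE, reference = "baseline")

  p1_ext <- window_extremum(trace, windows$P1, "max")
  p1_amp <- p1_ext$value - bl$mean
  p1_present <- p1_amp >= thr3 && p1_ext$interior
  p1 <- if (p1_present) {
    marker_row("P1", TRUE, p1_ext$time_ms, p1_amp, "baseline", "clear")
  } else marker_row("P1", FALSE, reference = "baseline")

  idx <- window_indices(trace, windows$N1)
  if (p1_present) idx <- idx[trace_time(trace)[idx] > p1_ext$time_ms]
  if (length(idx) == 0L) {
    n1 <- marker_row("N1", FALSE, reference = "P1_peak")
  } else {
    ext <- extremum_at(trace, idx, "min")
    n1_ref <- if (p1_present) "P1_peak" else "baseline"
    n1_level <- if (p1_present) p1_ext$value else bl$mean
    n1_amp <- n1_level - ext$value
    n1 <- if (n1_amp >= thr3 && ext$interior) {
      marker_row("N1", TRUE, ext$time_ms, n1_amp, n1_ref, "clear")
    } else marker_row("N1", FALSE, reference = n1_ref)
  }

  new_marker_set(
    rbind(n1o, p1, n1),
    conventions = list(adaptation = if (!is.null(trace$stimulus))
      trace$stimulus$adaptation else NA_character_,
      n1_reference = "P1_peak", channel = "VEP",
      presence_threshold_uV = thr3),
    noise_sd = bl$sd, baseline_mean = bl$mean)
}

get_marker <- function(markerset, name) {
  stopifnot(inherits(markerset, "marker_set"))
  row <- markerset$markers[markerset$markers$name == name, ]
  if (nrow(row) != 1L)
    stop(sprintf("no marker named '%s' in this marker set", name), call. = FALSE)
  row
}

#' Query marker amplitude or implicit time
#'
#' Amplitudes are positive magnitudes with their reference level
#' (`baseline`, `a_peak` or `P1_peak`) recorded in the marker set. Querying
#' an absent marker returns `NA` (an explicit absent value), not an error.
#'
#' @param markerset A `marker_set`.
#' @param name Marker name (`"a"`, `"a_o"`, `"b"`, `"P1"`, `"N1"`, `"N1_o"`).
#' @return Amplitude in µV / implicit time in ms, or `NA` if absent.
#' @export
marker_amplitude <- function(markerset, name) {
  row <- get_marker(markerset, name)
  if (!row$present) return(NA_real_)
  row$amplitude_uV
}

#' @rdname marker_amplitude
#' @export
marker_implicit_time <- function(markerset, name) {
  row <- get_marker(markerset, name)
  if (!row$present) return(NA_real_)
  row$implicit_time_ms
}
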