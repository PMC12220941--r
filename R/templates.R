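#' Parametric waveform component
#'
#' The simulator composes traces from simple parametric shapes:
#' \itemize{
#'   \item pulse kinds (`a`, `b`, `a_o`, `slow_positive`, `P1`, `N1`,
#'     `N1_o`): two-sided Gaussians with separate rise and decay widths,
#'     zero before stimulus onset. The `a_o` kind is special in that its
#'     Gaussian rise is cut at t = 0, so the trace is already displaced at
#'     the first post-stimulus sample — the virtually instantaneous onset of
#'     direct channel-gated currents.
#'   \item oscillatory kinds (`op_burst`, `post_ao_oscillation`):
#'     exponentially damped sinusoids starting at `peak_time_ms` (the burst
#'     onset), frequency restricted to the 75–300 Hz OP band.
#'   \item `mains`: an ongoing 50 Hz sinusoid (not stimulus-locked) with a
#'     phase offset in seconds.
#' }
#'
#' @param kind Component kind (see Details).
#' @param peak_time_ms Peak time for pulse kinds; burst onset for
#'   oscillatory kinds; ignored for `mains`.
#' @param peak_amplitude_uV Signed amplitude in µV (negative for troughs).
#' @param rise_sigma_ms,decay_sigma_ms Gaussian widths (pulse kinds).
#' @param frequency_hz Oscillation frequency (oscillatory kinds; `mains` is
#'   fixed at 50 Hz).
#' @param decay_tau_ms Envelope time constant (oscillatory kinds).
#' @param phase_s Phase offset in seconds (`mains` only).
#' @return An object of class `component_template`.
#' @export
component_template <- function(kind, peak_time_ms = NA_real_,
                               peak_amplitude_uV,
                               rise_sigma_ms = NA_real_,
                               decay_sigma_ms = NA_real_,
                               frequency_hz = NA_real_,
                               decay_tau_ms = NA_real_,
                               phase_s = 0) {
  pulse_kinds <- c("a", "b", "a_o", "slow_positive", "P1", "N1", "N1_o")
  osc_kinds <- c("op_burst", "post_ao_oscillation")
  if (!kind %in% c(pulse_kinds, osc_kinds, "mains"))
    stop(sprintf("unknown component kind '%s'", kind), call. = FALSE)
  if (kind %in% pulse_kinds) {
    stopifnot(is.finite(rise_sigma_ms), rise_sigma_ms > 0,
              is.finite(decay_sigma_ms), decay_sigma_ms > 0,
              is.finite(peak_time_ms))
  }
  if (kind %in% osc_kinds) {
    stopifnot(is.finite(frequency_hz), is.finite(decay_tau_ms),
              decay_tau_ms > 0, is.finite(peak_time_ms))
    if (frequency_hz < 75 || frequency_hz > 300)
      stop("oscillatory component frequency must lie in [75, 300] Hz",
           call. = FALSE)
  }
  if (kind == "mains") frequency_hz <- 50
  structure(
    list(kind = kind, peak_time_ms = peak_time_ms,
         peak_amplitude_uV = peak_amplitude_uV,
         rise_sigma_ms = rise_sigma_ms, decay_sigma_ms = decay_sigma_ms,
         frequency_hz = frequency_hz, decay_tau_ms = decay_tau_ms,
         phase_s = phase_s),
    class = "component_template")
}

#' Evaluate a component template on a time axis
#'
#' Deterministic, pure function of the template and the time axis.
#'
#' @param tpl A [component_template()].
#' @param t_ms Time axis in ms (stimulus onset at 0).
#' @return Voltage contribution in µV.
#' @export
component_wave <- function(tpl, t_ms) {
  stopifnot(inherits(tpl, "component_template"))
  k <- tpl$kind
  if (k == "mains") {
    return(tpl$peak_amplitude_uV *
             sin(2 * pi * 50 * (t_ms / 1000 + tpl$phase_s)))
  }
  if (k %in% c("op_burst", "post_ao_oscillation")) {
    dt <- t_ms - tpl$peak_time_ms
    y <- ifelse(dt < 0, 0,
                tpl$peak_amplitude_uV * exp(-dt / tpl$decay_tau_ms) *
                  sin(2 * pi * tpl$frequency_hz * dt / 1000))
    return(y)
  }
  sig <- ifelse(t_ms < tpl$peak_time_ms, tpl$rise_sigma_ms, tpl$decay_sigma_ms)
  y <- tpl$peak_amplitude_uV * exp(-0.5 * ((t_ms - tpl$peak_time_ms) / sig)^2)
  # stimulus-driven components cannot precede the stimulus
  y[t_ms < 0] <- 0
  y
}

hill_scale <- function(energy, e50, n, e_ref) {
  h <- function(E) E^n / (E^n + e50^n)
  if (energy <= 0) return(0)
  h(energy) / h(e_ref)
}

component_row <- function(class, kind, peak, amp, rise = NA, decay = NA,
                          freq = NA, tau = NA, e_ref = 1, e50 = 0, n = 1,
                          reachr = FALSE) {
  tibble::tibble(stimulus_class = class, kind = kind, peak_time_ms = peak,
                 amplitude_uV = amp, rise_sigma_ms = rise,
                 decay_sigma_ms = decay, frequency_hz = freq,
                 decay_tau_ms = tau, e_ref = e_ref, e50 = e50, hill_n = n,
                 reachr = reachr)
}

# Native retinal components shared by WT and WT+ReaChR. Amplitudes are
# anchored at reported group medians where available (b 61.92 uV at
# 10 cd.s/m2 light-adapted; timings a 17.4 ms, b 51.62 ms light / 35.75 ms
# dark; blue-on-amber b 107.86 uV at 5 cd.s/m2); the remaining shape
# parameters are the simplest values consistent with normal mouse flash-ERG
# morphology.
native_components <- function() {
  rbind(
    # dark-adapted (rod-dominated; a appears only at mesopic energies)
    component_row("dark", "a", 16, -150, rise = 2.5, decay = 5,
                  e_ref = 3, e50 = 1.5, n = 1),
    component_row("dark", "b", 35.75, 300, rise = 5.5, decay = 14,
                  e_ref = 3, e50 = 0.05, n = 1),
    component_row("dark", "op_burst", 25, 6, freq = 110, tau = 8,
                  e_ref = 3, e50 = 0.05, n = 1),
    # light-adapted (cone-driven) series on a 30 cd/m2 background
    component_row("light", "a", 17.4, -15, rise = 2.5, decay = 4,
                  e_ref = 100, e50 = 15, n = 1),
    component_row("light", "b", 51.62, 61.92, rise = 8.5, decay = 14,
                  e_ref = 10, e50 = 15, n = 1),
    component_row("light", "op_burst", 25, 3, freq = 110, tau = 8,
                  e_ref = 100, e50 = 15, n = 1),
    # blue flash on bright amber background (S-cone-driven b-wave)
    component_row("amber", "b", 48, 107.86, rise = 8.5, decay = 14,
                  e_ref = 5, e50 = 5, n = 1),
    component_row("amber", "op_burst", 25, 3, freq = 110, tau = 8,
                  e_ref = 5, e50 = 5, n = 1),
    # cortical components
    component_row("vep_dark", "P1", 40, 10, rise = 4.5, decay = 4.5,
                  e_ref = 1, e50 = 0.05, n = 1),
    component_row("vep_dark", "N1", 55.25, -15, rise = 6, decay = 6,
                  e_ref = 1, e50 = 0.05, n = 1),
    component_row("vep_light", "P1", 40, 10, rise = 4.5, decay = 4.5,
                  e_ref = 100, e50 = 15, n = 1),
    component_row("vep_light", "N1", 55.25, -15, rise = 6, decay = 6,
                  e_ref = 100, e50 = 15, n = 1))
}

# Optogenetic components: emitted only when the flash is ReaChR-activating.
# a_o amplitude at the 100 cd.s/m2 reference differs sharply between the
# nondegenerate (33.76 uV) and degenerate (6.36 uV) retina.
reachr_components <- function(genotype) {
  ao_amp <- if (genotype == "WT_ReaChR") -33.76 else -6.36
  rows <- rbind(
    component_row("light", "a_o", 8, ao_amp, rise = 4.8, decay = 2.5,
                  e_ref = 100, e50 = 150, n = 2, reachr = TRUE),
    component_row("vep_light", "N1_o", 27.12,
                  if (genotype == "WT_ReaChR") -6 else -4,
                  rise = 4, decay = 4, e_ref = 100, e50 = 150, n = 2,
                  reachr = TRUE))
  if (genotype == "WT_ReaChR") {
    rows <- rbind(rows,
      component_row("light", "post_ao_oscillation", 11, 10, freq = 140,
                    tau = 8, e_ref = 100, e50 = 150, n = 2, reachr = TRUE))
  } else {
    # in the degenerate retina a slow positive deflection follows a_o,
    # loosely resembling b-wave kinetics
    rows <- rbind(rows,
      component_row("light", "slow_positive", 70, 6, rise = 15, decay = 25,
                    e_ref = 100, e50 = 150, n = 2, reachr = TRUE))
  }
  rows
}

#' Genotype waveform template
#'
#' Bundles the per-stimulus-class component templates and interaction
#' parameters for one genotype:
#' \describe{
#'   \item{WT}{native rod/cone components only; no optogenetic components.}
#'   \item{WT_ReaChR}{native components plus the optogenetic a_o, the
#'     oscillations following it, and the cortical N1_o. The native
#'     light-adapted b-wave is dampened by `b_dampening` (0.556; 0.538 under
#'     a ReaChR-preactivating background) and delayed by `b_delay_ms`
#'     (16.13 ms) for ReaChR-activating flashes.}
#'   \item{RD1_ReaChR}{optogenetic components only (no surviving
#'     photoreceptors, hence no a or b); the a_o is small (6.36 µV at the
#'     reference energy) and followed by a slow positive deflection.}
#' }
#' Component amplitudes scale with flash energy through a saturating Hill
#' function anchored at each component's reference energy; optogenetic
#' components are additionally hard-gated by the ReaChR activation threshold
#' (via [classify_stimulus()]).
#'
#' @param genotype `"WT"`, `"WT_ReaChR"` or `"RD1_ReaChR"`.
#' @return An object of class `genotype_template`.
#' @export
genotype_template <- function(genotype = c("WT", "WT_ReaChR", "RD1_ReaChR")) {
  genotype <- match.arg(genotype)
  comps <- switch(genotype,
    WT = native_components(),
    WT_ReaChR = rbind(native_components(), reachr_components("WT_ReaChR")),
    RD1_ReaChR = reachr_components("RD1_ReaChR"))
  structure(
    list(genotype = genotype,
         components = comps,
         b_dampening = if (genotype == "WT_ReaChR") 0.556 else 1,
         b_dampening_preactivated = if (genotype == "WT_ReaChR") 0.538 else 1,
         b_delay_ms = if (genotype == "WT_ReaChR") 67.75 - 51.62 else 0),
    class = "genotype_template")
}

#' @export
print.genotype_template <- function(x, ...) {
  cat(sprintf("<genotype_template> %s: %d components", x$genotype,
              nrow(x$components)))
  if (x$genotype == "WT_ReaChR")
    cat(sprintf(" (b dampening %.3f/%.3f, b delay %.2f ms)",
                x$b_dampening, x$b_dampening_preactivated, x$b_delay_ms))
  cat("\n")
  invisible(x)
}

# Stimulus class used to select template components.
stimulus_class <- function(stim, channel, cal) {
  if (channel == "VEP")
    return(if (stim$adaptation == "dark") "vep_dark" else "vep_light")
  if (stim$adaptation == "dark") return("dark")
  cls <- classify_stimulus(stim, cal)
  if (cls$background == "preactivating_background") "amber" else "light"
}

# Noise-free summed trace for one genotype x stimulus. `effects` carries
# optional per-kind between-animal perturbations: a named list with
# `amp_mult` and `time_shift_ms`, each keyed by component kind.
simulate_signal <- function(genotype, stim, t_ms, channel = "ERG",
                            cal = photometry_calibration(), effects = NULL) {
  tpl <- if (inherits(genotype, "genotype_template")) genotype
         else genotype_template(genotype)
  cls <- classify_stimulus(stim, cal)
  activating <- cls$flash == "reachr_activating"
  sclass <- stimulus_class(stim, channel, cal)
  comps <- tpl$components[tpl$components$stimulus_class == sclass, ]
  y <- numeric(length(t_ms))
  for (i in seq_len(nrow(comps))) {
    row <- comps[i, ]
    if (row$reachr && !activating) next
    amp <- row$amplitude_uV *
      hill_scale(stim$flash_energy, row$e50, row$hill_n, row$e_ref)
    peak <- row$peak_time_ms
    if (row$kind == "b") {
      amp <- amp * (if (sclass == "amber") tpl$b_dampening_preactivated
                    else tpl$b_dampening)
      if (activating) peak <- peak + tpl$b_delay_ms
    }
    if (!is.null(effects)) {
      m <- effects$amp_mult[row$kind]
      if (!is.na(m)) amp <- amp * m
      s <- effects$time_shift_ms[row$kind]
      if (!is.na(s)) peak <- peak + s
    }
    if (amp == 0) next
    ct <- component_template(row$kind, peak_time_ms = peak,
                             peak_amplitude_uV = amp,
                             rise_sigma_ms = row$rise_sigma_ms,
                             decay_sigma_ms = row$decay_sigma_ms,
                             frequency_hz = row$frequency_hz,
                             decay_tau_ms = row$decay_tau_ms)
    y <- y + component_wave(ct, t_ms)
  }
  y
}
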