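#' Photometric calibration for optogenetic ERG stimuli
#'
#' Bundles the constants needed to place photometric stimulus descriptions
#' (flash energy in cd·s/m², steady background luminance in cd/m²) on the
#' retinal photon-flux scale used to reason about ReaChR activation.
#'
#' The default linear constant `k_flash` is anchored at the equivalence
#' 68 cd·s/m² = 8e14 photons/cm²/s, the minimum flux reported to change
#' ganglion-cell spike rates in ReaChR-expressing retinas. Flux scales
#' linearly with flash energy under full-field (ganzfeld) stimulation, so a
#' single constant suffices; no radiometric model of the LED spectra, pupil
#' area or eye geometry is attempted.
#'
#' Per-primary weights approximate the relative effectiveness of each LED
#' primary on ReaChR (lambda_max approximately 590 nm): red light is fully
#' effective, blue light only weakly so. "amber" denotes the red+green
#' mixture used as a ReaChR-preactivating background.
#'
#' @param k_flash Photons·cm⁻²·s⁻¹ per cd·s/m² of flash energy.
#' @param reachr_threshold_flux Flux at and above which a flash is classified
#'   as ReaChR-activating (photons·cm⁻²·s⁻¹). The comparison is inclusive.
#' @param primary_weights Named numeric vector of dimensionless weights in
#'   \[0, 1\] keyed by color (`red`, `green`, `blue`, `white`, `amber`).
#' @param background_integration_s Integration window (seconds) used to place
#'   a steady background luminance on the flash-energy scale.
#' @param preactivation_flux Background flux at and above which a background
#'   is considered to drive continuous (pre-activating) ReaChR currents.
#' @return An object of class `photometry_calibration`.
#' @examples
#' cal <- photometry_calibration()
#' retinal_flux(68, cal)   # 8e14
#' retinal_flux(100, cal)  # ~1.18e15
#' @export
photometry_calibration <- function(k_flash = 8e14 / 68,
                                   reachr_threshold_flux = 8e14,
                                   primary_weights = c(red = 1, green = 0.8,
                                                       blue = 0.2, white = 1,
                                                       amber = 0.9),
                                   background_integration_s = 1,
                                   preactivation_flux = 1e16) {
  stopifnot(is.numeric(k_flash), length(k_flash) == 1L, k_flash > 0,
            is.numeric(reachr_threshold_flux), reachr_threshold_flux > 0,
            is.numeric(background_integration_s), background_integration_s > 0,
            is.numeric(preactivation_flux), preactivation_flux > 0)
  if (is.null(names(primary_weights)) || any(!nzchar(names(primary_weights))))
    stop("`primary_weights` must be a named numeric vector", call. = FALSE)
  if (any(primary_weights < 0 | primary_weights > 1))
    stop("primary weights must lie in [0, 1]", call. = FALSE)
  structure(
    list(k_flash = k_flash,
         reachr_threshold_flux = reachr_threshold_flux,
         primary_weights = primary_weights,
         background_integration_s = background_integration_s,
         preactivation_flux = preactivation_flux),
    class = "photometry_calibration")
}

#' Describe a flash stimulus
#'
#' @param flash_energy Flash energy in cd·s/m² (>= 0).
#' @param flash_duration_ms Flash duration in ms, in (0, 4\]. Stimulators of
#'   this class deliver 4 ms flashes at most.
#' @param background_luminance Steady background luminance in cd/m² (>= 0).
#'   Must be 0 under dark adaptation.
#' @param flash_color,background_color Color keys into the calibration's
#'   primary weights.
#' @param adaptation `"dark"` or `"light"`.
#' @return An object of class `stimulus_spec`.
#' @examples
#' stimulus_spec(100, background_luminance = 30, adaptation = "light")
#' stimulus_spec(0.01, adaptation = "dark")
#' @export
stimulus_spec <- function(flash_energy,
                          flash_duration_ms = 4,
                          background_luminance = 0,
                          flash_color = "white",
                          background_color = "white",
                          adaptation = c("light", "dark")) {
  adaptation <- match.arg(adaptation)
  stopifnot(is.numeric(flash_energy), length(flash_energy) == 1L,
            is.numeric(flash_duration_ms), is.numeric(background_luminance))
  if (flash_energy < 0) stop("flash energy must be >= 0", call. = FALSE)
  if (background_luminance < 0) stop("background luminance must be >= 0", call. = FALSE)
  if (flash_duration_ms <= 0 || flash_duration_ms > 4)
    stop("flash duration must lie in (0, 4] ms", call. = FALSE)
  if (adaptation == "dark" && background_luminance != 0)
    stop("dark adaptation implies a zero background luminance", call. = FALSE)
  structure(
    list(flash_energy = flash_energy,
         flash_duration_ms = flash_duration_ms,
         background_luminance = background_luminance,
         flash_color = flash_color,
         background_color = background_color,
         adaptation = adaptation),
    class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus> %g cd.s/m2 %s flash (%g ms), %s-adapted",
              x$flash_energy, x$flash_color, x$flash_duration_ms, x$adaptation))
  if (x$background_luminance > 0)
    cat(sprintf(" on %g cd/m2 %s background", x$background_luminance,
                x$background_color))
  cat("\n")
  invisible(x)
}

#' Convert flash energy to retinal photon flux
#'
#' Linear conversion through the calibration anchor: flux = k_flash × energy.
#'
#' @param energy Flash energy in cd·s/m² (vectorized, >= 0).
#' @param cal A [photometry_calibration()].
#' @return Photon flux in photons·cm⁻²·s⁻¹.
#' @export
retinal_flux <- function(energy, cal = photometry_calibration()) {
  stopifnot(inherits(cal, "photometry_calibration"), is.numeric(energy))
  if (any(energy < 0)) stop("flash energy must be >= 0", call. = FALSE)
  cal$k_flash * energy
}

#' Convert retinal photon flux back to flash energy
#'
#' Exact inverse of [retinal_flux()] (round trip identity to within 1e-9
#' relative).
#'
#' @param flux Photon flux in photons·cm⁻²·s⁻¹ (vectorized, >= 0).
#' @inheritParams retinal_flux
#' @return Flash energy in cd·s/m².
#' @export
energy_for_flux <- function(flux, cal = photometry_calibration()) {
  stopifnot(inherits(cal, "photometry_calibration"), is.numeric(flux))
  if (any(flux < 0)) stop("flux must be >= 0", call. = FALSE)
  flux / cal$k_flash
}

weight_for_color <- function(color, cal) {
  w <- cal$primary_weights[color]
  if (anyNA(w))
    stop(sprintf("unknown color key '%s' in calibration primary weights", color),
         call. = FALSE)
  unname(w)
}

#' ReaChR-effective drive of a stimulus
#'
#' Places both the flash and the steady background of a stimulus on the
#' photon-flux scale, weighting each by the ReaChR-effectiveness of its
#' color. The background is integrated over
#' `cal$background_integration_s` seconds to make a cd/m² luminance
#' comparable to a cd·s/m² flash energy.
#'
#' @param stim A [stimulus_spec()].
#' @inheritParams retinal_flux
#' @return A list with `flash_flux` and `background_flux`
#'   (photons·cm⁻²·s⁻¹, both >= 0).
#' @export
reachr_drive <- function(stim, cal = photometry_calibration()) {
  stopifnot(inherits(stim, "stimulus_spec"))
  list(
    flash_flux = retinal_flux(stim$flash_energy, cal) *
      weight_for_color(stim$flash_color, cal),
    background_flux = cal$k_flash * stim$background_luminance *
      cal$background_integration_s * weight_for_color(stim$background_color, cal))
}

#' Classify a stimulus against the ReaChR activation threshold
#'
#' A flash is `reachr_activating` when its color-weighted flux reaches the
#' activation threshold (inclusive: the 68 cd·s/m² anchor *is* the
#' threshold). A background is `preactivating_background` when its
#' integrated, color-weighted flux reaches the pre-activation level —
#' bright enough to drive weak continuous ReaChR currents, as with the
#' amber 3,500 cd/m² background paradigm.
#'
#' @inheritParams reachr_drive
#' @return A list with `flash` (`"sub_threshold"` or `"reachr_activating"`)
#'   and `background` (`"no_preactivation"` or `"preactivating_background"`),
#'   plus the underlying fluxes.
#' @export
classify_stimulus <- function(stim, cal = photometry_calibration()) {
  drive <- reachr_drive(stim, cal)
  list(
    flash = if (drive$flash_flux >= cal$reachr_threshold_flux)
      "reachr_activating" else "sub_threshold",
    background = if (drive$background_flux >= cal$preactivation_flux)
      "preactivating_background" else "no_preactivation",
    flash_flux = drive$flash_flux,
    background_flux = drive$background_flux)
}
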