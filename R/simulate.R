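default_trial_count <- function(stim) {
  if (stim$adaptation == "dark") 3L
  else if (stim$flash_energy == 150) 5L
  else 20L
}

default_iti <- function(stim) {
  if (stim$adaptation == "dark") {
    if (stim$flash_energy <= 0.01) 5 else 10
  } else if (stim$flash_energy > 150) 1.987 else 0.987
}

#' Simulate a sweep set for one genotype and stimulus
#'
#' Builds the noise-free genotype waveform (sum of the template components,
#' Hill intensity scaling, ReaChR gating, b-wave dampening/delay) and adds,
#' per sweep, white measurement noise and a 50 Hz mains sinusoid whose phase
#' follows the trial onset times implied by the intertrial interval. With
#' the standard 987 ms interval the mains phases cover the cycle evenly and
#' average out; dark-adapted intervals (5 s, 10 s) are whole multiples of
#' the 20 ms mains period, so there the mains component survives averaging
#' and only the (wide-band) filters act on it.
#'
#' @param genotype `"WT"`, `"WT_ReaChR"`, `"RD1_ReaChR"`, or a
#'   [genotype_template()].
#' @param stim A [stimulus_spec()].
#' @param channel `"ERG"` or `"VEP"`.
#' @param n_sweeps Trials to simulate; default follows the protocol rules
#'   (3 dark-adapted, 5 at 150 cd·s/m², else 20).
#' @param noise_sd_uV Per-sample white-noise sd (µV).
#' @param mains_amplitude_uV Amplitude of the 50 Hz interference (µV).
#' @param iti_s Intertrial interval in seconds; default follows the
#'   protocol rules.
#' @param seed Optional integer seed (restores the RNG stream locally).
#' @param effects Optional per-kind between-animal effects (see
#'   [simulate_cohort()]).
#' @param cal A [photometry_calibration()].
#' @param sample_rate,pre_stimulus_ms,duration_ms Acquisition geometry;
#'   default 2 kHz sampling, 20 ms baseline, 320 ms total.
#' @return A [sweep_set()].
#' @export
simulate_sweepset <- function(genotype, stim, channel = c("ERG", "VEP"),
                              n_sweeps = NULL, noise_sd_uV = 3,
                              mains_amplitude_uV = 2, iti_s = NULL,
                              seed = NULL, effects = NULL,
                              cal = photometry_calibration(),
                              sample_rate = 2000, pre_stimulus_ms = 20,
                              duration_ms = 320) {
  channel <- match.arg(channel)
  stopifnot(inherits(stim, "stimulus_spec"))
  if (!inherits(genotype, "genotype_template"))
    genotype <- genotype_template(genotype)
  if (is.null(n_sweeps)) n_sweeps <- default_trial_count(stim)
  if (is.null(iti_s)) iti_s <- default_iti(stim)
  if (!is.null(seed)) set.seed(seed)

  n <- round(duration_ms * sample_rate / 1000)
  t_ms <- (seq_len(n) - 1) / sample_rate * 1000 - pre_stimulus_ms
  clean <- simulate_signal(genotype, stim, t_ms, channel = channel, cal = cal,
                           effects = effects)
  onsets <- (seq_len(n_sweeps) - 1) * iti_s
  sweeps <- vapply(seq_len(n_sweeps), function(k) {
    y <- clean
    if (mains_amplitude_uV > 0)
      y <- y + mains_amplitude_uV * sin(2 * pi * 50 * (t_ms / 1000 + onsets[k]))
    if (noise_sd_uV > 0)
      y <- y + stats::rnorm(n, sd = noise_sd_uV)
    y
  }, numeric(n))
  sweep_set(sweeps, sample_rate = sample_rate,
            pre_stimulus_ms = pre_stimulus_ms, channel = channel,
            stimulus = stim, trial_onset_times_s = onsets)
}

#' Default recording protocol
#'
#' The standard full-field session: dark-adapted 0.01 and 3 cd·s/m² flashes
#' (3 trials, 5 s / 10 s intervals), a light-adapted energy series
#' (10/30/100/150/900 cd·s/m² on a 30 cd/m² background; 20 trials at 987 ms
#' intervals, 5 trials at 150, 1,987 ms above 150), a 5 cd·s/m² blue flash
#' on a ReaChR-preactivating amber 3,500 cd/m² background, and dark- and
#' light-adapted flash VEP recordings.
#'
#' @return A tibble with one row per protocol step (`label`, `channel`,
#'   `n_trials`, `iti_s` and a `stimulus` list-column).
#' @export
default_protocol <- function() {
  step <- function(label, channel, stim, n_trials = NULL, iti_s = NULL) {
    tibble::tibble(label = label, channel = channel,
                   n_trials = if (is.null(n_trials)) default_trial_count(stim)
                              else as.integer(n_trials),
                   iti_s = if (is.null(iti_s)) default_iti(stim) else iti_s,
                   stimulus = list(stim))
  }
  la <- function(e) stimulus_spec(e, background_luminance = 30,
                                  adaptation = "light")
  rbind(
    step("DA_0.01", "ERG", stimulus_spec(0.01, adaptation = "dark")),
    step("DA_3", "ERG", stimulus_spec(3, adaptation = "dark")),
    step("LA_10", "ERG", la(10)),
    step("LA_30", "ERG", la(30)),
    step("LA_100", "ERG", la(100)),
    step("LA_150", "ERG", la(150)),
    step("LA_900", "ERG", la(900)),
    step("BLUE_AMBER_5", "ERG",
         stimulus_spec(5, background_luminance = 3500, flash_color = "blue",
                       background_color = "amber", adaptation = "light")),
    step("VEP_DA_1", "VEP", stimulus_spec(1, adaptation = "dark"), 20, 0.987),
    step("VEP_LA_100", "VEP", la(100)))
}

#' Cohort simulation settings
#'
#' Group sizes default to the study design this simulator emulates (6
#' wild-type, 11 ReaChR-expressing nondegenerate, 6 ReaChR-expressing
#' retina-degenerate animals). Between-animal variability is lognormal on
#' component amplitudes (median-unbiased, coefficient of variation
#' `between_animal_cv`) and additive normal on component peak times
#' (`time_jitter_sd_ms`).
#'
#' @param n_per_group Named integer vector of animals per genotype.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param noise_sd_uV Per-sample white-noise sd (µV).
#' @param mains_amplitude_uV 50 Hz interference amplitude (µV).
#' @param between_animal_cv CV of the lognormal amplitude multipliers.
#' @param time_jitter_sd_ms SD of the normal peak-time jitter (ms).
#' @param protocol Protocol tibble, see [default_protocol()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(WT = 6, WT_ReaChR = 11,
                                        RD1_ReaChR = 6),
                        seed = 1, noise_sd_uV = 3, mains_amplitude_uV = 2,
                        between_animal_cv = 0.2, time_jitter_sd_ms = 1,
                        protocol = default_protocol()) {
  stopifnot(all(n_per_group >= 1), between_animal_cv >= 0,
            time_jitter_sd_ms >= 0, noise_sd_uV >= 0)
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% c("WT", "WT_ReaChR", "RD1_ReaChR")))
    stop("n_per_group must be named with the three genotypes", call. = FALSE)
  structure(
    list(n_per_group = n_per_group, seed = as.integer(seed),
         noise_sd_uV = noise_sd_uV, mains_amplitude_uV = mains_amplitude_uV,
         between_animal_cv = between_animal_cv,
         time_jitter_sd_ms = time_jitter_sd_ms, protocol = protocol),
    class = "cohort_spec")
}

#' Simulate a full cohort with ground truth
#'
#' Draws per-animal component effects (amplitude multipliers and peak-time
#' shifts), simulates every protocol step for every animal, and returns the
#' recordings together with the generating parameters so that pipeline
#' recovery can be tested against the truth.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `recordings` (a list of records carrying `animal_id`,
#'   `genotype`, `label`, `channel` and the `sweep_set`), `truth` (a tibble
#'   of the realized per-animal effects), and `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  kinds <- c("a", "b", "a_o", "slow_positive", "P1", "N1", "N1_o",
             "op_burst", "post_ao_oscillation")
  sdlog <- sqrt(log(1 + spec$between_animal_cv^2))
  recordings <- list()
  truth <- list()
  for (g in names(spec$n_per_group)) {
    tpl <- genotype_template(g)
    for (i in seq_len(spec$n_per_group[[g]])) {
      id <- sprintf("%s_%02d", g, i)
      effects <- list(
        amp_mult = stats::setNames(
          if (spec$between_animal_cv > 0)
            stats::rlnorm(length(kinds), meanlog = 0, sdlog = sdlog)
          else rep(1, length(kinds)), kinds),
        time_shift_ms = stats::setNames(
          if (spec$time_jitter_sd_ms > 0)
            stats::rnorm(length(kinds), sd = spec$time_jitter_sd_ms)
          else rep(0, length(kinds)), kinds))
      truth[[id]] <- tibble::tibble(
        animal_id = id, genotype = g, kind = kinds,
        amp_mult = unname(effects$amp_mult),
        time_shift_ms = unname(effects$time_shift_ms))
      for (j in seq_len(nrow(spec$protocol))) {
        step <- spec$protocol[j, ]
        ss <- simulate_sweepset(
          tpl, step$stimulus[[1]], channel = step$channel,
          n_sweeps = step$n_trials, noise_sd_uV = spec$noise_sd_uV,
          mains_amplitude_uV = spec$mains_amplitude_uV, iti_s = step$iti_s,
          effects = effects)
        recordings[[length(recordings) + 1L]] <-
          list(animal_id = id, genotype = g, label = step$label,
               channel = step$channel, sweeps = ss)
      }
    }
  }
  list(recordings = recordings, truth = do.call(rbind, truth), spec = spec)
}
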