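test_that("component waves hit their template peaks exactly", {
  t_ms <- default_t_ms()
  b <- component_template("b", peak_time_ms = 51.5, peak_amplitude_uV = 60,
                          rise_sigma_ms = 8.5, decay_sigma_ms = 14)
  y <- component_wave(b, t_ms)
  expect_equal(y[t_ms == 51.5], 60)
  expect_identical(y[t_ms < 0], rep(0, sum(t_ms < 0)))

  # a_o: onset at t = 0, already clearly displaced at the first
  # post-stimulus sample (0.5 ms), beyond 3x the default noise sd
  ao <- component_template("a_o", peak_time_ms = 8,
                           peak_amplitude_uV = -33.76,
                           rise_sigma_ms = 4.8, decay_sigma_ms = 2.5)
  yo <- component_wave(ao, t_ms)
  expect_gt(abs(yo[t_ms == 0.5]), 3 * 3)
  expect_identical(yo[t_ms < 0], rep(0, sum(t_ms < 0)))
  expect_equal(yo[t_ms == 8], -33.76)

  mains <- component_template("mains", peak_amplitude_uV = 2, phase_s = 0.1)
  expect_equal(component_wave(mains, t_ms),
               2 * sin(2 * pi * 50 * (t_ms / 1000 + 0.1)))

  expect_error(component_template("op_burst", peak_time_ms = 25,
                                  peak_amplitude_uV = 3, frequency_hz = 40,
                                  decay_tau_ms = 15), "75, 300")
  expect_error(component_template("ringing", 1, 1), "unknown")
})

test_that("a noise-free sweep is the exact superposition of its components", {
  stim <- stimulus_spec(100, background_luminance = 30)
  ss <- simulate_sweepset("WT_ReaChR", stim, n_sweeps = 3, noise_sd_uV = 0,
                          mains_amplitude_uV = 0)
  # all sweeps identical to the clean sum
  expect_identical(ss$sweeps[, 1], ss$sweeps[, 3])
  t_ms <- default_t_ms()
  tpl <- genotype_template("WT_ReaChR")
  comps <- tpl$components[tpl$components$stimulus_class == "light", ]
  manual <- numeric(length(t_ms))
  for (i in seq_len(nrow(comps))) {
    row <- comps[i, ]
    amp <- row$amplitude_uV * hill_expected(100, row$e50, row$hill_n, row$e_ref)
    peak <- row$peak_time_ms
    if (row$kind == "b") {
      amp <- amp * tpl$b_dampening
      peak <- peak + tpl$b_delay_ms
    }
    manual <- manual + component_wave(component_template(
      row$kind, peak_time_ms = peak, peak_amplitude_uV = amp,
      rise_sigma_ms = row$rise_sigma_ms, decay_sigma_ms = row$decay_sigma_ms,
      frequency_hz = row$frequency_hz, decay_tau_ms = row$decay_tau_ms), t_ms)
  }
  expect_equal(ss$sweeps[, 1], manual, tolerance = 1e-12)
})

test_that("component amplitudes grow monotonically with flash energy", {
  energies <- c(1, 5, 10, 30, 68, 100, 300, 900)
  for (g in c("WT", "WT_ReaChR", "RD1_ReaChR")) {
    peaks <- vapply(energies, function(e) {
      ss <- simulate_sweepset(g, stimulus_spec(e, background_luminance = 30),
                              n_sweeps = 1, noise_sd_uV = 0,
                              mains_amplitude_uV = 0)
      max(abs(ss$sweeps[, 1]))
    }, 0)
    expect_true(all(diff(peaks) >= -1e-9), label = g)
  }
})

test_that("the simulated phenotypes match the genotype truth table", {
  # no early negative deflection in wild type even at bright flashes
  ss <- simulate_sweepset("WT", stimulus_spec(100, background_luminance = 30),
                          n_sweeps = 1, noise_sd_uV = 0, mains_amplitude_uV = 0)
  t_ms <- default_t_ms()
  early <- ss$sweeps[t_ms > 0 & t_ms <= 12, 1]
  expect_gt(min(early), -2)
  # the degenerate retina is silent below the activation threshold
  rd <- simulate_sweepset("RD1_ReaChR",
                          stimulus_spec(10, background_luminance = 30),
                          n_sweeps = 1, noise_sd_uV = 0, mains_amplitude_uV = 0)
  expect_lt(max(abs(rd$sweeps)), 2)
  # ReaChR-expressing: trough at the a_o time
  tr <- simulate_sweepset("WT_ReaChR",
                          stimulus_spec(100, background_luminance = 30),
                          n_sweeps = 1, noise_sd_uV = 0, mains_amplitude_uV = 0)
  idx <- which(t_ms > 0.5 & t_ms <= 12)
  expect_lt(abs(t_ms[idx[which.min(tr$sweeps[idx, 1])]] - 8.0), 0.51)
  expect_error(simulate_sweepset("MUTANT", stimulus_spec(1)), "arg")
})

test_that("cohort simulation is reproducible and honours cv = 0", {
  spec <- cohort_spec(n_per_group = c(WT = 2, WT_ReaChR = 2),
                      seed = 5, protocol = default_protocol()[3, ])
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$recordings[[3]]$sweeps$sweeps,
                   c2$recordings[[3]]$sweeps$sweeps)
  expect_identical(c1$truth, c2$truth)

  frozen <- cohort_spec(n_per_group = c(WT = 3), seed = 9, noise_sd_uV = 0,
                        mains_amplitude_uV = 0, between_animal_cv = 0,
                        time_jitter_sd_ms = 0,
                        protocol = default_protocol()[3, ])
  cf <- simulate_cohort(frozen)
  expect_identical(cf$recordings[[1]]$sweeps$sweeps,
                   cf$recordings[[3]]$sweeps$sweeps)
  expect_true(all(cf$truth$amp_mult == 1))
})
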