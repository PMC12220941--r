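test_that("detected extrema equal a brute-force window scan", {
  set.seed(101)
  wins <- default_marker_windows()
  for (rep in 1:8) {
    # smooth random trace with a quiet baseline
    x <- cumsum(rnorm(640)) * 0.5
    x <- x - mean(x[1:40])
    trace <- make_trace(x, stimulus = stimulus_spec(10,
      background_luminance = 30, adaptation = "light"))
    bl <- baseline_stats(trace)
    erg <- place_erg_markers(trace)
    vep <- place_vep_markers(trace)
    oracle_amp <- function(win, dir, ref_level = bl$mean) {
      o <- scan_extremum(trace, win[1], win[2], dir)
      list(time = o$time_ms,
           amp = if (dir == "min") ref_level - o$value else o$value - ref_level)
    }
    for (m in list(list("a_o", wins$a_o, "min", erg),
                   list("a", wins$a, "min", erg),
                   list("b", wins$b, "max", erg),
                   list("N1_o", wins$N1_o, "min", vep),
                   list("P1", wins$P1, "max", vep))) {
      row <- m[[4]]$markers[m[[4]]$markers$name == m[[1]], ]
      if (row$present) {
        o <- oracle_amp(m[[2]], m[[3]])
        expect_identical(row$implicit_time_ms, o$time)
        expect_equal(row$amplitude_uV, o$amp)
      }
    }
  }
})

test_that("scaling a trace scales amplitudes but not implicit times", {
  trace <- nf_trace("WT_ReaChR", 100)
  ms1 <- place_erg_markers(trace)
  trace$values <- trace$values * 3
  ms3 <- place_erg_markers(trace)
  for (nm in c("a_o", "a", "b")) {
    expect_identical(marker_implicit_time(ms3, nm),
                     marker_implicit_time(ms1, nm))
    expect_equal(marker_amplitude(ms3, nm), 3 * marker_amplitude(ms1, nm))
  }
})

test_that("a_o is detected only in ReaChR-expressing retinas at bright flashes", {
  ao <- detect_ao(nf_trace("WT_ReaChR", 100))
  expect_true(ao$present)
  expect_lt(abs(ao$implicit_time_ms - 8.0), 0.5 + 1e-9)
  for (e in c(10, 30, 100, 900)) {
    expect_false(detect_ao(nf_trace("WT", e))$present)
  }
  expect_false(detect_ao(nf_trace("WT_ReaChR", 30))$present)
  flat <- make_trace(rep(0, 640))
  expect_false(detect_ao(flat, noise_sd = 1)$present)
})

test_that("ERG conventions: dark b references the a-trough, light the baseline", {
  dark <- place_erg_markers(nf_trace("WT", 3, background = 0,
                                     adaptation = "dark"))
  expect_true(all(dark$markers$present[dark$markers$name %in% c("a", "b")]))
  expect_false(dark$markers$present[dark$markers$name == "a_o"])
  expect_identical(dark$conventions$b_reference, "a_peak")
  # dark b amplitude is trough-to-peak: larger than either deflection alone
  expect_gt(marker_amplitude(dark, "b"), marker_amplitude(dark, "a"))

  light <- place_erg_markers(nf_trace("WT", 10))
  expect_identical(light$conventions$b_reference, "baseline")

  none <- place_erg_markers(nf_trace("RD1_ReaChR", 10))
  expect_false(any(none$markers$present))

  # polarity check: a sign-flipped recording has no credible b-wave
  flipped <- nf_trace("WT", 10)
  orig_b <- marker_amplitude(place_erg_markers(flipped), "b")
  flipped$values <- -flipped$values
  ms <- place_erg_markers(flipped)
  b <- ms$markers[ms$markers$name == "b", ]
  expect_true(!b$present || b$amplitude_uV < 0.2 * orig_b)

  expect_error(place_erg_markers(make_trace(rep(0, 200),
    stimulus = stimulus_spec(3, adaptation = "dark"))), "120 ms")
})

test_that("a-wave is flagged low confidence when a_o contaminates it", {
  ms <- place_erg_markers(nf_trace("WT_ReaChR", 100))
  expect_identical(ms$markers$confidence[ms$markers$name == "a"], "low")
  clean <- place_erg_markers(nf_trace("WT", 100))
  expect_identical(clean$markers$confidence[clean$markers$name == "a"],
                   "clear")
})

test_that("VEP markers follow the P1-referenced N1 convention", {
  ms <- place_vep_markers(nf_trace("WT_ReaChR", 100, channel = "VEP"))
  expect_true(all(ms$markers$present))
  expect_lt(abs(marker_implicit_time(ms, "N1") - 55.25), 0.5 + 1e-9)
  expect_lt(abs(marker_implicit_time(ms, "N1_o") - 27.12), 0.5 + 1e-9)
  n1 <- ms$markers[ms$markers$name == "N1", ]
  expect_identical(n1$reference, "P1_peak")
  expect_gt(marker_implicit_time(ms, "N1"), marker_implicit_time(ms, "P1"))

  wt <- place_vep_markers(nf_trace("WT", 100, channel = "VEP"))
  expect_true(wt$markers$present[wt$markers$name == "N1"])
  expect_false(wt$markers$present[wt$markers$name == "N1_o"])

  flat <- place_vep_markers(make_trace(rep(0, 640), channel = "VEP"))
  expect_false(any(flat$markers$present))
})

test_that("absent markers answer queries with NA, not errors", {
  ms <- place_erg_markers(nf_trace("WT", 10))
  expect_true(is.na(marker_amplitude(ms, "a_o")))
  expect_true(is.na(marker_implicit_time(ms, "a_o")))
  expect_error(marker_amplitude(ms, "N1"), "no marker")
})

test_that("noise-free traces recover the generating template values", {
  tol_t <- 0.5 + 1e-9
  # implicit times, all genotypes x key stimuli
  cases <- list(
    list("WT", 100, "a", 17.4), list("WT", 10, "b", 51.62),
    list("WT", 30, "b", 51.62), list("WT", 100, "b", 51.62),
    list("WT_ReaChR", 100, "a_o", 8.0), list("WT_ReaChR", 100, "b", 67.75),
    list("WT_ReaChR", 10, "b", 51.62), list("RD1_ReaChR", 100, "a_o", 8.0),
    list("RD1_ReaChR", 150, "a_o", 8.0))
  for (cs in cases) {
    ms <- place_erg_markers(nf_trace(cs[[1]], cs[[2]]))
    expect_lt(abs(marker_implicit_time(ms, cs[[3]]) - cs[[4]]), tol_t,
              label = sprintf("%s @%g %s time", cs[[1]], cs[[2]], cs[[3]]))
  }
  # amplitudes within 1% where the measurement convention isolates the
  # component (baseline-referenced, uncontaminated)
  amp_cases <- list(
    list("WT_ReaChR", 100, "a_o", 33.76),
    list("RD1_ReaChR", 100, "a_o", 6.36),
    list("WT", 10, "b", 61.92),
    list("WT_ReaChR", 10, "b", 61.92 * 0.556),
    list("WT", 100, "a", 15))
  for (cs in amp_cases) {
    ms <- place_erg_markers(nf_trace(cs[[1]], cs[[2]]))
    expect_lt(abs(marker_amplitude(ms, cs[[3]]) - cs[[4]]) / cs[[4]], 0.01,
              label = sprintf("%s @%g %s amp", cs[[1]], cs[[2]], cs[[3]]))
  }
  # dark-adapted: b measured from the a trough recovers both components
  dark <- place_erg_markers(nf_trace("WT", 3, background = 0,
                                     adaptation = "dark"))
  expect_lt(abs(marker_implicit_time(dark, "a") - 16), tol_t)
  expect_lt(abs(marker_implicit_time(dark, "b") - 35.75), tol_t)
  expect_lt(abs(marker_amplitude(dark, "b") - 450) / 450, 0.01)
  # VEP amplitudes pass the narrow cortical band with some attenuation;
  # times are exact to the sample
  vep <- place_vep_markers(nf_trace("WT_ReaChR", 100, channel = "VEP"))
  expect_lt(abs(marker_amplitude(vep, "N1_o") - 6) / 6, 0.15)
})

test_that("marker presence matches the genotype phenotype table", {
  cal <- photometry_calibration()
  light_energies <- c(10, 30, 100, 150, 900)
  for (g in c("WT", "WT_ReaChR", "RD1_ReaChR")) {
    for (e in light_energies) {
      ms <- place_erg_markers(nf_trace(g, e))
      activating <- classify_stimulus(
        stimulus_spec(e, background_luminance = 30), cal)$flash ==
        "reachr_activating"
      expect_identical(
        marker_amplitude(ms, "a_o") > 0 & !is.na(marker_amplitude(ms, "a_o")),
        g != "WT" && activating,
        label = sprintf("a_o presence %s @%g", g, e))
      native <- g %in% c("WT", "WT_ReaChR")
      expect_identical(ms$markers$present[ms$markers$name == "a"], native,
                       label = sprintf("a presence %s @%g", g, e))
      # the b window picks up the native b-wave in sighted genotypes and,
      # in the degenerate retina, the slow optogenetic deflection that
      # follows a_o at activating energies
      expect_identical(ms$markers$present[ms$markers$name == "b"],
                       native || activating,
                       label = sprintf("b presence %s @%g", g, e))
    }
  }
})
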