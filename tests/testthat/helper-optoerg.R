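# Shared fixtures and independent oracles, built in code.

# Noise-free averaged trace for a genotype x stimulus, filtered the way the
# pipeline filters that channel.
nf_trace <- function(genotype, energy, background = 30,
                     adaptation = "light", channel = "ERG",
                     flash_color = "white", background_color = "white",
                     n_sweeps = 1) {
  stim <- stimulus_spec(energy, background_luminance = background,
                        adaptation = adaptation, flash_color = flash_color,
                        background_color = background_color)
  ss <- simulate_sweepset(genotype, stim, channel = channel,
                          n_sweeps = n_sweeps, noise_sd_uV = 0,
                          mains_amplitude_uV = 0)
  avg <- average_trials(ss)
  if (channel == "VEP") {
    avg <- bandpass(avg, 3, 100)
    if (adaptation == "light") avg <- notch50(avg)
  } else {
    avg <- bandpass(avg, 0.125, 300)
  }
  avg
}

make_trace <- function(values, sample_rate = 2000, pre_stimulus_ms = 20,
                       channel = "ERG", stimulus = NULL) {
  new_trace(values, sample_rate = sample_rate,
            pre_stimulus_ms = pre_stimulus_ms, channel = channel,
            stimulus = stimulus)
}

# Time axis matching the default acquisition geometry.
default_t_ms <- function(n = 640, sample_rate = 2000, pre_ms = 20) {
  (seq_len(n) - 1) / sample_rate * 1000 - pre_ms
}

# Brute-force extremum oracle: plain loop over samples inside a half-open
# (lo, hi] window, earliest extremum wins.
scan_extremum <- function(trace, lo, hi, direction) {
  t <- trace_time(trace)
  best_i <- NA_integer_
  for (i in seq_along(t)) {
    if (t[i] > lo && t[i] <= hi) {
      if (is.na(best_i) ||
          (direction == "min" && trace$values[i] < trace$values[best_i]) ||
          (direction == "max" && trace$values[i] > trace$values[best_i]))
        best_i <- i
    }
  }
  list(time_ms = t[best_i], value = trace$values[best_i])
}

# Independent DFT oracle: direct evaluation of the transform sum at one
# zero-padded grid frequency, power normalized by the unpadded length.
dft_power_oracle <- function(x, f_hz, sample_rate, n_pad) {
  n <- length(x)
  k <- f_hz * n_pad / sample_rate
  X <- sum(x * exp(-2i * pi * k * (seq_len(n) - 1) / n_pad))
  Mod(X)^2 / n
}

# Exact two-sided Wilcoxon rank-sum p by complete enumeration of all
# assignments of the pooled ranks to group A.
wilcoxon_enum_p <- function(a, b) {
  pooled <- c(a, b)
  ranks <- rank(pooled)
  na <- length(a)
  obs <- sum(ranks[seq_len(na)])
  mu <- na * (length(pooled) + 1) / 2
  combs <- utils::combn(length(pooled), na)
  sums <- apply(combs, 2, function(idx) sum(ranks[idx]))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

hill_expected <- function(E, e50, n, e_ref) {
  (E^n / (E^n + e50^n)) / (e_ref^n / (e_ref^n + e50^n))
}
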