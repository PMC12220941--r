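format_stim_header <- function(stim) {
  paste(sprintf("energy:%g", stim$flash_energy),
        sprintf("duration_ms:%g", stim$flash_duration_ms),
        sprintf("background:%g", stim$background_luminance),
        sprintf("flash_color:%s", stim$flash_color),
        sprintf("background_color:%s", stim$background_color),
        sprintf("adaptation:%s", stim$adaptation), sep = ";")
}

parse_stim_header <- function(txt) {
  kv <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  stimulus_spec(flash_energy = as.numeric(vals[["energy"]]),
                flash_duration_ms = as.numeric(vals[["duration_ms"]]),
                background_luminance = as.numeric(vals[["background"]]),
                flash_color = vals[["flash_color"]],
                background_color = vals[["background_color"]],
                adaptation = vals[["adaptation"]])
}

#' Write a sweep set to a plain-text CSV
#'
#' The dialect is self-describing: `# key=value` header lines
#' (`sample_rate_hz`, `pre_stimulus_ms`, `channel`, `stimulus`,
#' `trial_onsets_s`) followed by a `sweep_id,time_ms,voltage_uV` table.
#' UTF-8, LF line endings, `.` decimal separator.
#'
#' @param sweeps A [sweep_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweeps_csv <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con, sep = "\n")
  wl(sprintf("# sample_rate_hz=%g", sweeps$sample_rate))
  wl(sprintf("# pre_stimulus_ms=%g", sweeps$pre_stimulus_ms))
  wl(sprintf("# channel=%s", sweeps$channel))
  if (!is.null(sweeps$stimulus))
    wl(sprintf("# stimulus=%s", format_stim_header(sweeps$stimulus)))
  wl(sprintf("# trial_onsets_s=%s",
             paste(format(sweeps$trial_onset_times_s, digits = 15),
                   collapse = ",")))
  wl("sweep_id,time_ms,voltage_uV")
  n <- nrow(sweeps$sweeps)
  t_ms <- (seq_len(n) - 1) / sweeps$sample_rate * 1000 - sweeps$pre_stimulus_ms
  for (k in seq_len(ncol(sweeps$sweeps))) {
    wl(sprintf("%d,%s,%s", k, format(t_ms, digits = 10),
               format(sweeps$sweeps[, k], digits = 15)))
  }
  invisible(path)
}

#' Read a sweep set from CSV
#'
#' Counterpart of [write_sweeps_csv()].
#'
#' @param path CSV file path.
#' @return A [sweep_set()].
#' @export
read_sweeps_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key, default = NULL) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (length(m) == 0L) return(default)
    sub(sprintf("^# %s=", key), "", m[1])
  }
  sample_rate <- as.numeric(get("sample_rate_hz", "2000"))
  pre_ms <- as.numeric(get("pre_stimulus_ms", "20"))
  channel <- get("channel", "ERG")
  stim_txt <- get("stimulus")
  stim <- if (!is.null(stim_txt)) parse_stim_header(stim_txt) else NULL
  onsets_txt <- get("trial_onsets_s")
  body_start <- which(lines == "sweep_id,time_ms,voltage_uV")
  if (length(body_start) != 1L)
    stop(sprintf("'%s': missing sweep table header", path), call. = FALSE)
  body <- utils::read.csv(text = lines[(body_start):length(lines)])
  if (!all(c("sweep_id", "voltage_uV") %in% names(body)) || nrow(body) == 0L)
    stop(sprintf("'%s': malformed sweep table", path), call. = FALSE)
  ids <- unique(body$sweep_id)
  cols <- lapply(ids, function(id) body$voltage_uV[body$sweep_id == id])
  if (length(unique(lengths(cols))) != 1L)
    stop(sprintf("'%s': sweeps differ in length", path), call. = FALSE)
  onsets <- if (!is.null(onsets_txt))
    as.numeric(strsplit(onsets_txt, ",", fixed = TRUE)[[1]]) else NULL
  sweep_set(do.call(cbind, cols), sample_rate = sample_rate,
            pre_stimulus_ms = pre_ms, channel = channel, stimulus = stim,
            trial_onset_times_s = onsets)
}

#' Default pipeline configuration
#'
#' Filter settings per channel, marker windows, the OP analysis band and
#' window, the presence floor, and the photometric calibration. All fields
#' can be overridden through a YAML config file (see
#' [read_pipeline_config()]).
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    filters = list(
      erg_band = c(0.125, 300),
      vep_band = c(3, 100),
      order = 4,
      notch_q = 30),
    windows = default_marker_windows(),
    min_amplitude_uV = 2,
    op = list(band = c(75, 300), window_ms = c(20, 230)),
    calibration = photometry_calibration())
}

#' Read a pipeline configuration file
#'
#' A flat YAML file whose keys override [default_config()]; the
#' `calibration` block accepts `k_flash`, `reachr_threshold_flux`,
#' `primary_weights`, `background_integration_s` and `preactivation_flux`.
#'
#' @param path YAML file path.
#' @return A config list as from [default_config()].
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user$filters))
    cfg$filters <- utils::modifyList(cfg$filters, user$filters)
  if (!is.null(user$windows))
    cfg$windows <- utils::modifyList(cfg$windows,
                                     lapply(user$windows, as.numeric))
  if (!is.null(user$min_amplitude_uV))
    cfg$min_amplitude_uV <- as.numeric(user$min_amplitude_uV)
  if (!is.null(user$op)) cfg$op <- utils::modifyList(cfg$op, user$op)
  if (!is.null(user$calibration)) {
    cal_args <- user$calibration
    if (!is.null(cal_args$primary_weights))
      cal_args$primary_weights <- vapply(cal_args$primary_weights,
                                         as.numeric, 0)
    # YAML readers keep notations like "1.0e15" as strings
    for (f in c("k_flash", "reachr_threshold_flux",
                "background_integration_s", "preactivation_flux"))
      if (!is.null(cal_args[[f]])) cal_args[[f]] <- as.numeric(cal_args[[f]])
    cfg$calibration <- do.call(photometry_calibration, cal_args)
  }
  cfg
}
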