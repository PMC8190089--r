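#' Temperature profile
#'
#' A piecewise-constant temperature forcing function: the temperature on
#' `[times[i], times[i+1])` is `temps[i]` (left-closed, right-open steps); the
#' final step extends to `duration`. Time is measured in hours since
#' germination.
#'
#' @param times numeric vector of breakpoint times (hours), strictly
#'   increasing, first element 0.
#' @param temps numeric vector of temperatures (degrees C), one per breakpoint,
#'   all finite and within -20..60.
#' @param duration end of the profile in hours; must be at least the last
#'   breakpoint.
#' @param label free-text label, e.g. `"lab:+ACC+HS"` or `"field:Nara"`.
#' @return An object of class `temp_profile`.
#' @export
temperature_profile <- function(times, temps, duration = max(times),
                                label = "") {
  times <- as.numeric(times)
  temps <- as.numeric(temps)
  if (length(times) == 0L) stop("profile needs at least one breakpoint")
  if (length(times) != length(temps))
    stop("times and temps must have equal length")
  if (any(!is.finite(times)) || any(!is.finite(temps)))
    stop("times and temps must be finite")
  if (times[1] != 0) stop("first breakpoint must be at t = 0")
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1] + 1L
    stop(sprintf("times not increasing at row %d", bad))
  }
  if (any(temps < -20 | temps > 60))
    stop("temperatures must lie within [-20, 60] degrees C")
  if (duration < times[length(times)])
    stop("duration must be >= last breakpoint time")
  structure(list(times = times, temps = temps, duration = duration,
                 label = label),
            class = "temp_profile")
}

#' @method print temp_profile
#' @export
print.temp_profile <- function(x, ...) {
  cat(sprintf("Temperature profile%s: %d steps over %.1f h, range %.1f-%.1f degC\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$times), x$duration, min(x$temps), max(x$temps)))
  invisible(x)
}

#' Laboratory heat-treatment protocol
#'
#' Encodes the standard bench protocol: growth at a baseline temperature with
#' an optional acclimation (ACC) priming pulse (default 37 degC for 20 min at
#' 96 h after germination) and an optional heat-shock (HS) triggering pulse
#' (default 43.5 degC for 60 min at 168 h).
#'
#' @param baseline_temp baseline growth temperature (degC).
#' @param acc_enabled,acc_time,acc_temp,acc_duration acclimation window:
#'   enabled flag, start (h), temperature (degC), duration (h; default 1/3 h
#'   = 20 min).
#' @param hs_enabled,hs_time,hs_temp,hs_duration heat-shock window.
#' @param total_duration total profile length (h).
#' @return An object of class `lab_protocol`.
#' @export
lab_protocol <- function(baseline_temp = 22,
                         acc_enabled = TRUE, acc_time = 96, acc_temp = 37,
                         acc_duration = 1 / 3,
                         hs_enabled = TRUE, hs_time = 168, hs_temp = 43.5,
                         hs_duration = 1,
                         total_duration = 240) {
  pr <- structure(list(baseline_temp = baseline_temp,
                       acc_enabled = isTRUE(acc_enabled), acc_time = acc_time,
                       acc_temp = acc_temp, acc_duration = acc_duration,
                       hs_enabled = isTRUE(hs_enabled), hs_time = hs_time,
                       hs_temp = hs_temp, hs_duration = hs_duration,
                       total_duration = total_duration),
                  class = "lab_protocol")
  if (pr$acc_duration <= 0 || pr$hs_duration <= 0 || pr$total_duration <= 0)
    stop("all durations must be > 0")
  if (pr$acc_enabled && pr$hs_enabled &&
      pr$acc_time + pr$acc_duration > pr$hs_time + 1e-9)
    stop("acclimation and heat-shock windows overlap")
  pr
}

#' Build the temperature profile of a lab protocol
#'
#' @param protocol a [lab_protocol()].
#' @return A [temperature_profile()] equal to the baseline everywhere except
#'   the enabled heat windows, with breakpoints exactly at the window edges.
#' @export
build_lab_profile <- function(protocol) {
  stopifnot(inherits(protocol, "lab_protocol"))
  times <- 0
  temps <- protocol$baseline_temp
  add_window <- function(times, temps, t0, temp, dur) {
    list(times = c(times, t0, t0 + dur),
         temps = c(temps, temp, protocol$baseline_temp))
  }
  lbl <- "lab:"
  if (protocol$acc_enabled) {
    w <- add_window(times, temps, protocol$acc_time, protocol$acc_temp,
                    protocol$acc_duration)
    times <- w$times; temps <- w$temps
    lbl <- paste0(lbl, "+ACC")
  }
  if (protocol$hs_enabled) {
    w <- add_window(times, temps, protocol$hs_time, protocol$hs_temp,
                    protocol$hs_duration)
    times <- w$times; temps <- w$temps
    lbl <- paste0(lbl, "+HS")
  }
  if (lbl == "lab:") lbl <- "lab:baseline"
  temperature_profile(times, temps, duration = protocol$total_duration,
                      label = lbl)
}

#' Query a temperature profile
#'
#' @param profile a [temperature_profile()].
#' @param t time(s) in hours, each within `[0, duration]`.
#' @return Temperature(s) in degrees C (left-closed step convention; `t`
#'   exactly at `duration` returns the final step's value).
#' @export
temperature_at <- function(profile, t) {
  stopifnot(inherits(profile, "temp_profile"))
  if (any(t < 0 | t > profile$duration))
    stop("t outside [0, duration]")
  idx <- findInterval(t, profile$times)
  profile$temps[idx]
}

#' Read a temperature profile from CSV
#'
#' Expects a comma-separated file with header `time_h,temp_c`, '.' decimal,
#' times in hours. The profile duration is set to the last time plus the
#' median spacing, so an hourly file covers its final hour.
#'
#' @param path file path.
#' @param label optional profile label.
#' @return A [temperature_profile()].
#' @export
read_temperature_csv <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "temp_c") %in% names(df)))
    stop("CSV must have header columns time_h,temp_c")
  if (nrow(df) == 0L) stop("empty temperature file: ", path)
  tms <- as.numeric(df$time_h)
  if (any(diff(tms) <= 0)) {
    bad <- which(diff(tms) <= 0)[1] + 2L  # header is row 1
    stop(sprintf("times not increasing at row %d", bad))
  }
  spacing <- if (length(tms) > 1) stats::median(diff(tms)) else 1
  temperature_profile(tms, as.numeric(df$temp_c),
                      duration = tms[length(tms)] + spacing, label = label)
}

#' Write a temperature profile to CSV
#'
#' Inverse of [read_temperature_csv()] for hourly (evenly spaced) profiles.
#'
#' @param profile a [temperature_profile()].
#' @param path output file path.
#' @export
write_temperature_csv <- function(profile, path) {
  stopifnot(inherits(profile, "temp_profile"))
  utils::write.csv(data.frame(time_h = profile$times, temp_c = profile$temps),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect heat spikes and assign ACC/HS roles
#'
#' Finds the maximal time intervals during which the temperature strictly
#' exceeds `threshold`. Following the convention for fluctuating field
#' conditions, the first spike is labelled the acclimation event (ACC), the
#' second the heat shock (HS), and any further spikes "extra".
#'
#' @param profile a [temperature_profile()].
#' @param threshold spike-calling threshold in degC (default 30; spikes are
#'   strict exceedances, `T > threshold`).
#' @return A data.frame of class `spike_annotation` with columns `start_h`,
#'   `end_h`, `max_temp_c`, `role`; zero rows when nothing crosses the
#'   threshold.
#' @export
detect_spikes <- function(profile, threshold = 30) {
  stopifnot(inherits(profile, "temp_profile"))
  hot <- profile$temps > threshold
  ends <- c(profile$times[-1], profile$duration)
  out <- data.frame(start_h = numeric(0), end_h = numeric(0),
                    max_temp_c = numeric(0), role = character(0),
                    stringsAsFactors = FALSE)
  r <- rle(hot)
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- pos[k]; i1 <- pos[k + 1] - 1L
    out <- rbind(out, data.frame(start_h = profile$times[i0],
                                 end_h = ends[i1],
                                 max_temp_c = max(profile$temps[i0:i1]),
                                 role = "extra", stringsAsFactors = FALSE))
  }
  if (nrow(out) >= 1) out$role[1] <- "ACC"
  if (nrow(out) >= 2) out$role[2] <- "HS"
  attr(out, "threshold") <- threshold
  class(out) <- c("spike_annotation", "data.frame")
  out
}
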