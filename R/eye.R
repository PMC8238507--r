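# Eye-trace analysis: fixation-break screening, microsaccade detection,
# main sequence, pupil reactivity

#' Eye analysis parameters
#'
#' Velocity-threshold microsaccade detection in the Engbert-Kliegl lineage:
#' 2D velocity by a +/-2-sample weighted central difference, per-axis robust
#' SD from medians, an elliptic threshold at `lambda` robust SDs, minimum
#' event duration, and a merge gap for split events. The fixation window is
#' a square of width `fixation_window` degrees centred on the fixation spot.
#'
#' @param lambda velocity threshold multiplier (canonical 6)
#' @param min_duration minimum event duration, s (canonical 0.01)
#' @param smooth_halfwidth half-width of the velocity kernel, samples
#' @param fixation_window square window width, degrees (default 5)
#' @param analysis_window analysis interval, s re stimulus onset
#' @param merge_gap events closer than this are merged, s
#' @return list of class `eye_params`
#' @export
eye_params <- function(lambda = 6, min_duration = 0.01, smooth_halfwidth = 2,
                       fixation_window = 5, analysis_window = c(-0.5, 0.75),
                       merge_gap = 0.02) {
  p <- as.list(environment())
  stopifnot(p$lambda > 0, p$fixation_window > 0, p$min_duration > 0)
  class(p) <- "eye_params"
  p
}

eye_window <- function(trace, params) {
  stopifnot(is.data.frame(trace), nrow(trace) > 0)
  w <- params$analysis_window
  tr <- trace[trace$t_s >= w[1] & trace$t_s <= w[2] + 1e-9, , drop = FALSE]
  if (nrow(tr) == 0) stop("eye trace does not cover the analysis window")
  tr
}

#' Screen a repeat for fixation breaks
#'
#' A repeat is rejected when, inside the analysis window, the trace contains
#' a blink (NaN run) or the eye leaves the square fixation window (|x| or
#' |y| beyond half its width).
#'
#' @param trace eye-trace data frame (`t_s`, `x_deg`, `y_deg`, `pupil`)
#' @param params `eye_params`
#' @return TRUE if the repeat must be rejected
#' @export
detect_fixation_breaks <- function(trace, params = eye_params()) {
  tr <- eye_window(trace, params)
  half <- params$fixation_window / 2
  any(is.na(tr$x_deg)) || any(is.na(tr$y_deg)) ||
    any(abs(tr$x_deg) > half) || any(abs(tr$y_deg) > half)
}

# Engbert-Kliegl velocity: weighted central difference over +/- h samples;
# h = 2 gives the canonical v_t = (x[t+2] + x[t+1] - x[t-1] - x[t-2]) / (6 dt)
ek_velocity <- function(x, dt, h = 2) {
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n >= 2 * h + 1) {
    i <- (h + 1):(n - h)
    acc <- 0
    for (k in seq_len(h)) acc <- acc + x[i + k] - x[i - k]
    v[i] <- acc / (h * (h + 1) * dt)
  }
  v
}

#' Detect microsaccades with an elliptic velocity threshold
#'
#' Blink-free segments of the analysis window are processed separately.
#' Per-axis robust SDs `sigma = sqrt(median(v^2) - median(v)^2)` scale an
#' elliptic threshold at `lambda` SDs; threshold crossings sustained for at
#' least `min_duration` become events, events closer than `merge_gap` are
#' merged, and each event's peak velocity and maximum displacement are
#' recorded.
#'
#' @param trace eye-trace data frame
#' @param params `eye_params`
#' @return data frame with columns `onset_s`, `offset_s`, `peak_vel_dps`,
#'   `max_disp_deg` (zero rows when no event)
#' @export
detect_microsaccades <- function(trace, params = eye_params()) {
  tr <- eye_window(trace, params)
  dt <- stats::median(diff(tr$t_s))
  ok <- !is.na(tr$x_deg) & !is.na(tr$y_deg)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_vel_dps = numeric(0), max_disp_deg = numeric(0))
  out <- empty
  min_n <- max(1, round(params$min_duration / dt))
  for (s in seq_along(runs$lengths)) {
    if (!runs$values[s]) next
    idx <- starts[s]:ends[s]
    if (length(idx) < 2 * params$smooth_halfwidth + 1) {
      warning("blink-free segment shorter than the velocity kernel; skipped")
      next
    }
    x <- tr$x_deg[idx]; y <- tr$y_deg[idx]; tt <- tr$t_s[idx]
    h <- params$smooth_halfwidth
    vx <- ek_velocity(x, dt, h); vy <- ek_velocity(y, dt, h)
    val <- !is.na(vx)
    sig <- function(v) {
      s2 <- stats::median(v[val]^2) - stats::median(v[val])^2
      if (!is.finite(s2) || s2 <= 0) stats::sd(v[val]) else sqrt(s2)
    }
    sx <- sig(vx); sy <- sig(vy)
    if (!is.finite(sx) || sx == 0 || !is.finite(sy) || sy == 0) next
    crit <- (vx / (params$lambda * sx))^2 + (vy / (params$lambda * sy))^2 > 1
    crit[is.na(crit)] <- FALSE
    cr <- rle(crit)
    ce <- cumsum(cr$lengths)
    cs <- ce - cr$lengths + 1
    ev <- cbind(cs[cr$values & cr$lengths >= min_n],
                ce[cr$values & cr$lengths >= min_n])
    if (is.null(ev) || nrow(ev) == 0) next
    # merge events separated by less than merge_gap
    merged <- ev[1, , drop = FALSE]
    if (nrow(ev) > 1) {
      for (r in 2:nrow(ev)) {
        gap <- (ev[r, 1] - merged[nrow(merged), 2]) * dt
        if (gap < params$merge_gap) {
          merged[nrow(merged), 2] <- ev[r, 2]
        } else {
          merged <- rbind(merged, ev[r, ])
        }
      }
    }
    for (r in seq_len(nrow(merged))) {
      ii <- merged[r, 1]:merged[r, 2]
      pv <- max(sqrt(vx[ii]^2 + vy[ii]^2), na.rm = TRUE)
      disp <- sqrt(diff(range(x[ii]))^2 + diff(range(y[ii]))^2)
      out <- rbind(out, data.frame(onset_s = tt[merged[r, 1]],
                                   offset_s = tt[merged[r, 2]],
                                   peak_vel_dps = pv,
                                   max_disp_deg = disp))
    }
  }
  out
}

#' Main-sequence pairs and microsaccade rate
#'
#' @param events data frame from [detect_microsaccades()] (possibly pooled
#'   over repeats)
#' @param duration total analyzed duration in seconds (repeats x window)
#' @return list with `pairs` (data frame `log_disp`, `log_peak_vel`),
#'   `rate` (events per second) and `correlation` (log-log Pearson r, NA
#'   with fewer than 3 events)
#' @export
main_sequence <- function(events, duration) {
  stopifnot(duration > 0)
  if (nrow(events) == 0) {
    return(list(pairs = data.frame(log_disp = numeric(0),
                                   log_peak_vel = numeric(0)),
                rate = 0, correlation = NA_real_))
  }
  pairs <- data.frame(log_disp = log10(events$max_disp_deg),
                      log_peak_vel = log10(events$peak_vel_dps))
  corr <- if (nrow(pairs) >= 3) stats::cor(pairs$log_disp,
                                           pairs$log_peak_vel) else NA_real_
  list(pairs = pairs, rate = nrow(events) / duration, correlation = corr)
}

#' Coefficient of variation of pupil diameter
#'
#' Per-repeat pupillary reactivity: SD / mean of pupil diameter across time
#' within the analysis window, ignoring blink samples.
#'
#' @param trace eye-trace data frame
#' @param params `eye_params`
#' @return the CV (unitless)
#' @export
pupil_cv <- function(trace, params = eye_params()) {
  tr <- eye_window(trace, params)
  p <- tr$pupil[!is.na(tr$pupil)]
  if (length(p) == 0) stop("all pupil samples are NaN")
  stopifnot(all(p > 0))
  stats::sd(p) / mean(p)
}

#' Subject-level pupil reactivity
#' @param traces list of eye-trace data frames (analyzable repeats)
#' @param params `eye_params`
#' @return mean per-repeat CV
#' @export
pupil_cv_subject <- function(traces, params = eye_params()) {
  mean(vapply(traces, pupil_cv, numeric(1), params = params))
}
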