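# Synthetic cohort generator: trial-level EEG + eye traces with the
# statistical structure the analysis assumes (1/f background, baseline alpha
# with stimulus suppression, stimulus-gated narrow-band slow/fast gamma with
# group-dependent deficits, 32 Hz SSVEP on counterphase trials, onset ERP,
# occipito-parietal topography, fixational eye jitter, ballistic
# microsaccades, blinks, pupil dynamics).

#' Generator parameters
#'
#' Defaults define the simulated study conditions. Amplitudes are in uV at
#' the (unipolar) scalp for a unit-gain channel; the group deficit acts on
#' gamma amplitude (so a factor 0.6 scales induced gamma power by 0.36).
#' `fs` defaults to 500 Hz, keeping every analysis band (<= 84 Hz) well under
#' Nyquist. Background follows `P(f) = A * f^-beta`.
#'
#' @param fs sampling rate, Hz (must exceed 2 x 84 Hz)
#' @param epoch epoch limits in seconds re stimulus onset
#' @param background_A 1/f background scale, uV^2/Hz at 1 Hz
#' @param background_beta 1/f slope
#' @param alpha_amp baseline alpha amplitude, uV
#' @param alpha_suppression stimulus/baseline alpha power ratio (< 1)
#' @param gamma_amp named amplitudes `c(slow =, fast =)`, uV, for a healthy
#'   unit-gain subject
#' @param deficit_factor named amplitude factors per group,
#'   `c(healthy =, mci =, ad =)`, each in (0, 1]
#' @param subject_sd SD of the per-subject log-normal gamma gain
#' @param band_sd SD of the per-band log-normal gain within subject
#' @param age_slope per-year log-gain slope of gamma about age 70
#' @param gender_factor multiplicative gamma gain for females
#' @param sf_factor gamma amplitude factors per spatial frequency (cpd)
#' @param gamma_onset_latency gamma onset delay after stimulus onset, s
#' @param ramp envelope rise time, s
#' @param erp_amp ERP source amplitude scale, uV
#' @param ssvep_amp 32 Hz SSVEP source amplitude (counterphase trials), uV
#' @param topo_base,topo_sigma induced-component gain map: base gain plus a
#'   Gaussian of width `topo_sigma` (layout units) centred on Oz
#' @param evoked_sigma width of the (steeper) evoked-component gain map
#' @param artifact_rate per-repeat probability of an injected artifact
#' @param jitter_sd fixational drift SD per axis, degrees
#' @param tracker_noise white measurement-noise SD of the eye tracker,
#'   degrees
#' @param saccade_rate microsaccade rate, Hz
#' @param saccade_amp_meanlog,saccade_amp_sdlog log-normal microsaccade
#'   amplitude parameters (degrees)
#' @param saccade_duration microsaccade duration, s
#' @param blink_rate blink rate, Hz (blinks become NaN runs)
#' @param blink_duration blink duration, s
#' @param excursion_prob per-repeat probability of a fixation excursion
#'   beyond the 2.5 degree half-window
#' @param pupil_base,pupil_constriction,pupil_noise pupil diameter baseline
#'   (a.u.), relative stimulus constriction, and noise SD
#' @param seed integer seed driving the hierarchical RNG
#'   (cohort -> subject -> trial)
#' @return a validated list of class `gen_params`
#' @export
gen_params <- function(fs = 500, epoch = c(-1.0, 0.8),
                       background_A = 200, background_beta = 1.8,
                       alpha_amp = 5, alpha_suppression = 0.4,
                       gamma_amp = c(slow = 6.5, fast = 5.5),
                       deficit_factor = c(healthy = 1, mci = 0.6, ad = 0.5),
                       subject_sd = 0.25, band_sd = 0.1,
                       age_slope = -0.01, gender_factor = 1.1,
                       sf_factor = c("1" = 0.75, "2" = 1, "4" = 1),
                       gamma_onset_latency = 0.05, ramp = 0.02,
                       erp_amp = 25, ssvep_amp = 12,
                       topo_base = 0.15, topo_sigma = 0.35,
                       evoked_sigma = 0.18,
                       artifact_rate = 0.02,
                       jitter_sd = 0.15, tracker_noise = 0.005,
                       saccade_rate = 0.8,
                       saccade_amp_meanlog = log(0.35),
                       saccade_amp_sdlog = 0.35,
                       saccade_duration = 0.018,
                       blink_rate = 0.08, blink_duration = 0.15,
                       excursion_prob = 0.05,
                       pupil_base = 1000, pupil_constriction = 0.05,
                       pupil_noise = 4,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$fs > 2 * 84, p$epoch[1] < -0.5, p$epoch[2] >= 0.75,
            all(p$gamma_amp >= 0), p$alpha_amp >= 0, p$erp_amp >= 0,
            p$ssvep_amp >= 0, all(p$deficit_factor > 0),
            all(p$deficit_factor <= 1), p$artifact_rate >= 0,
            p$artifact_rate <= 1, p$alpha_suppression > 0,
            p$alpha_suppression <= 1)
  p$seed <- as.integer(p$seed)
  class(p) <- "gen_params"
  p
}

#' The standard stimulus condition sets
#'
#' Gamma experiment: static full-screen gratings at spatial frequencies
#' 1, 2, 4 cpd crossed with orientations 0, 45, 90, 135 degrees. SSVEP
#' experiment: one grating at 2 cpd / 90 degrees shown static (0 cps) or
#' counterphasing at 16 cps.
#'
#' @return data frame with columns `sf` (cpd), `ori` (deg), `tf` (cps)
#' @export
gamma_conditions <- function() {
  expand.grid(sf = c(1, 2, 4), ori = c(0, 45, 90, 135), tf = 0)
}

#' @rdname gamma_conditions
#' @export
ssvep_conditions <- function() {
  data.frame(sf = 2, ori = 90, tf = c(0, 16))
}

# per-channel gain maps, cached against the packaged layout
topography_gains <- function(params) {
  key <- sprintf("topo_%g_%g_%g", params$topo_base, params$topo_sigma,
                 params$evoked_sigma)
  if (!is.null(.gammacc_cache[[key]])) return(.gammacc_cache[[key]])
  layout <- build_layout()
  oz <- layout[layout$electrode == "Oz", ]
  d2 <- (layout$x - oz$x)^2 + (layout$y - oz$y)^2
  g <- params$topo_base +
    (1 - params$topo_base) * exp(-d2 / (2 * params$topo_sigma^2))
  h <- exp(-d2 / (2 * params$evoked_sigma^2))
  out <- list(induced = stats::setNames(g, layout$electrode),
              evoked = stats::setNames(h, layout$electrode),
              electrodes = layout$electrode)
  .gammacc_cache[[key]] <- out
  out
}

# squared magnitude response of a 4th-order Butterworth bandpass, used as a
# zero-phase spectral mask (the filtfilt-equivalent magnitude)
butter_mask <- function(f, lo, hi, order = 4) {
  w <- ifelse(f <= 0, Inf, (f^2 - lo * hi) / (f * (hi - lo)))
  1 / (1 + w^(2 * order))
}

# frequency-domain synthesis setup for one epoch length, cached
synth_masks <- function(n, fs, params) {
  key <- sprintf("masks_%d_%g_%g_%g", n, fs, params$background_A,
                 params$background_beta)
  if (!is.null(.gammacc_cache[[key]])) return(.gammacc_cache[[key]])
  k <- 1:(floor((n - 1) / 2))          # positive-frequency bins
  f <- k * fs / n
  s_bg <- params$background_A * f^(-params$background_beta)
  out <- list(
    k = k, f = f,
    bg_scale = sqrt(fs * n * s_bg / 2),
    slow = sqrt(butter_mask(f, 20, 34)),
    fast = sqrt(butter_mask(f, 36, 66)),
    alpha = sqrt(butter_mask(f, 8, 12))
  )
  .gammacc_cache[[key]] <- out
  out
}

# generate m real series (n x m) whose amplitude spectra follow the given
# per-bin scales (columns of `scales`, length = number of positive bins)
shaped_noise <- function(n, scales) {
  m <- ncol(scales)
  nk <- nrow(scales)
  re <- matrix(stats::rnorm(nk * m), nk, m)
  im <- matrix(stats::rnorm(nk * m), nk, m)
  p <- scales * (re + 1i * im) / sqrt(2)
  # pack two hermitian spectra per complex column: ifft(Z1 + i Z2) has the
  # first real series in its real part and the second in its imaginary part
  if (m %% 2 == 1) p <- cbind(p, 0)
  odd <- seq(1, ncol(p), 2)
  ztop <- p[, odd, drop = FALSE] + 1i * p[, odd + 1, drop = FALSE]
  zbot <- Conj(p[nk:1, odd, drop = FALSE]) +
    1i * Conj(p[nk:1, odd + 1, drop = FALSE])
  z <- matrix(0 + 0i, n, ncol(ztop))
  z[2:(nk + 1), ] <- ztop
  z[(n - nk + 1):n, ] <- zbot
  y <- stats::mvfft(z, inverse = TRUE) / n
  out <- matrix(0, n, ncol(p))
  out[, odd] <- Re(y)
  out[, odd + 1] <- Im(y)
  out[, seq_len(m), drop = FALSE]
}

# random mixing weights: m latent series -> 64 channels, unit-norm columns
mix_weights <- function(m, n_ch = 64) {
  w <- matrix(stats::rnorm(m * n_ch), m, n_ch)
  sweep(w, 2, sqrt(colSums(w^2)), "/")
}

# raised-cosine step from 0 to 1 centred on `at` with rise time `ramp`
smooth_step <- function(t, at, ramp) {
  s <- (t - at) / ramp
  s <- pmin(pmax(s, 0), 1)
  (1 - cos(pi * s)) / 2
}

#' Per-subject gamma gain implied by the profile
#'
#' Combines the group deficit, age and gender trends, and the subject-level
#' log-normal variability (drawn from the subject's own seeded stream).
#' @param subject a subject profile (list/row with `id`, `age`, `gender`,
#'   `group`)
#' @param params `gen_params`
#' @return named vector `c(slow =, fast =)` of amplitude gains
#' @keywords internal
subject_gamma_gain <- function(subject, params) {
  grp <- as.character(subject$group)
  deficit <- params$deficit_factor[[grp]]
  demo <- exp(params$age_slope * (subject$age - 70)) *
    if (identical(as.character(subject$gender), "female"))
      params$gender_factor else 1
  with_local_seed(mix_seed(params$seed, subject$id, "gain"), {
    subj <- exp(stats::rnorm(1, 0, params$subject_sd))
    band <- exp(stats::rnorm(2, 0, params$band_sd))
  })
  c(slow = deficit * demo * subj * band[1],
    fast = deficit * demo * subj * band[2])
}

generate_eye_trace <- function(t, fs, params) {
  n <- length(t)
  # fixational drift: stationary low-pass Gaussian process (spectral mask
  # exp(-(f/f0)^2), f0 = 3 Hz), so velocity noise stays well below
  # microsaccade peak velocities (sigma_v ~ pi * f0 * sigma_x ~ 1.4 deg/s)
  kf <- 1:(floor((n - 1) / 2))
  drift_mask <- matrix(exp(-(kf * fs / n / 3)^2), length(kf), 2)
  drift <- shaped_noise(n, drift_mask)
  x <- drift[, 1] / stats::sd(drift[, 1]) * params$jitter_sd +
    stats::rnorm(n, 0, params$tracker_noise)
  y <- drift[, 2] / stats::sd(drift[, 2]) * params$jitter_sd +
    stats::rnorm(n, 0, params$tracker_noise)
  kw <- 50
  smooth <- function(v) {
    cs <- cumsum(c(rep(v[1], kw), v, rep(v[length(v)], kw)))
    ((cs[(kw + 1):(kw + n) + kw %/% 2] -
        cs[(kw + 1):(kw + n) - (kw - kw %/% 2)]) / kw)
  }
  # ballistic microsaccades: minimum-jerk displacement profiles, directed
  # with a recentring bias so fixation stays bounded
  n_sac <- stats::rpois(1, params$saccade_rate * (t[n] - t[1]))
  events <- NULL
  if (n_sac > 0) {
    onsets <- sort(stats::runif(n_sac, t[2], t[n] - 2 * params$saccade_duration))
    dur <- params$saccade_duration
    nd <- max(2, round(dur * fs))
    s <- seq(0, 1, length.out = nd)
    jerk <- 10 * s^3 - 15 * s^4 + 6 * s^5   # minimum-jerk position profile
    for (on in onsets) {
      amp <- min(stats::rlnorm(1, params$saccade_amp_meanlog,
                               params$saccade_amp_sdlog), 1)
      i0 <- which.min(abs(t - on))
      if (i0 + nd > n) next
      cur <- c(x[i0], y[i0])
      ang <- atan2(-cur[2], -cur[1]) + stats::rnorm(1, 0, 0.9)
      step_x <- amp * cos(ang) * jerk
      step_y <- amp * sin(ang) * jerk
      idx <- i0:(i0 + nd - 1)
      x[idx] <- x[idx] + step_x
      y[idx] <- y[idx] + step_y
      if (i0 + nd <= n) {
        x[(i0 + nd):n] <- x[(i0 + nd):n] + step_x[nd]
        y[(i0 + nd):n] <- y[(i0 + nd):n] + step_y[nd]
      }
      events <- rbind(events, c(onset = on, offset = on + dur,
                                amplitude = amp))
    }
  }
  # occasional large excursion outside the fixation window (a ~30 ms gaze
  # shift held for ~200 ms, not an instantaneous step)
  if (stats::runif(1) < params$excursion_prob) {
    nd <- round(0.2 * fs)
    i0 <- sample.int(n - nd, 1)
    ramp <- pmin(seq_len(nd) / round(0.03 * fs), 1)
    x[i0:(i0 + nd - 1)] <- x[i0:(i0 + nd - 1)] + 3.5 * ramp
  }
  # pupil: slow stimulus-locked constriction plus noise
  constr <- smooth_step(t, 0.3, 0.4)
  pnoise <- smooth(stats::rnorm(n))
  pupil <- params$pupil_base * (1 - params$pupil_constriction * constr) +
    pnoise / stats::sd(pnoise) * params$pupil_noise
  # blinks: NaN runs in x, y, pupil
  n_blink <- stats::rpois(1, params$blink_rate * (t[n] - t[1]))
  if (n_blink > 0) {
    nb <- round(params$blink_duration * fs)
    for (b in seq_len(n_blink)) {
      i0 <- sample.int(n - nb, 1)
      idx <- i0:(i0 + nb - 1)
      x[idx] <- NaN; y[idx] <- NaN; pupil[idx] <- NaN
    }
  }
  structure(data.frame(t_s = t, x_deg = x, y_deg = y, pupil = pupil),
            events = events)
}

#' Generate one stimulus repeat for a subject
#'
#' The baseline segment contains 1/f background and alpha only; from
#' `gamma_onset_latency` after onset the stimulus segment additionally
#' carries band-limited slow (20-34 Hz) and fast (36-66 Hz) gamma (mixtures
#' of band-pass shaped Gaussian noise, amplitude-gated, scaled by the
#' occipito-parietal gain map and the subject's group-dependent gain), alpha
#' scaled by `alpha_suppression`, an onset ERP, and - for counterphase
#' trials (`tf == 16`) - a 32 Hz sinusoid.
#'
#' @param subject profile list/row with `id`, `age`, `gender`, `group`, `cdr`
#' @param condition list/row with `sf` (1, 2 or 4 cpd), `ori` (0/45/90/135),
#'   `tf` (0 or 16 cps)
#' @param params `gen_params`
#' @param repeat_index integer, part of the trial's seed
#' @param seed optional explicit seed (defaults to the hierarchical seed)
#' @return object of class `trial_recording`: list with `data` (samples x 64,
#'   uV, electrode column names), `time` (s re onset), `fs`, `condition`,
#'   `eye` (data frame `t_s`, `x_deg`, `y_deg`, `pupil`), `repeat_index`,
#'   `subject_id`
#' @export
generate_trial <- function(subject, condition, params, repeat_index = 1L,
                           seed = NULL) {
  stopifnot(inherits(params, "gen_params"))
  cond <- as.list(condition)
  if (!cond$sf %in% c(1, 2, 4) || !cond$ori %in% c(0, 45, 90, 135) ||
      !cond$tf %in% c(0, 16)) {
    stop("invalid stimulus condition")
  }
  fs <- params$fs
  n <- round((params$epoch[2] - params$epoch[1]) * fs)
  t <- params$epoch[1] + (seq_len(n) - 1) / fs
  masks <- synth_masks(n, fs, params)
  topo <- topography_gains(params)
  gains <- subject_gamma_gain(subject, params)
  sfac <- params$sf_factor[[as.character(cond$sf)]]
  if (is.null(seed)) {
    seed <- mix_seed(params$seed, subject$id, repeat_index,
                     round(cond$sf * 100 + cond$ori + cond$tf * 7))
  }
  with_local_seed(seed, {
    n_bg <- 16L; n_lat <- 4L
    scales <- cbind(
      matrix(masks$bg_scale, length(masks$k), n_bg),
      matrix(masks$slow, length(masks$k), n_lat),
      matrix(masks$fast, length(masks$k), n_lat),
      matrix(masks$alpha, length(masks$k), n_lat)
    )
    lat <- shaped_noise(n, scales)
    # normalise the narrow-band latents to unit SD; background keeps its
    # absolute 1/f scale
    j <- n_bg + 1:(3 * n_lat)
    sds <- sqrt(colSums(lat[, j]^2) / (n - 1) -
                  colSums(lat[, j])^2 / (n * (n - 1)))
    lat[, j] <- lat[, j] * rep(1 / sds, each = n)

    env <- smooth_step(t, params$gamma_onset_latency, params$ramp)
    lat[, n_bg + 1:(2 * n_lat)] <- lat[, n_bg + 1:(2 * n_lat)] * env
    lat[, n_bg + 2 * n_lat + 1:n_lat] <-
      lat[, n_bg + 2 * n_lat + 1:n_lat] *
      (params$alpha_amp * (1 - (1 - sqrt(params$alpha_suppression)) * env))

    erp <- params$erp_amp *
      (1.0 * exp(-(t - 0.10)^2 / (2 * 0.020^2)) -
       1.25 * exp(-(t - 0.17)^2 / (2 * 0.025^2)) +
       0.75 * exp(-(t - 0.23)^2 / (2 * 0.030^2)))
    evoked <- erp
    if (cond$tf == 16) {
      evoked <- evoked + params$ssvep_amp * env * sin(2 * pi * 32 * t)
    }

    # one mixing matrix: latents (and the evoked series) -> 64 channels
    g_ind <- topo$induced
    w <- rbind(
      mix_weights(n_bg),
      mix_weights(n_lat) *
        rep(gains[["slow"]] * sfac * params$gamma_amp[["slow"]] * g_ind,
            each = n_lat),
      mix_weights(n_lat) *
        rep(gains[["fast"]] * sfac * params$gamma_amp[["fast"]] * g_ind,
            each = n_lat),
      mix_weights(n_lat) * rep(g_ind, each = n_lat),
      topo$evoked
    )
    data <- cbind(lat, evoked) %*% w
    colnames(data) <- topo$electrodes
    eye <- generate_eye_trace(t, fs, params)
  })
  structure(list(data = data, time = t, fs = fs, condition = cond,
                 eye = eye, repeat_index = as.integer(repeat_index),
                 subject_id = subject$id),
            class = "trial_recording")
}

#' Inject artifacts into a trial
#'
#' With probability `rate`, adds a high-amplitude transient (~500 uV, far
#' beyond 6 x background SD) to one or two electrodes, or replaces an
#' electrode's series with a flat-spectrum (white) or rising-spectrum
#' (differenced white) series to trip the 1/f slope rule. Injected artifacts
#' are recorded in the `artifacts` element as ground truth.
#'
#' @param trial a `trial_recording`
#' @param params `gen_params` (`artifact_rate` is the default rate)
#' @param rate per-repeat probability override
#' @param type one of "random", "transient", "flat", "rising"
#' @param electrodes electrode names to target (default: random)
#' @param seed optional explicit seed
#' @return the modified `trial_recording`
#' @export
inject_artifacts <- function(trial, params, rate = params$artifact_rate,
                             type = "random", electrodes = NULL,
                             seed = NULL) {
  stopifnot(inherits(trial, "trial_recording"), rate >= 0, rate <= 1)
  if (is.null(seed)) {
    seed <- mix_seed(params$seed, trial$subject_id, trial$repeat_index,
                     "artifact")
  }
  hit <- with_local_seed(seed, stats::runif(1) < rate)
  if (!hit) return(trial)
  with_local_seed(mix_seed(seed, "kind"), {
    if (type == "random") {
      type <- sample(c("transient", "flat", "rising"), 1,
                     prob = c(0.7, 0.15, 0.15))
    }
    if (is.null(electrodes)) {
      electrodes <- sample(colnames(trial$data),
                           if (type == "transient") sample(1:2, 1) else 1)
    }
    n <- nrow(trial$data)
    for (e in electrodes) {
      if (type == "transient") {
        i0 <- sample.int(n - round(0.03 * trial$fs), 1)
        idx <- i0:(i0 + round(0.03 * trial$fs) - 1)
        shape <- exp(-((seq_along(idx) - length(idx) / 2)^2) /
                       (2 * (length(idx) / 5)^2))
        trial$data[idx, e] <- trial$data[idx, e] + 500 * shape
      } else if (type == "flat") {
        trial$data[, e] <- stats::rnorm(n, 0, stats::sd(trial$data[, e]))
      } else {
        w <- diff(stats::rnorm(n + 1))
        trial$data[, e] <- w / stats::sd(w) * stats::sd(trial$data[, e])
      }
      trial$artifacts <- c(trial$artifacts,
                           list(list(type = type, electrode = e)))
    }
    trial
  })
}

#' Generate all trials for one subject
#'
#' @param subject profile row/list
#' @param params `gen_params`
#' @param conditions data frame of conditions (default [gamma_conditions()])
#' @param repeats repeats per condition
#' @param inject apply [inject_artifacts()] at the default rate
#' @return list of `trial_recording`s (repeat indices run within condition)
#' @export
generate_subject_trials <- function(subject, params,
                                    conditions = gamma_conditions(),
                                    repeats = 30, inject = TRUE) {
  trials <- vector("list", nrow(conditions) * repeats)
  k <- 1
  for (ci in seq_len(nrow(conditions))) {
    for (r in seq_len(repeats)) {
      tr <- generate_trial(subject, conditions[ci, ], params,
                           repeat_index = (ci - 1) * repeats + r)
      if (inject) tr <- inject_artifacts(tr, params)
      trials[[k]] <- tr
      k <- k + 1
    }
  }
  trials
}

#' Generate subject profiles with guaranteed matchability
#'
#' Ages are drawn as integers in 50-92 and genders at random. Every case
#' (MCI or AD) is guaranteed at least one age- (within 1 year) and
#' gender-matched healthy subject: unmatched cases have a healthy subject
#' re-assigned (round robin) to a matching age and gender, emulating a
#' recruit-until-matched design. CDR follows the group (healthy 0, MCI 0.5,
#' AD 1 or 3).
#'
#' @param n_healthy,n_mci,n_ad group sizes
#' @param params `gen_params` (seed source)
#' @return data frame of class `subject_profiles`: `id`, `age`, `gender`,
#'   `group`, `cdr`
#' @export
generate_profiles <- function(n_healthy, n_mci, n_ad, params) {
  stopifnot(n_healthy >= 0, n_mci >= 0, n_ad >= 0)
  n_cases <- n_mci + n_ad
  if (n_cases > 0 && n_healthy < 1) {
    stop("impossible matching constraint: cases but no healthy subjects")
  }
  with_local_seed(mix_seed(params$seed, "profiles"), {
    n <- n_healthy + n_mci + n_ad
    grp <- c(rep("healthy", n_healthy), rep("mci", n_mci), rep("ad", n_ad))
    prof <- data.frame(
      id = sprintf("S%03d", seq_len(n)),
      age = sample(50:92, n, replace = TRUE),
      gender = sample(c("male", "female"), n, replace = TRUE),
      group = grp,
      stringsAsFactors = FALSE
    )
    prof$cdr <- c(healthy = 0, mci = 0.5, ad = NA)[prof$group]
    prof$cdr[prof$group == "ad"] <- sample(c(1, 3), n_ad, replace = TRUE,
                                           prob = c(0.8, 0.2))
    healthy_idx <- which(prof$group == "healthy")
    case_idx <- which(prof$group != "healthy")
    matches_case <- function(j, i) {
      abs(prof$age[j] - prof$age[i]) <= 1 && prof$gender[j] == prof$gender[i]
    }
    # re-draw healthy profiles until every case has a match; only healthy
    # subjects whose removal harms no case are reassigned, so fixing one
    # case can never unfix another
    for (pass in 1:10) {
      match_sets <- lapply(case_idx, function(i)
        healthy_idx[vapply(healthy_idx, matches_case, logical(1), i = i)])
      unmatched <- case_idx[lengths(match_sets) == 0]
      if (length(unmatched) == 0) break
      n_matches <- lengths(match_sets)
      for (i in unmatched) {
        harmless <- vapply(healthy_idx, function(j)
          all(n_matches[vapply(match_sets, function(s) j %in% s,
                               logical(1))] >= 2), logical(1))
        cand <- healthy_idx[harmless]
        j <- if (length(cand) > 0) cand[1] else healthy_idx[1]
        prof$age[j] <- prof$age[i]
        prof$gender[j] <- prof$gender[i]
      }
    }
  })
  class(prof) <- c("subject_profiles", "data.frame")
  prof
}

#' Generate a full synthetic cohort
#'
#' @param n_healthy,n_mci,n_ad group sizes
#' @param repeats_per_condition repeats of each condition per subject
#' @param params `gen_params`
#' @param conditions condition set (default [gamma_conditions()])
#' @param inject apply artifact injection
#' @return list of class `cohort`: `profiles` (data frame) and `subjects`,
#'   a list of `list(profile, trials)` in profile order
#' @export
generate_cohort <- function(n_healthy, n_mci, n_ad,
                            repeats_per_condition = 30,
                            params = gen_params(),
                            conditions = gamma_conditions(),
                            inject = TRUE) {
  prof <- generate_profiles(n_healthy, n_mci, n_ad, params)
  subjects <- lapply(seq_len(nrow(prof)), function(i) {
    list(profile = prof[i, ],
         trials = generate_subject_trials(prof[i, ], params, conditions,
                                          repeats_per_condition, inject))
  })
  structure(list(profiles = prof, subjects = subjects, params = params),
            class = "cohort")
}

#' Save / load a cohort
#'
#' Persists the in-memory cohort container: a plain-text metadata TSV mirror
#' (`profiles.tsv`) alongside an RDS file with the trial data.
#'
#' @param cohort a `cohort`
#' @param dir directory to write into (created if needed)
#' @return `save_cohort` returns `dir` invisibly; `load_cohort` the `cohort`
#' @export
save_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$profiles, file.path(dir, "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(cohort, file.path(dir, "cohort.rds"))
  invisible(dir)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(dir) {
  readRDS(file.path(dir, "cohort.rds"))
}
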