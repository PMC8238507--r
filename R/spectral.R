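# Single-taper multitaper spectral estimation and band-level statistics

#' Built-in frequency band definitions
#'
#' The analysis bands: alpha (8-12 Hz), slow gamma (20-34 Hz), fast gamma
#' (36-66 Hz), the narrower "sensitive" variants (26-34, 44-56 Hz), the
#' combined gamma band (20-66 Hz) and the traditional broad gamma band
#' (30-80 Hz). Band sums are inclusive of both edges on the frequency grid.
#'
#' @return data frame with columns `name`, `f_lo`, `f_hi` (Hz)
#' @export
band_definitions <- function() {
  data.frame(
    name = c("alpha", "slow_gamma", "fast_gamma", "slow_sensitive",
             "fast_sensitive", "combined_gamma", "traditional_gamma"),
    f_lo = c(8, 20, 36, 26, 44, 20, 30),
    f_hi = c(12, 34, 66, 34, 56, 66, 80),
    stringsAsFactors = FALSE
  )
}

resolve_band <- function(band) {
  if (is.character(band) && length(band) == 1) {
    defs <- band_definitions()
    i <- match(band, defs$name)
    if (is.na(i)) stop("unknown band name: ", band)
    return(c(f_lo = defs$f_lo[i], f_hi = defs$f_hi[i]))
  }
  if (is.list(band)) band <- c(band$f_lo, band$f_hi)
  band <- as.numeric(band)
  stopifnot(length(band) == 2, band[1] <= band[2], band[1] >= 0)
  c(f_lo = band[1], f_hi = band[2])
}

#' Multitaper power spectral density with a single Slepian taper
#'
#' One-sided PSD of a windowed segment using the leading DPSS taper with
#' time-bandwidth product `nw` (default 1, i.e. the minimal-taper multitaper
#' setting). Frequency spacing is `fs / n`, so a 500 ms segment at 500 Hz
#' gives the 2 Hz resolution the band sums assume.
#'
#' @param x numeric vector (one channel) or matrix (samples x channels)
#' @param fs sampling rate, Hz
#' @param nw time-bandwidth product of the taper
#' @param window optional label (e.g. "baseline", "stimulus") carried along
#' @return object of class `psd_estimate`: list with `freqs` (Hz), `power`
#'   (uV^2/Hz; vector, or matrix bins x channels), `fs`, `n_samples`,
#'   `n_repeats` (1), `window`
#' @export
multitaper_psd <- function(x, fs, nw = 1, window = NULL) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  stopifnot(is.numeric(x), fs > 0, nrow(x) >= 16)
  if (anyNA(x)) stop("segment contains NA/NaN; artifact rejection must precede")
  n <- nrow(x)
  taper <- dpss_taper(n, nw)
  xt <- x * taper
  ft <- stats::mvfft(xt)
  nb <- floor(n / 2) + 1
  pw <- (Mod(ft[seq_len(nb), , drop = FALSE])^2) / fs
  # one-sided: double all bins except DC (and Nyquist when n is even)
  dbl <- rep(2, nb)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nb] <- 1
  pw <- pw * dbl
  if (ncol(pw) == 1) pw <- drop(pw)
  structure(list(freqs = (seq_len(nb) - 1) * fs / n, power = pw, fs = fs,
                 n_samples = n, n_repeats = 1L, window = window),
            class = "psd_estimate")
}

#' Average PSD estimates across repeats and channels
#'
#' @param psds list of `psd_estimate`s on identical frequency grids
#' @param channels average across channels too (default TRUE), yielding a
#'   single spectrum
#' @return a `psd_estimate` with the averaged power and `n_repeats` set
#' @export
average_psd <- function(psds, channels = TRUE) {
  stopifnot(length(psds) >= 1)
  f0 <- psds[[1]]$freqs
  for (p in psds) stopifnot(isTRUE(all.equal(p$freqs, f0)))
  acc <- 0
  for (p in psds) {
    pw <- p$power
    if (channels && is.matrix(pw)) pw <- rowMeans(pw)
    acc <- acc + pw
  }
  out <- psds[[1]]
  out$power <- acc / length(psds)
  out$n_repeats <- length(psds)
  out
}

#' Change in band-limited power (dB)
#'
#' The central per-subject statistic: power is summed over all frequency bins
#' inside the band (inclusive of both edges) in the stimulus and baseline
#' spectra, and the change is one log ratio of the two sums,
#' `10 * log10(sum ST / sum BL)` - not a mean of per-frequency dB values, so
#' bins with more absolute power (lower frequencies) contribute more.
#'
#' @param st stimulus-window `psd_estimate` (averaged across repeats/pairs)
#' @param bl baseline-window `psd_estimate` on the same frequency grid
#' @param band a band name from [band_definitions()], or `c(f_lo, f_hi)` in Hz
#' @return object of class `band_power`: list with `band`, `delta_power`
#'   (dB), `st_sum`, `bl_sum`
#' @export
delta_power <- function(st, bl, band) {
  stopifnot(inherits(st, "psd_estimate"), inherits(bl, "psd_estimate"))
  if (!isTRUE(all.equal(st$freqs, bl$freqs)))
    stop("stimulus and baseline spectra are on different frequency grids")
  b <- resolve_band(band)
  sel <- st$freqs >= b[1] - 1e-9 & st$freqs <= b[2] + 1e-9
  if (!any(sel)) stop("band contains no frequency bins")
  stp <- st$power; blp <- bl$power
  if (is.matrix(stp)) stp <- rowMeans(stp)
  if (is.matrix(blp)) blp <- rowMeans(blp)
  st_sum <- sum(stp[sel])
  bl_sum <- sum(blp[sel])
  if (bl_sum <= 0) stop("baseline band power is zero; delta power undefined")
  structure(list(band = b, delta_power = 10 * log10(st_sum / bl_sum),
                 st_sum = st_sum, bl_sum = bl_sum),
            class = "band_power")
}

#' Moving-window spectrogram
#'
#' Single-taper spectrogram with 250 ms windows stepped by 25 ms (4 Hz
#' frequency resolution at the defaults). Power of multi-channel input is
#' averaged across channels.
#'
#' @param x numeric vector or matrix (samples x channels)
#' @param fs sampling rate, Hz
#' @param time time axis in seconds (0 = stimulus onset); defaults to
#'   sample index / fs
#' @param window window length, s
#' @param step step size, s
#' @param nw taper time-bandwidth product
#' @return object of class `spectrogram`: list with `times` (window centers,
#'   s), `freqs` (Hz), `power` (time x freq, uV^2/Hz), `fs`
#' @export
spectrogram <- function(x, fs, time = NULL, window = 0.25, step = 0.025,
                        nw = 1) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (is.null(time)) time <- (seq_len(n) - 1) / fs
  wl <- round(window * fs)
  if (n < wl) stop("epoch shorter than one spectrogram window")
  st <- round(step * fs)
  starts <- seq(1, n - wl + 1, by = st)
  taper <- dpss_taper(wl, nw)
  nb <- floor(wl / 2) + 1
  dbl <- rep(2, nb); dbl[1] <- 1
  if (wl %% 2 == 0) dbl[nb] <- 1
  pw <- matrix(0, length(starts), nb)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + wl - 1), , drop = FALSE] * taper
    p <- (Mod(stats::mvfft(seg)[seq_len(nb), , drop = FALSE])^2) / fs
    pw[i, ] <- rowMeans(p) * dbl
  }
  centers <- time[starts] + (wl - 1) / (2 * fs)
  structure(list(times = centers, freqs = (seq_len(nb) - 1) * fs / wl,
                 power = pw, fs = fs, window = window),
            class = "spectrogram")
}

#' Change-in-power spectrogram relative to a baseline period
#'
#' `10 * log10(power / baseline)` per frequency, where the baseline is the
#' mean power over windows lying fully inside the baseline interval.
#'
#' @param sg a `spectrogram`
#' @param baseline `c(lo, hi)` in seconds (default -0.5 to 0)
#' @return a `spectrogram` whose `power` is in dB re baseline
#' @export
spectrogram_change <- function(sg, baseline = c(-0.5, 0)) {
  stopifnot(inherits(sg, "spectrogram"))
  half <- sg$window / 2
  inb <- sg$times - half >= baseline[1] - 1e-9 &
    sg$times + half <= baseline[2] + 1e-9
  if (!any(inb)) stop("no spectrogram windows fully inside the baseline")
  ref <- colMeans(sg$power[inb, , drop = FALSE])
  if (any(ref <= 0)) stop("nonpositive baseline power")
  sg$power <- 10 * log10(sweep(sg$power, 2, ref, "/"))
  sg$baseline <- baseline
  sg
}

#' Fit a power law to a PSD segment
#'
#' Fits `P(f) = A * f^-beta` over `band` (default 56-84 Hz, the
#' artifact-screening range): closed-form log-log regression, optionally
#' refined by a derivative-free Nelder-Mead simplex search on the
#' linear-domain squared error.
#'
#' @param psd a `psd_estimate` (power must be a single spectrum)
#' @param band `c(f_lo, f_hi)` in Hz
#' @param refine run the simplex refinement (default TRUE); the rejection
#'   cascade uses the closed-form estimate, whose sign is what the rule needs
#' @return object of class `slope_fit`: list with `A`, `beta`, `fit_band`,
#'   `residual` (linear-domain sum of squares)
#' @export
fit_psd_slope <- function(psd, band = c(56, 84), refine = TRUE) {
  stopifnot(inherits(psd, "psd_estimate"))
  pw <- psd$power
  if (is.matrix(pw)) pw <- rowMeans(pw)
  b <- resolve_band(band)
  sel <- psd$freqs >= b[1] - 1e-9 & psd$freqs <= b[2] + 1e-9 & psd$freqs > 0
  f <- psd$freqs[sel]
  p <- pw[sel]
  if (length(f) < 5) stop("need at least 5 frequency bins in the fit band")
  if (any(p <= 0)) stop("nonpositive power in the fit band")
  lf <- log(f); lp <- log(p)
  beta <- -stats::cov(lf, lp) / stats::var(lf)
  logA <- mean(lp) + beta * mean(lf)
  if (refine) {
    obj <- function(par) sum((p - exp(par[1]) * f^(-par[2]))^2)
    fit <- stats::optim(c(logA, beta), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
    logA <- fit$par[1]; beta <- fit$par[2]
  }
  A <- exp(logA)
  structure(list(A = A, beta = beta, fit_band = unname(b),
                 residual = sum((p - A * f^(-beta))^2)),
            class = "slope_fit")
}

#' Orientation selectivity of band-limited power
#'
#' Circular-vector measure on absolute stimulus power across orientations:
#' `|sum_i R_i exp(j 2 theta_i)| / sum_i R_i`, with theta in radians
#' internally. 0 for flat tuning, 1 for power confined to one orientation.
#' Power should be averaged across spatial frequencies before the call.
#'
#' @param R absolute power (uV^2) per orientation, nonnegative
#' @param thetas_deg orientations in degrees (default 0, 45, 90, 135)
#' @return selectivity in `[0, 1]`
#' @export
orientation_selectivity <- function(R, thetas_deg = c(0, 45, 90, 135)) {
  stopifnot(length(R) == length(thetas_deg), all(R >= 0))
  if (sum(R) <= 0) stop("total power is zero; selectivity undefined")
  th <- thetas_deg * pi / 180
  Mod(sum(R * exp(2i * th))) / sum(R)
}

#' SSVEP change in power at the response frequency
#'
#' For counterphasing gratings the steady-state response lands at twice the
#' counterphase frequency (32 Hz for 16 cps). This is [delta_power()]
#' restricted to that single frequency bin, which must lie on the grid.
#'
#' @param st,bl stimulus and baseline `psd_estimate`s
#' @param freq response frequency in Hz (default 32)
#' @return a `band_power` at the single bin
#' @export
ssvep_power <- function(st, bl, freq = 32) {
  if (min(abs(st$freqs - freq)) > 1e-6)
    stop(freq, " Hz is not on the frequency grid; window length must make ",
         "the grid spacing divide it")
  delta_power(st, bl, c(freq, freq))
}

#' Trial-averaged event-related potential and its peaks
#'
#' Subtracts each repeat's baseline mean (over `baseline`), averages across
#' repeats, and reads off the three conventional visual-ERP peaks: P1 =
#' maximum in 75-125 ms, N1 = minimum in 125-200 ms, P2 = maximum in
#' 175-300 ms; plus the RMS of the onset response over 0-250 ms.
#'
#' @param epochs numeric matrix, repeats x samples (one derived channel, or
#'   already averaged across the analysis pairs)
#' @param time time axis in seconds, 0 = stimulus onset
#' @param baseline baseline interval, s
#' @param windows named list of `c(lo, hi)` peak-search windows, s
#' @return object of class `erp_result`: list with `waveform`, `time`,
#'   `peaks` (data frame: peak, latency, amplitude), `onset_rms`, `n_repeats`
#' @export
compute_erp <- function(epochs, time, baseline = c(-0.5, 0),
                        windows = list(P1 = c(0.075, 0.125),
                                       N1 = c(0.125, 0.200),
                                       P2 = c(0.175, 0.300))) {
  stopifnot(is.matrix(epochs), ncol(epochs) == length(time))
  if (nrow(epochs) < 10) stop("need at least 10 clean repeats for an ERP")
  lims <- range(unlist(windows))
  if (lims[1] < min(time) || lims[2] > max(time))
    stop("peak windows fall outside the epoch")
  blsel <- time_window(time, baseline[1], baseline[2])
  wf <- colMeans(epochs - rowMeans(epochs[, blsel, drop = FALSE]))
  pick <- function(w, fun) {
    sel <- which(time_window(time, w[1], w[2] + 1e-9))
    i <- sel[fun(wf[sel])]
    c(latency = time[i], amplitude = wf[i])
  }
  pk <- rbind(P1 = pick(windows$P1, which.max),
              N1 = pick(windows$N1, which.min),
              P2 = pick(windows$P2, which.max))
  onset <- time_window(time, 0, 0.25)
  structure(list(waveform = wf, time = time,
                 peaks = data.frame(peak = rownames(pk), pk,
                                    row.names = NULL),
                 onset_rms = sqrt(mean(wf[onset]^2)),
                 n_repeats = nrow(epochs)),
            class = "erp_result")
}
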