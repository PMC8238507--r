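# shared fixtures, built in code at test time

test_layout <- build_layout()
test_montage <- derive_bipolar(test_layout)

healthy_profile <- function(id = "T001", age = 70, gender = "male") {
  list(id = id, age = age, gender = gender, group = "healthy", cdr = 0)
}

mci_profile <- function(id = "T101", age = 70, gender = "male") {
  list(id = id, age = age, gender = gender, group = "mci", cdr = 0.5)
}

# a psd_estimate built by hand
mk_psd <- function(power, freqs = (seq_along(power) - 1) * 2, fs = 500) {
  structure(list(freqs = freqs, power = power, fs = fs,
                 n_samples = NA, n_repeats = 1L, window = NULL),
            class = "psd_estimate")
}

# averaged baseline/stimulus spectra over the nine analysis pairs for
# generated trials of one subject
averaged_pair_spectra <- function(profile, params, n_rep,
                                  condition = list(sf = 2, ori = 90, tf = 0),
                                  montage = test_montage) {
  st <- 0; bl <- 0
  for (i in seq_len(n_rep)) {
    tr <- generate_trial(profile, condition, params, repeat_index = i)
    bp <- bipolar_signals(tr$data, montage)
    bsel <- tr$time >= -0.5 & tr$time < 0
    ssel <- tr$time >= 0.25 & tr$time < 0.75
    bl <- bl + rowMeans(multitaper_psd(bp[bsel, ], params$fs)$power) / n_rep
    st <- st + rowMeans(multitaper_psd(bp[ssel, ], params$fs)$power) / n_rep
  }
  list(st = mk_psd(st), bl = mk_psd(bl))
}

# minimum-jerk saccade displacement profile on s in [0, 1]
min_jerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5

# a synthetic eye trace: quiet white jitter with optional injected saccades
# (list of c(onset, amplitude)), sampled at fs over [-1, 0.8)
quiet_trace <- function(fs = 500, jitter = 0.01, saccades = list(),
                        seed = 1) {
  withr::with_seed(seed, {
    t <- seq(-1, 0.8 - 1 / fs, by = 1 / fs)
    n <- length(t)
    x <- rnorm(n, 0, jitter)
    y <- rnorm(n, 0, jitter)
    dur <- 0.018
    nd <- round(dur * fs)
    for (s in saccades) {
      i0 <- which.min(abs(t - s[1]))
      prof <- s[2] * min_jerk(seq(0, 1, length.out = nd))
      x[i0:(i0 + nd - 1)] <- x[i0:(i0 + nd - 1)] + prof
      x[(i0 + nd):n] <- x[(i0 + nd):n] + s[2]
    }
    data.frame(t_s = t, x_deg = x, y_deg = y, pupil = 1000)
  })
}
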