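# Repeat/electrode/block artifact-rejection cascade

#' Rejection parameters
#'
#' Thresholds of the cascade: repeat-wise robust thresholding (median +
#' k * MAD on per-repeat max absolute amplitude and mean log PSD in the
#' -500 to 750 ms analysis window), the 30% bad-repeat electrode rule, the
#' 10% bad-electrode repeat rule, and the 56-84 Hz PSD slope rule.
#'
#' @param waveform_k MAD multiplier for the amplitude measure
#' @param psd_k MAD multiplier for the log-PSD measure
#' @param electrode_bad_repeat_frac discard an electrode when more than this
#'   fraction of repeats is bad (default 0.30)
#' @param repeat_bad_electrode_frac discard a repeat when it is bad on more
#'   than this fraction of the remaining electrodes (default 0.10)
#' @param slope_band frequency band for the power-law slope fit, Hz
#' @param analysis_window thresholding window, s re stimulus onset
#' @return list of class `rejection_params`
#' @export
rejection_params <- function(waveform_k = 6, psd_k = 6,
                             electrode_bad_repeat_frac = 0.30,
                             repeat_bad_electrode_frac = 0.10,
                             slope_band = c(56, 84),
                             analysis_window = c(-0.5, 0.75)) {
  p <- as.list(environment())
  stopifnot(p$electrode_bad_repeat_frac > 0, p$electrode_bad_repeat_frac < 1,
            p$repeat_bad_electrode_frac > 0, p$repeat_bad_electrode_frac < 1,
            p$waveform_k > 0, p$psd_k > 0)
  class(p) <- "rejection_params"
  p
}

#' Repeat-wise robust thresholding per electrode
#'
#' For each electrode, a repeat is flagged when its maximum absolute
#' amplitude or its mean log10 PSD inside the analysis window exceeds the
#' median + k * MAD of that measure across the electrode's repeats. An
#' all-NaN (or partially NaN) channel is flagged entirely.
#'
#' @param trials list of `trial_recording`s for one block
#' @param params `rejection_params`
#' @return logical matrix, electrodes x repeats, with electrode row names
#' @export
flag_repeats_per_electrode <- function(trials, params = rejection_params()) {
  stopifnot(length(trials) >= 8)
  w <- params$analysis_window
  sel <- time_window(trials[[1]]$time, w[1], w[2])
  fs <- trials[[1]]$fs
  n_e <- ncol(trials[[1]]$data)
  n_r <- length(trials)
  taper <- dpss_taper(sum(sel), 1)
  # all repeats in one batched FFT (columns = electrode x repeat blocks)
  big <- do.call(cbind, lapply(trials, function(tr)
    tr$data[sel, , drop = FALSE]))
  a <- abs(big)
  amp <- matrix(a[cbind(max.col(t(a), ties.method = "first"),
                        seq_len(ncol(a)))], n_e, n_r)
  pw <- fft_power_batch(big * taper) / fs
  lpsd <- matrix(colMeans(log10(pmax(pw, 1e-300))), n_e, n_r)
  rownames(amp) <- colnames(trials[[1]]$data)
  thresh_flags <- function(m, k) {
    med <- apply(m, 1, stats::median, na.rm = TRUE)
    md <- apply(m, 1, stats::mad, na.rm = TRUE)
    sweep(m, 1, med + k * md, ">")
  }
  flags <- thresh_flags(amp, params$waveform_k) |
    thresh_flags(lpsd, params$psd_k)
  # degenerate inputs: NaN samples or a dead (flat-zero) segment
  flags[is.na(amp) | is.na(lpsd) | is.na(flags) | amp == 0] <- TRUE
  rownames(flags) <- rownames(amp)
  flags
}

#' Apply the rejection cascade
#'
#' Fixed stage order: (1) discard electrodes bad on more than 30% of
#' repeats, (2) discard repeats bad on more than 10% of the remaining
#' electrodes, (3) discard electrodes whose baseline PSD slope beta is
#' negative, (4) evaluate the block rule - after propagating bad unipolar
#' electrodes to the bipolar montage, each of the three occipito-parietal
#' pair groups must retain at least one clean pair.
#'
#' @param flags logical matrix from [flag_repeats_per_electrode()]
#' @param montage a `bipolar_montage`
#' @param slopes named numeric vector of per-electrode PSD slopes (beta) from
#'   [fit_psd_slope()] on baseline spectra averaged over surviving repeats
#' @param params `rejection_params`
#' @param bad_input character vector of electrodes bad a priori (e.g. high
#'   impedance at recording time)
#' @return list of class `rejection_report`: `bad_electrodes` (named reason
#'   vector: impedance, repeat_fraction or slope), `bad_repeats` (integer
#'   indices), `bad_pairs`, `block_ok`, `counts`
#' @export
apply_cascade <- function(flags, montage, slopes,
                          params = rejection_params(),
                          bad_input = character()) {
  stopifnot(is.matrix(flags), inherits(montage, "bipolar_montage"))
  electrodes <- rownames(flags)
  if (length(electrodes) == 0) {
    return(structure(list(bad_electrodes = character(),
                          bad_repeats = integer(), bad_pairs = character(),
                          block_ok = FALSE,
                          counts = list(reason = "empty electrode set")),
                     class = "rejection_report"))
  }
  reasons <- character(0)
  if (length(bad_input) > 0) {
    reasons[intersect(bad_input, electrodes)] <- "impedance"
  }
  # stage 1: electrode rule
  frac_bad <- rowMeans(flags)
  s1 <- electrodes[frac_bad > params$electrode_bad_repeat_frac]
  s1 <- setdiff(s1, names(reasons))
  reasons[s1] <- "repeat_fraction"
  # stage 2: repeat rule on remaining electrodes
  remaining <- setdiff(electrodes, names(reasons))
  if (length(remaining) > 0) {
    frac_rep <- colMeans(flags[remaining, , drop = FALSE])
    bad_repeats <- which(frac_rep > params$repeat_bad_electrode_frac)
  } else {
    bad_repeats <- integer(0)
  }
  # stage 3: slope rule
  s3 <- remaining[!is.na(slopes[remaining]) & slopes[remaining] < 0]
  reasons[s3] <- "slope"
  # stage 4: block rule over the three analysis pair groups
  bad_pairs <- propagate_bad(montage, names(reasons))
  block_ok <- all(vapply(montage$analysis_groups,
                         function(g) any(!g %in% bad_pairs), logical(1)))
  structure(list(
    bad_electrodes = reasons,
    bad_repeats = as.integer(bad_repeats),
    bad_pairs = bad_pairs,
    block_ok = block_ok,
    counts = list(
      n_electrodes = length(electrodes), n_repeats = ncol(flags),
      impedance = sum(reasons == "impedance"),
      repeat_fraction = sum(reasons == "repeat_fraction"),
      slope = sum(reasons == "slope"),
      bad_repeats = length(bad_repeats))),
    class = "rejection_report")
}

#' Serialise a rejection report to JSON
#' @param report a `rejection_report`
#' @return a JSON string
#' @export
rejection_report_json <- function(report) {
  stopifnot(inherits(report, "rejection_report"))
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
}
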