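# Pipeline orchestration: screen -> reject -> re-reference -> spectra ->
# metrics -> match -> compare

#' Default pipeline configuration
#'
#' Every study parameter surfaces here: the analysis bands, the baseline
#' (-500 to 0 ms) and stimulus (250 to 750 ms) windows, rejection and eye
#' parameters, the spatial-frequency condition filter (2 and 4 cpd), the
#' matching tolerance, bootstrap iterations, and the seed all derived
#' randomness uses.
#'
#' @param seed integer master seed
#' @param bands band names (see [band_definitions()]) summarised per subject
#' @param baseline,stimulus analysis windows, s re onset
#' @param sf_filter spatial frequencies (cpd) entering the gamma analysis
#' @param rejection a `rejection_params`
#' @param eye an `eye_params`
#' @param age_tol matching tolerance, years
#' @param limit_n optional cap on controls per case
#' @param n_boot bootstrap iterations for group comparisons
#' @param microsaccade_filter "none" (all analyzable repeats), "without"
#'   (drop repeats containing microsaccades) or "with" (keep only those)
#' @param compute_eye_metrics compute microsaccade rate and pupil CV
#' @param compute_erp compute the trial-averaged ERP (needs >= 10 repeats)
#' @return list of class `pipeline_config`
#' @export
default_config <- function(seed = 1L,
                           bands = c("alpha", "slow_gamma", "fast_gamma"),
                           baseline = c(-0.5, 0), stimulus = c(0.25, 0.75),
                           sf_filter = c(2, 4),
                           rejection = rejection_params(),
                           eye = eye_params(),
                           age_tol = 1, limit_n = NULL, n_boot = 10000,
                           microsaccade_filter = "none",
                           compute_eye_metrics = TRUE,
                           compute_erp = TRUE) {
  cfg <- as.list(environment())
  stopifnot(all(bands %in% band_definitions()$name),
            microsaccade_filter %in% c("none", "without", "with"))
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path file path
#' @param cfg a `pipeline_config`
#' @return `read_config` returns a `pipeline_config`
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (inherits(x, c("rejection_params", "eye_params"))) unclass(x) else x),
    path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in intersect(names(raw), names(cfg))) {
    if (nm == "rejection") cfg$rejection <- do.call(rejection_params, raw[[nm]])
    else if (nm == "eye") cfg$eye <- do.call(eye_params, raw[[nm]])
    else cfg[[nm]] <- raw[[nm]]
  }
  cfg
}

# single-taper PSD of many same-length segments in one batched FFT;
# returns the mean one-sided power (bins x channels) across segments
batch_psd_mean <- function(seg_list, fs) {
  n <- nrow(seg_list[[1]])
  n_ch <- ncol(seg_list[[1]])
  big <- do.call(cbind, seg_list) * dpss_taper(n, 1)
  pw <- fft_power_batch(big) / fs
  nb <- floor(n / 2) + 1
  dbl <- rep(2, nb); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nb] <- 1
  acc <- 0
  for (r in seq_along(seg_list)) {
    acc <- acc + pw[, (r - 1) * n_ch + seq_len(n_ch), drop = FALSE]
  }
  (acc / length(seg_list)) * dbl
}

# psd_estimate wrapper around a precomputed power vector/matrix
as_psd <- function(power, n, fs, n_repeats = 1L, window = NULL) {
  nb <- floor(n / 2) + 1
  structure(list(freqs = (seq_len(nb) - 1) * fs / n, power = power, fs = fs,
                 n_samples = n, n_repeats = n_repeats, window = window),
            class = "psd_estimate")
}

#' Analyze one subject's block of trials
#'
#' Order of operations: fixation-break screening, repeat/electrode/block
#' artifact cascade (the slope rule on baseline spectra averaged over
#' surviving repeats), bipolar re-referencing to the clean analysis pairs,
#' condition filtering (static gratings at the configured spatial
#' frequencies for the gamma measures; counterphase trials for the SSVEP),
#' per-repeat single-taper spectra averaged across repeats and pairs, then
#' band-limited change in power.
#'
#' @param trials list of `trial_recording`s
#' @param config `pipeline_config`
#' @param montage a `bipolar_montage` (default: packaged)
#' @param profile subject profile row (default: reconstructed from trials)
#' @param bad_input a-priori bad electrodes (impedance list)
#' @return list of class `subject_summary`; `excluded` is TRUE (with
#'   `reason`) when the block rule fails or too few repeats survive
#' @export
run_subject <- function(trials, config = default_config(),
                        montage = derive_bipolar(build_layout()),
                        profile = NULL, bad_input = character()) {
  stopifnot(length(trials) > 0)
  if (is.null(profile)) {
    profile <- list(id = trials[[1]]$subject_id, age = NA, gender = NA,
                    group = NA, cdr = NA)
  }
  n_total <- length(trials)
  excluded <- function(reason, counts = list()) {
    structure(list(id = profile$id, profile = profile, excluded = TRUE,
                   reason = reason, counts = counts),
              class = "subject_summary")
  }
  # 1. fixation-break screening
  fix_break <- vapply(trials, function(tr)
    detect_fixation_breaks(tr$eye, config$eye), logical(1))
  kept <- trials[!fix_break]
  counts <- list(n_total = n_total, fixation_rejected = sum(fix_break))
  if (length(kept) < 8) return(excluded("too_few_repeats", counts))
  # optional microsaccade-based repeat filter
  events_per_repeat <- NULL
  if (config$microsaccade_filter != "none" || config$compute_eye_metrics) {
    events_per_repeat <- lapply(kept, function(tr)
      detect_microsaccades(tr$eye, config$eye))
  }
  if (config$microsaccade_filter != "none") {
    has_ms <- vapply(events_per_repeat, nrow, integer(1)) > 0
    sel <- if (config$microsaccade_filter == "without") !has_ms else has_ms
    counts$microsaccade_filtered <- sum(!sel)
    kept <- kept[sel]
    events_per_repeat <- events_per_repeat[sel]
    if (length(kept) < 8) return(excluded("too_few_repeats", counts))
  }
  # 2. artifact cascade
  flags <- flag_repeats_per_electrode(kept, config$rejection)
  interim <- apply_cascade(flags, montage,
                           stats::setNames(rep(NA_real_, nrow(flags)),
                                           rownames(flags)),
                           config$rejection, bad_input)
  surv_rep <- setdiff(seq_along(kept), interim$bad_repeats)
  if (length(surv_rep) == 0) return(excluded("no_clean_repeats", counts))
  time <- kept[[1]]$time
  fs <- kept[[1]]$fs
  bl_sel <- time_window(time, config$baseline[1], config$baseline[2])
  # baseline spectra of surviving repeats, for the slope rule
  mean_bl <- batch_psd_mean(lapply(kept[surv_rep], function(tr)
    tr$data[bl_sel, , drop = FALSE]), fs)
  freqs <- as_psd(NULL, sum(bl_sel), fs)$freqs
  # closed-form log-log power-law slope per electrode (vectorised; the
  # cascade only uses the sign of beta, see fit_psd_slope for the refined fit)
  sb <- config$rejection$slope_band
  fsel <- freqs >= sb[1] - 1e-9 & freqs <= sb[2] + 1e-9 & freqs > 0
  lf <- log(freqs[fsel])
  lfc <- lf - mean(lf)
  lp <- log(pmax(mean_bl[fsel, , drop = FALSE], 1e-300))
  slopes <- -as.numeric(crossprod(lfc, lp)) / sum(lfc^2)
  slopes[colSums(mean_bl[fsel, , drop = FALSE] <= 0) > 0] <- NA_real_
  names(slopes) <- colnames(kept[[1]]$data)
  report <- apply_cascade(flags, montage, slopes, config$rejection, bad_input)
  counts$bad_electrodes <- length(report$bad_electrodes)
  counts$bad_repeats <- length(report$bad_repeats)
  if (!report$block_ok) return(excluded("block_rule", counts))
  good_rep <- setdiff(seq_along(kept), report$bad_repeats)
  good_pairs <- setdiff(montage$analysis_set, report$bad_pairs)
  # 3. spectra on clean repeats / pairs, gamma conditions
  st_sel <- time_window(time, config$stimulus[1], config$stimulus[2])
  is_gamma <- vapply(kept, function(tr)
    tr$condition$tf == 0 && tr$condition$sf %in% config$sf_filter,
    logical(1))
  gamma_rep <- intersect(good_rep, which(is_gamma))
  if (length(gamma_rep) == 0) return(excluded("no_analyzable_repeats", counts))
  counts$n_analyzable <- length(gamma_rep)
  pair_segs <- function(reps, sel) lapply(kept[reps], function(tr)
    bipolar_signals(tr$data[sel, , drop = FALSE], montage, good_pairs))
  st_psd <- as_psd(batch_psd_mean(pair_segs(gamma_rep, st_sel), fs),
                   sum(st_sel), fs, length(gamma_rep), "stimulus")
  bl_psd <- as_psd(batch_psd_mean(pair_segs(gamma_rep, bl_sel), fs),
                   sum(bl_sel), fs, length(gamma_rep), "baseline")
  bands <- lapply(config$bands, function(b) delta_power(st_psd, bl_psd, b))
  names(bands) <- config$bands
  # 4. SSVEP on counterphase repeats
  is_cp <- vapply(kept, function(tr) tr$condition$tf == 16, logical(1))
  cp_rep <- intersect(good_rep, which(is_cp))
  ssvep <- NULL
  if (length(cp_rep) > 0) {
    st_cp <- as_psd(batch_psd_mean(pair_segs(cp_rep, st_sel), fs),
                    sum(st_sel), fs, length(cp_rep), "stimulus")
    bl_cp <- as_psd(batch_psd_mean(pair_segs(cp_rep, bl_sel), fs),
                    sum(bl_sel), fs, length(cp_rep), "baseline")
    ssvep <- ssvep_power(st_cp, bl_cp, 32)
  }
  # 5. ERP on pair-averaged clean epochs
  erp <- NULL
  if (config$compute_erp && length(gamma_rep) >= 10) {
    epochs <- t(vapply(kept[gamma_rep], function(tr)
      rowMeans(bipolar_signals(tr$data, montage, good_pairs)),
      numeric(length(time))))
    erp <- compute_erp(epochs, time, baseline = config$baseline)
  }
  # 6. eye metrics over analyzable repeats
  eye <- NULL
  if (config$compute_eye_metrics) {
    ev <- do.call(rbind, events_per_repeat[good_rep])
    win <- diff(config$eye$analysis_window)
    ms <- main_sequence(ev, duration = win * length(good_rep))
    eye <- list(microsaccade_rate = ms$rate,
                main_sequence_r = ms$correlation,
                n_events = nrow(ev),
                pupil_cv = pupil_cv_subject(lapply(kept[good_rep],
                                                   `[[`, "eye"), config$eye),
                fixation_rejected_frac = sum(fix_break) / n_total)
  }
  structure(list(
    id = profile$id, profile = profile, excluded = FALSE, reason = NA,
    counts = counts, bands = bands, ssvep = ssvep, erp = erp, eye = eye,
    st_spectrum = rowMeans(as.matrix(st_psd$power)),
    bl_spectrum = rowMeans(as.matrix(bl_psd$power)), freqs = freqs,
    good_pairs = good_pairs, rejection = report),
    class = "subject_summary")
}

#' Analyze every subject of a cohort
#' @param cohort a `cohort`
#' @param config `pipeline_config`
#' @param montage a `bipolar_montage`
#' @return list of `subject_summary`
#' @export
cohort_summaries <- function(cohort, config = default_config(),
                             montage = derive_bipolar(build_layout())) {
  lapply(cohort$subjects, function(s)
    run_subject(s$trials, config, montage, profile = s$profile))
}

#' Flatten subject summaries to a table
#' @param summaries list of `subject_summary`
#' @return data frame, one row per subject (excluded subjects carry NAs)
#' @export
summaries_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    base <- data.frame(id = s$id, group = as.character(s$profile$group),
                       age = s$profile$age,
                       gender = as.character(s$profile$gender),
                       cdr = s$profile$cdr, excluded = s$excluded,
                       reason = as.character(s$reason),
                       stringsAsFactors = FALSE)
    if (s$excluded) {
      return(cbind(base, n_analyzable = NA, alpha = NA, slow_gamma = NA,
                   fast_gamma = NA, ssvep_32 = NA, microsaccade_rate = NA,
                   pupil_cv = NA))
    }
    dp <- vapply(s$bands, `[[`, numeric(1), "delta_power")
    cbind(base,
          n_analyzable = s$counts$n_analyzable,
          alpha = unname(dp["alpha"]),
          slow_gamma = unname(dp["slow_gamma"]),
          fast_gamma = unname(dp["fast_gamma"]),
          ssvep_32 = if (is.null(s$ssvep)) NA else s$ssvep$delta_power,
          microsaccade_rate = if (is.null(s$eye)) NA
            else s$eye$microsaccade_rate,
          pupil_cv = if (is.null(s$eye)) NA else s$eye$pupil_cv)
  }))
}

# averaged-control spectra for one matched set -> per-band change in power
matched_control_delta <- function(summaries_by_id, control_ids, bands,
                                  template) {
  st <- 0; bl <- 0
  for (cid in control_ids) {
    s <- summaries_by_id[[cid]]
    st <- st + s$st_spectrum / length(control_ids)
    bl <- bl + s$bl_spectrum / length(control_ids)
  }
  stp <- template; stp$power <- st
  blp <- template; blp$power <- bl
  vapply(bands, function(b) delta_power(stp, blp, b)$delta_power,
         numeric(1))
}

#' Matched case-control comparison across bands
#'
#' For each case the age- and gender-matched healthy controls are selected
#' and their spectra averaged; the per-band change in power of the averaged
#' control spectra is paired with the case's. Per band: bootstrap medians
#' with SD, Kruskal-Wallis test on the two groups, and a one-tailed JZS
#' paired Bayes factor (right-tailed for gamma bands - control above case -
#' and left-tailed for alpha). The severity regression is fitted in the
#' matched condition (cases plus their averaged controls) and the unmatched
#' condition (every analyzable subject separately).
#'
#' @param summaries list of `subject_summary` (cases and controls)
#' @param config `pipeline_config`
#' @param case_groups which groups count as cases (default "mci";
#'   use `c("mci", "ad")` to pool)
#' @return list of class `comparison_report`: per-band statistics, matched
#'   sets, and regression results
#' @export
run_comparison <- function(summaries, config = default_config(),
                           case_groups = "mci") {
  ok <- !vapply(summaries, `[[`, logical(1), "excluded")
  summaries <- summaries[ok]
  if (length(summaries) == 0) stop("no analyzable subjects")
  grp <- vapply(summaries, function(s) as.character(s$profile$group),
                character(1))
  cases <- summaries[grp %in% case_groups]
  if (length(cases) == 0) stop("no analyzable cases")
  pool <- do.call(rbind, lapply(summaries[grp == "healthy"],
                                function(s) as.data.frame(s$profile)))
  by_id <- stats::setNames(summaries, vapply(summaries, `[[`, character(1),
                                             "id"))
  template <- list(freqs = cases[[1]]$freqs, power = NULL, fs = NA,
                   n_samples = NA, n_repeats = NA, window = NULL)
  class(template) <- "psd_estimate"
  bands <- config$bands
  # a case without any analyzable matched control is discarded, not matched
  # loosely
  matches <- lapply(cases, function(cs)
    tryCatch(match_controls(cs$profile, pool, limit_n = config$limit_n,
                            age_tol = config$age_tol),
             error = function(e) NULL))
  has_match <- !vapply(matches, is.null, logical(1))
  cases <- cases[has_match]
  matches <- matches[has_match]
  if (length(cases) == 0) stop("no case has an analyzable matched control")
  case_dp <- t(vapply(cases, function(cs)
    vapply(cs$bands, `[[`, numeric(1), "delta_power"), numeric(length(bands))))
  ctrl_dp <- t(vapply(matches, function(m)
    matched_control_delta(by_id, m$control_ids, bands, template),
    numeric(length(bands))))
  colnames(case_dp) <- colnames(ctrl_dp) <- bands
  band_stats <- lapply(bands, function(b) {
    x <- ctrl_dp[, b]; y <- case_dp[, b]
    tail <- if (b == "alpha") "left" else "right"
    list(band = b,
         case_median = stats::median(y), control_median = stats::median(x),
         case_boot = bootstrap_median(y, config$n_boot,
                                      seed = mix_seed(config$seed, b, 1)),
         control_boot = bootstrap_median(x, config$n_boot,
                                         seed = mix_seed(config$seed, b, 2)),
         kw = kruskal_wallis(list(control = x, case = y)),
         bf = if (length(x) >= 3) bayes_factor_paired_t(x, y, tail = tail)
              else NULL)
  })
  names(band_stats) <- bands
  # severity regressions
  reg <- lapply(bands, function(b) {
    mk <- function(dp, cdr, age, gender) fit_linear_model(dp, cdr, age, gender)
    case_prof <- do.call(rbind, lapply(cases, function(s)
      as.data.frame(s$profile)))
    ctrl_age <- vapply(matches, function(m)
      round(mean(pool$age[pool$id %in% m$control_ids])), numeric(1))
    matched <- tryCatch(mk(
      c(case_dp[, b], ctrl_dp[, b]),
      c(case_prof$cdr, rep(0, nrow(case_prof))),
      c(case_prof$age, ctrl_age),
      c(case_prof$gender, case_prof$gender)), error = function(e) NULL)
    all_prof <- do.call(rbind, lapply(summaries, function(s)
      as.data.frame(s$profile)))
    all_dp <- vapply(summaries, function(s) s$bands[[b]]$delta_power,
                     numeric(1))
    unmatched <- tryCatch(mk(all_dp, all_prof$cdr, all_prof$age,
                             all_prof$gender), error = function(e) NULL)
    list(matched = matched, unmatched = unmatched)
  })
  names(reg) <- bands
  structure(list(bands = band_stats, regression = reg,
                 case_values = case_dp, control_values = ctrl_dp,
                 matches = matches, case_groups = case_groups,
                 n_cases = nrow(case_dp)),
            class = "comparison_report")
}

#' Serialise a comparison report to JSON
#' @param report a `comparison_report`
#' @param path optional output file
#' @return JSON string (invisibly when written to file)
#' @export
comparison_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  out <- lapply(report$bands, function(b) list(
    H = b$kw$H, df = b$kw$df, p = b$kw$p,
    bf10 = if (is.null(b$bf)) NA else b$bf$bf10,
    bf_tail = if (is.null(b$bf)) NA else b$bf$tail,
    case_median = b$case_median, control_median = b$control_median,
    case_boot_sd = b$case_boot$sd_of_median,
    control_boot_sd = b$control_boot$sd_of_median))
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Seeded replicate study of the case-control effect pattern
#'
#' Repeats the full pipeline (generate cohort, screen, reject, re-reference,
#' spectra, match, Kruskal-Wallis per band) across `n_replicates` seeds and
#' reports per-band rejection rates at `alpha_level`. Only the subjects a
#' comparison needs (cases and their matched controls) are generated and
#' analyzed. The cohort mirrors the study's arithmetic: `n_mci` cases
#' against a pool of `n_controls` healthy subjects.
#'
#' @param n_replicates number of seeded replicates
#' @param base_seed integer; replicate r uses a seed derived from it
#' @param n_mci,n_controls cohort sizes
#' @param deficit gamma amplitude deficit factor for cases
#' @param repeats repeats per condition per subject
#' @param conditions condition set generated per subject
#' @param bands bands tested
#' @param alpha_level significance threshold for the rejection count
#' @param params_fn function(seed, deficit) -> `gen_params`, exposed so the
#'   study conditions stay in one place
#' @return list with `p` (matrix replicates x bands), `reject_rate` (named
#'   vector), `n_analyzed_cases` per replicate
#' @export
run_replicate_study <- function(n_replicates = 100, base_seed = 1,
                                n_mci = 12, n_controls = 74, deficit = 0.6,
                                repeats = 6,
                                conditions = data.frame(sf = c(2, 4),
                                                        ori = 90, tf = 0),
                                bands = c("alpha", "slow_gamma",
                                          "fast_gamma"),
                                alpha_level = 0.05,
                                params_fn = NULL) {
  if (is.null(params_fn)) {
    # the epoch is trimmed to the samples the analysis windows use
    # (-0.5 to 0.75 s plus the filter guard); all other generator defaults
    # are the study conditions
    params_fn <- function(seed, deficit)
      gen_params(seed = seed, epoch = c(-0.52, 0.8),
                 deficit_factor = c(healthy = 1, mci = deficit, ad = deficit))
  }
  montage <- derive_bipolar(build_layout())
  cfg <- default_config(compute_eye_metrics = FALSE, compute_erp = FALSE,
                        n_boot = 200)
  pmat <- matrix(NA_real_, n_replicates, length(bands),
                 dimnames = list(NULL, bands))
  n_cases_used <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    params <- params_fn(mix_seed(base_seed, "replicate", r), deficit)
    prof <- generate_profiles(n_controls, n_mci, 0, params)
    case_rows <- which(prof$group == "mci")
    # a case with no matched control is dropped from the comparison
    matches <- lapply(case_rows, function(i)
      tryCatch(match_controls(prof[i, ], prof), error = function(e) NULL))
    case_rows <- case_rows[!vapply(matches, is.null, logical(1))]
    matches <- matches[!vapply(matches, is.null, logical(1))]
    needed <- unique(c(prof$id[case_rows],
                       unlist(lapply(matches, `[[`, "control_ids"))))
    summaries <- lapply(needed, function(sid) {
      i <- match(sid, prof$id)
      trials <- generate_subject_trials(prof[i, ], params, conditions,
                                        repeats)
      run_subject(trials, cfg, montage, profile = prof[i, ])
    })
    cmp <- tryCatch(run_comparison(summaries, cfg, case_groups = "mci"),
                    error = function(e) NULL)
    if (is.null(cmp)) next
    n_cases_used[r] <- cmp$n_cases
    for (b in bands) pmat[r, b] <- cmp$bands[[b]]$kw$p
  }
  list(p = pmat,
       reject_rate = colMeans(pmat < alpha_level, na.rm = TRUE),
       n_analyzed_cases = n_cases_used)
}
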