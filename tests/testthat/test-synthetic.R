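test_that("the same hierarchical seed regenerates identical trials", {
  prof <- healthy_profile()
  params <- gen_params(seed = 4)
  a <- generate_trial(prof, list(sf = 2, ori = 45, tf = 0), params, 3)
  b <- generate_trial(prof, list(sf = 2, ori = 45, tf = 0), params, 3)
  expect_identical(a$data, b$data)
  expect_identical(a$eye, b$eye)
  d <- generate_trial(prof, list(sf = 2, ori = 45, tf = 0), params, 4)
  expect_false(identical(a$data, d$data))
  expect_error(generate_trial(prof, list(sf = 3, ori = 45, tf = 0), params),
               "condition")
})

test_that("trials have 64 channels covering the analysis window", {
  tr <- generate_trial(healthy_profile(), list(sf = 4, ori = 0, tf = 0),
                       gen_params(seed = 2))
  expect_equal(ncol(tr$data), 64)
  expect_identical(colnames(tr$data), test_layout$electrode)
  expect_lte(min(tr$time), -0.5)
  expect_gte(max(tr$time), 0.75)
})

test_that("null generator (no gamma, no suppression) gives ~0 dB change", {
  params <- gen_params(seed = 12, gamma_amp = c(slow = 0, fast = 0),
                       alpha_suppression = 1, erp_amp = 0,
                       artifact_rate = 0)
  sp <- averaged_pair_spectra(healthy_profile(), params, 100)
  for (b in c("alpha", "slow_gamma", "fast_gamma")) {
    expect_lt(abs(delta_power(sp$st, sp$bl, b)$delta_power), 0.3)
  }
})

test_that("a forced 4x band power ratio is recovered as ~6.02 dB", {
  # amplitude chosen analytically so injected slow-gamma power equals 3x the
  # 1/f background power inside the 20-34 Hz band sum
  A <- 200; beta <- 1.8
  fgrid <- (0:125) * 2
  band <- fgrid >= 20 & fgrid <= 34
  bg_band <- sum(A * fgrid[band]^-beta)
  ffine <- seq(0.1, 250, by = 0.1)
  mask <- 1 / (1 + ((ffine^2 - 20 * 34) / (ffine * (34 - 20)))^8)
  kap <- sum(mask[ffine >= 20 & ffine <= 34]) / sum(mask)
  amp <- sqrt(3 * 2 * bg_band / kap)
  params <- gen_params(seed = 3, background_A = A, background_beta = beta,
                       gamma_amp = c(slow = amp, fast = 0), alpha_amp = 0,
                       alpha_suppression = 1, erp_amp = 0, topo_base = 1,
                       subject_sd = 0, band_sd = 0, artifact_rate = 0)
  prof <- healthy_profile()
  st <- 0; bl <- 0
  for (i in 1:100) {
    tr <- generate_trial(prof, list(sf = 2, ori = 90, tf = 0), params, i)
    bsel <- tr$time >= -0.5 & tr$time < 0
    ssel <- tr$time >= 0.25 & tr$time < 0.75
    bl <- bl + rowMeans(multitaper_psd(tr$data[bsel, ], 500)$power) / 100
    st <- st + rowMeans(multitaper_psd(tr$data[ssel, ], 500)$power) / 100
  }
  dp <- delta_power(mk_psd(st), mk_psd(bl), "slow_gamma")$delta_power
  expect_equal(dp, 10 * log10(4), tolerance = 0.3 / (10 * log10(4)))
})

test_that("baseline background follows the parameterised power law", {
  params <- gen_params(seed = 11)
  prof <- healthy_profile()
  acc <- 0
  for (i in 1:100) {
    tr <- generate_trial(prof, list(sf = 2, ori = 90, tf = 0), params, i)
    bsel <- tr$time >= -0.5 & tr$time < 0
    acc <- acc + rowMeans(multitaper_psd(tr$data[bsel, ], 500)$power) / 100
  }
  expect_lt(abs(fit_psd_slope(mk_psd(acc))$beta - params$background_beta),
            0.15)
})

test_that("case deficit lowers gamma but not alpha change", {
  params <- gen_params(seed = 14, subject_sd = 0, band_sd = 0,
                       artifact_rate = 0)
  ctrl <- averaged_pair_spectra(healthy_profile(), params, 25)
  case <- averaged_pair_spectra(mci_profile(), params, 25)
  for (b in c("slow_gamma", "fast_gamma")) {
    expect_lt(delta_power(case$st, case$bl, b)$delta_power,
              delta_power(ctrl$st, ctrl$bl, b)$delta_power - 1)
  }
  expect_lt(abs(delta_power(case$st, case$bl, "alpha")$delta_power -
                  delta_power(ctrl$st, ctrl$bl, "alpha")$delta_power), 0.5)
  # alpha is suppressed in both groups
  expect_lt(delta_power(ctrl$st, ctrl$bl, "alpha")$delta_power, -0.5)
})

test_that("counterphase trials carry a 32 Hz peak above +/- 4 Hz neighbors", {
  params <- gen_params(seed = 15, artifact_rate = 0)
  sp <- averaged_pair_spectra(healthy_profile(), params, 40,
                              condition = list(sf = 2, ori = 90, tf = 16))
  d32 <- ssvep_power(sp$st, sp$bl, 32)$delta_power
  expect_gt(d32, ssvep_power(sp$st, sp$bl, 28)$delta_power)
  expect_gt(d32, ssvep_power(sp$st, sp$bl, 36)$delta_power)
  # no such peak in static trials
  sp0 <- averaged_pair_spectra(healthy_profile(), params, 40,
                               condition = list(sf = 2, ori = 90, tf = 0))
  expect_lt(abs(ssvep_power(sp0$st, sp0$bl, 32)$delta_power - d32), d32)
})

test_that("eye traces hold fixation with bounded jitter and a lawful main sequence", {
  params <- gen_params(seed = 16, blink_rate = 0, excursion_prob = 0)
  prof <- healthy_profile()
  sds <- c(); ev <- NULL
  for (i in 1:80) {
    e <- generate_trial(prof, list(sf = 2, ori = 90, tf = 0), params, i)$eye
    win <- e$t_s >= -0.5 & e$t_s <= 0.75
    sds <- c(sds, sd(e$x_deg[win]), sd(e$y_deg[win]))
    ev <- rbind(ev, detect_microsaccades(e))
  }
  expect_lt(mean(sds), 0.5)
  ms <- main_sequence(ev, 80 * 1.25)
  expect_gt(ms$correlation, 0.8)
  expect_gt(ms$rate, 0.2)
})

test_that("artifact injection respects rate and trips the slope rule", {
  params <- gen_params(seed = 17)
  prof <- healthy_profile()
  tr <- generate_trial(prof, list(sf = 2, ori = 90, tf = 0), params)
  expect_identical(inject_artifacts(tr, params, rate = 0), tr)
  # rising-spectrum replacement: fitted slope goes negative
  acc_r <- 0; acc_f <- 0
  for (i in 1:20) {
    tri <- generate_trial(prof, list(sf = 2, ori = 90, tf = 0), params, i)
    rise <- inject_artifacts(tri, params, rate = 1, type = "rising",
                             electrodes = "Oz", seed = 100 + i)
    flat <- inject_artifacts(tri, params, rate = 1, type = "flat",
                             electrodes = "Oz", seed = 200 + i)
    bsel <- tri$time >= -0.5 & tri$time < 0
    acc_r <- acc_r + multitaper_psd(rise$data[bsel, "Oz"], 500)$power / 20
    acc_f <- acc_f + multitaper_psd(flat$data[bsel, "Oz"], 500)$power / 20
  }
  expect_lt(fit_psd_slope(mk_psd(acc_r))$beta, 0)
  # flat replacement: slope near zero (the 20-repeat estimate carries an SE
  # of ~0.5), far from the background's 1.8
  expect_lt(abs(fit_psd_slope(mk_psd(acc_f))$beta), 1)
  # transient artifacts are recorded as ground truth
  tra <- inject_artifacts(tr, params, rate = 1, type = "transient", seed = 5)
  expect_gt(length(tra$artifacts), 0)
  expect_gt(max(abs(tra$data - tr$data)), 300)
})

test_that("cohort generation books matched controls and repeat counts", {
  params <- gen_params(seed = 18, epoch = c(-0.52, 0.8))
  coh <- generate_cohort(4, 1, 1, repeats_per_condition = 2,
                         params = params,
                         conditions = data.frame(sf = 2, ori = 90, tf = 0))
  expect_length(coh$subjects, 6)
  expect_equal(sum(vapply(coh$subjects, function(s) length(s$trials),
                          integer(1))), 6 * 2)
  prof <- coh$profiles
  for (i in which(prof$group != "healthy")) {
    ok <- prof$group == "healthy" & abs(prof$age - prof$age[i]) <= 1 &
      prof$gender == prof$gender[i]
    expect_gte(sum(ok), 1)
  }
  expect_error(generate_profiles(0, 1, 0, params), "impossible")
  # any subset regenerates identically from the same seed
  s2 <- generate_subject_trials(prof[2, ], params,
                                data.frame(sf = 2, ori = 90, tf = 0), 2)
  expect_identical(s2[[1]]$data, coh$subjects[[2]]$trials[[1]]$data)
})

test_that("a 12-case cohort leaves every case at least one matched control", {
  params <- gen_params(seed = 19)
  prof <- generate_profiles(74, 12, 0, params)
  expect_equal(nrow(prof), 86)
  expect_true(all(prof$age >= 50 & prof$age <= 92))
  for (i in which(prof$group == "mci")) {
    m <- match_controls(prof[i, ], prof)
    expect_gte(length(m$control_ids), 1)
  }
})
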