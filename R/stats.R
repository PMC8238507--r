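# Matched case-control construction and inferential machinery

#' Select age- and gender-matched controls for a case
#'
#' Qualifying controls are healthy subjects whose age is within
#' `age_tol` years of the case and whose gender matches. All qualifying
#' controls are returned unless `limit_n` restricts to the first N under
#' `ordering_key` (ascending). A case with zero qualifying controls is an
#' error - such cases are discarded from the study, not matched loosely.
#'
#' @param case profile row/list (`id`, `age`, `gender`)
#' @param pool data frame of candidate profiles; rows with a `group` column
#'   are filtered to `"healthy"`
#' @param limit_n optional cap on the number of controls
#' @param ordering_key optional numeric vector (one per pool row) ordering
#'   candidates for `limit_n`; default is absolute age difference with id as
#'   tie-break
#' @param age_tol matching tolerance in years (default 1)
#' @return list of class `matched_set`: `case_id`, `control_ids`,
#'   `matched_on`
#' @export
match_controls <- function(case, pool, limit_n = NULL, ordering_key = NULL,
                           age_tol = 1) {
  stopifnot(nrow(pool) > 0)
  if (!is.null(pool$group)) pool <- pool[pool$group == "healthy", ,
                                         drop = FALSE]
  pool <- pool[pool$id != case$id, , drop = FALSE]
  ok <- abs(pool$age - case$age) <= age_tol & pool$gender == case$gender
  if (!is.null(ordering_key)) ok_key <- ordering_key[ok]
  sel <- pool[ok, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no age- and gender-matched control for case ", case$id)
  }
  if (is.null(ordering_key)) {
    ord <- order(abs(sel$age - case$age), sel$id)
  } else {
    ord <- order(ok_key)
  }
  sel <- sel[ord, , drop = FALSE]
  if (!is.null(limit_n)) sel <- utils::head(sel, limit_n)
  structure(list(case_id = case$id, control_ids = sel$id,
                 matched_on = sprintf("age +/- %g year, gender", age_tol)),
            class = "matched_set")
}

#' Bootstrap median and its standard deviation
#'
#' Resamples with replacement `n_iter` times, taking the median of each
#' resample; reports the data median and the SD of the bootstrap medians.
#'
#' @param values numeric vector (length >= 2)
#' @param n_iter bootstrap iterations (default 10000)
#' @param seed optional seed for deterministic resampling
#' @return list of class `bootstrap_result`: `median`, `sd_of_median`,
#'   `n_iter`, `seed`
#' @export
bootstrap_median <- function(values, n_iter = 10000, seed = NULL) {
  stopifnot(length(values) >= 2, n_iter >= 2)
  run <- function() {
    m <- matrix(sample(values, length(values) * n_iter, replace = TRUE),
                nrow = length(values))
    meds <- apply(m, 2, stats::median)
    structure(list(median = stats::median(values),
                   sd_of_median = stats::sd(meds),
                   n_iter = as.integer(n_iter), seed = seed),
              class = "bootstrap_result")
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Kruskal-Wallis test on group medians
#'
#' Tie-corrected rank-based H with p from the chi-squared approximation on
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]). Fully
#' degenerate input (all values identical) yields H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 nonempty groups)
#' @return list of class `kw_result`: `H`, `df`, `p`, `tie_corrected`
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) > 0))
  all_v <- unlist(groups)
  df <- length(groups) - 1L
  if (length(unique(all_v)) == 1) {
    return(structure(list(H = 0, df = df, p = 1, tie_corrected = TRUE),
                     class = "kw_result"))
  }
  kt <- stats::kruskal.test(groups)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, tie_corrected = TRUE),
            class = "kw_result")
}

# JZS marginal likelihood ratio for a one-sample t on the differences:
# integrates the noncentral-t likelihood over a Cauchy(0, r) effect-size
# prior (truncated and renormalised for one-tailed variants)
jzs_bf <- function(t, n, r, tail) {
  nu <- n - 1
  f <- function(delta) {
    stats::dcauchy(delta, 0, r) * stats::dt(t, nu, ncp = delta * sqrt(n))
  }
  null_lik <- stats::dt(t, nu)
  quad <- function(lo, hi) {
    # dt(ncp =) warns about final-digit precision far in the tails; harmless
    # at the 1e-9 integration tolerance used here
    suppressWarnings(stats::integrate(f, lo, hi, rel.tol = 1e-9,
                                      abs.tol = 0,
                                      stop.on.error = FALSE)$value)
  }
  alt <- switch(tail,
    two = quad(-Inf, 0) + quad(0, Inf),
    right = 2 * quad(0, Inf),
    left = 2 * quad(-Inf, 0))
  alt / null_lik
}

#' Paired-samples Bayes factor (JZS, Cauchy prior)
#'
#' Bayes factor BF10 for a paired t-test on `x - y` with a Cauchy effect-size
#' prior of scale `prior_scale` (default 1). One-tailed variants truncate
#' the prior to the corresponding half-line and renormalise ("right" puts the
#' alternative mass on mean(x) > mean(y)). Interpretive bands: < 1 favors the
#' null; 1-3 anecdotal, 3-10 substantial, > 10 strong evidence for the
#' alternative.
#'
#' @param x,y paired numeric vectors (length >= 3)
#' @param tail "two", "right" or "left"
#' @param prior_scale Cauchy scale of the effect-size prior
#' @return list of class `bf_result`: `bf10`, `tail`, `prior_scale`, `n`,
#'   `t` (the paired t statistic), `evidence` (interpretive label)
#' @export
bayes_factor_paired_t <- function(x, y = NULL,
                                  tail = c("two", "right", "left"),
                                  prior_scale = 1) {
  tail <- match.arg(tail)
  d <- if (is.null(y)) x else x - y
  n <- length(d)
  stopifnot(n >= 3, is.null(y) || length(y) == n)
  s <- stats::sd(d)
  if (s == 0) stop("zero-variance differences; t statistic undefined")
  t <- mean(d) / (s / sqrt(n))
  bf <- jzs_bf(t, n, prior_scale, tail)
  evidence <- if (bf < 1) "null" else if (bf < 3) "anecdotal"
    else if (bf <= 10) "substantial" else "strong"
  structure(list(bf10 = bf, tail = tail, prior_scale = prior_scale,
                 n = n, t = t, evidence = evidence),
            class = "bf_result")
}

#' Linear model of band power change on disease severity, age and gender
#'
#' Ordinary least squares for
#' `delta_power = b0 + b_cdr * CDR + b_age * AGE + b_gender * GENDER + e`
#' with gender coded 0 = male, 1 = female and age in integer years. Reports
#' per-coefficient t statistics and two-sided p values.
#'
#' @param delta_power response, dB (one value per subject)
#' @param cdr Clinical Dementia Rating scores
#' @param age ages in years
#' @param gender "male"/"female" (or 0/1)
#' @return list of class `regression_result`: `coefficients` (data frame:
#'   term, estimate, t, p), `sigma2`, `n`
#' @export
fit_linear_model <- function(delta_power, cdr, age, gender) {
  n <- length(delta_power)
  stopifnot(n > 4, length(cdr) == n, length(age) == n, length(gender) == n)
  g <- if (is.numeric(gender)) gender else as.numeric(gender == "female")
  fit <- stats::lm(delta_power ~ cdr + age + g)
  if (anyNA(stats::coef(fit))) stop("rank-deficient design matrix")
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    coefficients = data.frame(
      term = c("intercept", "cdr", "age", "gender"),
      estimate = unname(co[, 1]), t = unname(co[, 3]), p = unname(co[, 4])),
    sigma2 = sm$sigma^2, n = n),
    class = "regression_result")
}

#' Optional multiplicity adjustment for a vector of p values
#'
#' The primary analyses are reported uncorrected (each band is a separate
#' planned comparison); this helper exposes standard corrections for users
#' who want them.
#'
#' @param p numeric vector of p values
#' @param method passed to [stats::p.adjust()] ("bonferroni", "BH", ...)
#' @return adjusted p values
#' @export
adjust_p <- function(p, method = "bonferroni") {
  stats::p.adjust(p, method = method)
}
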