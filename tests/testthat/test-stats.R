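test_that("control matching enforces the age and gender rule", {
  pool <- data.frame(id = c("a", "b", "c", "d"),
                     age = c(69, 71, 72, 70),
                     gender = c("male", "male", "male", "female"),
                     group = "healthy", stringsAsFactors = FALSE)
  case <- list(id = "case1", age = 70, gender = "male")
  m <- match_controls(case, pool)
  expect_setequal(m$control_ids, c("a", "b"))
  m1 <- match_controls(case, pool, limit_n = 1)
  expect_length(m1$control_ids, 1)
  # custom ordering key (e.g. experiment-date distance)
  mk <- match_controls(case, pool, limit_n = 1,
                       ordering_key = c(5, 1, 9, 9))
  expect_equal(mk$control_ids, "b")
  lone <- list(id = "case2", age = 92, gender = "female")
  expect_error(match_controls(lone, pool), "matched control")
})

test_that("bootstrap medians are deterministic with matching asymptotics", {
  expect_equal(bootstrap_median(rep(3, 10), 500, seed = 1)$sd_of_median, 0)
  b1 <- bootstrap_median(c(1, 5, 2, 8, 3), 2000, seed = 7)
  b2 <- bootstrap_median(c(1, 5, 2, 8, 3), 2000, seed = 7)
  expect_identical(b1, b2)
  withr::with_seed(81, x <- rnorm(100))
  b <- bootstrap_median(x, 10000, seed = 2)
  # asymptotic SE of the median of n standard normals: 1.2533 / sqrt(n)
  expect_equal(b$sd_of_median, 1.2533 / sqrt(100), tolerance = 0.15)
  # convergence: 5000 vs 10000 iterations changes the SD estimate little
  b5 <- bootstrap_median(x, 5000, seed = 3)
  expect_lt(abs(b5$sd_of_median - b$sd_of_median) / b$sd_of_median, 0.03)
  expect_error(bootstrap_median(numeric(0)), "2")
})

test_that("Kruskal-Wallis matches the hand-computed H and degenerate cases", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # H = 12/(N(N+1)) * sum(R^2/n) - 3(N+1) = 3.857
  expect_equal(kw$H, 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7,
               tolerance = 1e-9)
  expect_equal(kw$df, 1)
  expect_equal(kw$p, pchisq(kw$H, 1, lower.tail = FALSE))
  same <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
})

test_that("two-group Kruskal-Wallis equals the squared rank-sum z statistic", {
  withr::with_seed(82, {
    for (k in 1:10) {
      n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
      x <- sample(seq_len(200), n1)        # tie-free
      y <- sample(setdiff(seq_len(400), x), n2)
      kw <- kruskal_wallis(list(x, y))
      # normal approximation of the rank-sum statistic, by hand
      r <- rank(c(x, y))
      w <- sum(r[seq_len(n1)])
      z <- (w - n1 * (n1 + n2 + 1) / 2) /
        sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
      expect_equal(kw$H, z^2, tolerance = 1e-9)
    }
  })
})

test_that("Kruskal-Wallis p values are uniform under the null", {
  # groups of 30 keep the rank-statistic support fine enough for a KS check
  withr::with_seed(83, {
    p <- replicate(2000, kruskal_wallis(list(rnorm(30), rnorm(30)))$p)
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("JZS Bayes factor agrees with the dense-quadrature oracle", {
  # oracle: Zellner-Siow g-prior integral (independent formulation)
  bf_g <- function(t, n, r = 1) {
    nu <- n - 1
    null_l <- (1 + t^2 / nu)^(-(nu + 1) / 2)
    f <- function(g) (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      sqrt(r^2 / 2) / gamma(1 / 2) * g^(-3 / 2) * exp(-r^2 / (2 * g))
    integrate(f, 0, Inf, rel.tol = 1e-10)$value / null_l
  }
  for (n in c(5, 12, 30)) {
    for (t in seq(-5, 5, by = 1)) {
      expect_equal(gammacc:::jzs_bf(t, n, 1, "two"), bf_g(t, n),
                   tolerance = 1e-4)
    }
  }
})

test_that("one-tailed Bayes factors obey the prior-mixture identity", {
  withr::with_seed(84, {
    for (k in 1:5) {
      d <- rnorm(12, mean = runif(1, -1, 1))
      two <- bayes_factor_paired_t(d, tail = "two")$bf10
      right <- bayes_factor_paired_t(d, tail = "right")$bf10
      left <- bayes_factor_paired_t(d, tail = "left")$bf10
      expect_equal(right + left, 2 * two, tolerance = 1e-6)
    }
  })
})

test_that("Bayes factors point the right way for null and large effects", {
  withr::with_seed(85, d0 <- rnorm(20))
  d0 <- d0 - mean(d0) + 1e-9
  expect_lt(bayes_factor_paired_t(d0, tail = "two")$bf10, 1)
  withr::with_seed(86, d1 <- rnorm(12, 1, 0.1))
  bf1 <- bayes_factor_paired_t(d1, tail = "two")
  expect_gt(bf1$bf10, 10)
  expect_equal(bf1$evidence, "strong")
  expect_error(bayes_factor_paired_t(rep(1, 5), rep(0.5, 5)), "zero-variance")
})

test_that("severity regression recovers exact and simulated coefficients", {
  cdr <- c(0, 0, 0.5, 1, 0, 0.5, 1, 3, 0, 0.5)
  age <- c(62, 70, 75, 80, 66, 71, 68, 84, 77, 73)
  gender <- c("male", "female", "male", "female", "male", "male", "female",
              "female", "male", "female")
  y <- 2 - 0.5 * cdr + 0.01 * age + 0.3 * (gender == "female")
  # the exact interpolation triggers lm's perfect-fit note; that is the point
  fit <- suppressWarnings(fit_linear_model(y, cdr, age, gender))
  expect_equal(fit$coefficients$estimate,
               c(2, -0.5, 0.01, 0.3), tolerance = 1e-10)
  # OLS is unbiased for the severity slope
  withr::with_seed(87, {
    est <- replicate(500, {
      cdr_s <- sample(c(rep(0, 17), rep(0.5, 12), rep(1, 4), 3))
      age_s <- sample(55:85, 34, replace = TRUE)
      g_s <- sample(0:1, 34, replace = TRUE)
      y_s <- 1 - 0.5 * cdr_s + 0.005 * age_s + 0.2 * g_s + rnorm(34, 0, 0.3)
      fit_linear_model(y_s, cdr_s, age_s, g_s)$coefficients$estimate[2]
    })
  })
  expect_equal(mean(est), -0.5, tolerance = 0.05 / 0.5)
  expect_error(fit_linear_model(y, rep(1, 10), age, gender), "rank")
})

test_that("the gender coefficient is well calibrated under the null", {
  withr::with_seed(88, {
    p <- replicate(400, {
      n <- 30
      cdr_s <- sample(c(0, 0.5, 1), n, replace = TRUE)
      age_s <- sample(55:85, n, replace = TRUE)
      g_s <- sample(0:1, n, replace = TRUE)
      y_s <- 1 - 0.4 * cdr_s + rnorm(n, 0, 0.5)
      fit_linear_model(y_s, cdr_s, age_s, g_s)$coefficients$p[4]
    })
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})
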