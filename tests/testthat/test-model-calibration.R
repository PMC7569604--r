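test_that("the Janisch fit to egg medians reproduces the published parameters", {
  fit <- fit_lntime_model(egg_median_dev$temp, egg_median_dev$median)
  p <- fit$parameters
  expect_within(p[["D_min"]], 4.98, 0.05)
  expect_within(p[["T_opt"]], 27.4, 0.2)
  expect_within(p[["k"]], 0.15, 0.005)
  expect_within(fit$adj_r_squared, 0.988, 0.004)
  expect_within(fit$f_value, 249.3, 10)
  expect_equal(fit$df, c(2, 4))
})

test_that("the puparium fit matches the published adjusted R-squared", {
  fit <- fit_lntime_model(pupa_median_dev$temp, pupa_median_dev$median)
  expect_within(fit$adj_r_squared, 0.915, 0.02)
  expect_within(fit$parameters[["T_opt"]], 23, 0.6)
})

test_that("noise-free Janisch data are recovered essentially exactly", {
  truth <- list(D_min = 6.5, T_opt = 24, k = 0.18)
  temps <- c(10, 14, 18, 22, 26, 30, 34)
  med <- 1 / janisch_rate(truth, temps)
  fit <- fit_lntime_model(temps, med)
  for (nm in names(truth)) {
    expect_within(fit$parameters[[nm]], truth[[nm]], abs(truth[[nm]]) * 1e-3)
  }
  expect_lt(fit$rss, 1e-10)
})

test_that("refitting packaged curves to their own predictions is a fixed point", {
  b <- default_bundle()
  for (st in c("egg", "nymph", "puparium")) {
    truth <- b$development[[st]]
    med <- 1 / janisch_rate(truth, egg_median_dev$temp)
    fit <- fit_lntime_model(egg_median_dev$temp, med)
    expect_within(fit$parameters[["D_min"]], truth$D_min, truth$D_min * 1e-3)
    expect_within(fit$parameters[["T_opt"]], truth$T_opt, 0.05)
  }
})

test_that("the joint mortality fit shares one optimum near 21.8 degC", {
  d <- immature_mortality_table
  names(d) <- c("stage", "temp", "mortality")
  fit <- fit_mortality_model(d, share_Topt = TRUE)
  expect_equal(fit$k, 7)
  expect_within(fit$parameters[["T_opt"]], 21.8, 0.5)
  expect_gt(fit$r_squared, 0.9)

  full <- fit_mortality_model(d, share_Topt = FALSE)
  expect_equal(full$k, 9)
  expect_lte(full$rss, fit$rss + 1e-10)
  ft <- f_ratio_test(fit, full)
  expect_equal(ft$df, c(2, 10))
  expect_gte(ft$f, 0)
  # extra optima barely help here: AICc must punish them on n = 19
  expect_gt(aicc(rss = full$rss, n = full$n, k = full$k),
            aicc(rss = fit$rss, n = fit$n, k = fit$k))
})

test_that("mortality parameters are recovered from binomially noisy data", {
  set.seed(5)
  truth <- list(egg = list(H = 4e-4, B = 1.5), nymph = list(H = 1e-3, B = 1.8),
                puparium = list(H = 0.02, B = 2.4))
  Topt <- 22.5
  temps <- c(10, 14, 18, 22, 26, 30, 34)
  rows <- NULL
  for (st in names(truth)) {
    p <- c(truth[[st]], T_opt = Topt)
    m <- immature_mortality(p, temps)
    obs <- rbinom(length(temps), 100, m) / 100
    rows <- rbind(rows, data.frame(stage = st, temp = temps, mortality = obs))
  }
  fit <- fit_mortality_model(rows, share_Topt = TRUE)
  expect_within(fit$parameters[["T_opt"]], Topt, 1)
})

test_that("the fecundity fit explains over 99.9 % of the printed means", {
  fit <- fit_fecundity_model(mean_fecundity_table$temp, mean_fecundity_table$fecundity)
  expect_gte(fit$r_squared, 0.999)
  curve_max <- optimize(function(T) {
    -mean_fecundity(as.list(fit$parameters), T)
  }, c(5, 35))$minimum
  expect_within(curve_max, 20, 1.5)
  # noise-free synthetic data from the family: exact recovery
  truth <- list(H = 8, Tl = 14, Bl = 2, Bh = 12)
  temps <- c(12, 15, 18, 21, 24, 27, 30)
  f <- mean_fecundity(truth, temps)
  rec <- fit_fecundity_model(temps, f)
  expect_lt(rec$rss, 1e-8)
  for (nm in names(truth)) {
    expect_within(rec$parameters[[nm]], truth[[nm]], abs(truth[[nm]]) * 0.02)
  }
})

test_that("AICc applies the exact small-sample correction and ranks models sanely", {
  expect_equal(aicc(rss = 1, n = 7, k = 3) - (7 * log(1 / 7) + 2 * 3), 8)
  # correction vanishes as n grows
  expect_lt(aicc(loglik = -50, n = 1e6, k = 3) - (2 * 50 + 6), 1e-4)
  expect_error(aicc(rss = 1, n = 4, k = 3))
  expect_error(aicc(rss = 1, loglik = -2, n = 10, k = 2))

  # the generating family wins the AICc comparison in most replicates
  set.seed(8)
  temps <- c(10, 14, 18, 22, 26, 28)
  truth <- list(D_min = 8, T_opt = 26, k = 0.15)
  wins <- 0
  reps <- 50
  for (r in seq_len(reps)) {
    lnmed <- log(1 / janisch_rate(truth, temps)) + rnorm(length(temps), 0, 0.05)
    jan <- fit_lntime_model(temps, exp(lnmed), model = "janisch")
    lin <- fit_lntime_model(temps, exp(lnmed), model = "linear")
    wins <- wins + (aicc(rss = jan$rss, n = jan$n, k = jan$k) <
                      aicc(rss = lin$rss, n = lin$n, k = lin$k))
  }
  expect_gte(wins / reps, 0.8)
})
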