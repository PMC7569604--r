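bundle <- default_bundle()

test_that("Janisch rate peaks at 1/D_min at the optimum and matches hand evaluations", {
  egg <- bundle$development$egg
  expect_equal(janisch_rate(egg, 27.4), 1 / 4.98, tolerance = 1e-12)
  # direct evaluations of the closed form away from the optimum
  expect_equal(janisch_rate(egg, 15), 0.0610366, tolerance = 1e-4)
  expect_equal(1 / janisch_rate(egg, 15), 16.4, tolerance = 0.01) # inside the observed CI 14.9-19.7
  pup <- bundle$development$puparium
  expect_equal(janisch_rate(pup, 32), 0.0657873, tolerance = 1e-4)

  # bounded by 1/D_min with equality only at T_opt
  grid <- seq(0, 40, by = 0.05)
  r <- janisch_rate(egg, grid)
  expect_true(all(r <= 1 / egg$D_min + 1e-12))
  expect_true(all(r[abs(grid - egg$T_opt) > 0.1] < 1 / egg$D_min))
  expect_error(janisch_rate(egg, NaN))
})

test_that("immature mortality is symmetric about its minimum and stays in [0, 1]", {
  pup <- bundle$mortality$puparium
  expect_equal(immature_mortality(pup, 21.8), 1 - exp(-4 * 0.018), tolerance = 1e-12)
  egg <- bundle$mortality$egg
  expect_equal(immature_mortality(egg, 10), 0.842, tolerance = 1e-3) # observed 0.87
  expect_equal(immature_mortality(egg, 32), 0.271, tolerance = 1e-2) # observed 0.24

  for (st in names(bundle$mortality)) {
    p <- bundle$mortality[[st]]
    d <- seq(0.5, 15, by = 0.5)
    expect_equal(immature_mortality(p, p$T_opt + d), immature_mortality(p, p$T_opt - d))
    m <- immature_mortality(p, seq(-5, 45, by = 0.1))
    expect_true(all(m >= 0 & m <= 1))
    # numerical derivative vanishes at the optimum
    h <- 1e-5
    expect_lt(abs(immature_mortality(p, p$T_opt + h) -
                    immature_mortality(p, p$T_opt - h)) / (2 * h), 1e-6)
    # monotone increase away from the optimum
    up <- immature_mortality(p, seq(p$T_opt, 45, by = 0.25))
    expect_true(all(diff(up) >= -1e-12))
  }
})

test_that("adult median times decline exponentially with a constant sex ratio", {
  at <- bundle$adult_timing
  expect_equal(adult_median_time(at, 15, "oviposition"), 8.01, tolerance = 1e-3)
  expect_equal(adult_median_time(at, 15, "male_survival"), 8.01 * exp(-0.3615),
               tolerance = 1e-3)
  grid <- seq(5, 35, by = 1)
  ovi <- adult_median_time(at, grid, "oviposition")
  expect_true(all(diff(ovi) < 0))
  # the additive factors act multiplicatively on time, at every temperature
  ratio <- adult_median_time(at, grid, "male_survival") /
    adult_median_time(at, grid, "female_survival")
  expect_equal(ratio, rep(exp(at$factor_male - at$factor_female), length(grid)))
  # female survival and oviposition medians differ only by e^factor_female
  expect_equal(adult_median_time(at, grid, "female_survival") / ovi,
               rep(exp(at$factor_female), length(grid)))
})

test_that("the packaged fecundity curve peaks near 20 degC at about 40 eggs", {
  fec <- bundle$fecundity
  expect_equal(mean_fecundity(fec, 20), 40.1, tolerance = 0.02)
  opt <- optimize(function(T) -mean_fecundity(fec, T), c(5, 35))$minimum
  expect_within(opt, 20, 1.5)
  expect_lt(mean_fecundity(fec, 10), 2)   # reproduction collapses at low temperature
  expect_lt(mean_fecundity(fec, 10) / mean_fecundity(fec, opt), 0.05)
  grid <- seq(0, 40, by = 0.2)
  f <- mean_fecundity(fec, grid)
  expect_true(all(f >= 0))
  expect_equal(sum(diff(sign(diff(f))) != 0), 1) # unimodal
})

test_that("degree-day regression recovers exact lines and the egg threshold", {
  fit <- degree_day_fit(c(10, 15, 20), c(0.03, 0.08, 0.13))
  expect_equal(fit$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit$T0, 7, tolerance = 1e-9)
  expect_equal(fit$K, 100, tolerance = 1e-9)
  expect_equal(fit$K, 1 / fit$slope)

  # egg medians: points at >= 28 degC excluded before regression
  eg <- degree_day_fit(egg_median_dev$temp, 1 / egg_median_dev$median,
                       high_T_cutoff = 28, stage = "egg")
  expect_equal(eg$n, 5)
  expect_within(eg$T0, 8.4, 0.5) # re-computation from rounded printed medians
  expect_equal(eg$K, 1 / eg$slope)

  expect_error(degree_day_fit(c(10, 15), c(0.1, 0.2)), "3 points")
  expect_error(degree_day_fit(c(10, 15, 20), c(0.3, 0.2, 0.1)), "slope")
})

test_that("adjustment factors rescale only mortality spread, adult times and fecundity", {
  ident <- apply_adjustment(bundle, c(mortality_B = 1, adult_time = 1, fecundity = 1))
  grid <- seq(5, 35, by = 2.5)
  for (st in names(bundle$mortality)) {
    expect_equal(immature_mortality(ident$mortality[[st]], grid),
                 immature_mortality(bundle$mortality[[st]], grid))
  }
  expect_equal(mean_fecundity(ident$fecundity, grid),
               mean_fecundity(bundle$fecundity, grid))

  adj <- apply_adjustment(bundle)
  # widening B never increases mortality anywhere
  for (st in names(bundle$mortality)) {
    expect_true(all(immature_mortality(adj$mortality[[st]], grid) <=
                      immature_mortality(bundle$mortality[[st]], grid) + 1e-12))
    expect_equal(adj$mortality[[st]]$B, bundle$mortality[[st]]$B * 1.3)
  }
  expect_equal(mean_fecundity(adj$fecundity, 20), 4 * mean_fecundity(bundle$fecundity, 20))
  expect_equal(adult_median_time(adj$adult_timing, 20, "oviposition"),
               2 * adult_median_time(bundle$adult_timing, 20, "oviposition"))
  # development untouched
  expect_equal(janisch_rate(adj$development$egg, grid),
               janisch_rate(bundle$development$egg, grid))
  # original bundle unmodified
  expect_false(isTRUE(bundle$adjusted))
  expect_error(apply_adjustment(bundle, c(mortality_B = -1, adult_time = 2, fecundity = 4)))
})
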