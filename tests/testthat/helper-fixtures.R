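# Observed summaries from the constant-temperature life tables (10-32 degC)
# used as fitting inputs, plus small synthetic-data helpers.

egg_median_dev <- data.frame(
  temp = c(10, 15, 18, 20, 25, 28, 32),
  median = c(33.1, 17.3, 9.6, 9, 5.2, 5, 6.3)
)

pupa_median_dev <- data.frame(
  temp = c(15, 18, 20, 25, 28),
  median = c(11.6, 6.1, 4.9, 3.4, 6.8)
)

# mortality proportions by stage and temperature (immature stages)
immature_mortality_table <- data.frame(
  stage = c(rep("egg", 7), rep("nymph", 7), rep("puparium", 5)),
  temp = c(10, 15, 18, 20, 25, 28, 32,
           10, 15, 18, 20, 25, 28, 32,
           15, 18, 20, 25, 28),
  mortality = c(0.87, 0, 0, 0, 0, 0, 0.24,
                1, 0.14, 0.13, 0.04, 0.01, 0.14, 1,
                0.24, 0.13, 0.05, 0.10, 0.30)
)

mean_fecundity_table <- data.frame(
  temp = c(15, 18, 20, 25, 28),
  fecundity = c(10.3, 36.4, 40.1, 26.9, 19.2)
)

# interval-censored event times from a known link: true median `med`,
# daily observation, optional temperature-group structure
draw_interval_obs <- function(n, link, med, group = "g1", step = 1) {
  tt <- med * link_quantile(link, stats::runif(n))
  data.frame(lower = floor(tt / step) * step,
             upper = floor(tt / step) * step + step,
             group = group)
}

expect_within <- function(actual, expected, tol) {
  testthat::expect_true(
    abs(actual - expected) <= tol,
    label = sprintf("%.6g within %.3g of %.6g", actual, tol, expected)
  )
}
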