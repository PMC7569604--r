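#' Janisch development-rate curve
#'
#' Catenary-shaped relation between temperature and the median development
#' rate of an immature stage,
#' \deqn{r(T) = \left[\frac{D_{min}}{2}\left(e^{k(T-T_{opt})} +
#'   e^{-k(T-T_{opt})}\right)\right]^{-1} = \frac{1}{D_{min}\cosh(k(T-T_{opt}))},}
#' so the fastest development \eqn{1/D_{min}} occurs exactly at the optimum
#' temperature and the median development time grows symmetrically (on the
#' cosh scale) as temperature departs from it.
#'
#' @param params list with elements `D_min` (minimum median development time,
#'   days), `T_opt` (optimum temperature, deg C) and `k` (curvature, 1/deg C),
#'   e.g. one `development` block of [default_bundle()].
#' @param temp temperature(s), deg C; must be finite.
#' @return development rate(s), 1/day, floored at `1e-9` to keep reciprocal
#'   times finite at extreme temperatures.
#' @examples
#' egg <- default_bundle()$development$egg
#' janisch_rate(egg, 27.4)   # 1 / D_min at the optimum
#' 1 / janisch_rate(egg, 15) # median development time at 15 deg C
#' @export
janisch_rate <- function(params, temp) {
  stopifnot(is.numeric(temp), all(is.finite(temp)))
  check_positive(params, c("D_min", "k"))
  r <- 1 / (params$D_min * cosh(params$k * (temp - params$T_opt)))
  pmax(r, 1e-9)
}

#' Temperature-dependent mortality of an immature stage
#'
#' Mortality is minimal at a (stage-shared) optimum temperature and rises
#' towards 1 as temperature departs from it in either direction:
#' \deqn{m(T) = 1 - \exp\left[-H\,\bigl(1+e^{-(T-T_{opt})/B}\bigr)
#'   \bigl(1+e^{-(T_{opt}-T)/B}\bigr)\right].}
#' At the optimum this equals \eqn{1 - e^{-4H}}; the two logistic terms make
#' the curve symmetric in \eqn{T - T_{opt}} with spread controlled by `B`.
#' `form = "literal"` evaluates the raw printed variant
#' \eqn{1 - H(1+e^{-(T-T_{opt})/B})(1+e^{-(T_{opt}-T)/B})} (kept for
#' comparison only; it is not a usable mortality curve).
#'
#' @param params list with elements `H` (magnitude, dimensionless), `B`
#'   (spread, deg C) and `T_opt` (deg C).
#' @param temp temperature(s), deg C.
#' @param form `"reconstructed"` (default) or `"literal"`.
#' @return mortality proportion(s), clipped to `[0, 1]`.
#' @examples
#' pup <- default_bundle()$mortality$puparium
#' immature_mortality(pup, pup$T_opt) # 1 - exp(-4 H), the curve minimum
#' @export
immature_mortality <- function(params, temp, form = c("reconstructed", "literal")) {
  form <- match.arg(form)
  stopifnot(is.numeric(temp), all(is.finite(temp)))
  check_positive(params, c("H", "B"))
  u <- (temp - params$T_opt) / params$B
  g <- (1 + exp(-u)) * (1 + exp(u))
  m <- switch(form,
    reconstructed = 1 - exp(-params$H * g),
    literal = 1 - params$H * g
  )
  pmin(1, pmax(0, m))
}

#' Median adult event times as a function of temperature
#'
#' Median oviposition time declines exponentially with temperature,
#' \eqn{t(T) = 1 / (\mathrm{intercept}\cdot e^{\mathrm{slope}\cdot T})};
#' female and male median survival times are the same curve shifted by an
#' additive factor on the log-time scale, i.e. multiplied by
#' \eqn{e^{\mathrm{factor}}}. The male factor (about -0.36) reproduces the
#' roughly 25\% shorter male lifespan; the female factor is statistically
#' indistinguishable from zero (female lifetime and oviposition time do not
#' differ significantly).
#'
#' @param params list with elements `intercept` (1/day), `slope` (1/deg C),
#'   `factor_female`, `factor_male` (log-time scale).
#' @param temp temperature(s), deg C.
#' @param role one of `"oviposition"`, `"female_survival"`, `"male_survival"`.
#' @return median time(s), days.
#' @examples
#' ad <- default_bundle()$adult_timing
#' adult_median_time(ad, 15, "oviposition")  # about 8 days
#' adult_median_time(ad, 15, "male_survival")
#' @export
adult_median_time <- function(params, temp,
                              role = c("oviposition", "female_survival",
                                       "male_survival")) {
  role <- match.arg(role)
  stopifnot(is.numeric(temp), all(is.finite(temp)))
  check_positive(params, "intercept")
  fac <- switch(role,
    oviposition = 0,
    female_survival = params$factor_female,
    male_survival = params$factor_male
  )
  exp(fac) / (params$intercept * exp(params$slope * temp))
}

#' Mean lifetime fecundity per female as a function of temperature
#'
#' Asymmetric unimodal curve on the log-fecundity scale,
#' \deqn{\ln F(T) = \frac{H}{\bigl(1+e^{-(T-T_l)/B_l}\bigr)
#'   \bigl(1+e^{-(T_l-T)/B_h}\bigr)},}
#' with a steep rise above the lower inflection `Tl` (spread `Bl`) and a slow
#' decline on the warm side (spread `Bh`). The packaged parameters are a
#' refit to the observed mean fecundities at 15-28 deg C (see the methods
#' vignette); the curve peaks near 20 deg C at about 40 eggs/female.
#'
#' @param params list with elements `H`, `Tl` (deg C), `Bl` (deg C),
#'   `Bh` (deg C).
#' @param temp temperature(s), deg C.
#' @return mean eggs per female (non-negative).
#' @examples
#' fec <- default_bundle()$fecundity
#' mean_fecundity(fec, 20)
#' @export
mean_fecundity <- function(params, temp) {
  stopifnot(is.numeric(temp), all(is.finite(temp)))
  check_positive(params, c("Bl", "Bh"))
  mult <- if (is.null(params$mult)) 1 else params$mult
  mult * exp(params$H / ((1 + exp(-(temp - params$Tl) / params$Bl)) *
                           (1 + exp(-(params$Tl - temp) / params$Bh))))
}

#' Degree-day model from development rates by linear regression
#'
#' Ordinary least squares of development rate (1/median time, 1/day) on
#' temperature over the linear range. Points at or above `high_T_cutoff`
#' (where development slows again at high temperature) are removed before
#' fitting. The lower developmental threshold is the x-intercept
#' \eqn{T_0 = -\mathrm{intercept}/\mathrm{slope}} and the thermal constant is
#' \eqn{K = 1/\mathrm{slope}} degree-days.
#'
#' @param temp temperatures, deg C.
#' @param rate median development rates at those temperatures, 1/day.
#' @param high_T_cutoff exclude points with `temp >= high_T_cutoff`
#'   (default 28).
#' @param stage optional stage label carried into the result.
#' @return object of class `degree_day_fit`: list with `T0` (deg C), `K`
#'   (degree-days), `slope`, `intercept`, `n`, `stage` and the underlying
#'   `lm` fit.
#' @examples
#' fit <- degree_day_fit(c(10, 15, 20), c(0.03, 0.08, 0.13))
#' fit$T0; fit$K
#' @export
degree_day_fit <- function(temp, rate, high_T_cutoff = 28, stage = NULL) {
  stopifnot(length(temp) == length(rate), all(is.finite(temp)), all(is.finite(rate)))
  keep <- temp < high_T_cutoff
  if (sum(keep) < 3) {
    stop("degree_day_fit needs at least 3 points below the high-temperature cutoff")
  }
  if (length(unique(temp[keep])) < 2) stop("temperatures are all equal")
  fit <- stats::lm(rate ~ temp, data = data.frame(temp = temp[keep], rate = rate[keep]))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) stop("non-positive slope: lower threshold undefined")
  structure(
    list(T0 = -intercept / slope, K = 1 / slope, slope = slope,
         intercept = intercept, n = sum(keep), stage = stage, lm = fit),
    class = "degree_day_fit"
  )
}

#' @export
print.degree_day_fit <- function(x, ...) {
  cat("Degree-day model", if (!is.null(x$stage)) paste0("(", x$stage, ")"), "\n")
  cat(sprintf("  lower threshold T0 = %.2f degC, thermal constant K = %.1f DD (n = %d)\n",
              x$T0, x$K, x$n))
  invisible(x)
}

#' Apply fluctuating-temperature adjustment factors to a model bundle
#'
#' Returns a copy of the bundle with the empirical corrections for naturally
#' fluctuating temperature applied: the mortality spread parameter `B` of
#' every immature stage is multiplied by `factors["mortality_B"]` (widening
#' the survivable temperature window), adult median survival and oviposition
#' times by `factors["adult_time"]`, and mean fecundity per female by
#' `factors["fecundity"]`. All other parameters are untouched and the input
#' bundle is not modified. The default factors (1.3, 2, 4) are the packaged
#' calibration; identity factors return an equivalent bundle.
#'
#' @param bundle a model bundle, see [default_bundle()].
#' @param factors named numeric vector with elements `mortality_B`,
#'   `adult_time`, `fecundity`; defaults to the bundle's own
#'   `adjustment_factors`.
#' @return the adjusted bundle, with `bundle$adjusted` set to `TRUE`.
#' @examples
#' adj <- apply_adjustment(default_bundle())
#' adj$mortality$egg$B / default_bundle()$mortality$egg$B # 1.3
#' @export
apply_adjustment <- function(bundle, factors = NULL) {
  if (is.null(factors)) factors <- unlist(bundle$adjustment_factors)
  factors <- factors[c("mortality_B", "adult_time", "fecundity")]
  if (anyNA(factors) || any(factors <= 0)) {
    stop("factors must be positive and named mortality_B, adult_time, fecundity")
  }
  out <- bundle
  for (st in names(out$mortality)) {
    out$mortality[[st]]$B <- out$mortality[[st]]$B * factors[["mortality_B"]]
  }
  # times scale by f <=> the baseline rate constant scales by 1/f
  out$adult_timing$intercept <- out$adult_timing$intercept / factors[["adult_time"]]
  out$fecundity$mult <- factors[["fecundity"]] *
    (if (is.null(bundle$fecundity$mult)) 1 else bundle$fecundity$mult)
  out$adjusted <- TRUE
  out
}

# shared parameter sanity check
check_positive <- function(params, fields) {
  for (f in fields) {
    v <- params[[f]]
    if (is.null(v) || !is.finite(v) || v <= 0) {
      stop(sprintf("parameter '%s' must be a positive finite number", f))
    }
  }
  invisible(TRUE)
}
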