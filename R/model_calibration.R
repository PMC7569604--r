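#' Corrected Akaike information criterion
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)`, the small-sample correction that
#' penalizes extra parameters more strongly than plain AIC. Supply either a
#' log-likelihood or, for least-squares fits, a residual sum of squares (in
#' which case `AIC = n log(RSS/n) + 2k` up to an additive constant).
#'
#' @param loglik maximized log-likelihood (mutually exclusive with `rss`).
#' @param rss residual sum of squares of a least-squares fit.
#' @param n number of observations; must exceed `k + 1`.
#' @param k number of estimated parameters.
#' @return the AICc value.
#' @examples
#' aicc(rss = 1.2, n = 7, k = 3)
#' @export
aicc <- function(loglik = NULL, rss = NULL, n, k) {
  if (is.null(loglik) == is.null(rss)) {
    stop("supply exactly one of loglik or rss")
  }
  if (n <= k + 1) stop("AICc requires n > k + 1")
  aic <- if (!is.null(loglik)) -2 * loglik + 2 * k else n * log(rss / n) + 2 * k
  aic + 2 * k * (k + 1) / (n - k - 1)
}

fit_report <- function(model, parameters, se, observed, fitted, k,
                       data = NULL, scale = "ln") {
  n <- length(observed)
  resid <- observed - fitted
  rss <- sum(resid^2)
  tss <- sum((observed - mean(observed))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k)
  df1 <- k - 1
  df2 <- n - k
  f <- if (df2 > 0 && rss > 0) ((tss - rss) / df1) / (rss / df2) else NA_real_
  p <- if (is.finite(f)) stats::pf(f, df1, df2, lower.tail = FALSE) else NA_real_
  structure(
    list(model = model, parameters = parameters, se = se, rss = rss,
         tss = tss, r_squared = r2, adj_r_squared = adj_r2,
         f_value = f, df = c(df1, df2), p_value = p,
         aicc = if (n > k + 1) aicc(rss = rss, n = n, k = k) else NA_real_,
         sigma = if (df2 > 0) sqrt(rss / df2) else NA_real_,
         n = n, k = k, observed = observed, fitted = fitted,
         data = data, scale = scale),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("Nonlinear fit: %s (on the %s scale), n = %d, k = %d\n",
              x$model, x$scale, x$n, x$k))
  tab <- data.frame(estimate = x$parameters, se = x$se)
  print(format(tab, digits = 4))
  cat(sprintf("  RSS %.4g, R2 %.4f (adj. %.4f), F(%d, %d) = %.1f, P = %.3g, AICc %.2f\n",
              x$rss, x$r_squared, x$adj_r_squared, x$df[1], x$df[2],
              x$f_value, x$p_value, x$aicc))
  invisible(x)
}

#' Fit a development-time model on the ln-time scale
#'
#' Nonlinear least squares of `ln(median development time)` against the
#' model-implied log time as a function of temperature. The default
#' `"janisch"` family fits `ln t(T) = ln[D_min cosh(k (T - T_opt))]`; the
#' `"linear"` family fits a straight line to the rates `1/t` (the degree-day
#' regression is available separately via [degree_day_fit()]). Parameters
#' are reported on the natural scale with asymptotic standard errors, along
#' with RSS, F statistic, adjusted R-squared and AICc, all computed on the
#' fitted (ln-time) scale.
#'
#' @param temp temperatures, deg C.
#' @param median_time median event times at those temperatures, days (`> 0`).
#' @param model `"janisch"` or `"linear"`.
#' @param stage optional label carried into the report.
#' @return a `fit_report`.
#' @examples
#' fit_lntime_model(c(10, 15, 18, 20, 25, 28, 32),
#'                  c(33.1, 17.3, 9.6, 9, 5.2, 5, 6.3))
#' @export
fit_lntime_model <- function(temp, median_time, model = c("janisch", "linear"),
                             stage = NULL) {
  model <- match.arg(model)
  stopifnot(length(temp) == length(median_time), all(median_time > 0),
            all(is.finite(temp)))
  y <- log(median_time)
  d <- data.frame(temp = temp, y = y)
  if (model == "janisch") {
    if (length(temp) < 4) stop("the Janisch fit needs at least 4 points")
    start <- list(D_min = min(median_time),
                  T_opt = temp[which.min(median_time)], k = 0.1)
    fit <- minpack.lm::nlsLM(
      y ~ log(D_min * cosh(k * (temp - T_opt))), data = d, start = start,
      lower = c(D_min = 1e-3, T_opt = 0, k = 1e-4),
      upper = c(D_min = Inf, T_opt = 40, k = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    cf <- summary(fit)$coefficients
    rep <- fit_report(model = "janisch", parameters = cf[, 1], se = cf[, 2],
                      observed = y, fitted = stats::fitted(fit), k = 3,
                      data = d, scale = "ln")
  } else {
    if (length(temp) < 3) stop("the linear fit needs at least 3 points")
    fit <- stats::lm(y ~ temp, data = d)
    cf <- summary(fit)$coefficients
    rep <- fit_report(model = "linear", parameters = cf[, 1], se = cf[, 2],
                      observed = y, fitted = stats::fitted(fit), k = 2,
                      data = d, scale = "ln")
  }
  rep$stage <- stage
  rep
}

#' Joint fit of the immature mortality curves across stages
#'
#' Least squares on the proportion scale of the mortality model
#' (see [immature_mortality()]) to per-stage mortality proportions observed
#' over temperature. With `share_Topt = TRUE` (the default) one optimum
#' temperature is shared by all stages while `H` and `B` remain
#' stage-specific (7 parameters for three stages); otherwise every stage has
#' its own optimum (9 parameters). Starting values put `T_opt` at the
#' temperature of minimum mortality and solve `H` from the observed extreme
#' mortalities over a small deterministic grid of `B` starts; optimization is
#' Levenberg-Marquardt with positivity bounds and the best converged solution
#' by RSS is kept.
#'
#' @param data data.frame with columns `stage`, `temp`, `mortality`
#'   (proportions in `[0, 1]`).
#' @param share_Topt single shared optimum temperature? (default `TRUE`)
#' @return a `fit_report`; `parameters` are named `T_opt` (or
#'   `T_opt_<stage>`), `H_<stage>`, `B_<stage>`.
#' @seealso [f_ratio_test()] to compare the two nested variants.
#' @export
fit_mortality_model <- function(data, share_Topt = TRUE) {
  d <- as.data.frame(data)
  stopifnot(all(c("stage", "temp", "mortality") %in% names(d)),
            all(d$mortality >= 0 & d$mortality <= 1))
  stages <- unique(as.character(d$stage))
  ns <- length(stages)
  cnt <- table(factor(d$stage, levels = stages))
  if (any(cnt < 3)) stop("each stage needs at least 3 mortality points")
  idx <- match(as.character(d$stage), stages)

  nT <- if (share_Topt) 1L else ns
  lower <- c(rep(0, nT), rep(1e-12, ns), rep(1e-3, ns))
  upper <- c(rep(40, nT), rep(10, ns), rep(50, ns))

  pred <- function(par) {
    Topt <- if (share_Topt) rep(par[1], ns) else par[seq_len(ns)]
    H <- par[nT + seq_len(ns)]
    B <- par[nT + ns + seq_len(ns)]
    u <- (d$temp - Topt[idx]) / B[idx]
    pmin(1, 1 - exp(-H[idx] * (1 + exp(-u)) * (1 + exp(u))))
  }

  # Starting values: T_opt at the minimum observed mortality; H either from
  # the mortality at the optimum (1 - e^{-4H}) or back-solved from the most
  # extreme observed point given B; a small deterministic grid of B starts
  # guards against the flat/steep local attractors of the egg-type stages
  # (several zero mortalities next to near-total mortality at the extremes).
  start_T <- numeric(ns)
  for (i in seq_len(ns)) {
    di <- d[idx == i, ]
    start_T[i] <- di$temp[which.min(di$mortality)]
  }
  T0 <- mean(start_T)
  starts <- list()
  for (B0 in c(0.5, 1, 2, 4)) {
    H_min <- H_max <- numeric(ns)
    for (i in seq_len(ns)) {
      di <- d[idx == i, ]
      H_min[i] <- max(-log(1 - min(0.999, min(di$mortality))) / 4, 1e-6)
      j <- which.max(di$mortality)
      u <- (di$temp[j] - T0) / B0
      g <- (1 + exp(-u)) * (1 + exp(u))
      H_max[i] <- max(-log(1 - min(0.999, di$mortality[j])) / g, 1e-10)
    }
    Tpart <- if (share_Topt) T0 else start_T
    starts <- c(starts, list(c(Tpart, H_min, rep(B0, ns)),
                             c(Tpart, H_max, rep(B0, ns))))
  }
  fit <- NULL
  for (p0 in starts) {
    f <- try(minpack.lm::nls.lm(
      par = pmin(pmax(p0, lower), upper), lower = lower, upper = upper,
      fn = function(par) d$mortality - pred(par),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                           ptol = 1e-12)
    ), silent = TRUE)
    if (inherits(f, "try-error") || f$info %in% c(0, 9)) next
    if (is.null(fit) || f$deviance < fit$deviance) fit <- f
  }
  if (is.null(fit)) stop("mortality model fit did not converge from any start")
  par <- fit$par
  nm <- c(if (share_Topt) "T_opt" else paste0("T_opt_", stages),
          paste0("H_", stages), paste0("B_", stages))
  names(par) <- nm
  se <- tryCatch({
    s <- summary(fit)
    stats::setNames(s$coefficients[, "Std. Error"], nm)
  }, error = function(e) stats::setNames(rep(NA_real_, length(par)), nm))

  rep <- fit_report(model = if (share_Topt) "mortality (global T_opt)" else
                      "mortality (stage-specific T_opt)",
                    parameters = par, se = se, observed = d$mortality,
                    fitted = pred(par), k = length(par), data = d,
                    scale = "proportion")
  rep$stages <- stages
  rep$share_Topt <- share_Topt
  rep
}

#' F-ratio test between two nested least-squares fits
#'
#' Compares a reduced model against a fuller model fitted to the same data,
#' e.g. the global-optimum mortality fit against the stage-specific variant:
#' `F = [(RSS_reduced - RSS_full)/(k_full - k_reduced)] / [RSS_full/(n - k_full)]`.
#'
#' @param reduced,full `fit_report` objects with `full$k > reduced$k` and the
#'   same `n`.
#' @return list with `f`, `df` (numerator, denominator), `p`.
#' @export
f_ratio_test <- function(reduced, full) {
  stopifnot(inherits(reduced, "fit_report"), inherits(full, "fit_report"),
            reduced$n == full$n, full$k > reduced$k)
  df1 <- full$k - reduced$k
  df2 <- full$n - full$k
  f <- ((reduced$rss - full$rss) / df1) / (full$rss / df2)
  list(f = f, df = c(df1, df2), p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Fit the temperature-fecundity curve
#'
#' Least squares on the ln-fecundity scale of the 4-parameter asymmetric
#' unimodal family used by [mean_fecundity()]. A small deterministic grid of
#' starting values (lower inflection across the observed temperature range,
#' several spread combinations) feeds Levenberg-Marquardt; the best
#' converged solution by RSS is returned. R-squared is reported on the
#' fitted (ln) scale.
#'
#' @param temp temperatures, deg C (at least 5).
#' @param fecundity mean eggs per female at those temperatures (`> 0`).
#' @return a `fit_report` with parameters `H`, `Tl`, `Bl`, `Bh`.
#' @examples
#' fit_fecundity_model(c(15, 18, 20, 25, 28), c(10.3, 36.4, 40.1, 26.9, 19.2))
#' @export
fit_fecundity_model <- function(temp, fecundity) {
  stopifnot(length(temp) == length(fecundity), all(fecundity > 0))
  if (length(temp) < 5) stop("the fecundity fit needs at least 5 points")
  y <- log(fecundity)
  pred <- function(par) {
    par[1] / ((1 + exp(-(temp - par[2]) / par[3])) *
                (1 + exp(-(par[2] - temp) / par[4])))
  }
  lower <- c(1e-3, 0, 0.05, 0.05)
  upper <- c(100, 40, 50, 50)
  best <- NULL
  for (Tl0 in stats::quantile(temp, c(0, 0.25, 0.5, 0.75), names = FALSE)) {
    for (Bh0 in c(2, 5, 10, 20)) {
      for (Bl0 in c(1, 2, 5)) {
        f <- try(minpack.lm::nls.lm(
          par = c(2.2 * max(y), Tl0, Bl0, Bh0), lower = lower, upper = upper,
          fn = function(par) y - pred(par),
          control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                               ptol = 1e-12)
        ), silent = TRUE)
        if (inherits(f, "try-error") || f$info %in% c(0, 9)) next
        if (is.null(best) || f$deviance < best$deviance) best <- f
      }
    }
  }
  if (is.null(best)) stop("fecundity model fit did not converge from any start")
  par <- stats::setNames(best$par, c("H", "Tl", "Bl", "Bh"))
  se <- tryCatch({
    s <- summary(best)
    stats::setNames(s$coefficients[, "Std. Error"], names(par))
  }, error = function(e) stats::setNames(rep(NA_real_, 4), names(par)))
  rep <- fit_report(model = "fecundity (asymmetric unimodal, ln scale)",
                    parameters = par, se = se, observed = y,
                    fitted = pred(best$par), k = 4,
                    data = data.frame(temp = temp, fecundity = fecundity),
                    scale = "ln")
  rep
}
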