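#' Life-table parameters from survival and fecundity schedules
#'
#' Computes the standard cohort life-table statistics from daily age-specific
#' survival `l_x` (proportion of the initial female cohort alive at age `x`)
#' and fecundity `m_x` (female offspring per female per day):
#' \itemize{
#'   \item net reproduction rate \eqn{R_0 = \sum l_x m_x}
#'   \item gross reproduction rate \eqn{GRR = \sum m_x}
#'   \item `method = "lotka"`: the intrinsic rate of increase solves the
#'     Euler-Lotka equation \eqn{\sum e^{-r(x+0.5)} l_x m_x = 1} by bracketed
#'     root finding (mid-interval age correction for daily classes), and
#'     \eqn{T = \ln R_0 / r}
#'   \item `method = "approximate"`: \eqn{T = \sum x l_x m_x / \sum l_x m_x}
#'     and \eqn{r = \ln R_0 / T}
#' }
#' In both cases \eqn{\lambda = e^{r}} and \eqn{Dt = \ln 2 / r}. A schedule
#' with \eqn{R_0 = 0} has no growth rate: `r_m = -Inf`, `lambda = 0`,
#' `Dt = Inf`.
#'
#' @param schedule data.frame with columns `x` (age, days), `lx`, `mx`
#'   (e.g. the `schedule` element of [simulate_cohort()]).
#' @param method `"lotka"` or `"approximate"`.
#' @return object of class `life_table_params`: list with `R0`, `GRR`, `T`,
#'   `r_m`, `lambda`, `Dt`, `method`.
#' @examples
#' # all reproduction (R0 = 4) concentrated at age 10:
#' sched <- data.frame(x = 0:10, lx = 1, mx = c(rep(0, 10), 4))
#' life_table_params(sched, method = "approximate") # r = ln(4)/10
#' @export
life_table_params <- function(schedule, method = c("lotka", "approximate")) {
  method <- match.arg(method)
  stopifnot(all(c("x", "lx", "mx") %in% names(schedule)))
  x <- schedule$x
  lxmx <- schedule$lx * schedule$mx
  if (!all(is.finite(lxmx)) || any(lxmx < 0)) stop("l_x m_x must be finite and non-negative")
  R0 <- sum(lxmx)
  GRR <- sum(schedule$mx)
  if (R0 <= 0) {
    out <- list(R0 = R0, GRR = GRR, T = NA_real_, r_m = -Inf, lambda = 0,
                Dt = Inf, method = method)
    return(structure(out, class = "life_table_params"))
  }
  if (method == "lotka") {
    f <- function(r) sum(exp(-r * (x + 0.5)) * lxmx) - 1
    lo <- -2; hi <- 2
    while (f(hi) > 0) hi <- hi * 2
    while (f(lo) < 0) lo <- lo * 2
    r <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    Tg <- log(R0) / r
  } else {
    Tg <- sum(x * lxmx) / R0
    r <- log(R0) / Tg
  }
  structure(list(R0 = R0, GRR = GRR, T = Tg, r_m = r, lambda = exp(r),
                 Dt = log(2) / r, method = method),
            class = "life_table_params")
}

#' @export
print.life_table_params <- function(x, ...) {
  cat(sprintf("Life-table parameters (%s method)\n", x$method))
  cat(sprintf("  R0 = %.3f females/female, GRR = %.3f, T = %.2f d\n",
              x$R0, x$GRR, x$T))
  cat(sprintf("  r_m = %.4f /d, lambda = %.4f /d, doubling time = %.2f d\n",
              x$r_m, x$lambda, x$Dt))
  invisible(x)
}

#' Binomial standard error of a mortality proportion
#'
#' `SE = sqrt(m (1 - m) / N)` for a mortality rate `m` estimated from `N`
#' test insects.
#'
#' @param m mortality proportion(s) in `[0, 1]`.
#' @param N number(s) of individuals at risk, `>= 1`.
#' @return standard error(s).
#' @examples
#' mortality_se(0.24, 86) # 0.046
#' @export
mortality_se <- function(m, N) {
  if (any(m < 0 | m > 1)) stop("m must lie in [0, 1]")
  if (any(N < 1)) stop("N must be at least 1")
  sqrt(m * (1 - m) / N)
}

#' z-score comparison of an observed value against simulation replicates
#'
#' `z = (observed - mean(simulated)) / sd(simulated)`, with a two-sided
#' p-value from the t-distribution with `length(simulated) - 1` degrees of
#' freedom. Positive `z` means the observation exceeds the simulated mean.
#'
#' @param observed a single observed value.
#' @param simulated numeric vector of at least 2 replicate simulated values.
#' @return object of class `z_comparison`: list with `observed`, `sim_mean`,
#'   `sim_sd`, `z`, `p`, `df`.
#' @examples
#' z_compare(0.069, c(0.012, 0.030, 0.021, 0.021))
#' @export
z_compare <- function(observed, simulated) {
  stopifnot(length(observed) == 1, is.finite(observed))
  simulated <- simulated[is.finite(simulated)]
  if (length(simulated) < 2) stop("need at least 2 simulated replicate values")
  s <- stats::sd(simulated)
  if (s == 0) {
    if (observed == mean(simulated)) {
      z <- 0
    } else {
      stop("simulated replicates have zero standard deviation")
    }
  } else {
    z <- (observed - mean(simulated)) / s
  }
  df <- length(simulated) - 1
  structure(list(observed = observed, sim_mean = mean(simulated), sim_sd = s,
                 z = z, p = 2 * stats::pt(-abs(z), df = df), df = df),
            class = "z_comparison")
}

#' @export
print.z_comparison <- function(x, ...) {
  cat(sprintf("observed %.4g vs simulated %.4g (sd %.4g): z = %.2f, P = %.3g (df = %d)\n",
              x$observed, x$sim_mean, x$sim_sd, x$z, x$p, x$df))
  invisible(x)
}

#' Tabulated z-score validation of several life-table parameters
#'
#' Convenience wrapper around [z_compare()] for a Table-style comparison of
#' observed life-table parameters against per-replicate simulated values.
#'
#' @param observed named numeric vector of observed parameters.
#' @param simulated data.frame of per-replicate simulated parameters whose
#'   columns cover `names(observed)` (e.g. `params` from
#'   [simulate_replicates()]).
#' @return data.frame with one row per parameter: observed, simulated mean
#'   and sd, z and p.
#' @export
z_table <- function(observed, simulated) {
  stopifnot(!is.null(names(observed)), all(names(observed) %in% names(simulated)))
  rows <- lapply(names(observed), function(nm) {
    zc <- z_compare(observed[[nm]], simulated[[nm]])
    data.frame(parameter = nm, observed = zc$observed, sim_mean = zc$sim_mean,
               sim_sd = zc$sim_sd, z = zc$z, p = zc$p)
  })
  do.call(rbind, rows)
}
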