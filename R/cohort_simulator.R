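# Piecewise-linear accumulators over a temperature series.
#
# A temp_series holds temperatures on intervals [t_j, t_{j+1}); physiological
# (normalized) age accumulates at rate r(T_j) per day within each interval,
# so its cumulative curve is piecewise linear in time and can be evaluated
# and inverted exactly by interpolation.

series_days <- function(series) series$time_h / 24

cum_curve <- function(td, rates) c(0, cumsum(rates * diff(td)))

eval_cum <- function(td, V, t) stats::approx(td, V, xout = t, rule = 2)$y

# first time at which the non-decreasing node curve V reaches y (Inf if never)
invert_cum <- function(td, V, y) {
  J <- length(V)
  if (y <= V[1]) return(td[1])
  if (y > V[J]) return(Inf)
  j <- findInterval(y, V) # largest j with V[j] <= y
  if (j >= J) return(td[J])
  dV <- V[j + 1] - V[j]
  if (dV <= 0) return(td[j + 1])
  td[j] + (y - V[j]) / dV * (td[j + 1] - td[j])
}

#' Accumulate physiological age over a temperature series (rate summation)
#'
#' Integrates a temperature-dependent rate (1/day) over a fluctuating
#' temperature series until a target normalized age is reached. At constant
#' temperature the completion time is exactly `target / rate(T)`; under
#' fluctuation the completion time differs whenever the rate curve is
#' nonlinear over the visited temperature range (the Kaufmann, or rate
#' summation, effect).
#'
#' @param rate_fn function mapping temperature (deg C) to a rate (1/day).
#' @param series a [temp_series()].
#' @param start start time, days from the beginning of the series.
#' @param target normalized age to accumulate (`> 0`).
#' @return completion time in days from the series start, or `Inf` with
#'   attribute `censored = TRUE` if the series ends first.
#' @examples
#' egg <- default_bundle()$development$egg
#' s <- temp_series_constant(25, days = 30)
#' rate_summation(function(T) janisch_rate(egg, T), s, target = 1)
#' 1 / janisch_rate(egg, 25)
#' @export
rate_summation <- function(rate_fn, series, start = 0, target) {
  stopifnot(inherits(series, "temp_series"), target > 0, start >= 0)
  td <- series_days(series)
  rates <- rate_fn(series$temp[-length(series$temp)])
  if (any(rates < 0)) stop("rates must be non-negative")
  C <- cum_curve(td, rates)
  t_done <- invert_cum(td, C, eval_cum(td, C, start) + target)
  if (!is.finite(t_done)) {
    attr(t_done, "censored") <- TRUE
  }
  t_done
}

# Per-process grids used by the simulator: cumulative normalized age and, for
# immature stages, cumulative log survival weighted by normalized-age
# increments (exponent dx per step, so constant T reproduces 1 - m(T) per
# completed stage exactly).
build_grids <- function(bundle, series) {
  td <- series_days(series)
  temps <- series$temp[-length(series$temp)]
  dt <- diff(td)
  g <- list(td = td, end = td[length(td)])
  for (st in c("egg", "nymph", "puparium")) {
    r <- janisch_rate(bundle$development[[st]], temps)
    m <- pmin(immature_mortality(bundle$mortality[[st]], temps), 1 - 1e-12)
    dx <- r * dt
    g[[st]] <- list(C = cum_curve(td, r), D = c(0, cumsum(-log(1 - m) * dx)))
  }
  for (role in c("female_survival", "male_survival", "oviposition")) {
    r <- 1 / adult_median_time(bundle$adult_timing, temps, role)
    g[[role]] <- list(C = cum_curve(td, r))
  }
  g
}

#' Simulate a stochastic cohort life table
#'
#' Individual-based simulation of a cohort driven by a temperature series.
#' Each individual draws its sex (probability of female = the bundle's sex
#' ratio), a development-time quantile per immature stage from that stage's
#' distribution link, and one uniform mortality draw per stage; physiological
#' age accumulates by rate summation and per-step survival is
#' `(1 - m(T))^dx` with `dx` the fraction of the stage's normalized age
#' completed in the step (so at constant temperature stage survival is
#' exactly `1 - m(T)`). Emerging females draw a lifetime fecundity around the
#' temperature-dependent mean, a senescence quantile and an oviposition-end
#' quantile; eggs are laid over the female's own oviposition window by the
#' increments of the oviposition link CDF and truncated at death.
#'
#' With the default `oviposition_window = "drawn_quantile"`, each female's
#' window ends at her drawn oviposition-end quantile and her drawn total is
#' distributed over that window (CDF increments rescaled by the window
#' mass), so a female surviving her full oviposition period realizes her
#' drawn total — keeping the simulated population mean consistent with the
#' calibrated mean-fecundity curve, which was fitted to observed lifetime
#' totals — while females dying early realize only part of it.
#' `oviposition_window = "lifetime"` instead spreads the total over the
#' unrescaled link CDF for as long as the female lives.
#'
#' @param bundle a model bundle ([default_bundle()]); pass
#'   `adjusted = TRUE` to apply the packaged fluctuating-temperature
#'   adjustment factors first.
#' @param series a [temp_series()] long enough for the cohort to die out
#'   (individuals alive at the series end are right-censored).
#' @param n number of individuals (eggs) to start.
#' @param seed integer seed; identical seeds reproduce identical cohorts.
#' @param adjusted apply [apply_adjustment()] with the bundle's packaged
#'   factors before simulating.
#' @param fecundity_temperature `"adult_mean"` (default: mean series
#'   temperature over the female's adult span) or `"emergence"` (temperature
#'   on the emergence day) as the driver of mean fecundity.
#' @param oviposition_window `"drawn_quantile"` (default) or `"lifetime"`;
#'   see Details.
#' @return object of class `cohort_sim`: list with `individuals` (one row per
#'   individual: sex, per-stage completion/death days, emergence day, death
#'   day, censoring flag, drawn and laid eggs), `eggs` (long table: female
#'   id, cohort age day, eggs laid), `schedule` (the female-based life-table
#'   schedule: age `x`, survival `lx`, daily female offspring `mx`), and
#'   bookkeeping (`n`, `n_females`, `seed`, `adjusted`).
#' @examples
#' sim <- simulate_cohort(default_bundle(), temp_series_constant(20, 150),
#'                        n = 50, seed = 1)
#' life_table_params(sim$schedule)
#' @export
simulate_cohort <- function(bundle, series, n = 100, seed = NULL,
                            adjusted = FALSE,
                            fecundity_temperature = c("adult_mean", "emergence"),
                            oviposition_window = c("drawn_quantile", "lifetime")) {
  fecundity_temperature <- match.arg(fecundity_temperature)
  oviposition_window <- match.arg(oviposition_window)
  stopifnot(inherits(series, "temp_series"), n >= 1)
  validate_bundle(bundle)
  if (adjusted && !isTRUE(bundle$adjusted)) bundle <- apply_adjustment(bundle)
  if (!is.null(seed)) set.seed(seed)

  g <- build_grids(bundle, series)
  td <- g$td
  stages <- c("egg", "nymph", "puparium")
  sex_ratio <- if (is.null(bundle$sex_ratio)) 0.5 else bundle$sex_ratio
  sigma_f <- if (is.null(bundle$fecundity$sigma_ln)) 0 else bundle$fecundity$sigma_ln

  ind <- data.frame(id = seq_len(n), sex = NA_character_,
                    egg = NA_real_, nymph = NA_real_, puparium = NA_real_,
                    emergence = NA_real_, death = NA_real_,
                    died_stage = NA_character_, censored = FALSE,
                    eggs_potential = NA_real_, eggs_laid = NA_real_)
  egg_rows <- vector("list", n)

  for (i in seq_len(n)) {
    female <- stats::runif(1) < sex_ratio
    ind$sex[i] <- if (female) "female" else "male"
    t <- 0
    dead <- FALSE
    for (st in stages) {
      x_tgt <- link_quantile(bundle$links[[st]], stats::runif(1))
      C <- g[[st]]$C; D <- g[[st]]$D
      c0 <- eval_cum(td, C, t)
      t_done <- invert_cum(td, C, c0 + x_tgt)
      u_mort <- stats::runif(1)
      d0 <- eval_cum(td, D, t)
      d_end <- if (is.finite(t_done)) eval_cum(td, D, t_done) else D[length(D)]
      m_total <- 1 - exp(-(d_end - d0) / x_tgt)
      if (u_mort < m_total) {
        t_death <- invert_cum(td, D, d0 - x_tgt * log(1 - u_mort))
        ind$death[i] <- min(t_death, t_done, g$end)
        ind$died_stage[i] <- st
        dead <- TRUE
        break
      }
      if (!is.finite(t_done)) { # series ended mid-stage
        ind$death[i] <- g$end
        ind$censored[i] <- TRUE
        dead <- TRUE
        break
      }
      ind[[st]][i] <- t_done
      t <- t_done
    }
    if (dead) next

    ind$emergence[i] <- t
    role <- if (female) "female_survival" else "male_survival"
    Cs <- g[[role]]$C
    x_s <- link_quantile(bundle$links$adult_survival, stats::runif(1))
    t_death <- invert_cum(td, Cs, eval_cum(td, Cs, t) + x_s)
    if (!is.finite(t_death)) {
      t_death <- g$end
      ind$censored[i] <- TRUE
    }
    ind$death[i] <- t_death

    if (female) {
      tf <- if (fecundity_temperature == "adult_mean") {
        sel <- td >= t & td <= t_death
        if (any(sel)) mean(series$temp[sel]) else series$temp[findInterval(t, td)]
      } else {
        series$temp[max(findInterval(t, td), 1)]
      }
      fbar <- mean_fecundity(bundle$fecundity, tf)
      G <- if (sigma_f > 0) {
        stats::rlnorm(1, meanlog = log(fbar) - sigma_f^2 / 2, sdlog = sigma_f)
      } else fbar
      ind$eggs_potential[i] <- G

      Co <- g$oviposition$C
      ov_link <- bundle$links$oviposition
      co0 <- eval_cum(td, Co, t)
      if (oviposition_window == "drawn_quantile") {
        x_end <- link_quantile(ov_link, stats::runif(1))
        window_mass <- link_cdf(ov_link, x_end)
        t_stop <- min(t_death, invert_cum(td, Co, co0 + x_end), g$end)
      } else {
        window_mass <- 1
        t_stop <- min(t_death, g$end)
      }
      if (t_stop > t) {
        bnd <- sort(unique(c(t, seq(ceiling(t), floor(t_stop)), t_stop)))
        bnd <- bnd[bnd >= t & bnd <= t_stop]
        if (length(bnd) >= 2) {
          x_at <- pmax(eval_cum(td, Co, bnd) - co0, 0)
          Fv <- link_cdf(ov_link, x_at)
          eggs <- G * diff(Fv) / window_mass
          day <- floor(bnd[-length(bnd)])
          keep <- eggs > 0
          if (any(keep)) {
            egg_rows[[i]] <- data.frame(id = i, day = day[keep],
                                        eggs = eggs[keep])
          }
        }
      }
      ind$eggs_laid[i] <- if (is.null(egg_rows[[i]])) 0 else sum(egg_rows[[i]]$eggs)
    }
  }

  eggs <- if (length(el <- Filter(Negate(is.null), egg_rows))) {
    stats::aggregate(eggs ~ id + day, data = do.call(rbind, el), FUN = sum)
  } else {
    data.frame(id = integer(), day = numeric(), eggs = numeric())
  }

  schedule <- schedule_from_individuals(ind, eggs)
  structure(list(individuals = ind, eggs = eggs, schedule = schedule,
                 n = n, n_females = sum(ind$sex == "female"),
                 seed = seed, adjusted = isTRUE(bundle$adjusted)),
            class = "cohort_sim")
}

# Female-based daily life-table schedule: lx = fraction of initial females
# alive at age x, mx = female offspring (sex ratio applied) per living female
# per day.
schedule_from_individuals <- function(ind, eggs, sex_ratio = 0.5) {
  females <- ind[ind$sex == "female", , drop = FALSE]
  nf <- nrow(females)
  if (nf == 0) {
    return(structure(data.frame(x = 0, lx = 1, mx = 0),
                     class = c("life_table_schedule", "data.frame")))
  }
  death <- females$death
  horizon <- max(ceiling(max(death, eggs$day + 1, 1)), 1)
  x <- 0:horizon
  alive <- vapply(x, function(a) sum(death > a), numeric(1))
  lx <- alive / nf
  daily <- numeric(length(x))
  if (nrow(eggs)) {
    tot <- tapply(eggs$eggs, eggs$day, sum)
    dd <- as.numeric(names(tot))
    sel <- dd <= horizon
    daily[dd[sel] + 1] <- tot[sel]
  }
  mx <- ifelse(alive > 0, sex_ratio * daily / alive, 0)
  structure(data.frame(x = x, lx = lx, mx = mx),
            class = c("life_table_schedule", "data.frame"))
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Stochastic cohort: %d individuals (%d females)%s%s\n",
              x$n, x$n_females,
              if (x$adjusted) ", adjusted model" else "",
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  surv <- mean(!is.na(x$individuals$emergence))
  cat(sprintf("  immature survival %.2f; eggs laid in total %.0f\n",
              surv, sum(x$individuals$eggs_laid, na.rm = TRUE)))
  invisible(x)
}

#' Simulate replicate cohorts and pool their schedules
#'
#' Runs [simulate_cohort()] `reps` times with seeds derived from `seed`
#' (`seed`, `seed + 1`, ...), pools all individuals into one schedule, and
#' computes life-table parameters per replicate and for the pool.
#'
#' @inheritParams simulate_cohort
#' @param reps number of replicate cohorts.
#' @param method life-table method, see [life_table_params()].
#' @return list with `replicates` (the `cohort_sim` objects), `params`
#'   (data.frame of per-replicate life-table parameters), `pooled_schedule`
#'   and `pooled_params`.
#' @export
simulate_replicates <- function(bundle, series, n = 100, reps = 4, seed = NULL,
                                adjusted = FALSE, method = "approximate") {
  seeds <- if (is.null(seed)) rep(list(NULL), reps) else as.list(seed + seq_len(reps) - 1)
  sims <- lapply(seeds, function(s) {
    simulate_cohort(bundle, series, n = n, seed = s, adjusted = adjusted)
  })
  params <- do.call(rbind, lapply(sims, function(s) {
    as.data.frame(unclass(life_table_params(s$schedule, method = method))[
      c("R0", "GRR", "T", "r_m", "lambda", "Dt")])
  }))
  all_ind <- do.call(rbind, lapply(sims, `[[`, "individuals"))
  all_eggs <- do.call(rbind, lapply(seq_along(sims), function(k) {
    e <- sims[[k]]$eggs
    if (nrow(e)) e$id <- e$id + (k - 1) * sims[[k]]$n
    e
  }))
  pooled <- schedule_from_individuals(all_ind, all_eggs)
  list(replicates = sims, params = params, pooled_schedule = pooled,
       pooled_params = life_table_params(pooled, method = method))
}
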