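#' Generate a synthetic interval-censored cohort observation table
#'
#' Emulates the constant-temperature life-table design used to parameterize
#' the model — a fixed number of newly laid eggs per temperature, daily
#' observation, per-stage binomial attrition, sexing at adult emergence and
#' lifetime fecundity per female — from known bundle parameters, so that the
#' fitting functions ([fit_aft()], [fit_lntime_model()],
#' [fit_mortality_model()], [fit_fecundity_model()]) can be tested for
#' parameter recovery without any external data.
#'
#' Stage durations are drawn from each stage's distribution link scaled by
#' the temperature-dependent median; the observed bounds are the bracketing
#' daily checks. Stage deaths occur with probability `m(T)` at a uniformly
#' drawn day within the stage. Adult survival and oviposition-end times use
#' the adult links; adults still alive at `study_days` are right-censored
#' (`upper = Inf`). Reported fecundity totals are completed lifetime
#' fecundities drawn around the temperature mean (death truncation is not
#' applied here; the generator targets the fitted-curve scale).
#'
#' @param bundle a model bundle.
#' @param n eggs per temperature (`>= 10`).
#' @param temps design temperatures, deg C.
#' @param seed integer seed.
#' @param study_days right-censoring horizon for adult events (days from
#'   adult emergence); `Inf` disables censoring.
#' @return data.frame with columns `id`, `stage`, `group` (deg C), `lower`,
#'   `upper` (days; `Inf` when right-censored), `event` (`"development"`,
#'   `"death"`, `"oviposition_end"`), `sex`; the per-female fecundity table
#'   (`id`, `group`, `eggs`) is attached as attribute `"fecundity"`.
#' @examples
#' obs <- generate_synthetic_cohort(default_bundle(), n = 50,
#'                                  temps = c(15, 20, 25), seed = 1)
#' head(obs)
#' @export
generate_synthetic_cohort <- function(bundle, n = 100,
                                      temps = c(10, 15, 18, 20, 25, 28, 32),
                                      seed = NULL, study_days = Inf) {
  validate_bundle(bundle)
  if (n < 10) stop("n must be at least 10 per temperature")
  if (!is.null(seed)) set.seed(seed)
  stages <- c("egg", "nymph", "puparium")
  rows <- list()
  fec <- list()
  idc <- 0L
  for (tmp in temps) {
    med <- vapply(stages, function(st) {
      1 / janisch_rate(bundle$development[[st]], tmp)
    }, numeric(1))
    mrt <- vapply(stages, function(st) {
      immature_mortality(bundle$mortality[[st]], tmp)
    }, numeric(1))
    for (i in seq_len(n)) {
      idc <- idc + 1L
      sex <- if (stats::runif(1) < bundle$sex_ratio) "female" else "male"
      alive <- TRUE
      for (s in seq_along(stages)) {
        dur <- med[s] * link_quantile(bundle$links[[stages[s]]], stats::runif(1))
        if (stats::runif(1) < mrt[s]) {
          dday <- floor(stats::runif(1, 0, dur))
          rows[[length(rows) + 1]] <- data.frame(
            id = idc, stage = stages[s], group = tmp, lower = dday,
            upper = dday + 1, event = "death", sex = NA_character_)
          alive <- FALSE
          break
        }
        rows[[length(rows) + 1]] <- data.frame(
          id = idc, stage = stages[s], group = tmp, lower = floor(dur),
          upper = floor(dur) + 1, event = "development", sex = NA_character_)
      }
      if (!alive) next
      role <- if (sex == "female") "female_survival" else "male_survival"
      surv <- adult_median_time(bundle$adult_timing, tmp, role) *
        link_quantile(bundle$links$adult_survival, stats::runif(1))
      cens <- surv > study_days
      rows[[length(rows) + 1]] <- data.frame(
        id = idc, stage = "adult", group = tmp,
        lower = if (cens) study_days else floor(surv),
        upper = if (cens) Inf else floor(surv) + 1,
        event = "death", sex = sex)
      if (sex == "female") {
        ovi <- adult_median_time(bundle$adult_timing, tmp, "oviposition") *
          link_quantile(bundle$links$oviposition, stats::runif(1))
        ocens <- ovi > study_days
        rows[[length(rows) + 1]] <- data.frame(
          id = idc, stage = "adult", group = tmp,
          lower = if (ocens) study_days else floor(ovi),
          upper = if (ocens) Inf else floor(ovi) + 1,
          event = "oviposition_end", sex = sex)
        fbar <- mean_fecundity(bundle$fecundity, tmp)
        s_f <- if (is.null(bundle$fecundity$sigma_ln)) 0 else bundle$fecundity$sigma_ln
        eggs <- if (s_f > 0) {
          stats::rlnorm(1, log(fbar) - s_f^2 / 2, s_f)
        } else fbar
        fec[[length(fec) + 1]] <- data.frame(id = idc, group = tmp, eggs = eggs)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fecundity") <- if (length(fec)) do.call(rbind, fec) else
    data.frame(id = integer(), group = numeric(), eggs = numeric())
  out
}

#' Read an observation table from delimited text
#'
#' Accepts comma- or tab-delimited files with a header; requires the columns
#' `lower`, `upper` and `group` used by [fit_aft()] (`upper` may contain
#' `"inf"` for right censoring) and passes through `id`, `stage`, `event`
#' and `sex` when present.
#'
#' @param path file path.
#' @return data.frame of observations.
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(d) == 1) d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lower", "upper", "group")
  if (!all(need %in% names(d))) {
    stop("observation table must have columns: ", paste(need, collapse = ", "))
  }
  d$upper <- suppressWarnings(as.numeric(ifelse(tolower(trimws(d$upper)) %in%
                                                  c("inf", "na", ""), Inf, d$upper)))
  d$lower <- as.numeric(d$lower)
  d
}
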