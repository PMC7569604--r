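#' Load, validate and save model bundles
#'
#' A model bundle collects every temperature-response submodel and
#' distribution link the simulator needs: Janisch development parameters per
#' immature stage, mortality parameters per stage (with the global optimum
#' temperature), adult timing constants, the fecundity curve with its
#' residual log-scale spread, median-normalized distribution links per
#' process, the sex ratio and the fluctuating-temperature adjustment
#' factors. Bundles are serialized as JSON; distribution links are restored
#' as [dist_link()] objects on load.
#'
#' @param path JSON file path.
#' @return a validated bundle (list) with class `model_bundle`.
#' @seealso [default_bundle()] for the packaged greenhouse-whitefly bundle.
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle file not found: ", path)
  b <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  b$links <- lapply(b$links, function(l) dist_link(l$family, l$delta))
  b <- structure(b, class = "model_bundle")
  validate_bundle(b)
  b
}

#' @rdname load_bundle
#' @param bundle a model bundle.
#' @export
save_bundle <- function(bundle, path) {
  validate_bundle(bundle)
  b <- unclass(bundle)
  b$links <- lapply(b$links, function(l) list(family = l$family, delta = l$delta))
  jsonlite::write_json(b, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The packaged greenhouse-whitefly model bundle
#'
#' Parameter values for *Trialeurodes vaporariorum* estimated from
#' constant-temperature life tables at 10-32 deg C: Janisch development
#' curves and AFT distribution links for egg, nymph and puparium, the joint
#' immature mortality model with a global optimum of 21.8 deg C, exponential
#' adult senescence/oviposition timing with additive sex factors, the
#' refitted fecundity curve, and the fluctuating-temperature adjustment
#' factors (mortality spread x1.3, adult times x2, fecundity x4).
#'
#' @return a `model_bundle`.
#' @examples
#' b <- default_bundle()
#' janisch_rate(b$development$egg, 27.4)
#' @export
default_bundle <- function() {
  load_bundle(system.file("extdata", "trialeurodes_vaporariorum.json",
                          package = "phenofly", mustWork = TRUE))
}

#' @rdname load_bundle
#' @export
validate_bundle <- function(bundle) {
  req_stages <- c("egg", "nymph", "puparium")
  for (blk in c("development", "mortality", "links", "adult_timing",
                "fecundity", "adjustment_factors")) {
    if (is.null(bundle[[blk]])) stop("bundle is missing the '", blk, "' block")
  }
  for (st in req_stages) {
    if (is.null(bundle$development[[st]])) {
      stop("development block is missing stage '", st, "'")
    }
    check_positive(bundle$development[[st]], c("D_min", "k"))
    if (is.null(bundle$mortality[[st]])) {
      stop("mortality block is missing stage '", st, "'")
    }
    check_positive(bundle$mortality[[st]], c("H", "B"))
  }
  for (lk in c(req_stages, "adult_survival", "oviposition")) {
    if (is.null(bundle$links[[lk]])) stop("links block is missing '", lk, "'")
    if (!inherits(bundle$links[[lk]], "dist_link")) {
      stop("link '", lk, "' is not a dist_link")
    }
  }
  check_positive(bundle$adult_timing, "intercept")
  check_positive(bundle$fecundity, c("Bl", "Bh"))
  sr <- bundle$sex_ratio
  if (!is.null(sr) && (sr < 0 || sr > 1)) stop("sex_ratio must lie in [0, 1]")
  invisible(TRUE)
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("Model bundle: %s%s\n",
              if (is.null(x$species)) "unnamed species" else x$species,
              if (isTRUE(x$adjusted)) " (fluctuating-temperature adjusted)" else ""))
  for (st in names(x$development)) {
    d <- x$development[[st]]
    cat(sprintf("  %-9s D_min %.2f d, T_opt %.1f C, k %.2f; %s link delta %.3f\n",
                st, d$D_min, d$T_opt, d$k,
                x$links[[st]]$family, x$links[[st]]$delta))
  }
  cat(sprintf("  mortality optimum %.1f C; fecundity peak near %.0f C\n",
              x$mortality[[1]]$T_opt,
              stats::optimize(function(T) -mean_fecundity(x$fecundity, T),
                              c(0, 40))$minimum))
  invisible(x)
}

# Polynomial rolling hash of the canonical JSON serialization; used by the
# command-line interface to log which bundle produced a run.
bundle_hash <- function(bundle) {
  b <- unclass(bundle)
  b$links <- lapply(b$links, function(l) list(family = l$family, delta = l$delta))
  s <- jsonlite::toJSON(b, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (v in utf8ToInt(as.character(s))) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}
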