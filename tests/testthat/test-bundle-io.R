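test_that("the packaged bundle loads, validates and evaluates", {
  b <- default_bundle()
  expect_s3_class(b, "model_bundle")
  expect_equal(janisch_rate(b$development$egg, 27.4), 0.2008, tolerance = 1e-4)
  expect_equal(b$links$egg$alpha, 1 / 0.044)
  expect_equal(b$sex_ratio, 0.5)
  expect_true(validate_bundle(b))
})

test_that("bundles round-trip through JSON and bad bundles fail loudly", {
  b <- default_bundle()
  b$development$egg$D_min <- 5.5
  b$mortality$nymph$B <- 1.33
  b$links$puparium <- dist_link("lognormal", 0.21)
  f <- withr::local_tempfile(fileext = ".json")
  save_bundle(b, f)
  b2 <- load_bundle(f)
  expect_equal(b2$development, b$development, tolerance = 1e-12)
  expect_equal(b2$mortality, b$mortality, tolerance = 1e-12)
  expect_equal(b2$links$puparium$family, "lognormal")
  expect_equal(b2$adjustment_factors, b$adjustment_factors, tolerance = 1e-12)

  bad <- default_bundle()
  bad$mortality$nymph <- NULL
  expect_error(validate_bundle(bad), "nymph")
  bad2 <- default_bundle()
  bad2$development$egg$D_min <- -1
  expect_error(validate_bundle(bad2), "positive")
})

test_that("synthetic cohorts mirror the experimental design structure", {
  b <- default_bundle()
  obs <- generate_synthetic_cohort(b, n = 60, temps = c(10, 20, 28), seed = 7)
  expect_true(all(c("id", "stage", "group", "lower", "upper", "event", "sex") %in%
                    names(obs)))
  expect_true(all(obs$upper > obs$lower))
  # attrition: far fewer individuals reach the puparium at 10 degC (m_egg ~ 0.84)
  n_pup <- function(g) {
    length(unique(obs$id[obs$group == g & obs$stage == "puparium" &
                           obs$event == "development"]))
  }
  expect_lt(n_pup(10), n_pup(20) / 2)
  fec <- attr(obs, "fecundity")
  expect_true(all(fec$eggs >= 0))
  # right-censoring is emitted when adults outlive the study horizon
  cens <- generate_synthetic_cohort(b, n = 60, temps = 20, seed = 8, study_days = 4)
  expect_true(any(is.infinite(cens$upper)))
})

test_that("generation followed by fitting recovers the generating parameters", {
  b <- default_bundle()
  devs <- numeric(0)
  set.seed(0)
  seeds <- 1:10
  topts <- vapply(seeds, function(sd) {
    obs <- generate_synthetic_cohort(b, n = 100,
                                     temps = c(10, 15, 18, 20, 25, 28, 32),
                                     seed = sd)
    eggs <- obs[obs$stage == "egg" & obs$event == "development", ]
    aft <- fit_aft(eggs, family = "loglogistic")
    jan <- fit_lntime_model(as.numeric(aft$medians$group), aft$medians$median)
    jan$parameters[["T_opt"]]
  }, numeric(1))
  expect_true(all(abs(topts - b$development$egg$T_opt) < 1))

  # near-deterministic generation (tiny link scales, negligible mortality)
  b0 <- b
  for (st in c("egg", "nymph", "puparium")) {
    b0$links[[st]] <- dist_link("loglogistic", 1e-3)
    b0$mortality[[st]]$H <- 1e-10
  }
  obs <- generate_synthetic_cohort(b0, n = 30, temps = c(10, 14, 18, 22, 26, 30),
                                   seed = 1)
  eggs <- obs[obs$stage == "egg" & obs$event == "development", ]
  med <- tapply((eggs$lower + eggs$upper) / 2, eggs$group, median)
  jan <- fit_lntime_model(as.numeric(names(med)), as.numeric(med))
  expect_within(jan$parameters[["T_opt"]], b$development$egg$T_opt, 0.5)
  expect_within(jan$parameters[["D_min"]], b$development$egg$D_min, 0.3)
})

test_that("the command-line interface runs end-to-end on generated fixtures", {
  cli <- system.file("cli", "phenofly.R", package = "phenofly")
  tmp <- withr::local_tempdir()
  # make sure the child process sees the same library as this session
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  run <- function(...) {
    res <- suppressWarnings(system2("Rscript", c(cli, ...), stdout = TRUE,
                                    stderr = TRUE))
    status <- attr(res, "status")
    list(out = res, status = if (is.null(status)) 0 else status)
  }

  obs_file <- file.path(tmp, "obs.csv")
  r1 <- run("synth", "--out", obs_file, "--n", "60", "--temps", "15,20,25,28",
            "--seed", "3")
  expect_equal(r1$status, 0)
  expect_true(file.exists(obs_file))

  r2 <- run("fit-dev", "--obs", obs_file, "--stage", "egg",
            "--family", "loglogistic")
  expect_equal(r2$status, 0)
  parsed <- jsonlite::fromJSON(paste(grep("^\\[phenofly\\]|^wrote", r2$out,
                                          invert = TRUE, value = TRUE),
                                     collapse = "\n"))
  expect_within(parsed$janisch$parameters$T_opt, 27.4, 2)

  sched_file <- file.path(tmp, "sched.csv")
  r3 <- run("simulate", "--constant", "24", "--n", "40", "--reps", "2",
            "--seed", "5", "--adjusted", "--out", sched_file)
  expect_equal(r3$status, 0)
  expect_true(file.exists(sched_file))

  r4 <- run("life-table", "--schedule", sched_file, "--method", "approximate")
  expect_equal(r4$status, 0)
  lt <- jsonlite::fromJSON(paste(grep("^\\[phenofly\\]", r4$out, invert = TRUE,
                                      value = TRUE), collapse = "\n"))
  expect_gt(lt$lambda, 1)

  # validation errors exit with a distinct status
  r5 <- run("life-table", "--schedule", file.path(tmp, "missing.csv"))
  expect_gt(r5$status, 0)
})
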