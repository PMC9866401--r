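cp_larva_truth <- tpc_params("briere1_99",
                             c(a = 3.3e-5, CTmin = 13.5, CTmax = 37.1))

test_that("zero-noise data recover the generating parameters exactly", {
  temps <- c(15, 18, 20, 25, 28, 30, 33, 36)
  obs <- noiseless_obs(cp_larva_truth, temps)
  fit <- suppressWarnings(fit_stage(obs, "briere1_99", seed = 1))
  expect_true(fit$converged)
  expect_equal(fit$params$values, cp_larva_truth$values, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  diag <- residual_diagnostics(fit)
  expect_equal(nrow(diag$table), length(temps))
  expect_true(all(abs(diag$table$residual) < 1e-8))
})

test_that("the AIC convention and its arithmetic hold", {
  expect_equal(tpc_aic(0.001, 10, 3), 10 * log(1e-4) + 8)
  expect_equal(tpc_aic(0.001, 10, 3), -84.103, tolerance = 1e-3)
  # equal RSS, one extra parameter -> exactly +2 AIC
  expect_equal(tpc_aic(0.05, 12, 4) - tpc_aic(0.05, 12, 3), 2)
  expect_warning(res <- tpc_aic(0, 10, 3), "perfect fit")
  expect_identical(res, -Inf)
  expect_error(tpc_aic(-1, 10, 3), "negative")
})

test_that("too few observations for the parameter count is an error", {
  obs <- noiseless_obs(cp_larva_truth, c(20, 25, 30))
  expect_error(fit_stage(obs, "analytis_77"), "insufficient data")
})

test_that("the selection ledger orders and filters fits as specified", {
  make_fit <- function(model, values, rss, n) {
    k <- length(values)
    structure(list(species = "x", stage = "larva", model = model,
                   params = tpc_params(model, values),
                   stderrs = setNames(rep(NA_real_, k), names(values)),
                   rss = rss, n_obs = n, aic = tpc_aic(rss, n, k),
                   delta_aic = NA_real_, traits = NULL, converged = TRUE,
                   status = "unranked", observations = NULL),
              class = "stage_fit")
  }
  n <- 12
  f_small <- make_fit("briere1_99", c(a = 3e-5, CTmin = 13, CTmax = 37),
                      rss = 0.004, n = n)
  f_big <- make_fit("briere2_99", c(a = 3e-5, b = 2, CTmin = 13, CTmax = 37),
                    rss = 0.004, n = n)
  f_cold <- make_fit("kontodimas_04", c(a = 5e-5, CTmin = -1.2, CTmax = 40),
                     rss = 0.005, n = n)
  f_hot <- make_fit("perf2_11", c(c = 9e-3, k = 0.9, CTmin = 12, CTmax = 51),
                    rss = 0.0045, n = n)
  f_bad <- make_fit("analytis_77", c(a = 1e-4, b = 2, c = 1, CTmin = 12,
                                     CTmax = 38), rss = 0.03, n = n)

  sel <- select_model(list(f_cold, f_small, f_big, f_hot, f_bad))
  status <- setNames(vapply(sel$fits, function(f) f$status, character(1)),
                     vapply(sel$fits, function(f) f$model, character(1)))
  # biological filters beat AIC rank: the lowest-AIC fit has CTmin < 0
  expect_identical(unname(status["kontodimas_04"]), "discarded_biology")
  expect_identical(unname(status["perf2_11"]), "discarded_biology")
  expect_identical(unname(status["analytis_77"]), "discarded_aic")
  # equal RSS, one parameter more: exactly +2 AIC, smaller model wins
  expect_equal(f_big$aic - f_small$aic, 2)
  expect_identical(sel$selected$model, "briere1_99")
  expect_identical(unname(status["briere2_99"]), "equivalent")

  # a single converged fit passing the filters is returned as-is
  one <- select_model(list(f_small))
  expect_identical(one$selected$model, "briere1_99")
  expect_equal(one$selected$delta_aic, 0)

  # no survivor -> error naming the casualties
  expect_error(select_model(list(f_cold, f_hot)), "no fit survives")
})

test_that("selection depends only on AIC differences, not the constant", {
  temps <- c(15, 17, 19, 21, 24, 27, 30, 32, 34, 36)
  set.seed(42)
  obs <- noiseless_obs(cp_larva_truth, temps)
  obs$mean_dev_time_days <- obs$mean_dev_time_days * exp(rnorm(10, 0, 0.05))
  obs$rate <- NULL
  fits <- lapply(c("briere1_99", "kontodimas_04", "perf2_11"),
                 function(m) fit_stage(obs, m, seed = 3))
  sel1 <- select_model(fits)
  shifted <- lapply(fits, function(f) { f$aic <- f$aic + 57.3; f })
  sel2 <- select_model(shifted)
  expect_identical(sel1$selected$model, sel2$selected$model)
  expect_equal(vapply(sel1$fits, function(f) f$delta_aic, numeric(1)),
               vapply(sel2$fits, function(f) f$delta_aic, numeric(1)))
})

test_that("refitting with permuted observation order gives the same fit", {
  temps <- c(15, 18, 20, 25, 28, 30, 33, 36)
  set.seed(9)
  obs <- noiseless_obs(cp_larva_truth, temps)
  obs$mean_dev_time_days <- obs$mean_dev_time_days * exp(rnorm(8, 0, 0.08))
  obs$rate <- NULL
  f1 <- fit_stage(obs, "briere1_99", seed = 5)
  f2 <- fit_stage(obs[sample(nrow(obs)), ], "briere1_99", seed = 5)
  expect_equal(f1$params$values, f2$params$values, tolerance = 1e-8)
})

test_that("noisy synthetic data recover CTmax within two standard errors", {
  sm <- species_model("cp", cp_larva_truth, cp_larva_truth, cp_larva_truth,
                      cv = 0.15)
  obs <- suppressMessages(
    generate_observations(sm, c(18, 20, 25, 30, 32, 35), n_reps = 50,
                          cv = 0.15, seed = 77))
  fit <- fit_stage(obs[obs$stage == "larva", ], "briere1_99", seed = 2)
  expect_true(fit$converged)
  err <- abs(fit$params$values[["CTmax"]] - 37.1)
  expect_lt(err, 2 * fit$stderrs[["CTmax"]] + 1e-9)
})

test_that("residual diagnostics behave on seeded noisy fits", {
  temps <- c(15, 17, 19, 21, 24, 27, 30, 32, 34, 36)
  set.seed(21)
  obs <- noiseless_obs(cp_larva_truth, temps)
  obs$mean_dev_time_days <- obs$mean_dev_time_days * exp(rnorm(10, 0, 0.04))
  obs$rate <- NULL
  fit <- fit_stage(obs, "briere1_99", seed = 1)
  d <- residual_diagnostics(fit)
  expect_equal(nrow(d$table), 10)
  expect_gt(d$shapiro_p, 0.01)
  expect_true(is.finite(d$scale_location_slope))
})

test_that("study-effect ANOVA flags an injected offset and not a null", {
  truth <- stemborer_models()[["chilo_partellus"]]
  temps <- c(18, 20, 25, 30, 32, 35)
  # null: two studies drawn from the same process
  obs0 <- suppressMessages(
    generate_observations(truth, temps, n_reps = 50, cv = 0.15,
                          study_offsets = c(A = 1, B = 1), seed = 31))
  f0 <- fit_stage(obs0[obs0$stage == "larva", ], "briere1_99", seed = 1)
  chk0 <- study_effect_check(f0)
  expect_true(chk0$applicable)
  expect_gt(chk0$p, 0.01)
  # +20% development-time offset in study B
  obs1 <- suppressMessages(
    generate_observations(truth, temps, n_reps = 50, cv = 0.15,
                          study_offsets = c(A = 1, B = 1.2), seed = 31))
  f1 <- fit_stage(obs1[obs1$stage == "larva", ], "briere1_99", seed = 1)
  expect_lt(study_effect_check(f1)$p, 0.01)
  # single study: not applicable
  obs2 <- obs1[obs1$study_id == "A" & obs1$stage == "larva", ]
  f2 <- fit_stage(obs2, "briere1_99", seed = 1)
  expect_false(study_effect_check(f2)$applicable)
})
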