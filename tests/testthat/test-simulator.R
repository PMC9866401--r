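models <- stemborer_models()
cp <- models[["chilo_partellus"]]
bf <- models[["busseola_fusca"]]

test_that("individual rate draws follow the truncated-normal stage model", {
  st <- sim_settings(n_individuals = 5000, seed = 4)
  # cv = 0 collapses to the deterministic stage rates
  cp0 <- stemborer_models(cv = 0)[["chilo_partellus"]]
  r0 <- draw_individual_rates(cp0, 25, st)
  taus <- vapply(cp0$stages, tpc_rate, numeric(1), temp = 25)
  expect_equal(unname(r0[1, ]), unname(taus), tolerance = 1e-12)
  expect_true(all(apply(r0, 2, function(x) length(unique(x)) == 1)))
  # a stage outside its thermal domain contributes an all-zero column
  r5 <- draw_individual_rates(cp, 5, st)
  expect_true(all(r5 == 0))
  # sample mean of 5000 truncated-normal draws at tau = 0.1, cv = 0.15:
  # truncation mass at 6.7 sigma is negligible, so mean = 0.1 +- 3 s.e.
  one <- tpc_params("kontodimas_04", c(a = 1, CTmin = 0, CTmax = 50))
  sc <- 0.1 / tpc_rate(one, 25)
  flat <- tpc_params("kontodimas_04", c(a = sc, CTmin = 0, CTmax = 50))
  smod <- species_model("synthetic_sp", flat, flat, flat, cv = 0.15)
  r <- draw_individual_rates(smod, 25, st)
  se <- 0.15 * 0.1 / sqrt(5000)
  expect_lt(abs(mean(r[, 1]) - 0.1), 3 * se)
  expect_error(species_model("x", flat, flat, flat, cv = -0.1), "cv")
})

test_that("draws are deterministic under the seed and stable across grids", {
  st <- sim_settings(n_individuals = 1000, seed = 12)
  expect_identical(draw_individual_rates(cp, 25, st),
                   draw_individual_rates(cp, 25, st))
  # the per-temperature stream does not depend on other grid points
  a <- simulate_dev_times(cp, 25, st)$times
  invisible(simulate_dev_times(cp, 30, st))
  b <- simulate_dev_times(cp, 25, st)$times
  expect_identical(a, b)
})

test_that("cv = 0 total time is the deterministic stage-time sum", {
  bf0 <- stemborer_models(cv = 0)[["busseola_fusca"]]
  st <- sim_settings(n_individuals = 100, seed = 1)
  d <- simulate_dev_times(bf0, 15.2, st)
  # 19.46 + 123.07 + 38.84 days by direct arithmetic on the stage curves
  expect_equal(d$mean, 181.3701, tolerance = 1e-3)
  expect_equal(d$q2.5, d$q97.5)
  expect_equal(d$failure_fraction, 0)  # 181.37 <= 182: deadline is inclusive
})

test_that("temperatures below every CTmin fail completely", {
  st <- sim_settings(seed = 2)
  d <- simulate_dev_times(cp, 5, st)
  expect_identical(d$failure_fraction, 1)
  expect_true(all(is.infinite(d$times)))
})

test_that("simulated failure fractions match numeric integration", {
  st <- sim_settings(n_individuals = 5000, seed = 8)
  for (sp in list(cp, bf)) {
    ctmin <- max(vapply(sp$stages, function(s) s$values[["CTmin"]], 1))
    ctmax <- min(vapply(sp$stages, function(s) s$values[["CTmax"]], 1))
    temps <- seq(ctmin + 1, ctmax - 0.5, length.out = 5)
    for (T in temps) {
      mc <- simulate_dev_times(sp, T, st)$failure_fraction
      quad <- failure_prob_quadrature(sp, T, st$deadline_days)
      expect_lt(abs(mc - quad), 0.02)
    }
  }
})

test_that("median simulated time tracks the deterministic sum at cv=0.15", {
  st <- sim_settings(seed = 19)
  for (T in c(20, 25, 28, 30)) {
    det <- 1 / total_rate_curve(cp, T)
    med <- simulate_dev_times(cp, T, st)$median
    expect_lt(abs(med - det) / det, 0.02)
  }
})

test_that("failure fraction is non-increasing in the deadline", {
  r <- draw_individual_rates(cp, 18, sim_settings(seed = 3))
  d <- rowSums(1 / r)
  fracs <- vapply(c(120, 150, 182, 250, 400), function(D) mean(d > D),
                  numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("thermal windows hit the published anchors for the two
           reproducible species", {
  st <- sim_settings(seed = 6)
  wcp <- thermal_window(cp, st)
  expect_equal(wcp$T50min, 16.6, tolerance = 0.2)
  expect_equal(wcp$T50max, 37.1, tolerance = 0.2)
  wbf <- thermal_window(bf, st)
  expect_equal(wbf$T50min, 15.2, tolerance = 0.2)
  expect_equal(wbf$T50max, 33.0, tolerance = 0.2)
})

test_that("window bounds stay inside the joint stage thermal domain", {
  st <- sim_settings(seed = 13)
  for (sp in models) {
    w <- thermal_window(sp, st)
    ctmin <- max(vapply(sp$stages, function(s) s$values[["CTmin"]], 1))
    ctmax <- min(vapply(sp$stages, function(s) s$values[["CTmax"]], 1))
    expect_false(isTRUE(w$empty))
    expect_gte(w$T50min, ctmin)
    expect_lte(w$T50max, ctmax)
    expect_lte(w$T50min, w$T50max)
  }
})

test_that("cv = 0 window equals the deterministic deadline crossings", {
  cp0 <- stemborer_models(cv = 0)[["chilo_partellus"]]
  st <- sim_settings(n_individuals = 200, seed = 1)
  w <- thermal_window(cp0, st, refine_tol = 0.01)
  cross <- deterministic_crossings(cp0, 182)
  expect_equal(w$T50min, cross[1], tolerance = 0.02)
  expect_equal(w$T50max, cross[2], tolerance = 0.02)
})

test_that("doubling the cohort size leaves the window essentially unchanged", {
  w1 <- thermal_window(cp, sim_settings(n_individuals = 5000, seed = 10),
                       refine_tol = 0.01)
  w2 <- thermal_window(cp, sim_settings(n_individuals = 10000, seed = 10),
                       refine_tol = 0.01)
  expect_lt(abs(w1$T50min - w2$T50min), 0.05)
  expect_lt(abs(w1$T50max - w2$T50max), 0.05)
})

test_that("the total-rate curve is the harmonic combination of stages", {
  expect_equal(total_rate_curve(cp, 25), 0.02206, tolerance = 1e-3)
  expect_identical(total_rate_curve(cp, 12), 0)  # egg develops, larva does not
  grid <- seq(0, 50, by = 0.5)
  r <- total_rate_curve(cp, grid)
  # the harmonic sum is bounded by the slowest stage everywhere
  stage_rates <- vapply(cp$stages, tpc_rate, numeric(length(grid)),
                        temp = grid)
  expect_true(all(r <= apply(stage_rates, 1, min) + 1e-12))
})

test_that("rmax sits between the stage optima and scales homogeneously", {
  rm1 <- total_rmax(cp)
  topts <- vapply(cp$stages, function(s) tpc_traits(s)$Topt, 1)
  expect_gte(rm1$T_at_rmax, min(topts))
  expect_lte(rm1$T_at_rmax, max(topts))
  # doubling every stage scale doubles rmax, argmax unchanged
  dbl <- lapply(cp$stages, function(s) {
    v <- s$values
    v[[if ("a" %in% names(v)) "a" else "c"]] <-
      2 * v[[if ("a" %in% names(v)) "a" else "c"]]
    tpc_params(s$model, v)
  })
  cp2 <- species_model("cp2", dbl$egg, dbl$larva, dbl$pupa)
  rm2 <- total_rmax(cp2)
  expect_equal(rm2$rmax, 2 * rm1$rmax, tolerance = 1e-10)
  expect_equal(rm2$T_at_rmax, rm1$T_at_rmax, tolerance = 1e-9)
})
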