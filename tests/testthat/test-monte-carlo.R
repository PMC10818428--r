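tox <- default_toxicology()
es <- element_set()

point_exposure_dists <- function(profile) {
  nms <- c("ingestion_rate", "exposure_frequency", "exposure_duration",
           "body_weight", "skin_area", "adherence_factor",
           "dermal_absorption", "inhalation_rate", "pef")
  setNames(lapply(nms, function(nm) dist_spec("point", value = profile[[nm]])),
           nms)
}

point_conc_dists <- function(values) {
  lapply(values, function(v) dist_spec("point", value = v))
}

test_that("invalid distribution parameters fail before sampling", {
  expect_error(dist_spec("normal", mean = 1), "sd")
  expect_error(dist_spec("triangular", min = 3, mode = 2, max = 1), "min")
  expect_error(dist_spec("uniform", min = 2, max = 1), "min < max")
  expect_error(dist_spec("point", value = 1, lower = 2, upper = 1), "lower")
})

test_that("triangular sampling matches its analytic mean and support", {
  set.seed(2)
  x <- sample_dist(dist_spec("triangular", min = 180, mode = 350, max = 365),
                   20000)
  expect_true(all(x >= 180 & x <= 365))
  expect_equal(mean(x), (180 + 350 + 365) / 3, tolerance = 0.01)
})

test_that("truncation bounds are honoured", {
  set.seed(3)
  x <- sample_dist(dist_spec("normal", mean = 0, sd = 5, lower = 0), 5000)
  expect_true(all(x >= 0))
})

test_that("point-mass distributions reproduce the deterministic model
           exactly", {
  prof <- default_exposure_profiles()$child
  conc <- lumped_rey_conc(240.5)
  vals <- setNames(as.numeric(as.data.frame(conc)[1, es$reys]), es$reys)
  det_hi <- hazard(conc, prof, tox, es$reys)$summary$hi
  det_tcr <- cancer_risk(conc, prof, tox, es$reys)$summary$tcr
  for (ep in c("HI", "TCR")) {
    r <- run_mcs(point_conc_dists(vals), point_exposure_dists(prof),
                 tox, receptor = "child", endpoint = ep, n = 50, seed = 4)
    expect_equal(r$sd, 0)
    expect_equal(r$mean, if (ep == "HI") det_hi else det_tcr)
    expect_equal(unname(r$percentiles[["50%"]]), r$mean)
  }
})

test_that("identical seed and config give identical results", {
  prof <- default_exposure_profiles()$adult
  cd <- point_conc_dists(setNames(as.numeric(serbia_fly_means()), es$reys))
  r1 <- run_mcs(cd, tox = tox, receptor = "adult", endpoint = "HI",
                n = 200, seed = 99)
  r2 <- run_mcs(cd, tox = tox, receptor = "adult", endpoint = "HI",
                n = 200, seed = 99)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$sensitivity, r2$sensitivity)
  r3 <- run_mcs(cd, tox = tox, receptor = "adult", endpoint = "HI",
                n = 1, seed = 99)
  r4 <- run_mcs(cd, tox = tox, receptor = "adult", endpoint = "HI",
                n = 1, seed = 99)
  expect_identical(r3$draws, r4$draws)
})

test_that("with only body weight varying its sensitivity is -1 and the
           rest are degenerate", {
  prof <- default_exposure_profiles()$child
  ed <- point_exposure_dists(prof)
  ed$body_weight <- dist_spec("normal", mean = prof$body_weight,
                              sd = 0.2 * prof$body_weight, lower = 1)
  cd <- point_conc_dists(setNames(as.numeric(serbia_fly_means()), es$reys))
  r <- run_mcs(cd, ed, tox, receptor = "child", endpoint = "HI",
               n = 500, seed = 8)
  expect_equal(unname(r$sensitivity[["body_weight"]]), -1)
  rk <- sensitivity_ranking(r)
  expect_identical(rk$variable[1], "body_weight")
  expect_equal(nrow(rk), 1)   # all other inputs are point masses
})

test_that("default distributions rank BW, IR and EF as the sensitive
           exposure factors", {
  conc <- generate_concentrations(generator_config(seed = 15))
  cd <- conc_dists_from_table(conc, es$reys)
  r <- run_mcs(cd, tox = tox, receptor = "child", endpoint = "HI",
               n = 4000, seed = 16)
  rk <- sensitivity_ranking(r)
  exposure_vars <- rk$variable[!startsWith(rk$variable, "conc_")]
  expect_setequal(exposure_vars,
                  c("body_weight", "ingestion_rate", "exposure_frequency"))
  # and their sensitivities are non-trivial
  expect_true(all(rk$abs_rho[match(exposure_vars, rk$variable)] > 0.1))
})

test_that("tied sensitivities rank alphabetically", {
  r <- structure(list(sensitivity = c(b_var = 0.5, a_var = -0.5, zz = 0.9)),
                 class = "mcs_result")
  rk <- sensitivity_ranking(r)
  expect_identical(rk$variable, c("zz", "a_var", "b_var"))
})

test_that("the MCS mean converges to the deterministic value at the
           distribution means", {
  prof <- default_exposure_profiles()$child
  ed <- point_exposure_dists(prof)
  # symmetric variation in body weight alone biases the mean upward only
  # through 1/BW nonlinearity; use concentration noise (linear) instead
  cd <- lapply(setNames(as.numeric(serbia_fly_means()), es$reys),
               function(mu) dist_spec("normal", mean = mu, sd = 0.05 * mu,
                                      lower = 0))
  r <- run_mcs(cd, ed, tox, receptor = "child", endpoint = "HI",
               n = 10000, seed = 21)
  det <- hazard(conc_row(serbia_fly_means()), prof, tox, es$reys)$summary$hi
  se <- r$sd / sqrt(r$n_iterations)
  expect_lt(abs(r$mean - det), 3 * se)
})

test_that("percentiles are monotone and exceedance is a probability", {
  conc <- generate_concentrations(generator_config(seed = 33))
  cd <- conc_dists_from_table(conc, es$reys)
  r <- run_mcs(cd, tox = tox, receptor = "child", endpoint = "HI",
               n = 2000, seed = 34)
  expect_true(all(diff(r$percentiles) >= 0))
  expect_gte(r$exceedance_prob, 0)
  expect_lte(r$exceedance_prob, 1)
  expect_equal(r$exceedance_prob, 0)  # REY hazard is far below HI = 1
})

test_that("a seed is required and n validated", {
  cd <- point_conc_dists(c(La = 10))
  expect_error(run_mcs(cd, tox = tox, endpoint = "HI", n = 10), "seed")
  expect_error(run_mcs(cd, tox = tox, endpoint = "HI", n = 0, seed = 1),
               "n must be")
})
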