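# Decay coefficients, thermal sums, benthic temperature inference and the
# Tea Bag Index.

test_that("thermal_sum handles constant, sub-zero and sinusoidal series", {
  expect_equal(thermal_sum(make_series(30, 10),
                           as.POSIXct("2016-10-25", tz = "UTC"),
                           as.POSIXct("2016-11-24", tz = "UTC")), 300)
  suppressWarnings(
    expect_equal(thermal_sum(make_series(10, -2),
                             as.POSIXct("2016-10-25", tz = "UTC"),
                             as.POSIXct("2016-11-04", tz = "UTC")), 0))
  # diel sinusoid 10 +/- 5 C: daily means are 10 C, so 30 days = 300 dd
  sinser <- make_series(30, function(h) 10 + 5 * sin(2 * pi * h / 24))
  expect_equal(thermal_sum(sinser, as.POSIXct("2016-10-25", tz = "UTC"),
                           as.POSIXct("2016-11-24", tz = "UTC")),
               300, tolerance = 0.1 / 300)
})

test_that("thermal_sum is additive at a day boundary and validates input", {
  ser <- make_series(20, function(h) 8 + 3 * sin(2 * pi * h / 24) +
                       0.1 * h / 24)
  a <- as.POSIXct("2016-10-25", tz = "UTC")
  b <- as.POSIXct("2016-11-01", tz = "UTC")
  c <- as.POSIXct("2016-11-13", tz = "UTC")
  expect_equal(thermal_sum(ser, a, b) + thermal_sum(ser, b, c),
               thermal_sum(ser, a, c))
  expect_error(thermal_sum(ser, b, a), "after")
  expect_error(thermal_sum(ser, a + 100 * 86400, a + 101 * 86400),
               "no temperature readings")
  bad <- ser[c(2, 1, 3:10), ]
  expect_error(thermal_sum(bad, a, c), "strictly increasing")
})

test_that("benthic inference recovers an exact linear map and the identity", {
  hz <- make_series(10, function(h) 8 + 2 * sin(2 * pi * h / 24))
  idx <- c(10, 300, 700, 1100)
  spots <- data.frame(timestamp = hz$timestamp[idx],
                      celsius = 1.2 * hz$celsius[idx] + 0.5)
  fit <- infer_benthic_temperature(spots, hz)
  expect_equal(fit$slope, 1.2, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$series$celsius, 1.2 * hz$celsius + 0.5,
               tolerance = 1e-10)

  ident <- infer_benthic_temperature(
    data.frame(timestamp = hz$timestamp[idx], celsius = hz$celsius[idx]),
    hz)
  expect_equal(ident$series$celsius, hz$celsius, tolerance = 1e-10)
})

test_that("benthic inference is unbiased under noise and rejects degenerate input", {
  set.seed(42)
  hz <- make_series(10, function(h) 8 + 2 * sin(2 * pi * h / 24))
  ests <- t(replicate(200, {
    idx <- sort(sample(nrow(hz), 12))
    spots <- data.frame(timestamp = hz$timestamp[idx],
                        celsius = 0.5 + 1.2 * hz$celsius[idx] +
                          rnorm(12, 0, 0.3))
    fit <- infer_benthic_temperature(spots, hz)
    c(fit$slope, fit$intercept)
  }))
  expect_lt(abs(mean(ests[, 1]) - 1.2), 3 * sd(ests[, 1]) / sqrt(200))
  expect_lt(abs(mean(ests[, 2]) - 0.5), 3 * sd(ests[, 2]) / sqrt(200))

  expect_error(infer_benthic_temperature(
    data.frame(timestamp = hz$timestamp[1:2], celsius = 1:2), hz),
    "at least 3")
  flat <- make_series(5, 7)
  spots <- data.frame(timestamp = flat$timestamp[c(1, 100, 200)],
                      celsius = c(7.1, 7.2, 7.0))
  expect_error(infer_benthic_temperature(spots, flat), "zero variance")
  # spot far outside the logger span does not count as matched
  far <- data.frame(timestamp = hz$timestamp[c(1, 2, 3)] + c(0, 0, 1e7),
                    celsius = c(8, 8, 8))
  expect_error(infer_benthic_temperature(far, hz), "matched")
})

test_that("decay coefficient matches the closed form and its invariances", {
  expect_equal(decay_coefficient(1, 1, 123), 0)
  expect_equal(decay_coefficient(1, 0.5, 1000), log(2) / 1000)
  # scale invariance
  expect_equal(decay_coefficient(3.7, 1.85, 400),
               decay_coefficient(1, 0.5, 400))
  # monotonicity
  k <- decay_coefficient(1, c(0.8, 0.6, 0.4), 500)
  expect_true(all(diff(k) > 0))
  expect_gt(decay_coefficient(1, 0.5, 300), decay_coefficient(1, 0.5, 600))
  # degenerate and noisy inputs
  expect_error(decay_coefficient(1, 0, 100), "infinite")
  expect_error(decay_coefficient(0, 0.5, 100), "positive")
  expect_warning(k0 <- decay_coefficient(1, 1.05, 100), "clamped")
  expect_equal(k0, 0)
})

test_that("tea bag index matches its closed forms and flags edge cases", {
  # green decomposed exactly its hydrolysable fraction -> S = 0
  r1 <- tea_bag_index(1, 1 - 0.842, 1, 0.7, 1000)
  expect_equal(r1$S, 0)
  expect_equal(r1$a_r, 0.552)
  # green decomposed 0.6315 -> S = 0.25, a_r = 0.414
  r2 <- tea_bag_index(1, 1 - 0.6315, 1, 0.8, 1000)
  expect_equal(r2$S, 0.25)
  expect_equal(r2$a_r, 0.552 * 0.75)
  # S = 0, rooibos remaining 0.700, t = 1000 -> K ~ 7.84e-4
  r3 <- tea_bag_index(1, 1 - 0.842, 1, 0.700, 1000)
  expect_equal(r3$K, -log((0.700 - 0.448) / 0.552) / 1000)
  expect_equal(r3$K, 7.84e-4, tolerance = 1e-3)
  # rooibos at/below its recalcitrant floor: K undefined, flagged not thrown
  r4 <- tea_bag_index(1, 1 - 0.842, 1, 0.44, 1000)
  expect_true(r4$k_undefined)
  expect_true(is.na(r4$K))
  # green decomposed beyond the labile pool: S < 0, flagged
  r5 <- tea_bag_index(1, 0.10, 1, 0.7, 1000)
  expect_lt(r5$S, 0)
  expect_true(r5$s_out_of_range)
})

test_that("TBI round trip recovers S and K from generated masses", {
  params <- tbi_parameters()
  grid <- expand.grid(S = c(0, 0.1, 0.25, 0.4), K = c(5e-4, 1e-3, 3e-3),
                      t_dd = c(250, 480, 900))
  for (i in seq_len(nrow(grid))) {
    S <- grid$S[i]; K <- grid$K[i]; t_dd <- grid$t_dd[i]
    a_r <- params$h_rooibos * (1 - S)
    green_final <- 1 - params$h_green * (1 - S)
    rooibos_final <- a_r * exp(-K * t_dd) + (1 - a_r)
    out <- tea_bag_index(1, green_final, 1, rooibos_final, t_dd, params)
    expect_equal(out$S, S, tolerance = 1e-9)
    expect_equal(out$K, K, tolerance = 1e-9)
  }
})

test_that("decay_table computes per-bioassay metrics from raw tables", {
  sim <- simulate_study(design = study_design(n_catchments = 2,
                                              streams_per_catchment = 2),
                        seed = 3, tables = "core")
  dk <- decay_table(sim$assays, sim$temperatures, sim$spot_pairs)
  expect_setequal(dk$bioassay_id, sim$analysis$bioassay_id)
  m <- match(sim$analysis$bioassay_id, dk$bioassay_id)
  expect_equal(dk$t_dd[m], sim$analysis$t_dd)
  expect_equal(dk$k_green[m], sim$analysis$k_green, tolerance = 1e-12)
  expect_equal(dk$k_cotton[m], sim$analysis$k_cotton, tolerance = 1e-12)
  expect_equal(dk$S[m], sim$analysis$S, tolerance = 1e-12)
  expect_error(decay_table(sim$assays, sim$temperatures, NULL),
               "spot_pairs")
})
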