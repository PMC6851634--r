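# The forward simulator: determinism, configured effects, positivity
# guards, and the forward/inverse round trip.

test_that("the same seed and configuration give an identical bundle", {
  d <- study_design(n_catchments = 2, streams_per_catchment = 2)
  s1 <- simulate_study(d, seed = 7)
  s2 <- simulate_study(d, seed = 7)
  for (t in c("sites", "assays", "temperatures", "spot_pairs", "organisms",
              "volumes", "prokaryotes", "ecoplates", "analysis")) {
    expect_identical(s1[[t]], s2[[t]])
  }
  s3 <- simulate_study(d, seed = 8)
  expect_false(identical(s1$analysis, s3$analysis))
  # skipping the biology tables does not change the analysis table
  s4 <- simulate_study(d, seed = 7, tables = "core")
  expect_identical(s1$analysis, s4$analysis)
})

test_that("zone means of the mediators converge to the configured shifts", {
  sim <- simulate_study(
    study_design(replicates_per_zone = 40),
    effects = single_mediator_config(), seed = 12, tables = "core")
  a <- sim$analysis
  diff_hat <- mean(a$biofilm[a$zone == "BZ"]) -
    mean(a$biofilm[a$zone == "HZ"])
  se <- sqrt(var(a$biofilm[a$zone == "BZ"]) / sum(a$zone == "BZ") +
               var(a$biofilm[a$zone == "HZ"]) / sum(a$zone == "HZ"))
  # clustered draws make the i.i.d. SE optimistic; 3x that scale still
  # brackets the configured 1 SD shift
  expect_lt(abs(diff_hat - 1.0), 3 * se * 3)
})

test_that("the recorded truth matches the closed-form decomposition", {
  cfg <- single_mediator_config()    # direct 0.5, a = 1, b = 0.5
  expect_equal(cfg$total_effect, 1.0)
  expect_equal(cfg$proportion_mediated, 0.5)
  sim <- simulate_study(study_design(n_catchments = 2,
                                     streams_per_catchment = 2),
                        effects = cfg, seed = 3, tables = "core")
  tr <- sim$truth$effects
  expect_equal(tr$c, rep(1.0, 3))
  expect_equal(tr$proportion_mediated, rep(0.5, 3))
  # null configuration: no effect anywhere
  cfg0 <- effect_config(c(biofilm = 0), c(biofilm = 0), 0, k_intercept = 5,
                        noise_sd_k = 0.5)
  expect_true(is.na(cfg0$proportion_mediated))
})

test_that("configurations implying non-positive decay rates are rejected", {
  bad <- effect_config(c(m = 1), c(m = 0.1), -4.9,
                       k_intercept = 5, noise_sd_k = 0.5,
                       site_intercept_sd = 0.2)
  expect_error(simulate_study(study_design(2, 2), effects = bad),
               "expected k <= 0")
  bad2 <- effect_config(c(m = 0), c(m = 0), 0, k_intercept = 0.5,
                        noise_sd_k = 0.1, site_intercept_sd = 0.4)
  expect_error(simulate_study(study_design(2, 2), effects = bad2),
               "expected k <= 0")
})

test_that("noise-free forward simulation is inverted exactly by the decay module", {
  sim <- simulate_study(study_design(n_catchments = 2,
                                     streams_per_catchment = 2),
                        seed = 9, noise_free = TRUE, tables = "core")
  dk <- decay_table(sim$assays, sim$temperatures, sim$spot_pairs)
  m <- match(sim$analysis$bioassay_id, dk$bioassay_id)
  for (col in c("k_green", "k_red", "k_cotton")) {
    rel <- abs(dk[[col]][m] - sim$analysis[[col]]) / sim$analysis[[col]]
    expect_lt(max(rel), 1e-6)          # >= 6 significant digits
  }
  expect_lt(max(abs(dk$S[m] - sim$analysis$S)), 1e-9)
})

test_that("simulated tables respect their container invariants", {
  sim <- simulate_study(study_design(n_catchments = 2,
                                     streams_per_catchment = 2), seed = 10)
  expect_true(all(sim$volumes$volume_l >= 0.038 &
                    sim$volumes$volume_l <= 0.045))
  expect_true(all(sim$assays$initial > 0))
  expect_true(all(sim$assays$final >= 0))
  expect_true(all(sim$analysis$t_dd > 0))
  expect_true(all(table(sim$assays$bioassay_id) == 3))  # three substrates
  expect_true(all(sim$organisms$count >= 1))
  expect_true(all(sim$organisms$length_um >= sim$organisms$width_um))
  # temperature series at a strict 10-minute step within each site
  one <- sim$temperatures[sim$temperatures$site == sim$sites$site[1], ]
  expect_true(all(diff(as.numeric(one$timestamp)) == 600))
})

test_that("write_study / read_study round-trip the bundle", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(study_design(n_catchments = 1,
                                     streams_per_catchment = 2), seed = 4)
  write_study(sim, dir)
  back <- read_study(dir)
  expect_equal(nrow(back$assays), nrow(sim$assays))
  expect_equal(back$analysis$k_green, sim$analysis$k_green,
               tolerance = 1e-12)
  expect_equal(as.numeric(back$temperatures$timestamp[1:5]),
               as.numeric(sim$temperatures$timestamp[1:5]))
  expect_equal(back$truth_effects$proportion_mediated,
               sim$truth$effects$proportion_mediated, tolerance = 1e-12)
})
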