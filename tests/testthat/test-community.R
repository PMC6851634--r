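# Carbon biomass from counts/dimensions and Hill-number rarefaction.

test_that("individual carbon follows the ellipsoid biovolume model", {
  coefs <- carbon_coefficients()
  # sphere when L = W
  expect_equal(individual_carbon(50, 50, "eumetazoa"),
               coefs$eumetazoa$cv * (pi / 6 * 50^3)^coefs$eumetazoa$exp)
  # doubling all linear dimensions multiplies biovolume by 8
  v_ratio <- (individual_carbon(200, 100, "eumetazoa") /
                individual_carbon(100, 50, "eumetazoa"))^(1 / coefs$eumetazoa$exp)
  expect_equal(v_ratio, 8)
  # hand evaluation for a 100 x 50 um ciliate
  v <- pi / 6 * 100 * 50^2
  expect_equal(v, 1.309e5, tolerance = 1e-3)
  expect_equal(individual_carbon(100, 50, "ciliate"),
               0.216e-9 * v^0.939)
  expect_error(individual_carbon(0, 10, "ciliate"), "positive")
  expect_error(individual_carbon(10, 5, "nematode"), "unknown group")
})

test_that("sample biomass is density times individual carbon, additively", {
  # one taxon, 10 individuals in 0.040 L, 1e-5 mg C each -> 2.5e-3 mg C/L
  v_ind <- pi / 6 * 10^3
  coefs <- carbon_coefficients(eumetazoa = list(cv = 1e-5 / v_ind, exp = 1))
  rec <- data.frame(taxon = "t1", group = "eumetazoa", count = 10,
                    length_um = 10, width_um = 10)
  out <- sample_biomass(rec, 0.040, coefs)
  expect_equal(out$biomass_mg_l[out$group == "eumetazoa"], 2.5e-3)
  # empty sample: all-zero biomasses, not an error
  empty <- sample_biomass(rec[0, ], 0.040, coefs)
  expect_equal(empty$biomass_mg_l, rep(0, 3))
  # splitting one record into two half-count records changes nothing
  rec2 <- rbind(transform(rec, count = 5), transform(rec, count = 5))
  expect_equal(sample_biomass(rec2, 0.040, coefs), out)
})

test_that("prokaryote biomass is linear in density and matches arithmetic", {
  expect_equal(prokaryote_biomass(0, 1), 0)
  # 1e6 cells/ml at 1 um diameter, 200 fg C/um3:
  # 1e9 cells/L * (pi/6) um3 * 200e-12 mg C
  expect_equal(prokaryote_biomass(1e6, 1), 1e9 * pi / 6 * 200e-12)
  expect_equal(prokaryote_biomass(2e6, 1), 2 * prokaryote_biomass(1e6, 1))
  expect_error(prokaryote_biomass(1e6, 0.05), "mean_diameter_um")
})

test_that("interpolated Shannon matches the enumeration oracle", {
  expect_equal(rarefied_shannon(c(5), 3), 0)
  expect_equal(rarefied_shannon(c(8, 2), 2), enum_expected_entropy(c(8, 2), 2))
  set.seed(11)
  for (i in 1:10) {
    x <- as.integer(sample(1:8, sample(2:5, 1), replace = TRUE))
    m <- sample(seq_len(sum(x)), 1)
    expect_equal(rarefied_shannon(x, m), enum_expected_entropy(x, m),
                 tolerance = 1e-12)
  }
})

test_that("rarefied Shannon endpoint, bounds and permutation invariance", {
  x <- c(12, 5, 3, 1)
  n <- sum(x)
  p <- x / n
  expect_equal(rarefied_shannon(x, n), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(rarefied_shannon(x, 7), rarefied_shannon(rev(x), 7))
  set.seed(21)
  for (i in 1:20) {
    x <- as.integer(sample(1:9, sample(2:6, 1), replace = TRUE))
    m <- sample(seq_len(sum(x)), 1)
    expect_lte(rarefied_shannon(x, m), log(sum(x > 0)) + 1e-12)
    expect_gte(rarefied_shannon(x, m), 0)
  }
  expect_error(rarefied_shannon(c(0, 0), 2), "no individuals")
  expect_error(rarefied_shannon(c(1.5, 2), 2), "integers")
})

test_that("extrapolated Shannon is continuous at n and approaches the asymptote", {
  x <- c(10, 6, 3, 2, 1, 1)
  n <- sum(x)
  h_n <- rarefied_shannon(x, n)
  expect_equal(rarefied_shannon(x, n), h_n)
  hs <- vapply(c(n, n + 5, n + 20, n + 100, n + 1000), function(m)
    rarefied_shannon(x, m), numeric(1))
  expect_true(all(diff(hs) >= -1e-12))
  # far extrapolation approaches the asymptotic entropy estimate from below
  expect_lt(abs(hs[5] - rarefied_shannon(x, n + 1e5)), 0.01)
})

test_that("base sample size follows the doubling cap convention", {
  expect_equal(base_sample_size(c(10, 100)), 20)
  expect_equal(base_sample_size(c(60, 80, 100)), 100)
  expect_equal(base_sample_size(50), 50)
})

test_that("biological summary assembles mediators per bioassay", {
  sim <- simulate_study(design = study_design(n_catchments = 2,
                                              streams_per_catchment = 2),
                        seed = 5)
  bio <- biological_summary(sim$organisms, sim$volumes, sim$prokaryotes,
                            ecoplates = sim$ecoplates)
  expect_equal(nrow(bio), nrow(sim$analysis))
  expect_true(all(c("inv_biomass", "prot_biomass", "prok_biomass",
                    "inv_diversity", "prot_diversity", "plate_awcd",
                    "metab_richness", "metab_diversity") %in% names(bio)))
  expect_true(all(bio$inv_biomass >= 0))
  # computed biomasses track the latent generating mediators
  m <- match(bio$bioassay_id, sim$analysis$bioassay_id)
  expect_gt(cor(log(bio$prok_biomass), sim$analysis$prok_biomass[m]), 0.95)
  expect_gt(cor(bio$metab_diversity, sim$analysis$metab_diversity[m]), 0.95)
  expect_gt(cor(log(bio$inv_biomass + 1e-6),
                sim$analysis$inv_biomass[m]), 0.6)
})
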