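# Mixed models, compartment contrasts, model selection and the three-step
# mediation analysis.

test_that("standardization is exact, idempotent and drops constants", {
  d <- data.frame(a = c(8, 10, 12, 14), b = scale(1:8)[1:4], k = rep(3, 4))
  expect_warning(out <- standardize_mediators(d, c("a", "b", "k")),
                 "zero-variance")
  expect_equal(attr(out, "dropped"), "k")
  expect_false("k" %in% names(out))
  # mean 10ish, SD: value maps to (x - mean)/sd
  expect_equal(out$a, (d$a - mean(d$a)) / sd(d$a))
  expect_equal((14 - 10) / 2, 2)  # the hand case: mean 10, SD 2 -> 14 is 2.0
  d2 <- data.frame(x = as.numeric(scale(rnorm(20))))
  out2 <- standardize_mediators(d2, "x")
  expect_equal(out2$x, d2$x, tolerance = 1e-12)
})

test_that("fit_lmm matches an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  set.seed(101)
  d <- make_nested_frame(site_sd = 0.8, catchment_sd = 0.4)
  ours <- fit_lmm(d, y ~ x + (1 | catchment / site))
  ref <- nlme::lme(y ~ x, random = ~ 1 | catchment / site, data = d,
                   method = "REML")
  expect_equal(unname(lme4::fixef(ours)), unname(nlme::fixef(ref)),
               tolerance = 1e-4)
  cs <- lmm_coefs(ours)
  expect_equal(cs$se, unname(sqrt(diag(ref$varFix))), tolerance = 1e-4)
})

test_that("with no random-effect variance the LMM reduces to OLS", {
  set.seed(102)
  d <- make_nested_frame(site_sd = 0, catchment_sd = 0)
  fit <- fit_lmm(d, y ~ x + (1 | catchment / site))
  ols <- lm(y ~ x, data = d)
  expect_equal(unname(lme4::fixef(fit)), unname(coef(ols)),
               tolerance = 1e-6)
  expect_true(attr(fit, "singular"))
  # formula without random terms falls back to lm directly
  direct <- fit_lmm(d, y ~ x)
  expect_s3_class(direct, "lm")
})

test_that("zone contrast is location-invariant and needs both zones", {
  set.seed(103)
  sim <- simulate_study(design = study_design(n_catchments = 3,
                                              streams_per_catchment = 2),
                        seed = 31, tables = "core")
  a1 <- anova_zone_contrast(sim$analysis, "inv_biomass")
  shifted <- sim$analysis
  shifted$inv_biomass <- shifted$inv_biomass + 100
  a2 <- anova_zone_contrast(shifted, "inv_biomass")
  expect_equal(a1$f, a2$f, tolerance = 1e-8)
  expect_equal(a1$estimate, a2$estimate, tolerance = 1e-8)
  expect_equal(a2$mean_bz - a2$mean_hz, a2$estimate)
  expect_error(anova_zone_contrast(sim$analysis[sim$analysis$zone == "BZ", ],
                                   "inv_biomass"), "both compartments")
})

test_that("zone contrast detects a 1 SD shift at the survey design size", {
  set.seed(104)
  hits <- vapply(1:40, function(i) {
    sim <- simulate_study(effects = single_mediator_config(),
                          seed = 500 + i, tables = "core")
    anova_zone_contrast(sim$analysis, "biofilm")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("nested OLS decomposition c = c' + a b holds exactly", {
  set.seed(105)
  n <- 200
  d <- data.frame(zone = rep(c("BZ", "HZ"), each = n / 2))
  z <- as.integer(d$zone == "BZ")
  d$m <- 1.0 * z + rnorm(n)
  d$y <- 0.5 * z + 0.5 * d$m + rnorm(n, 0, 0.5)
  med <- mediate_three_step(d, "y", "m", random = NULL, select = FALSE,
                            standardize = FALSE)
  a <- med$a_paths$estimate
  b <- med$b_paths$estimate
  expect_equal(med$c, med$c_prime + a * b, tolerance = 1e-6)
  # proportion mediated is invariant to affine rescaling of the response
  d2 <- d; d2$y <- 1000 * d$y + 5
  med2 <- mediate_three_step(d2, "y", "m", random = NULL, select = FALSE,
                             standardize = FALSE)
  expect_equal(med$proportion_mediated, med2$proportion_mediated,
               tolerance = 1e-10)
})

test_that("mediation gates on the total effect and flags inconsistency", {
  set.seed(106)
  n <- 120
  d <- data.frame(zone = rep(c("BZ", "HZ"), each = n / 2))
  z <- as.integer(d$zone == "BZ")
  d$m <- rnorm(n)
  d$y <- 0.01 * z + rnorm(n)   # no real total effect
  med <- mediate_three_step(d, "y", "m", random = NULL, select = FALSE)
  expect_true(is.na(med$proportion_mediated))
  expect_true("total_effect_not_significant" %in% med$flags)
  expect_equal(med$classification, "none")

  # suppression: strong positive indirect path, strong negative direct one
  d$m <- 2 * z + rnorm(n, 0, 0.3)
  d$y <- -1.5 * z + 1 * d$m + rnorm(n, 0, 0.3)
  med2 <- mediate_three_step(d, "y", "m", random = NULL, select = FALSE)
  expect_true("inconsistent_mediation" %in% med2$flags)
})

test_that("backward selection keeps signal and discards noise", {
  set.seed(107)
  null_kept <- vapply(1:100, function(i) {
    n <- 120
    d <- data.frame(zone = rep(c("BZ", "HZ"), each = n / 2))
    z <- as.integer(d$zone == "BZ")
    d$m1 <- rnorm(n); d$m2 <- rnorm(n)
    d$y <- 0.5 * z + rnorm(n)
    sel <- select_model(transform(d, zone_bz = z), "y", c("m1", "m2"),
                        interactions = FALSE, random = NULL)
    length(sel$retained) > 0
  }, logical(1))
  expect_lte(mean(null_kept), 0.10 * 2 + 0.05)  # ~ alpha per candidate

  strong_kept <- vapply(1:60, function(i) {
    n <- 120
    d <- data.frame(zone = rep(c("BZ", "HZ"), each = n / 2))
    z <- as.integer(d$zone == "BZ")
    d$m1 <- rnorm(n)
    d$y <- 0.5 * z + 1.0 * d$m1 + rnorm(n)
    sel <- select_model(transform(d, zone_bz = z), "y", "m1",
                        interactions = FALSE, random = NULL)
    "m1" %in% sel$retained
  }, logical(1))
  expect_gte(mean(strong_kept), 0.95)
})

test_that("selection outcome ignores candidate ordering", {
  set.seed(108)
  n <- 150
  d <- data.frame(zone = rep(c("BZ", "HZ"), each = n / 2))
  z <- as.integer(d$zone == "BZ")
  d$m1 <- rnorm(n); d$m2 <- rnorm(n); d$m3 <- rnorm(n)
  d$y <- 0.4 * z + 1.2 * d$m1 + rnorm(n)
  d$zone_bz <- z
  s1 <- select_model(d, "y", c("m1", "m2", "m3"), interactions = FALSE,
                     random = NULL)
  s2 <- select_model(d, "y", c("m3", "m2", "m1"), interactions = FALSE,
                     random = NULL)
  expect_setequal(s1$retained, s2$retained)
})

test_that("a purely direct effect classifies as no mediation, a purely
           indirect one as full mediation", {
  set.seed(109)
  sim_direct <- simulate_study(effects = single_mediator_config(b = 0),
                               seed = 61, tables = "core")
  med_d <- mediate_three_step(sim_direct$analysis, "k_green", "biofilm",
                              interactions = FALSE)
  expect_equal(med_d$classification, "none")
  prop_d <- med_d$proportion_mediated
  expect_lt(abs(ifelse(is.na(prop_d), 0, prop_d)), 0.2)

  sim_full <- simulate_study(effects = single_mediator_config(direct = 0),
                             seed = 62, tables = "core")
  med_f <- mediate_three_step(sim_full$analysis, "k_green", "biofilm",
                              interactions = FALSE)
  expect_equal(med_f$classification, "full")
  expect_gt(med_f$proportion_mediated, 0.8)
})

test_that("tidy and glance expose the mediation decomposition", {
  set.seed(110)
  sim <- simulate_study(effects = single_mediator_config(), seed = 63,
                        tables = "core")
  med <- mediate_three_step(sim$analysis, "k_green", "biofilm",
                            select = FALSE, interactions = FALSE)
  td <- tidy(med)
  expect_setequal(unique(td$path), c("c", "c_prime", "a", "b"))
  gl <- glance(med)
  expect_equal(gl$indirect, gl$c - gl$c_prime)
  expect_equal(gl$proportion_mediated,
               (gl$c - gl$c_prime) / gl$c)
  p <- autoplot(med)
  expect_s3_class(p, "ggplot")
})
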