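# Forward simulator of the survey: hierarchical mediators, decay
# coefficients from the structural model, substrate masses by inverting the
# decay model, temperature series, and community/prokaryote/EcoPlate tables
# rendered from the latent mediators.

K_FLOOR <- 1e-6  # decay model is undefined at k <= 0

# Fixed synthetic taxa pools. Body dimensions (um) span the realistic range
# for streambed Eumetazoa invertebrates and ciliates; flagellates are pooled
# as one small-bodied group.
invert_taxa_pool <- function() {
  n <- 18
  len <- round(exp(seq(log(250), log(4000), length.out = n)))
  tibble(
    taxon = paste0("Eumetazoa_t", sprintf("%02d", seq_len(n))),
    group = "eumetazoa",
    length_um = len,
    width_um = pmax(round(len * 0.25), 20)
  )
}

ciliate_taxa_pool <- function() {
  n <- 10
  len <- round(exp(seq(log(40), log(200), length.out = n)))
  tibble(
    taxon = paste0("Ciliata_t", sprintf("%02d", seq_len(n))),
    group = "ciliate",
    length_um = len,
    width_um = pmax(round(len * 0.5), 10)
  )
}

flagellate_taxon <- function() {
  tibble(taxon = "Flagellata", group = "flagellate",
         length_um = 8, width_um = 5)
}

# Geometric-series relative abundances with a body-size bias: the benthic
# zone over-represents large-bodied taxa, the hyporheic zone small-bodied
# ones, which is what lets the ordination separate the compartments.
taxa_weights <- function(pool, theta, size_bias) {
  base <- theta^(seq_len(nrow(pool)) - 1)
  s <- scale(log(pool$length_um))[, 1]
  if (all(!is.finite(s))) s <- rep(0, nrow(pool))
  w <- base * exp(size_bias * s)
  w / sum(w)
}

# Shannon entropy of a 31-substrate geometric profile with rate lambda.
geometric_entropy <- function(lambda, n = 31) {
  i <- seq_len(n) - 1
  z <- exp(-lambda * i)
  p <- z / sum(z)
  p <- p[p > 0]
  -sum(p * log(p))
}

solve_geometric_lambda <- function(target_h, n = 31) {
  target_h <- min(max(target_h, 1e-3), log(n) - 1e-6)
  uniroot(function(l) geometric_entropy(l, n) - target_h,
          lower = 1e-9, upper = 50, tol = 1e-10)$root
}

check_positive_rates <- function(cfg, substrate) {
  a <- cfg$zone_effect_on_mediators
  b <- cfg$mediator_effects_on_k
  re_sd <- sqrt(cfg$site_intercept_sd^2 + cfg$catchment_intercept_sd^2)
  for (z in c(0, 1)) {
    mu <- cfg$k_intercept + cfg$direct_zone_effect_on_k * z + sum(b * a * z)
    if (mu - 3 * re_sd <= 0) {
      abort(sprintf(
        "effect sizes for '%s' give expected k <= 0 at +/-3 SD of the random intercepts (zone %s); unusable configuration",
        substrate, if (z == 1) "BZ" else "HZ"))
    }
  }
  invisible(TRUE)
}

#' Forward-simulate a complete survey dataset with known ground truth
#'
#' Generates the full survey hierarchy: sites nested in
#' catchments, two streambed compartments, replicate bioassays, 10-minute
#' hyporheic temperature series (diel sinusoid plus noise) with paired
#' benthic spot measurements, latent standardized mediators with
#' compartment shifts and site/catchment random intercepts, per-substrate
#' decay coefficients from the linear structural model (floored at
#' `1e-6` per degree-day), substrate masses/strengths obtained by inverting
#' the exponential decay model over the known degree-days, and community,
#' prokaryote and EcoPlate tables rendered from the latent mediators
#' (multinomial counts over a geometric-series taxa pool with a
#' body-size-biased down-weighting in the hyporheic zone).
#'
#' Because the degree-days entering the inversion are computed with
#' [thermal_sum()] on the generated series (benthic via
#' [infer_benthic_temperature()]), running [decay_table()] on the bundle
#' recovers the recorded true decay coefficients to machine precision.
#'
#' @param design A [study_design()].
#' @param effects A single [effect_config()] (recycled over the three
#'   substrates) or a named list with elements `green_tea`, `rooibos_tea`,
#'   `cotton`. Mediator-side settings must agree across substrates.
#' @param seed Integer seed; identical seed and configuration give a
#'   byte-identical bundle.
#' @param tables `"all"` (default) or `"core"`; `"core"` skips the
#'   community/prokaryote/EcoPlate rendering (the analysis table is
#'   identical in both modes under the same seed).
#' @param noise_free Zero out temperature, spot, mediator and decay noise
#'   (random intercepts included), leaving only the structural signal.
#' @param temp_base_range,temp_amplitude,temp_noise_sd Hyporheic temperature
#'   model: per-site baseline range (C), diel amplitude (C), reading noise
#'   SD (C).
#' @param bz_slope,bz_intercept,bz_noise_sd,n_spots Benthic spot model: the
#'   linear map from hyporheic to benthic temperature, spot noise SD, and
#'   number of spot measurements per site.
#' @return A list of class `study_simulation` with tibbles `sites`,
#'   `assays`, `temperatures`, `spot_pairs`, `analysis` (per-bioassay latent
#'   mediators and true coefficients), `truth` (per-substrate effect
#'   decomposition with `a_paths`/`b_paths`), and - unless
#'   `tables = "core"` - `organisms`, `volumes`, `prokaryotes`, `ecoplates`.
#' @export
#' @examples
#' sim <- simulate_study(study_design(n_catchments = 2,
#'                                    streams_per_catchment = 2),
#'                       seed = 1, tables = "core")
#' sim$truth$effects
simulate_study <- function(design = study_design(),
                           effects = default_effect_configs(),
                           seed = 1,
                           tables = c("all", "core"),
                           noise_free = FALSE,
                           temp_base_range = c(7, 12),
                           temp_amplitude = 1.2,
                           temp_noise_sd = 0.15,
                           bz_slope = 1.15, bz_intercept = 0.5,
                           bz_noise_sd = 0.2, n_spots = 12) {
  stopifnot(inherits(design, "study_design"))
  tables <- match.arg(tables)
  seed <- assert_count(seed, "seed", lower = 0L)
  substrates <- c("green_tea", "rooibos_tea", "cotton")
  if (inherits(effects, "effect_config")) {
    effects <- setNames(list(effects, effects, effects), substrates)
  }
  if (!all(substrates %in% names(effects))) {
    abort("`effects` must name configurations for green_tea, rooibos_tea and cotton")
  }
  med_names <- effects[[1]]$mediators
  for (s in substrates) {
    if (!identical(effects[[s]]$mediators, med_names) ||
        !identical(effects[[s]]$zone_effect_on_mediators,
                   effects[[1]]$zone_effect_on_mediators)) {
      abort("mediator-side settings must agree across substrate configurations")
    }
    check_positive_rates(effects[[s]], s)
  }
  if (noise_free) {
    temp_noise_sd <- 0; bz_noise_sd <- 0
    for (s in substrates) {
      effects[[s]]$noise_sd_k <- 0
      effects[[s]]$site_intercept_sd <- 0
      effects[[s]]$catchment_intercept_sd <- 0
      effects[[s]]$noise_sd_mediators <- 0
      effects[[s]]$mediator_site_sd <- 0
      effects[[s]]$mediator_catchment_sd <- 0
    }
  }
  cfg1 <- effects[[1]]

  set.seed(seed)

  # --- sites -----------------------------------------------------------
  catchments <- sprintf("C%02d", seq_len(design$n_catchments))
  sites <- tidyr::expand_grid(catchment = catchments,
                              stream = seq_len(design$streams_per_catchment)) %>%
    mutate(site = sprintf("%s-S%d", .data$catchment, .data$stream)) %>%
    select("catchment", "site")
  n_sites <- nrow(sites)
  sites <- sites %>%
    mutate(
      ph = round(rnorm(n_sites, 7.5, 0.6), 2),
      altitude_m = round(exp(rnorm(n_sites, log(120), 0.7))),
      nitrate_mg_l = round(exp(rnorm(n_sites, log(2), 0.8)), 3),
      din_mg_l = round(exp(rnorm(n_sites, log(2.5), 0.7)), 3),
      deploy_days = sample(seq(design$deployment_days[1],
                               design$deployment_days[2]), n_sites,
                           replace = TRUE),
      deploy_start = design$start_date,
      deploy_end = design$start_date + .data$deploy_days
    )

  # --- hyporheic temperature and benthic spot measurements -------------
  start_t <- as.POSIXct(paste(design$start_date, "00:00:00"), tz = "UTC")
  temp_list <- vector("list", n_sites)
  spot_list <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    n_read <- sites$deploy_days[i] * 144L + 1L
    ts <- start_t + 600 * (seq_len(n_read) - 1L)
    base <- runif(1, temp_base_range[1], temp_base_range[2])
    hours <- as.numeric(ts - start_t, units = "hours")
    celsius <- base + temp_amplitude * sin(2 * pi * hours / 24) +
      rnorm(n_read, 0, temp_noise_sd)
    temp_list[[i]] <- tibble(site = sites$site[i], zone = "HZ",
                             timestamp = ts, celsius = celsius)
    idx <- sort(sample(n_read, min(n_spots, n_read)))
    spot_list[[i]] <- tibble(
      site = sites$site[i],
      timestamp = ts[idx],
      celsius = bz_intercept + bz_slope * celsius[idx] +
        rnorm(length(idx), 0, bz_noise_sd))
  }
  temperatures <- bind_rows(temp_list)
  spot_pairs <- bind_rows(spot_list)

  # Degree-days per site and zone, via the same path the analysis uses.
  t_dd_tbl <- map_dfr(seq_len(n_sites), function(i) {
    hz <- temp_list[[i]][c("timestamp", "celsius")]
    bz <- infer_benthic_temperature(spot_list[[i]], hz)$series
    tibble(site = sites$site[i],
           zone = c("BZ", "HZ"),
           t_dd = c(
             thermal_sum(bz, sites$deploy_start[i], sites$deploy_end[i]),
             thermal_sum(hz, sites$deploy_start[i], sites$deploy_end[i])))
  })

  # --- bioassays and latent mediators ----------------------------------
  assays_frame <- tidyr::expand_grid(
    site = sites$site, zone = c("BZ", "HZ"),
    replicate = seq_len(design$replicates_per_zone)) %>%
    left_join(sites %>% select("catchment", "site"), by = "site") %>%
    mutate(bioassay_id = sprintf("%s-%s-%d", .data$site, .data$zone,
                                 .data$replicate)) %>%
    left_join(t_dd_tbl, by = c("site", "zone"))
  n_assay <- nrow(assays_frame)
  z <- as.integer(assays_frame$zone == "BZ")

  a <- cfg1$zone_effect_on_mediators
  med <- matrix(NA_real_, n_assay, length(med_names),
                dimnames = list(NULL, med_names))
  for (j in seq_along(med_names)) {
    u_site <- rnorm(n_sites, 0, cfg1$mediator_site_sd)
    u_catch <- rnorm(design$n_catchments, 0, cfg1$mediator_catchment_sd)
    med[, j] <- a[j] * z +
      u_site[match(assays_frame$site, sites$site)] +
      u_catch[match(assays_frame$catchment, catchments)] +
      rnorm(n_assay, 0, cfg1$noise_sd_mediators)
  }

  k_true <- matrix(NA_real_, n_assay, 3,
                   dimnames = list(NULL, substrates))
  for (s in substrates) {
    cfg <- effects[[s]]
    u_site <- rnorm(n_sites, 0, cfg$site_intercept_sd)
    u_catch <- rnorm(design$n_catchments, 0, cfg$catchment_intercept_sd)
    k <- cfg$k_intercept + cfg$direct_zone_effect_on_k * z +
      drop(med %*% cfg$mediator_effects_on_k) +
      u_site[match(assays_frame$site, sites$site)] +
      u_catch[match(assays_frame$catchment, catchments)] +
      rnorm(n_assay, 0, cfg$noise_sd_k)
    k_true[, s] <- pmax(k, K_FLOOR)
  }

  # --- substrate assays by inverting the decay model -------------------
  init_noise <- function(mu, sd) {
    if (noise_free) rep(mu, n_assay) else rnorm(n_assay, mu, sd)
  }
  initials <- list(green_tea = init_noise(2.0, 0.05),
                   rooibos_tea = init_noise(2.0, 0.05),
                   cotton = init_noise(260, 15))
  assays <- map_dfr(substrates, function(s) {
    tibble(bioassay_id = assays_frame$bioassay_id,
           site = assays_frame$site,
           catchment = assays_frame$catchment,
           zone = assays_frame$zone,
           substrate = s,
           initial = initials[[s]],
           final = initials[[s]] * exp(-k_true[, s] * assays_frame$t_dd),
           deploy_start = sites$deploy_start[match(assays_frame$site,
                                                   sites$site)],
           deploy_end = sites$deploy_end[match(assays_frame$site,
                                               sites$site)])
  })

  # True TBI parameters implied by the generated tea masses.
  tbi_true <- tea_bag_index(
    1, exp(-k_true[, "green_tea"] * assays_frame$t_dd),
    1, exp(-k_true[, "rooibos_tea"] * assays_frame$t_dd),
    assays_frame$t_dd)

  analysis <- bind_cols(
    assays_frame %>% select("bioassay_id", "catchment", "site", "zone",
                            "t_dd"),
    as_tibble(k_true) %>%
      rename(k_green = "green_tea", k_red = "rooibos_tea",
             k_cotton = "cotton"),
    tibble(S = tbi_true$S, K = tbi_true$K),
    as_tibble(med)
  )

  truth_effects <- map_dfr(substrates, function(s) {
    cfg <- effects[[s]]
    tibble(substrate = s,
           c = cfg$total_effect,
           c_prime = cfg$direct_zone_effect_on_k,
           indirect = cfg$total_effect - cfg$direct_zone_effect_on_k,
           proportion_mediated = cfg$proportion_mediated)
  })
  truth_paths <- map_dfr(substrates, function(s) {
    cfg <- effects[[s]]
    tibble(substrate = s, mediator = med_names,
           a = unname(cfg$zone_effect_on_mediators),
           b = unname(cfg$mediator_effects_on_k))
  })

  out <- list(design = design, effects = effects, seed = seed,
              sites = sites, assays = assays,
              temperatures = temperatures, spot_pairs = spot_pairs,
              analysis = analysis,
              truth = list(effects = truth_effects, paths = truth_paths))

  if (tables == "all") {
    out <- c(out, simulate_biology(assays_frame, med, noise_free))
  }
  structure(out, class = "study_simulation")
}

# Render community, prokaryote and EcoPlate tables from latent mediators.
simulate_biology <- function(assays_frame, med, noise_free) {
  n_assay <- nrow(assays_frame)
  z <- as.integer(assays_frame$zone == "BZ")
  inv_pool <- invert_taxa_pool()
  cil_pool <- ciliate_taxa_pool()
  fla <- flagellate_taxon()
  inv_carbon <- individual_carbon(inv_pool$length_um, inv_pool$width_um,
                                  inv_pool$group)
  cil_carbon <- individual_carbon(cil_pool$length_um, cil_pool$width_um,
                                  cil_pool$group)

  volumes <- tibble(bioassay_id = assays_frame$bioassay_id,
                    volume_l = round(runif(n_assay, 0.038, 0.045), 4))

  org_list <- vector("list", n_assay)
  for (i in seq_len(n_assay)) {
    size_bias <- if (z[i] == 1) 0.6 else -0.6
    v <- volumes$volume_l[i]

    theta_inv <- stats::plogis(stats::qlogis(0.72) +
                                 0.4 * med[i, "inv_diversity"])
    w_inv <- taxa_weights(inv_pool, theta_inv, size_bias)
    b_inv <- 2.5 * exp(0.6 * med[i, "inv_biomass"])        # mg C/L target
    n_inv <- round(b_inv * v / sum(w_inv * inv_carbon))
    cnt_inv <- if (n_inv > 0) drop(rmultinom(1, n_inv, w_inv)) else
      rep(0L, nrow(inv_pool))

    theta_cil <- stats::plogis(stats::qlogis(0.75) +
                                 0.4 * med[i, "prot_diversity"])
    w_cil <- taxa_weights(cil_pool, theta_cil, size_bias / 2)
    b_cil <- 0.02 * exp(0.6 * med[i, "prot_biomass"])
    n_cil <- round(b_cil * v / sum(w_cil * cil_carbon))
    cnt_cil <- if (n_cil > 0) drop(rmultinom(1, n_cil, w_cil)) else
      rep(0L, nrow(cil_pool))

    n_fla <- max(0L, round(14 * exp(0.3 * med[i, "prot_biomass"]) +
                             if (noise_free) 0 else rnorm(1, 0, 2)))

    rec <- bind_rows(
      inv_pool %>% mutate(count = cnt_inv),
      cil_pool %>% mutate(count = cnt_cil),
      fla %>% mutate(count = n_fla)
    ) %>% filter(.data$count > 0)
    if (nrow(rec)) {
      rec$bioassay_id <- assays_frame$bioassay_id[i]
      org_list[[i]] <- rec
    }
  }
  organisms <- bind_rows(org_list) %>%
    select("bioassay_id", "taxon", "group", "count", "length_um",
           "width_um")

  prokaryotes <- tibble(
    bioassay_id = assays_frame$bioassay_id,
    cell_density = round(1e6 * exp(0.5 * med[, "prok_biomass"])),
    mean_diameter_um = if (noise_free) rep(0.8, n_assay) else
      pmin(pmax(rnorm(n_assay, 0.8, 0.03), 0.3), 2)
  )

  eco_list <- vector("list", n_assay)
  substrates31 <- sprintf("C%02d", seq_len(31))
  for (i in seq_len(n_assay)) {
    h_target <- 2.6 + 0.35 * med[i, "metab_diversity"]
    lambda <- solve_geometric_lambda(h_target)
    iidx <- seq_len(31) - 1
    p <- exp(-lambda * iidx); p <- p / sum(p)
    awcd <- 0.45 * exp(0.35 * med[i, "metab_diversity"])
    sub_awcd <- 31 * awcd * p
    ctrl_mu <- 0.05
    od_noise <- function(n, sd) if (noise_free) rep(0, n) else rnorm(n, 0, sd)
    eco_list[[i]] <- bind_rows(
      tibble(bioassay_id = assays_frame$bioassay_id[i],
             substrate = rep(substrates31, each = 3),
             replicate = rep(1:3, 31),
             od = pmax(ctrl_mu + rep(sub_awcd, each = 3) +
                         od_noise(93, 0.02), 0),
             is_control = FALSE),
      tibble(bioassay_id = assays_frame$bioassay_id[i],
             substrate = "water", replicate = 1:3,
             od = pmax(ctrl_mu + od_noise(3, 0.005), 0),
             is_control = TRUE))
  }
  ecoplates <- bind_rows(eco_list)

  list(organisms = organisms, volumes = volumes,
       prokaryotes = prokaryotes, ecoplates = ecoplates)
}

#' @export
print.study_simulation <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "Simulated survey: %d catchments x %d streams x 2 zones x %d replicates (%d bioassays)\n",
    d$n_catchments, d$streams_per_catchment, d$replicates_per_zone,
    nrow(x$analysis)))
  cat("tables:", paste(intersect(
    c("sites", "assays", "temperatures", "spot_pairs", "organisms",
      "volumes", "prokaryotes", "ecoplates", "analysis"), names(x)),
    collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated study bundle as CSV files
#'
#' One CSV per table, UTF-8, ISO-8601 dates; the per-substrate truth is
#' written alongside as `truth_effects.csv` / `truth_paths.csv`.
#'
#' @param sim A `study_simulation`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "study_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("sites", "assays", "temperatures", "spot_pairs", "organisms",
              "volumes", "prokaryotes", "ecoplates", "analysis")
  written <- character(0)
  for (t in intersect(tables, names(sim))) {
    f <- file.path(dir, paste0(t, ".csv"))
    readr::write_csv(sim[[t]], f)
    written <- c(written, f)
  }
  f1 <- file.path(dir, "truth_effects.csv")
  f2 <- file.path(dir, "truth_paths.csv")
  readr::write_csv(sim$truth$effects, f1)
  readr::write_csv(sim$truth$paths, f2)
  invisible(c(written, f1, f2))
}

#' Read a study bundle written by [write_study()]
#'
#' @param dir Directory containing the CSV files.
#' @return A list of tibbles (class `study_bundle`) with whatever tables are
#'   present.
#' @export
read_study <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) abort(sprintf("no CSV tables found in '%s'", dir))
  out <- map(set_names(files, sub("\\.csv$", "", basename(files))),
             ~ readr::read_csv(.x, show_col_types = FALSE))
  if (!is.null(out$temperatures)) {
    out$temperatures$timestamp <- as.POSIXct(out$temperatures$timestamp,
                                             tz = "UTC")
  }
  if (!is.null(out$spot_pairs)) {
    out$spot_pairs$timestamp <- as.POSIXct(out$spot_pairs$timestamp,
                                           tz = "UTC")
  }
  structure(out, class = "study_bundle")
}
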