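# Configuration objects for the forward simulator: the hierarchical survey
# design and the structural (mediation) effect sizes.

#' Hierarchical survey design
#'
#' The default mirrors a regional field survey: 10 catchments, 3 streams
#' per catchment, bioassays deployed in pairs (one benthic, one hyporheic)
#' with 3 replicate pairs per stream, for 29-61 days starting at peak leaf
#' fall.
#'
#' @param n_catchments Number of catchments (>= 1).
#' @param streams_per_catchment Streams (sites) per catchment (>= 1).
#' @param replicates_per_zone Replicate bioassays per stream and zone
#'   (>= 1).
#' @param deployment_days Integer pair: min and max deployment length in
#'   days, within \[1, 365\].
#' @param start_date Deployment start date (shared across sites).
#' @return A list of class `study_design`.
#' @export
#' @examples
#' study_design()
study_design <- function(n_catchments = 10, streams_per_catchment = 3,
                         replicates_per_zone = 3,
                         deployment_days = c(29, 61),
                         start_date = as.Date("2016-10-25")) {
  n_catchments <- assert_count(n_catchments, "n_catchments")
  streams_per_catchment <- assert_count(streams_per_catchment,
                                        "streams_per_catchment")
  replicates_per_zone <- assert_count(replicates_per_zone,
                                      "replicates_per_zone")
  if (length(deployment_days) != 2L || any(deployment_days < 1) ||
      any(deployment_days > 365) ||
      deployment_days[2] < deployment_days[1]) {
    abort("`deployment_days` must be an increasing pair within [1, 365]")
  }
  structure(list(
    n_catchments = n_catchments,
    streams_per_catchment = streams_per_catchment,
    replicates_per_zone = replicates_per_zone,
    deployment_days = as.integer(deployment_days),
    start_date = as.Date(start_date)
  ), class = "study_design")
}

#' Structural effect sizes for one breakdown response
#'
#' Encodes the linear mediation diagram for one substrate's decay
#' coefficient: the compartment shifts each mediator by
#' `zone_effect_on_mediators` (BZ minus HZ, in mediator SD units), each
#' mediator moves the decay coefficient by `mediator_effects_on_k` (k units
#' per mediator SD), and `direct_zone_effect_on_k` is the unmediated
#' compartment effect. The implied total effect is
#' `c = direct + sum(a_j * b_j)` and the generating proportion mediated is
#' `(c - direct) / c`.
#'
#' @param zone_effect_on_mediators Named numeric: per-mediator standardized
#'   BZ-HZ shift (`a_j`).
#' @param mediator_effects_on_k Named numeric: per-mediator slope in k units
#'   per mediator SD (`b_j`); names must be a subset of the mediator names.
#' @param direct_zone_effect_on_k Direct compartment effect on k (k units).
#' @param k_intercept Expected k in the hyporheic zone at mediator means
#'   (k units, > 0).
#' @param noise_sd_k Residual SD of k (k units).
#' @param site_intercept_sd,catchment_intercept_sd Random-intercept SDs of k
#'   at stream and catchment level (k units).
#' @param noise_sd_mediators Residual SD of the mediators (SD units).
#' @param mediator_site_sd,mediator_catchment_sd Random-intercept SDs of the
#'   mediators at stream and catchment level (SD units).
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(zone_effect_on_mediators,
                          mediator_effects_on_k,
                          direct_zone_effect_on_k,
                          k_intercept,
                          noise_sd_k,
                          site_intercept_sd = 0,
                          catchment_intercept_sd = 0,
                          noise_sd_mediators = 0.9,
                          mediator_site_sd = 0.3,
                          mediator_catchment_sd = 0.2) {
  a <- zone_effect_on_mediators
  b <- mediator_effects_on_k
  if (is.null(names(a)) || any(names(a) == "")) {
    abort("`zone_effect_on_mediators` must be a fully named vector")
  }
  if (is.null(names(b)) || !all(names(b) %in% names(a))) {
    abort("`mediator_effects_on_k` names must match mediator names")
  }
  b_full <- setNames(rep(0, length(a)), names(a))
  b_full[names(b)] <- b
  sds <- c(noise_sd_k = noise_sd_k, site_intercept_sd = site_intercept_sd,
           catchment_intercept_sd = catchment_intercept_sd,
           noise_sd_mediators = noise_sd_mediators,
           mediator_site_sd = mediator_site_sd,
           mediator_catchment_sd = mediator_catchment_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort("all SDs must be finite and non-negative")
  }
  assert_number(direct_zone_effect_on_k, "direct_zone_effect_on_k")
  assert_number(k_intercept, "k_intercept", lower = 1e-12)
  total <- direct_zone_effect_on_k + sum(a * b_full)
  if (!is.finite(total)) abort("implied total effect is not finite")
  structure(list(
    mediators = names(a),
    zone_effect_on_mediators = a,
    mediator_effects_on_k = b_full,
    direct_zone_effect_on_k = direct_zone_effect_on_k,
    k_intercept = k_intercept,
    noise_sd_k = noise_sd_k,
    site_intercept_sd = site_intercept_sd,
    catchment_intercept_sd = catchment_intercept_sd,
    noise_sd_mediators = noise_sd_mediators,
    mediator_site_sd = mediator_site_sd,
    mediator_catchment_sd = mediator_catchment_sd,
    total_effect = total,
    proportion_mediated = if (total != 0) (total - direct_zone_effect_on_k) /
      total else NA_real_
  ), class = "effect_config")
}

# Default mediator set shared by the default substrate configurations.
default_mediator_names <- function() {
  c("inv_biomass", "prot_biomass", "prok_biomass",
    "inv_diversity", "prot_diversity", "metab_diversity")
}

#' Default per-substrate effect configurations
#'
#' Emulates the surveyed gradient structure: a strong benthic excess in
#' biomass and diversity of Protozoa and Eumetazoa and in prokaryote
#' metabolic diversity (no compartment effect on prokaryote biomass), decay
#' coefficients averaging about 4.0, 3.0 and 0.7 (x 1e-3 per degree-day) for
#' cotton, green tea and rooibos tea, a roughly five-fold benthic excess for
#' cotton and 1.5-fold for the teas, and generating proportions mediated of
#' roughly 0.6-0.8, largest for rooibos (whose direct compartment effect is
#' weakest).
#'
#' @return Named list of [effect_config()] objects
#'   (`green_tea`, `rooibos_tea`, `cotton`).
#' @export
default_effect_configs <- function() {
  a <- c(inv_biomass = 1.5, prot_biomass = 1.5, prok_biomass = 0,
         inv_diversity = 1.2, prot_diversity = 1.2, metab_diversity = 1.0)
  list(
    green_tea = effect_config(
      zone_effect_on_mediators = a,
      mediator_effects_on_k = c(inv_biomass = 0.02e-3,
                                prot_biomass = 0.25e-3,
                                inv_diversity = 0.25e-3,
                                prot_diversity = 0.02e-3,
                                metab_diversity = 0.08e-3),
      direct_zone_effect_on_k = 0.45e-3,
      k_intercept = 2.37e-3, noise_sd_k = 0.25e-3,
      site_intercept_sd = 0.15e-3, catchment_intercept_sd = 0.10e-3),
    rooibos_tea = effect_config(
      zone_effect_on_mediators = a,
      mediator_effects_on_k = c(prot_biomass = 0.06e-3,
                                prok_biomass = 0.05e-3,
                                inv_diversity = 0.06e-3,
                                metab_diversity = 0.06e-3),
      direct_zone_effect_on_k = 0.055e-3,
      k_intercept = 0.56e-3, noise_sd_k = 0.08e-3,
      site_intercept_sd = 0.05e-3, catchment_intercept_sd = 0.04e-3),
    cotton = effect_config(
      zone_effect_on_mediators = a,
      mediator_effects_on_k = c(inv_biomass = 1.2e-3,
                                prot_biomass = 0.25e-3,
                                inv_diversity = 1.2e-3,
                                prot_diversity = 0.05e-3,
                                metab_diversity = 0.10e-3),
      direct_zone_effect_on_k = 1.70e-3,
      k_intercept = 1.33e-3, noise_sd_k = 0.50e-3,
      site_intercept_sd = 0.25e-3, catchment_intercept_sd = 0.20e-3)
  )
}
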