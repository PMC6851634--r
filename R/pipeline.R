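# End-to-end pipeline: simulate (or load) -> decay metrics -> biological
# summary -> ordination -> compartment contrasts -> mediation, with a
# manifest recording every parameter that can change a number.

default_run_config <- function() {
  list(
    seed = 1,
    simulate = list(design = list(), effects = "default",
                    noise_free = FALSE),
    input_dir = NULL,
    out_dir = NULL,
    tbi = list(h_green = 0.842, h_rooibos = 0.552),
    base_temp = 0,
    od_threshold = 0.25,
    alpha = 0.05,
    nmds = list(n_starts = 50, n_dim = 2),
    n_perm = 1000,
    mediation = list(
      responses = c("k_cotton", "k_green", "k_red", "K", "S"),
      mediators = "auto",
      select = TRUE, interactions = TRUE),
    stages = list(decay = TRUE, community = TRUE, ordination = TRUE,
                  mediation = TRUE)
  )
}

parse_effects <- function(x) {
  if (is.character(x) && identical(x, "default")) {
    return(default_effect_configs())
  }
  if (inherits(x, "effect_config")) return(x)
  as_cfg <- function(l) do.call(effect_config, map(l, ~ {
    if (is.list(.x)) unlist(.x) else .x
  }))
  if (is.list(x) && all(c("green_tea", "rooibos_tea", "cotton") %in%
                        names(x))) {
    return(map(x, ~ if (inherits(.x, "effect_config")) .x else as_cfg(.x)))
  }
  if (is.list(x)) return(as_cfg(x))
  abort("unrecognised `effects` specification")
}

#' Load a pipeline run configuration
#'
#' @param config A list, a path to a YAML file, or `NULL` for the defaults.
#'   Supplied fields override the defaults (see [run_pipeline()]).
#' @return A complete configuration list.
#' @export
load_run_config <- function(config = NULL) {
  base <- default_run_config()
  if (is.null(config)) return(base)
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  modifyList(base, config)
}

stage_result <- function(status, value = NULL, message = NULL) {
  list(status = status, value = value, message = message)
}

run_stage <- function(name, enabled, deps_ok, expr) {
  if (!enabled) return(stage_result("disabled"))
  if (!deps_ok) return(stage_result("skipped (upstream failure)"))
  tryCatch(stage_result("ok", value = expr),
           error = function(e) stage_result("failed", message = conditionMessage(e)))
}

#' Run the full breakdown-analysis pipeline
#'
#' Executes the enabled stages in dependency order on either a simulated
#' dataset (the default) or a CSV bundle in `input_dir` (as written by
#' [write_study()]): per-bioassay decay metrics and Tea Bag Index, the
#' biological summary, compartment ANOVA contrasts, Bray-Curtis NMDS with
#' permutation-fitted covariates, and three-step mediation models for each
#' breakdown response. A stage failure marks downstream stages as skipped;
#' upstream outputs are retained.
#'
#' Reruns with the same configuration are bit-identical: every stochastic
#' stage is seeded from `config$seed` and the manifest contains no
#' wall-clock information.
#'
#' @param config See [load_run_config()]; notable fields are `seed`,
#'   `simulate` (design/effects for the generator), `input_dir`, `out_dir`
#'   (when set, every table is written as CSV next to a `manifest.yaml`),
#'   `tbi`, `base_temp`, `od_threshold`, `alpha`, `nmds`, `n_perm` and
#'   `mediation` (`responses`, `mediators = "auto"` picks the biological
#'   variables significantly associated with the ordination).
#' @return A list of class `litter_pipeline`: `data` (the input bundle),
#'   `decay`, `biology`, `analysis`, `zone_contrasts`, `ordination`,
#'   `vectors`, `mediation` (list of `litter_mediation`),
#'   `mediation_summary` and `manifest`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- load_run_config(config)
  warn_count <- 0L
  stages <- list()
  withCallingHandlers({

    # --- input data ----------------------------------------------------
    if (!is.null(cfg$input_dir)) {
      sim <- read_study(cfg$input_dir)
    } else {
      design <- do.call(study_design, cfg$simulate$design %||% list())
      sim <- simulate_study(design,
                            effects = parse_effects(cfg$simulate$effects),
                            seed = cfg$seed,
                            noise_free = isTRUE(cfg$simulate$noise_free))
    }
    site_info <- distinct(sim$assays, .data$bioassay_id, .data$site,
                          .data$catchment, .data$zone)

    # --- decay metrics -------------------------------------------------
    stages$decay <- run_stage("decay", isTRUE(cfg$stages$decay), TRUE, {
      decay_table(sim$assays, sim$temperatures, sim$spot_pairs,
                  params = tbi_parameters(cfg$tbi$h_green, cfg$tbi$h_rooibos),
                  base_temp = cfg$base_temp) %>%
        left_join(distinct(site_info, .data$site, .data$catchment),
                  by = "site")
    })
    decay <- stages$decay$value

    # --- biological summary --------------------------------------------
    has_bio <- all(c("organisms", "volumes", "prokaryotes") %in% names(sim))
    stages$community <- run_stage(
      "community", isTRUE(cfg$stages$community) && has_bio, TRUE, {
        biological_summary(sim$organisms, sim$volumes, sim$prokaryotes,
                           ecoplates = sim$ecoplates,
                           od_threshold = cfg$od_threshold)
      })
    biology <- stages$community$value

    bio_vars <- if (!is.null(biology)) {
      intersect(c("inv_biomass", "prot_biomass", "prok_biomass",
                  "inv_diversity", "prot_diversity", "metab_diversity",
                  "plate_awcd", "metab_richness"), names(biology))
    } else character(0)

    analysis <- NULL
    if (!is.null(decay) && !is.null(biology)) {
      analysis <- decay %>% left_join(biology, by = "bioassay_id")
    }

    # --- compartment contrasts -----------------------------------------
    stages$zone_contrasts <- run_stage(
      "zone_contrasts", isTRUE(cfg$stages$community), !is.null(analysis), {
        map_dfr(bio_vars, function(v) {
          tryCatch(anova_zone_contrast(analysis, v),
                   error = function(e) tibble(variable = v))
        })
      })

    # --- ordination ----------------------------------------------------
    stages$ordination <- run_stage(
      "ordination", isTRUE(cfg$stages$ordination),
      has_bio && !is.null(decay), {
        pooled <- pool_abundances(sim$organisms, sim$volumes,
                                  assay_info = site_info)
        ord <- run_nmds(bray_curtis(pooled$mat),
                        n_dim = cfg$nmds$n_dim %||% 2,
                        n_starts = cfg$nmds$n_starts %||% 50,
                        seed = cfg$seed + 1L)
        covars <- pooled$meta %>%
          left_join(sim$sites %>%
                      select("site", "ph", "altitude_m", "nitrate_mg_l",
                             "din_mg_l"),
                    by = "site") %>%
          left_join(
            analysis %>%
              group_by(.data$site, .data$zone) %>%
              summarise(dplyr::across(dplyr::all_of(
                c(bio_vars, "k_cotton", "k_green", "k_red", "S")),
                ~ mean(.x, na.rm = TRUE)), .groups = "drop"),
            by = c("site", "zone"))
        vectors <- fit_vectors(
          ord, covars %>% select(-"row", -"site"),
          n_perm = cfg$n_perm, seed = cfg$seed + 2L)
        list(ordination = ord, vectors = vectors, pooled = pooled)
      })
    ord_res <- stages$ordination$value

    # --- mediation -----------------------------------------------------
    stages$mediation <- run_stage(
      "mediation", isTRUE(cfg$stages$mediation), !is.null(analysis), {
        meds <- cfg$mediation$mediators
        if (identical(meds, "auto")) {
          meds <- if (!is.null(ord_res)) {
            sig <- ord_res$vectors %>%
              filter(.data$variable %in% bio_vars,
                     .data$p_perm < cfg$alpha) %>%
              pull(.data$variable) %>% unique()
            if (length(sig)) sig else bio_vars
          } else bio_vars
          meds <- setdiff(meds, c("plate_awcd", "metab_richness"))
        }
        responses <- intersect(cfg$mediation$responses, names(analysis))
        fits <- map(set_names(responses), function(r) {
          tryCatch(
            mediate_three_step(analysis, r, meds, alpha = cfg$alpha,
                               select = isTRUE(cfg$mediation$select),
                               interactions = isTRUE(cfg$mediation$interactions)),
            error = function(e) e)
        })
        fits
      })

  }, warning = function(w) {
    warn_count <<- warn_count + 1L
    invokeRestart("muffleWarning")
  })

  mediation <- stages$mediation$value
  mediation_ok <- !is.null(mediation) &&
    any(map_chr(mediation, ~ class(.x)[1]) == "litter_mediation")
  mediation_summary <- if (mediation_ok) {
    map_dfr(mediation[map_chr(mediation, ~ class(.x)[1]) ==
                        "litter_mediation"], glance)
  } else NULL

  manifest <- list(
    package = as.character(packageVersion("streamlitter")),
    seed = cfg$seed,
    config_hash = hash(cfg),
    warnings = warn_count,
    stages = map(stages, function(s) {
      out <- list(status = s$status)
      if (!is.null(s$message)) out$message <- s$message
      out
    }),
    output_hashes = list(
      decay = if (!is.null(decay)) hash(decay),
      biology = if (!is.null(biology)) hash(biology),
      ordination = if (!is.null(ord_res))
        hash(ord_res$ordination$points),
      vectors = if (!is.null(ord_res)) hash(ord_res$vectors),
      mediation = if (!is.null(mediation_summary)) hash(mediation_summary))
  )

  out <- structure(list(
    config = cfg, data = sim, decay = decay, biology = biology,
    analysis = analysis,
    zone_contrasts = stages$zone_contrasts$value,
    ordination = if (!is.null(ord_res)) ord_res$ordination,
    vectors = if (!is.null(ord_res)) ord_res$vectors,
    mediation = mediation,
    mediation_summary = mediation_summary,
    manifest = manifest
  ), class = "litter_pipeline")

  if (!is.null(cfg$out_dir)) write_pipeline(out, cfg$out_dir)
  out
}

write_pipeline <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, f) if (!is.null(x)) readr::write_csv(x, file.path(dir, f))
  wr(run$decay, "decay.csv")
  wr(run$biology, "biological_summary.csv")
  wr(run$analysis, "analysis.csv")
  wr(run$zone_contrasts, "zone_contrasts.csv")
  if (!is.null(run$ordination)) {
    wr(run$ordination$points, "nmds_coordinates.csv")
    wr(run$vectors, "fitted_vectors.csv")
  }
  wr(run$mediation_summary, "mediation_summary.csv")
  yaml::write_yaml(run$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.litter_pipeline <- function(x, ...) {
  cat("streamlitter pipeline run (seed", x$config$seed, ")\n")
  for (s in names(x$manifest$stages)) {
    cat(sprintf("  %-15s %s\n", s, x$manifest$stages[[s]]$status))
  }
  if (!is.null(x$ordination)) {
    cat(sprintf("  NMDS stress %.4f (linear R2 %.3f, non-metric R2 %.3f)\n",
                x$ordination$stress, x$ordination$linear_r2,
                x$ordination$nonmetric_r2))
  }
  if (!is.null(x$mediation_summary)) {
    print(x$mediation_summary[, c("response", "c", "c_prime",
                                  "proportion_mediated", "classification")])
  }
  invisible(x)
}
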