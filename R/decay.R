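# Degree-day normalized breakdown metrics: exponential decay coefficients for
# teas and cotton strips, and the Tea Bag Index (S, K).

#' Tea Bag Index hydrolysable fractions
#'
#' The two-pool tea model splits each tea into a chemically hydrolysable
#' (labile) fraction and a recalcitrant remainder. The defaults are the
#' published fractions for Lipton green tea (0.842) and rooibos tea (0.552);
#' both are exposed here because batches of tea may differ.
#'
#' @param h_green Hydrolysable fraction of green tea, in (0, 1).
#' @param h_rooibos Hydrolysable fraction of rooibos tea, in (0, 1).
#' @return A named list with class `tbi_parameters`.
#' @export
#' @examples
#' tbi_parameters()
tbi_parameters <- function(h_green = 0.842, h_rooibos = 0.552) {
  assert_number(h_green, "h_green", 1e-6, 1 - 1e-6)
  assert_number(h_rooibos, "h_rooibos", 1e-6, 1 - 1e-6)
  structure(list(h_green = h_green, h_rooibos = h_rooibos),
            class = "tbi_parameters")
}

validate_temperature_series <- function(series, what = "series") {
  assert_cols(series, c("timestamp", "celsius"), what)
  ts <- series$timestamp
  if (anyNA(ts) || is.unsorted(ts, strictly = TRUE)) {
    abort(sprintf("`%s` timestamps must be strictly increasing with no NA",
                  what))
  }
  bad <- !is.na(series$celsius) &
    (series$celsius < -10 | series$celsius > 45)
  if (any(bad)) {
    warn(sprintf("%d reading(s) in `%s` outside the plausible [-10, 45] C range",
                 sum(bad), what))
  }
  invisible(series)
}

#' Infer the benthic temperature series from spot measurements
#'
#' Hyporheic loggers record continuously while the benthic zone (BZ) is only
#' spot-sampled. Each spot measurement is matched to the nearest hyporheic
#' reading (within `max_gap` minutes) and an ordinary least-squares regression
#' of BZ spot temperature on the matched hyporheic temperature is used to
#' predict a full BZ series over the hyporheic timeline.
#'
#' @param spot_pairs Data frame with columns `timestamp`, `celsius`: spot
#'   measurements taken in the benthic zone.
#' @param hz_series Data frame with columns `timestamp`, `celsius`: the
#'   10-minute hyporheic logger series.
#' @param max_gap Maximum time gap, in minutes, allowed when matching a spot
#'   measurement to a hyporheic reading (default 5).
#' @return A list of class `bz_inference` with elements `series` (tibble:
#'   `timestamp`, `celsius`, `zone = "BZ"`), `slope`, `intercept`,
#'   `r_squared` and `n_matched`.
#' @export
infer_benthic_temperature <- function(spot_pairs, hz_series, max_gap = 5) {
  assert_cols(spot_pairs, c("timestamp", "celsius"), "spot_pairs")
  validate_temperature_series(hz_series, "hz_series")
  if (nrow(spot_pairs) < 3L) {
    abort("at least 3 benthic spot measurements are required")
  }
  hz_t <- as.numeric(hz_series$timestamp)
  sp_t <- as.numeric(spot_pairs$timestamp)
  idx <- vapply(sp_t, function(t) which.min(abs(hz_t - t)), integer(1))
  gap_min <- abs(hz_t[idx] - sp_t) / 60
  keep <- gap_min <= max_gap
  if (sum(keep) < 3L) {
    abort(sprintf(
      "only %d spot measurement(s) matched a hyporheic reading within %s min",
      sum(keep), format(max_gap)))
  }
  x <- hz_series$celsius[idx[keep]]
  y <- spot_pairs$celsius[keep]
  if (sd(x) < 1e-12) {
    abort("matched hyporheic temperatures have zero variance; regression is degenerate")
  }
  fit <- lm(y ~ x)
  pred <- unname(coef(fit)[1] + coef(fit)[2] * hz_series$celsius)
  structure(list(
    series = tibble(timestamp = hz_series$timestamp,
                    celsius = pred, zone = "BZ"),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    n_matched = sum(keep)
  ), class = "bz_inference")
}

#' Thermal sum (degree-days) over a deployment window
#'
#' Accumulates daily mean temperature above a base temperature over calendar
#' days. The window is half-open: readings with
#' `start <= timestamp < end` contribute, so adjacent windows split at a day
#' boundary add exactly. Partial first and last days use whatever readings
#' fall inside the window. Daily means below `base_temp` contribute zero.
#'
#' @param series Data frame with `timestamp` (POSIXct) and `celsius` columns.
#' @param start,end Window bounds (POSIXct or Date); `end` must exceed `start`.
#' @param base_temp Base temperature in degrees C (default 0, the usual
#'   ecological convention).
#' @return Degree-days (a single non-negative number).
#' @export
#' @examples
#' ts <- seq(as.POSIXct("2016-10-25", tz = "UTC"), by = 600,
#'           length.out = 30 * 144)
#' thermal_sum(data.frame(timestamp = ts, celsius = 10),
#'             ts[1], ts[1] + 30 * 86400)  # 300 degree-days
thermal_sum <- function(series, start, end, base_temp = 0) {
  validate_temperature_series(series)
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (!end > start) abort("`end` must be after `start`")
  inside <- series$timestamp >= start & series$timestamp < end
  if (!any(inside)) abort("no temperature readings inside [start, end)")
  day <- as.Date(series$timestamp[inside], tz = "UTC")
  daily <- tapply(series$celsius[inside], day, mean, na.rm = TRUE)
  sum(pmax(daily - base_temp, 0))
}

#' Exponential decay coefficient per degree-day
#'
#' Single-retrieval decay model `X_t / X_0 = exp(-k t)`, with biological time
#' `t` measured in degree-days. The same formula applies to tea dry mass and
#' to cotton-strip tensile strength. A final value exceeding the initial one
#' (measurement noise) is clamped to `k = 0` with a warning; a final value of
#' zero has no finite `k` and is an error.
#'
#' @param initial,final Initial and final quantity (g dry mass or tensile
#'   strength units); vectors recycle.
#' @param t_dd Degree-days of deployment (> 0).
#' @return Decay coefficient(s) `k` in per-degree-day units.
#' @export
#' @examples
#' decay_coefficient(1, 0.5, 1000)  # ln(2)/1000
decay_coefficient <- function(initial, final, t_dd) {
  n <- max(length(initial), length(final), length(t_dd))
  initial <- rep_len(initial, n); final <- rep_len(final, n)
  t_dd <- rep_len(t_dd, n)
  if (any(!is.finite(initial) | initial <= 0)) {
    abort("`initial` must be positive and finite")
  }
  if (any(!is.finite(t_dd) | t_dd <= 0)) abort("`t_dd` must be positive")
  if (any(!is.finite(final) | final < 0)) {
    abort("`final` must be non-negative and finite")
  }
  if (any(final == 0)) {
    abort("`final` of 0 implies an infinite decay coefficient")
  }
  k <- log(initial / final) / t_dd
  if (any(k < 0)) {
    warn(sprintf(
      "%d assay(s) gained mass/strength (final > initial); k clamped to 0",
      sum(k < 0)))
    k <- pmax(k, 0)
  }
  k
}

#' Tea Bag Index stabilization and decay parameters
#'
#' From the decomposed mass fraction of green tea the stabilization factor is
#' `S = 1 - a_g / H_g` (the share of the labile pool that escaped
#' decomposition), the decomposable fraction of rooibos is
#' `a_r = H_r (1 - S)`, and the global decay coefficient `K` solves the
#' two-pool model `W_t / W_0 = a_r exp(-K t) + (1 - a_r)` for the observed
#' rooibos mass ratio.
#'
#' `K` is undefined (returned as `NA` with `k_undefined = TRUE`) when the
#' rooibos remaining fraction is at or below its recalcitrant floor
#' `1 - a_r`. Negative `S` (green tea decomposed beyond its nominal labile
#' pool) is returned but flagged via `s_out_of_range`.
#'
#' @param green_initial,green_final Green tea dry mass before/after (g).
#' @param rooibos_initial,rooibos_final Rooibos dry mass before/after (g).
#' @param t_dd Degree-days of deployment.
#' @param params A [tbi_parameters()] object.
#' @return A tibble with columns `S`, `a_r`, `K`, `s_out_of_range`,
#'   `k_undefined`.
#' @export
#' @examples
#' tea_bag_index(1, 1 - 0.6315, 1, 0.7, t_dd = 1000)
tea_bag_index <- function(green_initial, green_final,
                          rooibos_initial, rooibos_final,
                          t_dd, params = tbi_parameters()) {
  stopifnot(inherits(params, "tbi_parameters"))
  n <- max(length(green_initial), length(green_final),
           length(rooibos_initial), length(rooibos_final), length(t_dd))
  gi <- rep_len(green_initial, n); gf <- rep_len(green_final, n)
  ri <- rep_len(rooibos_initial, n); rf <- rep_len(rooibos_final, n)
  t_dd <- rep_len(t_dd, n)
  if (any(gi <= 0 | ri <= 0)) abort("initial masses must be positive")
  if (any(t_dd <= 0)) abort("`t_dd` must be positive")
  a_g <- 1 - gf / gi                       # observed decomposed green fraction
  s <- 1 - a_g / params$h_green
  a_r <- params$h_rooibos * (1 - s)
  ratio <- rf / ri
  inner <- (ratio - (1 - a_r)) / a_r
  k_ok <- is.finite(inner) & inner > 0 & a_r > 0
  k <- ifelse(k_ok, -log(pmax(inner, .Machine$double.xmin)) / t_dd, NA_real_)
  tibble(
    S = s, a_r = a_r, K = k,
    s_out_of_range = s < 0 | s > 1,
    k_undefined = !k_ok
  )
}

#' Per-bioassay decay metrics from assay and temperature tables
#'
#' Computes, for every bioassay, the degree-days of deployment (from the
#' hyporheic logger series for HZ bioassays, or from the regression-inferred
#' benthic series for BZ bioassays), the decay coefficients of green tea,
#' rooibos tea and cotton, and the Tea Bag Index parameters.
#'
#' @param assays Data frame with columns `bioassay_id`, `site`, `zone`
#'   (`"BZ"`/`"HZ"`), `substrate` (`"green_tea"`, `"rooibos_tea"`,
#'   `"cotton"`), `initial`, `final`, `deploy_start`, `deploy_end`.
#' @param temperatures Data frame of hyporheic logger readings with columns
#'   `site`, `timestamp`, `celsius`.
#' @param spot_pairs Data frame of benthic spot measurements with columns
#'   `site`, `timestamp`, `celsius`; required when any assay is from the BZ.
#' @param params A [tbi_parameters()] object.
#' @param base_temp Degree-day base temperature (C), see [thermal_sum()].
#' @return A tibble with one row per bioassay: `bioassay_id`, `site`, `zone`,
#'   `t_dd`, `k_green`, `k_red`, `k_cotton`, `S`, `a_r`, `K` and TBI flags.
#'   Assays whose final value is zero yield `NA` coefficients with a warning
#'   rather than an error, so one ruined strip does not sink a survey.
#' @export
decay_table <- function(assays, temperatures, spot_pairs = NULL,
                        params = tbi_parameters(), base_temp = 0) {
  assert_cols(assays, c("bioassay_id", "site", "zone", "substrate",
                        "initial", "final", "deploy_start", "deploy_end"))
  assert_cols(temperatures, c("site", "timestamp", "celsius"))
  bad_sub <- setdiff(unique(assays$substrate),
                     c("green_tea", "rooibos_tea", "cotton"))
  if (length(bad_sub)) {
    abort(paste0("unknown substrate(s): ", paste(bad_sub, collapse = ", ")))
  }

  hz_by_site <- split(temperatures[c("timestamp", "celsius")],
                      temperatures$site)
  bz_by_site <- list()
  if (any(assays$zone == "BZ")) {
    if (is.null(spot_pairs)) {
      abort("`spot_pairs` are required to infer benthic temperatures")
    }
    assert_cols(spot_pairs, c("site", "timestamp", "celsius"))
    sp_by_site <- split(spot_pairs[c("timestamp", "celsius")],
                        spot_pairs$site)
    for (s in unique(assays$site[assays$zone == "BZ"])) {
      if (is.null(hz_by_site[[s]]) || is.null(sp_by_site[[s]])) {
        abort(sprintf("no temperature data for site '%s'", s))
      }
      bz_by_site[[s]] <-
        infer_benthic_temperature(sp_by_site[[s]], hz_by_site[[s]])$series
    }
  }

  per_assay <- assays %>%
    distinct(.data$bioassay_id, .data$site, .data$zone,
             .data$deploy_start, .data$deploy_end)
  per_assay$t_dd <- purrr::pmap_dbl(
    list(per_assay$site, per_assay$zone,
         per_assay$deploy_start, per_assay$deploy_end),
    function(site, zone, ds, de) {
      ser <- if (zone == "BZ") bz_by_site[[site]] else hz_by_site[[site]]
      if (is.null(ser)) abort(sprintf("no temperature data for site '%s'", site))
      thermal_sum(ser, ds, de, base_temp = base_temp)
    })

  wide <- assays %>%
    select("bioassay_id", "substrate", "initial", "final") %>%
    tidyr::pivot_wider(names_from = "substrate",
                       values_from = c("initial", "final"))
  out <- per_assay %>% left_join(wide, by = "bioassay_id")

  safe_k <- function(initial, final, t_dd) {
    ok <- is.finite(initial) & is.finite(final) & final > 0
    if (!all(ok, na.rm = TRUE)) {
      warn(sprintf("%d assay(s) with missing or zero final value; k set to NA",
                   sum(!ok)))
    }
    k <- rep(NA_real_, length(t_dd))
    if (any(ok)) k[ok] <- decay_coefficient(initial[ok], final[ok], t_dd[ok])
    k
  }
  out$k_green <- safe_k(out$initial_green_tea, out$final_green_tea, out$t_dd)
  out$k_red <- safe_k(out$initial_rooibos_tea, out$final_rooibos_tea, out$t_dd)
  out$k_cotton <- safe_k(out$initial_cotton, out$final_cotton, out$t_dd)

  tbi <- tea_bag_index(out$initial_green_tea, out$final_green_tea,
                       out$initial_rooibos_tea, out$final_rooibos_tea,
                       out$t_dd, params = params)
  dplyr::bind_cols(
    out %>% select("bioassay_id", "site", "zone", "t_dd",
                   "k_green", "k_red", "k_cotton"),
    tbi
  )
}
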