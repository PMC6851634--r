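# Community metrics: carbon biomass from counts and body dimensions, and
# rarefied/extrapolated Shannon alpha-diversity via order-1 Hill numbers.

#' Carbon conversion coefficients
#'
#' Body volume is converted to carbon as `C = cv * V^exp` (mg C, V in cubic
#' micrometres). Defaults follow widely used literature allometries: for
#' protists (ciliates, flagellates) a power function with exponent 0.939 and
#' 0.216 pg C per scaled cubic micrometre; for Eumetazoa invertebrates a
#' linear wet-volume conversion (1.1 g/cm3 wet density, 25% dry matter, 40%
#' carbon). All values are configuration, not measurements.
#'
#' @param ciliate,flagellate,eumetazoa Each a list with elements `cv`
#'   (mg C per cubic-micrometre-to-the-`exp`) and `exp`.
#' @return A named list of per-group coefficient lists.
#' @export
carbon_coefficients <- function(
    ciliate = list(cv = 0.216e-9, exp = 0.939),
    flagellate = list(cv = 0.216e-9, exp = 0.939),
    eumetazoa = list(cv = 1.1e-10, exp = 1)) {
  out <- list(ciliate = ciliate, flagellate = flagellate,
              eumetazoa = eumetazoa)
  for (g in names(out)) {
    if (!is.numeric(out[[g]]$cv) || out[[g]]$cv <= 0 ||
        !is.numeric(out[[g]]$exp) || out[[g]]$exp <= 0) {
      abort(sprintf("invalid carbon coefficients for group '%s'", g))
    }
  }
  out
}

#' Carbon content of one individual from its body dimensions
#'
#' Biovolume uses the ellipsoid model `V = (pi/6) L W^2` (cubic micrometres)
#' and is converted to carbon with per-group coefficients.
#'
#' @param length_um,width_um Body length and width in micrometres
#'   (`length_um >= width_um > 0`); vectors recycle.
#' @param group One of `"ciliate"`, `"flagellate"`, `"eumetazoa"`.
#' @param coefs A [carbon_coefficients()] list.
#' @return mg C per individual.
#' @export
#' @examples
#' individual_carbon(100, 50, "ciliate")
individual_carbon <- function(length_um, width_um, group,
                              coefs = carbon_coefficients()) {
  n <- max(length(length_um), length(width_um), length(group))
  length_um <- rep_len(length_um, n); width_um <- rep_len(width_um, n)
  group <- rep_len(group, n)
  if (any(!is.finite(length_um) | !is.finite(width_um) |
          length_um <= 0 | width_um <= 0)) {
    abort("body dimensions must be positive")
  }
  bad <- setdiff(unique(group), names(coefs))
  if (length(bad)) abort(paste0("unknown group(s): ", paste(bad, collapse = ", ")))
  v <- pi / 6 * length_um * width_um^2
  cv <- map_dbl(coefs, "cv")[group]
  ex <- map_dbl(coefs, "exp")[group]
  unname(cv * v^ex)
}

#' Per-group carbon biomass of one community sample
#'
#' Biomass (mg C/L) per taxonomic group is the sum over taxa of individual
#' carbon content times individual density (`count / volume`). An empty
#' record table is a valid all-zero sample.
#'
#' @param records Data frame with columns `taxon`, `group`, `count`,
#'   `length_um`, `width_um`.
#' @param volume_l Effective sampled volume in litres (> 0).
#' @param coefs A [carbon_coefficients()] list.
#' @return A tibble with columns `group`, `biomass_mg_l`, one row for each of
#'   the three groups (zero when absent).
#' @export
sample_biomass <- function(records, volume_l,
                           coefs = carbon_coefficients()) {
  assert_number(volume_l, "volume_l", lower = 1e-12)
  groups <- names(coefs)
  if (nrow(records) == 0L) {
    return(tibble(group = groups, biomass_mg_l = 0))
  }
  assert_cols(records, c("taxon", "group", "count", "length_um", "width_um"))
  if (any(records$count < 0)) abort("counts must be non-negative")
  records %>%
    mutate(carbon = individual_carbon(.data$length_um, .data$width_um,
                                      .data$group, coefs),
           contrib = .data$carbon * .data$count / volume_l) %>%
    group_by(group = factor(.data$group, levels = groups)) %>%
    summarise(biomass_mg_l = sum(.data$contrib), .groups = "drop") %>%
    tidyr::complete(group, fill = list(biomass_mg_l = 0)) %>%
    mutate(group = as.character(.data$group))
}

#' Prokaryote carbon biomass from cell counts and diameters
#'
#' Cells are treated as spheres of the mean diameter; the default conversion
#' applies a fixed carbon density (fg C per cubic micrometre) to the cell
#' volume.
#'
#' @param cell_density Cells per millilitre (vectorised).
#' @param mean_diameter_um Mean cell diameter in micrometres, in (0.1, 5).
#' @param fg_c_per_um3 Carbon density, fg C per cubic micrometre
#'   (default 200, a mid-range literature value; configuration).
#' @return mg C/L.
#' @export
#' @examples
#' prokaryote_biomass(1e6, 1)
prokaryote_biomass <- function(cell_density, mean_diameter_um,
                               fg_c_per_um3 = 200) {
  if (any(cell_density < 0)) abort("`cell_density` must be non-negative")
  if (any(mean_diameter_um <= 0.1 | mean_diameter_um >= 5)) {
    abort("`mean_diameter_um` must lie in (0.1, 5)")
  }
  v <- pi / 6 * mean_diameter_um^3                  # um^3 per cell
  # cells/ml * 1000 ml/L * um^3 * fgC/um^3 * 1e-12 mg/fg
  cell_density * 1000 * v * fg_c_per_um3 * 1e-12
}

# Exact expected Shannon entropy of a without-replacement subsample of size m,
# via species-wise hypergeometric expectations.
interpolated_entropy <- function(x, m) {
  x <- x[x > 0]
  n <- sum(x)
  total <- 0
  for (k in seq_len(m)) {
    w <- if (k == m) 0 else -(k / m) * log(k / m)
    if (w == 0) next
    xi <- x[x >= k]
    if (!length(xi)) next
    p <- exp(lchoose(xi, k) + lchoose(n - xi, m - k) - lchoose(n, m))
    total <- total + w * sum(p)
  }
  total
}

# Asymptotic (low-bias) Shannon entropy estimator from sample frequencies.
chao_entropy <- function(x) {
  x <- x[x > 0]
  n <- sum(x)
  if (n <= 1) return(0)
  xi <- x[x <= n - 1]
  part1 <- if (length(xi)) {
    sum(vapply(xi, function(v) v / n * sum(1 / (v:(n - 1))), numeric(1)))
  } else 0
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f1 == 0) return(part1)
  a <- if (f2 > 0) {
    2 * f2 / ((n - 1) * f1 + 2 * f2)
  } else if (f1 > 1) {
    2 / ((n - 1) * (f1 - 1) + 2)
  } else 1
  if (a >= 1) return(part1)
  r <- seq_len(n - 1)
  part1 + f1 / n * (1 - a)^(1 - n) * (-log(a) - sum((1 - a)^r / r))
}

#' Rarefied or extrapolated Shannon diversity via order-1 Hill numbers
#'
#' Standardizes Shannon diversity to a common base sample size. For
#' `base_size <= n` the exact expected entropy of a without-replacement
#' subsample is computed from species-wise hypergeometric expectations
#' (interpolation). For `base_size > n` the entropy is extrapolated as a
#' size-weighted mixture of the observed plug-in entropy and the asymptotic
#' low-bias entropy estimator, so the curve is continuous at `n` and
#' approaches the asymptotic estimate as the base size grows.
#'
#' @param counts Non-negative integer abundance vector (at least one
#'   individual in total).
#' @param base_size Target sample size (>= 1 individuals).
#' @return Shannon `H` (natural log) of the standardized sample; `exp(H)` is
#'   the order-1 Hill number (effective number of taxa).
#' @export
#' @examples
#' rarefied_shannon(c(8, 2), 2)
rarefied_shannon <- function(counts, base_size) {
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers")
  }
  x <- counts[counts > 0]
  if (!length(x)) abort("`counts` has no individuals")
  base_size <- assert_count(base_size, "base_size")
  n <- sum(x)
  if (base_size <= n) {
    interpolated_entropy(x, base_size)
  } else {
    p <- x / n
    h_obs <- -sum(p * log(p))
    w <- n / base_size
    w * h_obs + (1 - w) * max(chao_entropy(x), h_obs)
  }
}

#' Common base sample size for diversity comparison
#'
#' The comparison size is the largest total abundance, capped at twice the
#' smallest (the usual rarefaction/extrapolation convention: extrapolate no
#' further than double the smallest sample).
#'
#' @param totals Vector of per-sample total abundances (>= 1 each).
#' @param cap Extrapolation cap as a multiple of the smallest sample
#'   (default 2).
#' @return A single integer base size.
#' @export
base_sample_size <- function(totals, cap = 2) {
  totals <- totals[is.finite(totals) & totals >= 1]
  if (!length(totals)) abort("no usable sample totals")
  as.integer(max(1, min(max(totals), floor(cap * min(totals)))))
}

#' Per-bioassay biological summary (the mediator table)
#'
#' Combines organism counts/dimensions, prokaryote counts and (optionally)
#' EcoPlate readings into one row per bioassay: group biomasses, rarefied
#' alpha-diversities of Protozoa and Eumetazoa, and prokaryote metrics.
#' Flagellates contribute to Protozoa biomass but count as a single taxon in
#' diversity.
#'
#' @param organisms Data frame: `bioassay_id`, `taxon`, `group`
#'   (`"ciliate"`, `"flagellate"`, `"eumetazoa"`), `count`, `length_um`,
#'   `width_um`.
#' @param volumes Data frame: `bioassay_id`, `volume_l`.
#' @param prokaryotes Data frame: `bioassay_id`, `cell_density`,
#'   `mean_diameter_um`.
#' @param ecoplates Optional long EcoPlate table, see [ecoplate_table()].
#' @param coefs [carbon_coefficients()] list.
#' @param base_sizes Optional named list with elements `eumetazoa` and
#'   `protozoa` overriding the automatic [base_sample_size()] choice.
#' @param fg_c_per_um3 Prokaryote carbon density, see
#'   [prokaryote_biomass()].
#' @param od_threshold Activity threshold for EcoPlate metabolic richness.
#' @return A tibble with one row per bioassay: `inv_biomass`,
#'   `prot_biomass`, `prok_biomass` (mg C/L), `inv_diversity`,
#'   `prot_diversity` (Shannon H), and when `ecoplates` is supplied
#'   `plate_awcd`, `metab_richness`, `metab_diversity`.
#' @export
biological_summary <- function(organisms, volumes, prokaryotes,
                               ecoplates = NULL,
                               coefs = carbon_coefficients(),
                               base_sizes = NULL,
                               fg_c_per_um3 = 200,
                               od_threshold = 0.25) {
  assert_cols(organisms, c("bioassay_id", "taxon", "group", "count",
                           "length_um", "width_um"))
  assert_cols(volumes, c("bioassay_id", "volume_l"))
  assert_cols(prokaryotes, c("bioassay_id", "cell_density",
                             "mean_diameter_um"))

  ids <- unique(volumes$bioassay_id)
  org_split <- split(organisms, factor(organisms$bioassay_id, levels = ids))

  biomass <- imap(org_split, function(rec, id) {
    vol <- volumes$volume_l[match(id, volumes$bioassay_id)]
    sample_biomass(rec, vol, coefs) %>%
      tidyr::pivot_wider(names_from = "group", values_from = "biomass_mg_l")
  }) %>%
    bind_rows(.id = "bioassay_id") %>%
    mutate(inv_biomass = .data$eumetazoa,
           prot_biomass = .data$ciliate + .data$flagellate) %>%
    select("bioassay_id", "inv_biomass", "prot_biomass")

  # Diversity count vectors: Eumetazoa by taxon; Protozoa = ciliate taxa plus
  # the pooled flagellate group.
  div_counts <- function(rec) {
    eum <- rec %>% filter(.data$group == "eumetazoa") %>%
      group_by(.data$taxon) %>% summarise(n = sum(.data$count), .groups = "drop")
    cil <- rec %>% filter(.data$group == "ciliate") %>%
      group_by(.data$taxon) %>% summarise(n = sum(.data$count), .groups = "drop")
    fla <- sum(rec$count[rec$group == "flagellate"])
    list(eumetazoa = eum$n, protozoa = c(cil$n, if (fla > 0) fla))
  }
  counts <- map(org_split, div_counts)
  totals <- function(which) map_dbl(counts, ~ sum(.x[[which]]))
  safe_base <- function(tt) {
    tt <- tt[tt >= 1]
    if (length(tt)) base_sample_size(tt) else NA_integer_
  }
  base_eum <- base_sizes$eumetazoa %||% safe_base(totals("eumetazoa"))
  base_pro <- base_sizes$protozoa %||% safe_base(totals("protozoa"))
  shannon_or_na <- function(x, m) {
    if (is.na(m) || sum(x) < 1) NA_real_ else rarefied_shannon(x, m)
  }
  diversity <- tibble(
    bioassay_id = names(counts),
    inv_diversity = map_dbl(counts, ~ shannon_or_na(.x$eumetazoa, base_eum)),
    prot_diversity = map_dbl(counts, ~ shannon_or_na(.x$protozoa, base_pro))
  )

  prok <- prokaryotes %>%
    mutate(prok_biomass = prokaryote_biomass(.data$cell_density,
                                             .data$mean_diameter_um,
                                             fg_c_per_um3)) %>%
    select("bioassay_id", "prok_biomass")

  out <- tibble(bioassay_id = ids) %>%
    left_join(biomass, by = "bioassay_id") %>%
    left_join(diversity, by = "bioassay_id") %>%
    left_join(prok, by = "bioassay_id")

  if (!is.null(ecoplates)) {
    eco <- ecoplate_table(ecoplates, activity_threshold = od_threshold)
    out <- left_join(out, eco %>% select("bioassay_id", "plate_awcd",
                                         "metab_richness", "metab_diversity"),
                     by = "bioassay_id")
  }
  out
}
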