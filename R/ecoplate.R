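# EcoPlate metrics: average well colour development (AWCD), metabolic
# richness and Shannon metabolic diversity from 96-well absorbance data.

#' Summarise one EcoPlate reading
#'
#' Each plate carries 31 carbon-source substrates in triplicate plus three
#' water controls. Wells are blanked against the mean control absorbance and
#' floored at zero; the per-substrate AWCD is the mean of the three blanked
#' replicates, the plate AWCD is the mean over the 31 substrates, metabolic
#' richness counts substrates whose AWCD exceeds `activity_threshold`, and
#' metabolic diversity is the Shannon index of the relative substrate AWCDs.
#'
#' @param plate Data frame in long format with columns `substrate`,
#'   `replicate`, `od` and logical `is_control` (3 control rows, 31 x 3
#'   substrate rows).
#' @param activity_threshold OD threshold above which a substrate counts as
#'   utilised (default 0.25, a common EcoPlate convention).
#' @return A list with `plate_awcd`, `substrate_awcd` (named vector),
#'   `metab_richness`, `metab_diversity` and `diversity_defined` (FALSE when
#'   no substrate developed colour, in which case H' is reported as 0).
#' @export
#' @examples
#' plate <- expand.grid(substrate = paste0("S", 1:31), replicate = 1:3)
#' plate$od <- 0.3; plate$is_control <- FALSE
#' ctrl <- data.frame(substrate = "water", replicate = 1:3, od = 0.05,
#'                    is_control = TRUE)
#' ecoplate_summary(rbind(plate, ctrl))$metab_diversity  # log(31)
ecoplate_summary <- function(plate, activity_threshold = 0.25) {
  assert_cols(plate, c("substrate", "replicate", "od", "is_control"))
  if (any(plate$od < 0)) abort("absorbances must be non-negative")
  ctrl <- plate$od[plate$is_control]
  subs <- plate[!plate$is_control, ]
  if (length(ctrl) != 3L) abort("expected exactly 3 control wells")
  n_rep <- table(subs$substrate)
  if (length(n_rep) != 31L || any(n_rep != 3L)) {
    abort("expected 31 substrates with 3 replicate wells each")
  }
  blanked <- pmax(subs$od - mean(ctrl), 0)
  substrate_awcd <- tapply(blanked, subs$substrate, mean)
  substrate_awcd <- substrate_awcd[sort(names(substrate_awcd))]
  plate_awcd <- mean(substrate_awcd)
  richness <- sum(substrate_awcd > activity_threshold)
  tot <- sum(substrate_awcd)
  if (tot > 0) {
    p <- substrate_awcd[substrate_awcd > 0] / tot
    h <- -sum(p * log(p))
    defined <- TRUE
  } else {
    h <- 0
    defined <- FALSE
  }
  list(plate_awcd = unname(plate_awcd),
       substrate_awcd = substrate_awcd,
       metab_richness = as.integer(richness),
       metab_diversity = unname(h),
       diversity_defined = defined)
}

#' Summarise a table of EcoPlate readings
#'
#' Applies [ecoplate_summary()] to each bioassay in a long plate table.
#'
#' @param plates Data frame with columns `bioassay_id`, `substrate`,
#'   `replicate`, `od`, `is_control`.
#' @param activity_threshold See [ecoplate_summary()].
#' @return A tibble with one row per bioassay: `plate_awcd`,
#'   `metab_richness`, `metab_diversity`, `diversity_defined`.
#' @export
ecoplate_table <- function(plates, activity_threshold = 0.25) {
  assert_cols(plates, c("bioassay_id", "substrate", "replicate", "od",
                        "is_control"))
  map_dfr(split(plates, plates$bioassay_id), function(p) {
    s <- ecoplate_summary(p, activity_threshold)
    tibble(plate_awcd = s$plate_awcd,
           metab_richness = s$metab_richness,
           metab_diversity = s$metab_diversity,
           diversity_defined = s$diversity_defined)
  }, .id = "bioassay_id")
}
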