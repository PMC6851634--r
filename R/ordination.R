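# Community-structure ordination: Bray-Curtis dissimilarity, multi-start
# non-metric multidimensional scaling, and permutation-tested fitting of
# environmental/biological vectors and factors onto the ordination.

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 sum(min(x_i, y_i)) / sum(x_i + y_i)`, the
#' abundance-weighted compositional distance. Computed with
#' [vegan::vegdist()]. Rows whose abundances are all zero have no defined
#' dissimilarity and raise an error.
#'
#' @param mat Numeric matrix or data frame: rows are pooled communities,
#'   columns are taxa, cells are non-negative abundances.
#' @return A `dist` object.
#' @export
#' @examples
#' bray_curtis(rbind(a = c(2, 0), b = c(1, 1)))  # 0.5
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) abort("abundances must be non-negative")
  zero <- rowSums(mat) == 0
  if (any(zero)) {
    abort(sprintf("all-zero row(s) have undefined dissimilarity: %s",
                  paste(rownames(mat)[zero] %||% which(zero), collapse = ", ")))
  }
  vegan::vegdist(mat, method = "bray")
}

#' Non-metric multidimensional scaling with random restarts
#'
#' Minimises Kruskal stress-1 by monotone (isotonic) regression of
#' configuration distances on the supplied dissimilarities
#' ([vegan::monoMDS()], global model). The first start is initialised from
#' metric scaling; the remaining `n_starts - 1` use random configurations,
#' and the lowest-stress solution is kept. The run is reproducible under
#' `seed`.
#'
#' @param dissim A `dist` object (or symmetric matrix) of dissimilarities
#'   for at least 4 points.
#' @param n_dim Number of ordination dimensions (default 2).
#' @param n_starts Number of starts including the metric one (default 50).
#' @param maxit Maximum iterations per start (default 500).
#' @param seed Optional integer seed for the random starts.
#' @param ties Tie treatment in the monotone regression: `"weak"` (default;
#'   tied dissimilarities may map to different fitted distances) or
#'   `"strong"` (tied dissimilarities share one fitted value — needed for
#'   highly symmetric configurations whose geometry is only pinned down by
#'   the tie structure, such as the corners of a square).
#' @return An object of class `litter_nmds`: list with `points` (tibble of
#'   coordinates `NMDS1..`, plus `row` labels), `stress` (Kruskal stress-1,
#'   in \[0, 1\]), `linear_r2`, `nonmetric_r2`, `n_obs`, `n_starts` and the
#'   best `vegan::monoMDS` fit in `$fit`.
#' @details The non-metric fit is `R^2 = 1 - stress^2`; the linear fit is the
#'   squared correlation between the monotone-fitted values and the
#'   ordination distances, both as conventionally reported alongside Shepard
#'   plots.
#' @export
run_nmds <- function(dissim, n_dim = 2, n_starts = 50, maxit = 500,
                     seed = NULL, ties = c("weak", "strong")) {
  ties <- match.arg(ties)
  if (!inherits(dissim, "dist")) dissim <- stats::as.dist(dissim)
  n <- attr(dissim, "Size")
  if (n < 4) abort("NMDS needs at least 4 rows")
  assert_count(n_dim, "n_dim"); assert_count(n_starts, "n_starts")
  if (!is.null(seed)) set.seed(seed)
  ctrl <- list(model = "global", k = n_dim, maxit = maxit,
               weakties = ties == "weak",
               smin = 1e-12, sfgrmin = 1e-12, sratmax = 1 - 1e-9)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- if (s == 1L) {
      do.call(vegan::monoMDS, c(list(dissim), ctrl))
    } else {
      init <- matrix(rnorm(n * n_dim), n, n_dim)
      do.call(vegan::monoMDS, c(list(dissim, y = init), ctrl))
    }
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- as_tibble(best$points, .name_repair = "minimal")
  names(pts) <- paste0("NMDS", seq_len(n_dim))
  pts$row <- attr(dissim, "Labels") %||% as.character(seq_len(n))
  structure(list(
    points = pts[, c("row", paste0("NMDS", seq_len(n_dim)))],
    stress = best$stress,
    linear_r2 = stats::cor(best$dist, best$dhat)^2,
    nonmetric_r2 = 1 - best$stress^2,
    n_obs = n, n_dim = n_dim, n_starts = n_starts,
    fit = best
  ), class = "litter_nmds")
}

nmds_scores <- function(ordination) {
  if (inherits(ordination, "litter_nmds")) {
    as.matrix(ordination$points[, paste0("NMDS", seq_len(ordination$n_dim))])
  } else {
    as.matrix(ordination)
  }
}

#' Fit environmental and biological variables to an ordination
#'
#' For a continuous variable, the direction and squared correlation come from
#' the least-squares projection of the (centred) variable onto the ordination
#' coordinates. For a factor, goodness of fit is the between-centroid share
#' of the coordinate sum of squares. Significance is assessed by permuting
#' the variable across rows: `p = (1 + #[R2_perm >= R2_obs]) / (1 + n_perm)`,
#' so the smallest attainable p-value is `1 / (1 + n_perm)`.
#'
#' @param ordination A `litter_nmds` object or a coordinate matrix.
#' @param variables Data frame of covariates aligned with the ordination
#'   rows; numeric columns are fitted as vectors, character/factor columns as
#'   factors.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return A tibble with one row per continuous variable and one row per
#'   factor level: `variable`, `type`, `level` (factors only), axis
#'   coordinates (unit direction for vectors, level centroids for factors),
#'   `r2`, `p_perm` and a `constant` flag (constant variables get `r2 = 0`,
#'   `p_perm = 1`).
#' @export
fit_vectors <- function(ordination, variables, n_perm = 1000, seed = NULL) {
  x <- nmds_scores(ordination)
  n <- nrow(x)
  if (nrow(variables) != n) {
    abort("`variables` must have one row per ordination point")
  }
  if (!is.null(seed)) set.seed(seed)
  xc <- scale(x, center = TRUE, scale = FALSE)
  hat <- xc %*% solve(crossprod(xc)) %*% t(xc)
  axis_names <- paste0("NMDS", seq_len(ncol(x)))

  perm_idx <- replicate(n_perm, sample.int(n))

  fit_one <- function(v, name) {
    if (is.numeric(v)) {
      if (sd(v) < 1e-12) {
        out <- tibble(variable = name, type = "vector", level = NA_character_,
                      r2 = 0, p_perm = 1, constant = TRUE)
        out[axis_names] <- NA_real_
        return(out[, c("variable", "type", "level", axis_names,
                       "r2", "p_perm", "constant")])
      }
      vc <- v - mean(v)
      r2_of <- function(vm) colSums((hat %*% vm)^2) / colSums(vm^2)
      r2 <- r2_of(cbind(vc))
      coefs <- solve(crossprod(xc), crossprod(xc, vc))
      dir <- drop(coefs) / sqrt(sum(coefs^2))
      vp <- matrix(vc[perm_idx], nrow = n)
      p <- (1 + sum(r2_of(vp) >= r2)) / (1 + n_perm)
      out <- tibble(variable = name, type = "vector", level = NA_character_,
                    r2 = unname(r2), p_perm = p, constant = FALSE)
      out[axis_names] <- as.list(dir)
      out[, c("variable", "type", "level", axis_names,
              "r2", "p_perm", "constant")]
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L) {
        out <- tibble(variable = name, type = "factor",
                      level = levels(f)[1] %||% NA_character_,
                      r2 = 0, p_perm = 1, constant = TRUE)
        out[axis_names] <- NA_real_
        return(out[, c("variable", "type", "level", axis_names,
                       "r2", "p_perm", "constant")])
      }
      ss_tot <- sum(xc^2)
      r2_of <- function(ff) {
        within <- 0
        for (l in levels(ff)) {
          rows <- xc[ff == l, , drop = FALSE]
          if (nrow(rows)) {
            within <- within +
              sum(scale(rows, center = TRUE, scale = FALSE)^2)
          }
        }
        1 - within / ss_tot
      }
      r2 <- r2_of(f)
      p <- (1 + sum(vapply(seq_len(n_perm),
                           function(i) r2_of(f[perm_idx[, i]]),
                           numeric(1)) >= r2)) / (1 + n_perm)
      cent <- t(vapply(levels(f),
                       function(l) colMeans(x[f == l, , drop = FALSE]),
                       numeric(ncol(x))))
      out <- tibble(variable = name, type = "factor", level = levels(f),
                    r2 = r2, p_perm = p, constant = FALSE)
      out[axis_names] <- as_tibble(cent, .name_repair = "minimal") %>%
        set_names(axis_names)
      out[, c("variable", "type", "level", axis_names,
              "r2", "p_perm", "constant")]
    }
  }

  imap(as.list(variables), fit_one) %>% bind_rows()
}

#' Pool bioassay abundances by site and zone
#'
#' Replicate bioassays are pooled per stream x compartment prior to
#' ordination: per-taxon densities (count / volume, individuals per litre)
#' are summed over the replicate bioassays.
#'
#' @param organisms Organism table (see [biological_summary()]) with
#'   additional `site` and `zone` columns, or joined via `assay_info`.
#' @param volumes Data frame `bioassay_id`, `volume_l`.
#' @param assay_info Data frame `bioassay_id`, `site`, `zone` (only needed
#'   when `organisms` lacks those columns).
#' @return A list with `mat` (site-zone x taxa abundance matrix, ind/L) and
#'   `meta` (tibble with `row`, `site`, `zone`).
#' @export
pool_abundances <- function(organisms, volumes, assay_info = NULL) {
  if (!all(c("site", "zone") %in% names(organisms))) {
    assert_cols(assay_info, c("bioassay_id", "site", "zone"), "assay_info")
    organisms <- left_join(organisms,
                           distinct(assay_info, .data$bioassay_id,
                                    .data$site, .data$zone),
                           by = "bioassay_id")
  }
  assert_cols(volumes, c("bioassay_id", "volume_l"))
  dens <- organisms %>%
    left_join(volumes, by = "bioassay_id") %>%
    mutate(density = .data$count / .data$volume_l,
           row = paste(.data$site, .data$zone, sep = ":")) %>%
    group_by(.data$row, .data$site, .data$zone, .data$taxon) %>%
    summarise(density = sum(.data$density), .groups = "drop")
  wide <- dens %>%
    tidyr::pivot_wider(names_from = "taxon", values_from = "density",
                       values_fill = 0) %>%
    arrange(.data$row)
  mat <- as.matrix(wide[, setdiff(names(wide), c("row", "site", "zone"))])
  rownames(mat) <- wide$row
  list(mat = mat, meta = wide[, c("row", "site", "zone")])
}
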