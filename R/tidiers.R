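# broom-style tidiers for the package's result objects.

#' Tidy an NMDS ordination
#'
#' @param x A `litter_nmds` object.
#' @param ... Unused.
#' @return Tibble of row labels and ordination coordinates.
#' @exportS3Method generics::tidy
tidy.litter_nmds <- function(x, ...) x$points

#' One-row summary of an NMDS ordination
#'
#' @param x A `litter_nmds` object.
#' @param ... Unused.
#' @return Tibble with `stress`, `linear_r2`, `nonmetric_r2`, `n_obs`,
#'   `n_dim`, `n_starts`.
#' @exportS3Method generics::glance
glance.litter_nmds <- function(x, ...) {
  tibble(stress = x$stress, linear_r2 = x$linear_r2,
         nonmetric_r2 = x$nonmetric_r2, n_obs = x$n_obs,
         n_dim = x$n_dim, n_starts = x$n_starts)
}

#' @export
print.litter_nmds <- function(x, ...) {
  cat(sprintf(
    "NMDS (%d points, %d dimensions, %d starts)\n  stress-1 = %.5f, linear R2 = %.4f, non-metric R2 = %.4f\n",
    x$n_obs, x$n_dim, x$n_starts, x$stress, x$linear_r2, x$nonmetric_r2))
  invisible(x)
}

#' Tidy a three-step mediation fit
#'
#' One row per estimated path: the total effect (`c`), direct effect
#' (`c_prime`), compartment-to-mediator paths (`a`) and mediator-to-response
#' paths (`b`, for retained mediators).
#'
#' @param x A `litter_mediation` object.
#' @param ... Unused.
#' @return Tibble with `path`, `mediator`, `estimate`, `se`, `df`,
#'   `statistic`, `p_value`, `stars`.
#' @exportS3Method generics::tidy
tidy.litter_mediation <- function(x, ...) {
  bind_rows(
    tibble(path = "c", mediator = NA_character_, estimate = x$c,
           se = x$c_se, df = NA_real_, statistic = x$c / x$c_se,
           p_value = x$c_p),
    tibble(path = "c_prime", mediator = NA_character_,
           estimate = x$c_prime, se = x$c_prime_se, df = NA_real_,
           statistic = x$c_prime / x$c_prime_se, p_value = x$c_prime_p),
    x$a_paths %>%
      mutate(path = "a") %>%
      select("path", "mediator", "estimate", "se", "df", "statistic",
             "p_value"),
    x$b_paths %>%
      mutate(path = "b") %>%
      select("path", "mediator", "estimate", "se", "df", "statistic",
             "p_value")
  ) %>% mutate(stars = p_stars(.data$p_value))
}

#' One-row summary of a three-step mediation fit
#'
#' @param x A `litter_mediation` object.
#' @param ... Unused.
#' @return Tibble with the total/direct effects, proportion mediated with
#'   its delta-method CI, classification, flags and fit size.
#' @exportS3Method generics::glance
glance.litter_mediation <- function(x, ...) {
  tibble(response = x$response,
         c = x$c, c_se = x$c_se, c_p = x$c_p,
         c_prime = x$c_prime, c_prime_se = x$c_prime_se,
         c_prime_p = x$c_prime_p,
         indirect = x$c - x$c_prime,
         proportion_mediated = x$proportion_mediated,
         proportion_se = x$proportion_se,
         ci_lower = x$proportion_ci[1], ci_upper = x$proportion_ci[2],
         classification = x$classification,
         flags = paste(x$flags, collapse = ";"),
         mediators_retained = paste(x$selection$retained, collapse = ";"),
         n_obs = x$n_obs)
}
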