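# Random-factors ANOVA and causal three-step mediation analysis over linear
# mixed models with site-within-catchment random intercepts.

#' Standardize mediator columns
#'
#' Centres and scales the named columns by their sample mean and SD, so
#' model coefficients are comparable across mediators. Zero-variance columns
#' are dropped with a warning. The transform parameters are stored in the
#' `"std_params"` attribute for back-conversion.
#'
#' @param data A data frame.
#' @param vars Character vector of columns to standardize.
#' @return `data` with the surviving columns standardized; attributes
#'   `std_params` (tibble of `variable`, `center`, `scale`) and
#'   `dropped` (character vector).
#' @export
standardize_mediators <- function(data, vars) {
  assert_cols(data, vars)
  params <- tibble(variable = vars,
                   center = map_dbl(vars, ~ mean(data[[.x]], na.rm = TRUE)),
                   scale = map_dbl(vars, ~ sd(data[[.x]], na.rm = TRUE)))
  dropped <- params$variable[!is.finite(params$scale) | params$scale < 1e-12]
  if (length(dropped)) {
    warn(paste0("dropping zero-variance mediator(s): ",
                paste(dropped, collapse = ", ")))
    data <- data[, setdiff(names(data), dropped)]
    params <- params[!params$variable %in% dropped, ]
  }
  for (i in seq_len(nrow(params))) {
    v <- params$variable[i]
    data[[v]] <- (data[[v]] - params$center[i]) / params$scale[i]
  }
  attr(data, "std_params") <- params
  attr(data, "dropped") <- dropped
  data
}

#' Fit a (mixed) linear model by REML
#'
#' Thin wrapper around [lmerTest::lmer()] giving Satterthwaite degrees of
#' freedom for t-tests. A formula without random-effect terms falls back to
#' ordinary least squares via [lm()]. Singular fits (a variance component at
#' zero) are retained and flagged via the `"singular"` attribute.
#'
#' @param data Model frame.
#' @param formula Model formula; random intercepts in `lme4` syntax, e.g.
#'   `y ~ zone_bz + (1 | catchment / site)`.
#' @param reml Use REML (default) or maximum likelihood.
#' @return The fitted model (`lmerModLmerTest` or `lm`).
#' @export
fit_lmm <- function(data, formula, reml = TRUE) {
  formula <- as.formula(formula)
  has_ranef <- length(lme4::findbars(formula)) > 0
  if (!has_ranef) {
    fit <- lm(formula, data = data)
    attr(fit, "singular") <- FALSE
    return(fit)
  }
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- lmerTest::lmer(formula, data = data, REML = reml, control = ctrl)
  attr(fit, "singular") <- lme4::isSingular(fit, tol = 1e-5)
  fit
}

#' Coefficient table of a fitted (mixed) model
#'
#' @param fit A model from [fit_lmm()].
#' @return Tibble with `term`, `estimate`, `se`, `df`, `statistic`,
#'   `p_value`.
#' @export
lmm_coefs <- function(fit) {
  cs <- coef(summary(fit))
  terms <- rownames(cs)
  cs <- unname(cs)
  if (inherits(fit, "lm")) {
    tibble(term = terms, estimate = cs[, 1], se = cs[, 2],
           df = fit$df.residual, statistic = cs[, 3], p_value = cs[, 4])
  } else {
    tibble(term = terms, estimate = cs[, 1], se = cs[, 2], df = cs[, 3],
           statistic = cs[, 4], p_value = cs[, 5])
  }
}

# Variance components of an lmer fit as a named vector (residual included).
variance_components <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  setNames(vc$vcov, ifelse(is.na(vc$grp), "residual", vc$grp))
}

# Total error variance of a fit: residual variance plus random-intercept
# variances (lm: residual variance only).
total_error_variance <- function(fit) {
  if (inherits(fit, "lm")) return(summary(fit)$sigma^2)
  sum(variance_components(fit))
}

zone_indicator <- function(zone) {
  bad <- setdiff(unique(as.character(zone)), c("BZ", "HZ"))
  if (length(bad)) {
    abort(paste0("`zone` must be 'BZ' or 'HZ'; found: ",
                 paste(bad, collapse = ", ")))
  }
  as.integer(zone == "BZ")  # positive coefficients mean faster benthic rates
}

#' Random-factors ANOVA contrast between streambed compartments
#'
#' Mixed-model one-way ANOVA of a biological variable against the streambed
#' compartment, with site-within-catchment random intercepts absorbing the
#' repeated measures per stream.
#'
#' @param data Data frame with the variable plus `zone`, `site`,
#'   `catchment` columns.
#' @param variable Name of the response column.
#' @param random Random-effects term (default site nested in catchment);
#'   `NULL` for plain one-way ANOVA.
#' @return One-row tibble: `variable`, `estimate` (BZ minus HZ), `se`,
#'   `f`, `df_num`, `df_den`, `p_value`, `mean_bz`, `mean_hz`, `stars`.
#' @export
anova_zone_contrast <- function(data, variable,
                                random = "(1 | catchment / site)") {
  assert_cols(data, c(variable, "zone"))
  if (length(unique(data$zone)) < 2L) {
    abort("both compartments (BZ and HZ) must be present")
  }
  data$zone_bz <- zone_indicator(data$zone)
  rhs <- if (is.null(random)) "zone_bz" else paste("zone_bz +", random)
  fit <- fit_lmm(data, paste(variable, "~", rhs))
  cs <- lmm_coefs(fit)
  av <- anova(fit)
  zrow <- grep("zone_bz", rownames(av))
  if (inherits(fit, "lm")) {
    f <- av[zrow, "F value"]; df1 <- av[zrow, "Df"]
    df2 <- av["Residuals", "Df"]; p <- av[zrow, "Pr(>F)"]
  } else {
    f <- av[zrow, "F value"]; df1 <- av[zrow, "NumDF"]
    df2 <- av[zrow, "DenDF"]; p <- av[zrow, "Pr(>F)"]
  }
  b0 <- cs$estimate[cs$term == "(Intercept)"]
  b1 <- cs$estimate[cs$term == "zone_bz"]
  tibble(variable = variable, estimate = b1,
         se = cs$se[cs$term == "zone_bz"],
         f = f, df_num = df1, df_den = df2, p_value = p,
         mean_bz = b0 + b1, mean_hz = b0, stars = p_stars(p))
}

#' Backward model selection for the mediated regression
#'
#' Backward elimination on maximum-likelihood fits comparing AIC:
#' zone-by-mediator interactions are considered before main effects, a main
#' effect is only droppable while no retained interaction involves it, and a
#' term is dropped when its removal does not worsen AIC by more than
#' `aic_keep` (so only terms carrying at least that much information are
#' kept). The compartment term is never dropped. The final specification is
#' meant to be refitted by REML (as [mediate_three_step()] does).
#'
#' @param data Model frame containing `zone_bz`, the response and mediators.
#' @param response Response column name.
#' @param mediators Character vector of candidate (standardized) mediators.
#' @param interactions Consider `zone_bz:mediator` interactions (default
#'   TRUE).
#' @param random Random-effects term or `NULL`.
#' @param aic_keep AIC margin a term must carry to stay (default 2).
#' @return List with `formula` (character), `retained` (mains),
#'   `retained_interactions`, and `log` (tibble of the elimination path).
#' @export
select_model <- function(data, response, mediators, interactions = TRUE,
                         random = "(1 | catchment / site)", aic_keep = 2) {
  if (!length(mediators)) abort("at least one candidate mediator is needed")
  mains <- mediators
  ints <- if (interactions) paste0("zone_bz:", mediators) else character(0)
  build <- function(mains, ints) {
    rhs <- paste(c("zone_bz", mains, ints), collapse = " + ")
    if (!is.null(random)) rhs <- paste(rhs, "+", random)
    paste(response, "~", rhs)
  }
  aic_of <- function(mains, ints) {
    AIC(fit_lmm(data, build(mains, ints), reml = FALSE))
  }
  log <- list()
  current_aic <- aic_of(mains, ints)
  step <- 0L
  repeat {
    droppable_ints <- ints
    droppable_mains <- setdiff(mains, sub("^zone_bz:", "", ints))
    cands <- c(droppable_ints, droppable_mains)
    if (!length(cands)) break
    trial <- map_dbl(cands, function(term) {
      if (term %in% ints) aic_of(mains, setdiff(ints, term))
      else aic_of(setdiff(mains, term), ints)
    })
    # interactions take precedence when both are droppable
    order_key <- ifelse(cands %in% ints, 0, 1)
    ok <- trial < current_aic + aic_keep
    if (!any(ok)) break
    idx_ok <- which(ok)
    pick <- idx_ok[order(order_key[idx_ok], trial[idx_ok])][1]
    term <- cands[pick]
    step <- step + 1L
    log[[step]] <- tibble(step = step, dropped = term,
                          aic_before = current_aic, aic_after = trial[pick])
    if (term %in% ints) ints <- setdiff(ints, term)
    else mains <- setdiff(mains, term)
    current_aic <- trial[pick]
  }
  list(formula = build(mains, ints), retained = mains,
       retained_interactions = ints,
       log = if (length(log)) bind_rows(log) else
         tibble(step = integer(), dropped = character(),
                aic_before = numeric(), aic_after = numeric()))
}

#' Causal three-step mediation analysis
#'
#' Decomposes the effect of the streambed compartment on a breakdown
#' response into a direct and a biologically mediated part:
#' step 1 regresses the response on compartment alone (total effect `c`);
#' step 2 regresses each mediator on compartment (paths `a_j`); step 3
#' regresses the response on compartment plus the mediators (direct effect
#' `c'` and paths `b_j`), optionally after backward AIC selection of
#' mediators and zone-by-mediator interactions. All models carry
#' site-within-catchment random intercepts and are reported from REML fits.
#'
#' The proportion mediated is the difference-in-coefficients estimator
#' `(c - c') / c`, reported only when the total effect is significant at
#' `alpha`; its confidence interval uses a delta-method standard error with
#' the nested-model identity `Cov(c, c') = Var(c)`. Opposite signs of `c`
#' and `c'` are flagged as inconsistent mediation.
#'
#' @param data Data frame with the response, mediators and `zone`, `site`,
#'   `catchment` columns.
#' @param response Response column name (e.g. `"k_green"`).
#' @param mediators Character vector of mediator columns.
#' @param alpha Significance level for gating and classification
#'   (default 0.05).
#' @param select Run [select_model()] before step 3 (default TRUE).
#' @param interactions Consider zone-by-mediator interactions during
#'   selection (default TRUE).
#' @param random Random-effects term; `NULL` fits ordinary least squares
#'   (useful for designs without repeated measures).
#' @param standardize Standardize mediators first (default TRUE).
#' @return An object of class `litter_mediation`; see [tidy()] and
#'   [glance()] methods.
#' @export
mediate_three_step <- function(data, response, mediators, alpha = 0.05,
                               select = TRUE, interactions = TRUE,
                               random = "(1 | catchment / site)",
                               standardize = TRUE) {
  assert_cols(data, c(response, mediators, "zone"))
  keep <- complete.cases(data[, c(response, mediators, "zone")])
  if (!all(keep)) {
    warn(sprintf("dropping %d row(s) with missing values", sum(!keep)))
    data <- data[keep, ]
  }
  data$zone_bz <- zone_indicator(data$zone)
  if (standardize) {
    data <- standardize_mediators(data, mediators)
    mediators <- intersect(mediators, names(data))
  }

  re <- if (is.null(random)) "" else paste(" +", random)

  # Step 1: total effect of compartment.
  m1 <- fit_lmm(data, paste0(response, " ~ zone_bz", re))
  c1 <- lmm_coefs(m1) %>% filter(.data$term == "zone_bz")

  # Step 2: compartment effect on each mediator.
  a_paths <- map_dfr(mediators, function(m) {
    fit <- fit_lmm(data, paste0(m, " ~ zone_bz", re))
    lmm_coefs(fit) %>% filter(.data$term == "zone_bz") %>%
      mutate(mediator = m)
  })

  # Step 3: direct effect with mediators, optionally after selection.
  if (select) {
    sel <- select_model(data, response, mediators,
                        interactions = interactions, random = random)
    form3 <- sel$formula
  } else {
    rhs <- paste(c("zone_bz", mediators), collapse = " + ")
    sel <- list(retained = mediators, retained_interactions = character(0),
                log = tibble())
    form3 <- paste0(response, " ~ ", rhs, re)
  }
  m3 <- fit_lmm(data, form3)
  cs3 <- lmm_coefs(m3)
  c3 <- cs3 %>% filter(.data$term == "zone_bz")
  b_paths <- cs3 %>%
    filter(.data$term %in% mediators) %>%
    rename(mediator = "term")

  c_hat <- c1$estimate; c_se <- c1$se; c_p <- c1$p_value
  cp_hat <- c3$estimate; cp_se <- c3$se; cp_p <- c3$p_value
  c_sig <- is.finite(c_p) && c_p < alpha

  prop <- prop_se <- NA_real_
  flags <- character(0)
  if (c_sig) {
    prop <- (c_hat - cp_hat) / c_hat
    # Delta method on (c - c')/c. For nested linear models
    # Cov(c, c') = sigma2_full / (z'z) = Var(c) * sigma2_full / sigma2_reduced,
    # estimated through the total error variances of the two fits.
    cov_ccp <- c_se^2 *
      min(1, total_error_variance(m3) / total_error_variance(m1))
    v <- (cp_hat / c_hat^2)^2 * c_se^2 + cp_se^2 / c_hat^2 -
      2 * cp_hat / c_hat^3 * cov_ccp
    if (!is.finite(v) || v <= 0) {
      v <- (cp_hat / c_hat^2)^2 * c_se^2 + cp_se^2 / c_hat^2
    }
    prop_se <- sqrt(v)
    if (sign(c_hat) != sign(cp_hat) && cp_p < alpha) {
      flags <- c(flags, "inconsistent_mediation")
    }
  } else {
    flags <- c(flags, "total_effect_not_significant")
  }

  sig_path <- any(vapply(sel$retained, function(m) {
    pa <- a_paths$p_value[a_paths$mediator == m]
    pb <- b_paths$p_value[b_paths$mediator == m]
    length(pa) && length(pb) && pa < alpha && pb < alpha
  }, logical(1)))
  classification <- if (!c_sig || !sig_path) {
    "none"
  } else if (cp_p >= alpha) "full" else "partial"

  structure(list(
    response = response, mediators = mediators, alpha = alpha,
    c = c_hat, c_se = c_se, c_p = c_p,
    c_prime = cp_hat, c_prime_se = cp_se, c_prime_p = cp_p,
    a_paths = a_paths, b_paths = b_paths,
    proportion_mediated = prop, proportion_se = prop_se,
    proportion_ci = if (is.na(prop)) c(NA_real_, NA_real_) else
      prop + c(-1, 1) * qnorm(0.975) * prop_se,
    classification = classification, flags = flags,
    selection = sel, n_obs = nrow(data),
    singular = c(step1 = isTRUE(attr(m1, "singular")),
                 step3 = isTRUE(attr(m3, "singular"))),
    models = list(step1 = m1, step3 = m3)
  ), class = "litter_mediation")
}

#' @export
print.litter_mediation <- function(x, ...) {
  cat(sprintf("Three-step mediation for %s (n = %d)\n", x$response, x$n_obs))
  cat(sprintf("  total effect c      = % .4g (p = %.3g)\n", x$c, x$c_p))
  cat(sprintf("  direct effect c'    = % .4g (p = %.3g)\n",
              x$c_prime, x$c_prime_p))
  if (!is.na(x$proportion_mediated)) {
    cat(sprintf("  proportion mediated = %.3f [%.3f, %.3f]\n",
                x$proportion_mediated, x$proportion_ci[1],
                x$proportion_ci[2]))
  }
  cat(sprintf("  classification: %s mediation\n", x$classification))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
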