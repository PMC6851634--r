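# Independent oracles and small fixture builders used across the tests.

# All integer vectors 0 <= k_i <= caps_i with sum m (multivariate
# hypergeometric support).
enum_compositions <- function(m, caps) {
  if (length(caps) == 1L) {
    if (m <= caps[1]) return(matrix(m, 1, 1)) else
      return(matrix(numeric(0), 0, 1))
  }
  out <- list()
  for (k in 0:min(m, caps[1])) {
    rest <- enum_compositions(m - k, caps[-1])
    if (nrow(rest)) out[[length(out) + 1L]] <- cbind(k, rest)
  }
  if (!length(out)) matrix(numeric(0), 0, length(caps)) else
    do.call(rbind, out)
}

# Exact expected Shannon entropy of a without-replacement subsample of size
# m, by enumerating every joint outcome (independent of the species-wise
# hypergeometric route used by the implementation).
enum_expected_entropy <- function(x, m) {
  x <- x[x > 0]
  n <- sum(x)
  stopifnot(m <= n)
  kk <- enum_compositions(m, x)
  xmat <- matrix(x, nrow(kk), length(x), byrow = TRUE)
  probs <- exp(rowSums(lchoose(xmat, kk)) - lchoose(n, m))
  ent <- apply(kk, 1, function(k) {
    p <- k[k > 0] / m
    -sum(p * log(p))
  })
  sum(probs * ent)
}

# Monte-Carlo resampling estimate of the same expectation, with its SE.
mc_expected_entropy <- function(x, m, n_rep = 2000) {
  pool <- rep(seq_along(x), x)
  h <- replicate(n_rep, {
    tab <- tabulate(sample(pool, m), nbins = length(x))
    p <- tab[tab > 0] / m
    -sum(p * log(p))
  })
  list(mean = mean(h), se = sd(h) / sqrt(n_rep))
}

# All unordered positive count vectors with at most `max_taxa` entries
# summing to n (permutation invariance makes ordered duplicates redundant).
partitions_up_to <- function(n, max_taxa) {
  rec <- function(n, max_part, parts_left) {
    if (n == 0) return(list(integer(0)))
    if (parts_left == 0) return(list())
    out <- list()
    for (p in seq_len(min(n, max_part))) {
      for (tail in rec(n - p, p, parts_left - 1)) {
        out[[length(out) + 1L]] <- c(p, tail)
      }
    }
    out
  }
  rec(n, n, max_taxa)
}

# Hand-rolled Bray-Curtis for cross-checking.
bray_by_hand <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / sum(x + y)
}

# A regular 10-minute temperature series.
make_series <- function(days, celsius, start = as.POSIXct("2016-10-25",
                                                          tz = "UTC")) {
  n <- days * 144L + 1L
  ts <- start + 600 * (seq_len(n) - 1L)
  if (is.function(celsius)) {
    hours <- as.numeric(ts - start, units = "hours")
    celsius <- celsius(hours)
  }
  data.frame(timestamp = ts, celsius = celsius)
}

# A balanced nested frame (catchment / site) with optional random
# intercepts, for mixed-model tests.
make_nested_frame <- function(n_catchment = 10, n_site = 3, n_rep = 6,
                              site_sd = 0, catchment_sd = 0,
                              resid_sd = 1, beta = c(1, 0.5)) {
  d <- expand.grid(catchment = sprintf("C%02d", seq_len(n_catchment)),
                   s = seq_len(n_site), rep = seq_len(n_rep),
                   stringsAsFactors = FALSE)
  d$site <- paste0(d$catchment, "-S", d$s)
  d$x <- rnorm(nrow(d))
  u_s <- rnorm(length(unique(d$site)), 0, site_sd)
  u_c <- rnorm(n_catchment, 0, catchment_sd)
  d$y <- beta[1] + beta[2] * d$x +
    u_s[as.integer(factor(d$site))] +
    u_c[as.integer(factor(d$catchment))] +
    rnorm(nrow(d), 0, resid_sd)
  d
}

# Config with a single mediator used by the mediation-recovery tests:
# direct effect 0.5, one path a = 1, b = 0.5, so the generating proportion
# mediated is 0.5.
single_mediator_config <- function(b = 0.5, direct = 0.5) {
  effect_config(
    zone_effect_on_mediators = c(biofilm = 1.0),
    mediator_effects_on_k = c(biofilm = b),
    direct_zone_effect_on_k = direct,
    k_intercept = 5, noise_sd_k = 0.5,
    site_intercept_sd = 0.2, catchment_intercept_sd = 0.1)
}
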