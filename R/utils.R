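# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

assert_number <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  what, format(lower), format(upper)))
  }
  invisible(x)
}

assert_count <- function(x, what, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x != round(x)) {
    abort(sprintf("`%s` must be a whole number >= %d", what, lower))
  }
  invisible(as.integer(x))
}

# Significance stars at the conventional reporting thresholds.
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p)    ~ "",
    p < 1e-4    ~ "***",
    p < 1e-3    ~ "**",
    p < 0.05    ~ "*",
    TRUE        ~ ""
  )
}
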