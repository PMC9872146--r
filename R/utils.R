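# shared internal helpers

# round half away from zero (base round() is round-half-even); report
# tables print allele-frequency statistics at fixed decimals like
# published SSR panel tables do
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# alphabetic cluster labels: A..Z, then AA, AB, ...
alpha_labels <- function(n) {
  stopifnot(n >= 1)
  labs <- LETTERS
  while (length(labs) < n) {
    labs <- c(labs, as.vector(t(outer(LETTERS, LETTERS, paste0))))
  }
  labs[seq_len(n)]
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s must have column(s): %s", what, paste(missing, collapse = ", ")
    ))
  }
}

`%||%` <- rlang::`%||%`
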