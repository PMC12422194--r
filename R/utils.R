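# internal helpers shared across modules

# Deterministic child seed for a named random stream. Keeps all derived
# seeds positive and below 2^31 so they are valid R integer seeds.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(seed) %% 65011) * 33029 + h * 7919) %% 2147483647L
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

assert_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", name,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# quadrature sum of independent 1-sigma uncertainties
quadrature <- function(...) sqrt(sum(c(...)^2))
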