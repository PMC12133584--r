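`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic seed derivation: one master seed, independent "streams" per
# stage (splits, permutations, sign-flips, MI iterations, generator), indexed
# within each stream. Kept inside 32-bit integer range.
.derive_seed <- function(seed, stream, index = 0L) {
  s <- (abs(as.double(seed)) + 97561 * as.double(stream) + as.double(index)) %% 2147483629
  as.integer(s) + 1L
}

# Two-sided p-value for a Pearson correlation via the t transform with n-2 df.
.r_to_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}

.assert_numeric_matrix <- function(x, what = "edges") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}

# %.17g formatting: delimited-text round trips reproduce doubles exactly.
.fmt_num <- function(x) sprintf("%.17g", x)
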