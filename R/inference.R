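#' Permutation test of cross-validated prediction accuracy
#'
#' Significance of the mean prediction accuracy is assessed by randomly
#' reassigning the outcome over subjects and rerunning the full
#' cross-validated pipeline — feature selection, fitting, and testing over
#' the splits — for each permutation. The p-value is the proportion of
#' permuted mean accuracies numerically greater (strictly) than the
#' observed mean accuracy; a zero count is reported as a bound below
#' `1/n_permutations`. The conventional (k+1)/(n+1) estimator is available
#' via `estimator = "plus_one"`.
#'
#' Permutations reuse the split definitions of the observed run, so the
#' permutation of the outcome is the only varying factor. For desk-scale
#' runs, `perm_splits` restricts each permutation to the first few splits;
#' this is logged prominently.
#'
#' @inheritParams run_cpm
#' @param n_permutations Number of permutations (default 1000; below 100 a
#'   warning, below 20 an error).
#' @param perm_splits Splits evaluated per permutation (default: all splits
#'   in `scheme`).
#' @param estimator `"proportion"` (strict exceedance proportion) or
#'   `"plus_one"`.
#' @return A `permutation_null`: `observed_mean_r`, `null_mean_r`,
#'   `p_value`, `p_display`, settings.
#' @export
permutation_test <- function(edges, y, scheme, p_threshold = 0.01,
                             score_mode = c("combined", "positive_only", "negative_only"),
                             n_permutations = 1000L, perm_splits = NULL,
                             estimator = c("proportion", "plus_one"),
                             covariate = NULL) {
  score_mode <- match.arg(score_mode)
  estimator <- match.arg(estimator)
  if (inherits(edges, "connectome_set")) edges <- edges$edges
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 20L) stop("fewer than 20 permutations is uninterpretable")
  if (n_permutations < 100L) warning("fewer than 100 permutations: p resolution is coarse")
  n <- nrow(edges)
  prep <- .prepare_splits(edges, scheme)
  obs <- .cv_engine(prep, edges, y, p_threshold, score_mode, covariate = covariate)
  if (all(is.na(obs$r))) stop("observed run failed on every split")
  observed <- mean(obs$r, na.rm = TRUE)
  subset <- NULL
  if (!is.null(perm_splits) && perm_splits < scheme$n_splits) {
    subset <- seq_len(perm_splits)
    message(sprintf("permutation_test: fast mode, %d of %d splits per permutation",
                    perm_splits, scheme$n_splits))
  }
  null_mean_r <- rep(NA_real_, n_permutations)
  for (b in seq_len(n_permutations)) {
    set.seed(.derive_seed(scheme$seed, 2L, b))
    yp <- y[sample.int(n)]
    eng <- .cv_engine(prep, edges, yp, p_threshold, score_mode,
                      covariate = covariate, split_subset = subset)
    null_mean_r[b] <- mean(eng$r, na.rm = TRUE)
  }
  valid <- !is.na(null_mean_r)
  exceed <- sum(null_mean_r[valid] > observed)
  p <- switch(estimator,
              proportion = exceed / sum(valid),
              plus_one = (exceed + 1) / (sum(valid) + 1))
  structure(list(observed_mean_r = observed, null_mean_r = null_mean_r,
                 n_permutations = n_permutations, p_value = p,
                 p_display = if (exceed == 0L && estimator == "proportion")
                   sprintf("< %g", 1 / sum(valid)) else sprintf("%g", p),
                 estimator = estimator, per_split_r = obs$r,
                 score_mode = score_mode, p_threshold = p_threshold),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> observed mean r = %.3f, p %s (%d permutations, %s)\n",
              x$observed_mean_r, x$p_display, x$n_permutations, x$estimator))
  invisible(x)
}

#' Bonferroni correction
#'
#' `p_corrected = min(1, m * p)` with an explicit comparison count `m`
#' (at least as large as the number of p-values supplied), e.g. m = 3 for
#' the three cognitive outcomes, m = 12 for the lesioned networks.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @param m Number of comparisons.
#' @return Corrected p-values, capped at 1.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (m < length(p_values)) stop("m must be at least the number of p-values")
  pmin(1, m * p_values)
}
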