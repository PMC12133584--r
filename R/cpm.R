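#' Edge-wise correlation with an outcome
#'
#' Pearson correlation of every edge (column) with the outcome across
#' subjects (rows), with a two-sided p-value from the t transform on
#' n - 2 degrees of freedom. Constant edges get r = 0, p = 1 with a
#' warning; a constant outcome is an error because no feature can be
#' selected against it.
#'
#' @param edges n x E numeric matrix (subjects x edges).
#' @param y Outcome vector, length n, n >= 4.
#' @return `list(r, p)`, each of length E.
#' @export
correlate_edges <- function(edges, y) {
  .assert_numeric_matrix(edges)
  n <- nrow(edges)
  if (n < 4L) stop("need at least 4 subjects to correlate edges")
  if (length(y) != n) stop("y length must equal the number of subjects")
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  if (ssy == 0) stop("outcome is constant; cannot select features")
  xc <- edges - rep(colMeans(edges), each = n)
  css <- colSums(xc^2)
  const <- css <= 0
  r <- as.vector(crossprod(xc, yc)) / sqrt(pmax(css, .Machine$double.xmin) * ssy)
  r <- pmin(pmax(r, -1), 1)
  p <- .r_to_p(r, n)
  if (any(const)) {
    warning(sprintf("%d constant edge(s): r set to 0, p to 1", sum(const)))
    r[const] <- 0
    p[const] <- 1
  }
  list(r = r, p = p)
}

#' Select positive and negative feature sets
#'
#' Edges with selection p below the threshold are split by the sign of
#' their correlation with the outcome: the positive set correlates
#' positively, the negative set negatively. Empty sets are permitted here;
#' downstream scoring enforces non-emptiness where required.
#'
#' @param r,p Vectors from [correlate_edges()].
#' @param p_threshold Feature-defining threshold (default 0.01; 0.05 is the
#'   common lenient alternative).
#' @return A `feature_mask`: `list(positive, negative, p_threshold)` with
#'   sorted 1-based edge positions.
#' @export
select_features <- function(r, p, p_threshold = 0.01) {
  if (length(r) != length(p)) stop("r and p must have the same length")
  sel <- p < p_threshold
  out <- list(positive = which(sel & r > 0),
              negative = which(sel & r < 0),
              p_threshold = p_threshold)
  class(out) <- "feature_mask"
  out
}

#' Network-strength summary score
#'
#' The combined score of a subject is the sum of connectivity over the
#' positive feature set minus the sum over the negative set;
#' `positive_only` and `negative_only` use one set alone. A score mode
#' whose required set(s) are empty is an error.
#'
#' @param edges Edge vector (one subject) or n x E matrix.
#' @param mask A `feature_mask` from [select_features()].
#' @param score_mode `"combined"`, `"positive_only"` or `"negative_only"`.
#' @return Numeric score(s), one per subject.
#' @export
summary_score <- function(edges, mask,
                          score_mode = c("combined", "positive_only", "negative_only")) {
  score_mode <- match.arg(score_mode)
  if (is.null(dim(edges))) edges <- matrix(edges, nrow = 1L)
  need_pos <- score_mode %in% c("combined", "positive_only")
  need_neg <- score_mode %in% c("combined", "negative_only")
  if (need_pos && !length(mask$positive))
    stop("positive feature set is empty; cannot compute ", score_mode, " score")
  if (need_neg && !length(mask$negative))
    stop("negative feature set is empty; cannot compute ", score_mode, " score")
  spos <- if (need_pos) rowSums(edges[, mask$positive, drop = FALSE]) else 0
  sneg <- if (need_neg) rowSums(edges[, mask$negative, drop = FALSE]) else 0
  switch(score_mode,
         combined = spos - sneg,
         positive_only = spos,
         negative_only = sneg)
}

#' Fit a CPM on a training sample
#'
#' Selects features at `p_threshold`, computes the summary score of each
#' training subject, and fits ordinary least squares of the outcome on the
#' scalar score. The returned model carries the feature mask and the
#' linear coefficients, so it can be applied unchanged to new subjects
#' (including a different cohort sharing the same parcellation).
#'
#' @inheritParams correlate_edges
#' @inheritParams summary_score
#' @param p_threshold Selection threshold.
#' @return A `cpm_model`: mask, `slope`, `intercept`, `score_mode`,
#'   `train_n`, `n_edges`.
#' @export
fit_cpm <- function(edges, y, p_threshold = 0.01,
                    score_mode = c("combined", "positive_only", "negative_only")) {
  score_mode <- match.arg(score_mode)
  ce <- correlate_edges(edges, y)
  mask <- select_features(ce$r, ce$p, p_threshold)
  s <- summary_score(edges, mask, score_mode)
  if (length(unique(s)) < 3L)
    stop("fewer than 3 distinct training summary scores; cannot fit")
  v <- stats::var(s)
  if (v == 0) stop("zero-variance summary scores; cannot fit")
  slope <- stats::cov(s, y) / v
  intercept <- mean(y) - slope * mean(s)
  structure(list(mask = mask, score_mode = score_mode, slope = slope,
                 intercept = intercept, train_n = nrow(edges),
                 n_edges = ncol(edges)),
            class = "cpm_model")
}

#' @export
print.cpm_model <- function(x, ...) {
  cat(sprintf(paste0("<cpm_model> %s score, p<%g selection: %d positive / %d ",
                     "negative edges\n  y = %.4g + %.4g * score  (train n=%d, E=%d)\n"),
              x$score_mode, x$mask$p_threshold, length(x$mask$positive),
              length(x$mask$negative), x$intercept, x$slope, x$train_n, x$n_edges))
  invisible(x)
}

#' Predict outcomes from a fitted CPM
#'
#' @param object A `cpm_model`.
#' @param edges m x E edge matrix (E must match the training edge count) or
#'   a single edge vector.
#' @param invert_scores Negate every summary score before applying the
#'   fixed fitted coefficients (the inverted-model transform; coefficients
#'   untouched).
#' @param ... Unused.
#' @return Numeric predictions, one per subject.
#' @export
predict.cpm_model <- function(object, edges, invert_scores = FALSE, ...) {
  if (is.null(dim(edges))) edges <- matrix(edges, nrow = 1L)
  if (ncol(edges) != object$n_edges)
    stop(sprintf("edge count mismatch: model trained on E=%d, got E=%d",
                 object$n_edges, ncol(edges)))
  s <- summary_score(edges, object$mask, object$score_mode)
  if (invert_scores) s <- -s
  object$intercept + object$slope * s
}

#' Train/test split scheme
#'
#' Subject-level simple random splits, reproducible from the seed; split k
#' is drawn under a seed derived from (seed, k), so any single split can be
#' regenerated in isolation. Duplicate splits are rejected and redrawn, so
#' all `n_splits` index sets are unique.
#'
#' @param n_splits Number of splits (default 100).
#' @param train_fraction Fraction of subjects trained on (default 0.70).
#' @param seed Master seed for the scheme.
#' @return A `split_scheme`.
#' @export
split_scheme <- function(n_splits = 100L, train_fraction = 0.70, seed = 1L) {
  n_splits <- as.integer(n_splits)
  if (n_splits < 1L) stop("n_splits must be positive")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)")
  structure(list(n_splits = n_splits, train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "split_scheme")
}

.split_indices <- function(n, scheme) {
  n_train <- floor(scheme$train_fraction * n)
  if (n_train < 3L) stop("training sets would have fewer than 3 subjects")
  if (n - n_train < 3L) stop("test sets would have fewer than 3 subjects")
  out <- vector("list", scheme$n_splits)
  seen <- character(scheme$n_splits)
  k <- 1L; bump <- 0L
  while (k <= scheme$n_splits) {
    set.seed(.derive_seed(scheme$seed, 1L, k + bump * 100003L))
    tr <- sort(sample.int(n, n_train))
    key <- paste(tr, collapse = ",")
    if (key %in% seen[seq_len(k - 1L)]) {
      bump <- bump + 1L
      if (bump > 1000L) stop("could not draw ", scheme$n_splits, " unique splits")
    } else {
      out[[k]] <- tr
      seen[k] <- key
      k <- k + 1L
      bump <- 0L
    }
  }
  out
}

# Per-split precomputation. When memory permits, the centered training
# matrix and its column sums of squares are cached so repeated runs over
# the same splits (notably the permutation null, where only y changes)
# reduce to one BLAS crossprod per split.
.prepare_splits <- function(edges, scheme, precompute = NULL) {
  n <- nrow(edges)
  idx <- .split_indices(n, scheme)
  n_train <- length(idx[[1L]])
  pre <- precompute %||%
    (as.double(scheme$n_splits) * n_train * ncol(edges) <= 2e8)
  sp <- lapply(idx, function(tr) {
    te <- setdiff(seq_len(n), tr)
    s <- list(train = tr, test = te)
    if (pre) {
      xt <- edges[tr, , drop = FALSE]
      s$mx <- colMeans(xt)
      s$xtc <- xt - rep(s$mx, each = n_train)
      s$css <- colSums(s$xtc^2)
      s$xte <- edges[te, , drop = FALSE]
    }
    s
  })
  structure(list(splits = sp, pre = pre, n = n), class = "cpm_prep")
}

# Critical |r| equivalent to a two-sided selection threshold p < thr at
# sample size n: selection compares |r| once instead of transforming every
# edge's r to a p-value.
.r_crit <- function(p_threshold, n) {
  tc <- stats::qt(1 - p_threshold / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

# One split of the CPM pipeline: edge-wise selection on the training half,
# summary scores, scalar OLS, prediction on the test half, Pearson accuracy
# (partial given a covariate). Returns ok=FALSE with a reason for the
# degenerate cases run_cpm records as missing.
.run_split <- function(sp, edges, y, p_threshold, score_mode,
                       covariate = NULL, mask_exclude = NULL,
                       collect_mask = FALSE, prep_pre = TRUE) {
  tr <- sp$train; te <- sp$test
  ytr <- y[tr]
  yc <- ytr - mean(ytr)
  ssy <- sum(yc^2)
  if (ssy == 0) return(list(ok = FALSE, why = "constant training outcome"))
  if (prep_pre) {
    xtc <- sp$xtc; css <- sp$css; mx <- sp$mx; xte <- sp$xte
  } else {
    xt <- edges[tr, , drop = FALSE]
    mx <- colMeans(xt)
    xtc <- xt - rep(mx, each = length(tr))
    css <- colSums(xtc^2)
    xte <- edges[te, , drop = FALSE]
  }
  r <- as.vector(crossprod(xtc, yc)) / sqrt(css * ssy)
  r[css <= 0] <- 0                        # constant edges are never selected
  rc <- .r_crit(p_threshold, length(tr))  # p < thr  <=>  |r| > r_crit
  pos <- which(r > rc)
  neg <- which(r < -rc)
  if (length(mask_exclude)) {
    pos <- setdiff(pos, mask_exclude)
    neg <- setdiff(neg, mask_exclude)
  }
  need_pos <- score_mode %in% c("combined", "positive_only")
  need_neg <- score_mode %in% c("combined", "negative_only")
  if ((need_pos && !length(pos)) || (need_neg && !length(neg)))
    return(list(ok = FALSE, why = "empty feature set",
                mask = if (collect_mask) list(positive = pos, negative = neg)))
  sc <- function(xm, cols, centered_offset = 0)
    rowSums(xm[, cols, drop = FALSE]) + centered_offset
  str_pos <- if (need_pos) sc(xtc, pos, sum(mx[pos])) else 0
  str_neg <- if (need_neg) sc(xtc, neg, sum(mx[neg])) else 0
  s_tr <- switch(score_mode, combined = str_pos - str_neg,
                 positive_only = str_pos, negative_only = str_neg)
  v <- stats::var(s_tr)
  if (v == 0) return(list(ok = FALSE, why = "zero-variance summary scores"))
  slope <- stats::cov(s_tr, ytr) / v
  intercept <- mean(ytr) - slope * mean(s_tr)
  ste_pos <- if (need_pos) sc(xte, pos) else 0
  ste_neg <- if (need_neg) sc(xte, neg) else 0
  s_te <- switch(score_mode, combined = ste_pos - ste_neg,
                 positive_only = ste_pos, negative_only = ste_neg)
  pred <- intercept + slope * s_te
  yte <- y[te]
  if (stats::sd(pred) == 0 || stats::sd(yte) == 0)
    return(list(ok = FALSE, why = "degenerate test-set variance",
                mask = if (collect_mask) list(positive = pos, negative = neg)))
  if (is.null(covariate)) {
    acc <- stats::cor(pred, yte)
  } else {
    acc <- .partial_cor(pred, yte, covariate[te])
    if (is.na(acc))
      return(list(ok = FALSE, why = "partial correlation undefined in test set",
                  mask = if (collect_mask) list(positive = pos, negative = neg)))
  }
  list(ok = TRUE, r = acc,
       mask = if (collect_mask) list(positive = pos, negative = neg))
}

# First-order partial Pearson correlation of x and y given z; NA when any
# marginal is degenerate or |r_xz| or |r_yz| is 1.
.partial_cor <- function(x, y, z) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  if (stats::sd(z) == 0) return(stats::cor(x, y))
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den <= .Machine$double.eps) return(NA_real_)
  (rxy - rxz * ryz) / sqrt(den)
}

# Shared engine over prepared splits; returns per-split accuracies (NA for
# recorded-missing splits), failure reasons, and optional per-split masks.
.cv_engine <- function(prep, edges, y, p_threshold, score_mode,
                       covariate = NULL, mask_exclude = NULL,
                       collect_masks = FALSE, split_subset = NULL) {
  ks <- split_subset %||% seq_along(prep$splits)
  rs <- rep(NA_real_, length(ks))
  whys <- character(0)
  masks <- if (collect_masks) vector("list", length(ks))
  for (a in seq_along(ks)) {
    res <- .run_split(prep$splits[[ks[a]]], edges, y, p_threshold, score_mode,
                      covariate = covariate, mask_exclude = mask_exclude,
                      collect_mask = collect_masks, prep_pre = prep$pre)
    if (res$ok) rs[a] <- res$r else whys <- c(whys, res$why)
    if (collect_masks) masks[[a]] <- res$mask
  }
  list(r = rs, whys = whys, masks = masks)
}

#' Cross-validated CPM prediction accuracy
#'
#' Runs the full CPM pipeline over repeated train/test splits: edge-wise
#' feature selection on each training set, summary-score OLS fit,
#' prediction of the held-out subjects, and Pearson correlation between
#' predicted and observed outcomes as the per-split accuracy. Splits where
#' a required feature set is empty (or accuracy is undefined) are recorded
#' as missing with a warning and excluded from the mean; if more than half
#' of the splits fail, the run aborts with guidance to relax the threshold.
#'
#' @inheritParams fit_cpm
#' @param scheme A [split_scheme()].
#' @param outcome_name Optional label carried into the result.
#' @param return_masks Keep the per-split selected feature sets (needed by
#'   [selection_fraction_matrix()]).
#' @param mask_exclude Optional edge positions barred from selection (the
#'   mask-pruning lesion variant). With edge-wise selection this is
#'   equivalent to removing the columns before selection.
#' @param covariate Optional covariate: per-split accuracy becomes the
#'   partial correlation between predicted and observed outcomes
#'   controlling for the covariate in the test set (see
#'   [covaried_prediction()]).
#' @return A `prediction_result`: `per_split_r`, `mean_r`, failure count,
#'   scheme and settings, optional masks.
#' @export
run_cpm <- function(edges, y, scheme, p_threshold = 0.01,
                    score_mode = c("combined", "positive_only", "negative_only"),
                    outcome_name = NULL, return_masks = FALSE,
                    mask_exclude = NULL, covariate = NULL) {
  score_mode <- match.arg(score_mode)
  if (inherits(edges, "connectome_set")) edges <- edges$edges
  .assert_numeric_matrix(edges)
  if (length(y) != nrow(edges)) stop("y length must equal the number of subjects")
  prep <- .prepare_splits(edges, scheme)
  eng <- .cv_engine(prep, edges, y, p_threshold, score_mode,
                    covariate = covariate, mask_exclude = mask_exclude,
                    collect_masks = return_masks)
  n_fail <- sum(is.na(eng$r))
  if (n_fail > 0L)
    warning(sprintf("%d of %d splits recorded missing accuracy (%s)",
                    n_fail, scheme$n_splits,
                    paste(unique(eng$whys), collapse = "; ")))
  if (n_fail > scheme$n_splits / 2)
    stop("more than half of the splits failed feature selection; ",
         "relax p_threshold (e.g. 0.05) or use more subjects")
  structure(list(per_split_r = eng$r, mean_r = mean(eng$r, na.rm = TRUE),
                 n_failed = n_fail, outcome_name = outcome_name,
                 score_mode = score_mode, p_threshold = p_threshold,
                 scheme = scheme, masks = if (return_masks) eng$masks,
                 permutation_p = NULL, corrected_p = NULL),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result>%s %s score, p<%g: mean r = %.3f over %d splits (%d missing)\n",
              if (is.null(x$outcome_name)) "" else paste0(" ", x$outcome_name, ","),
              x$score_mode, x$p_threshold, x$mean_r,
              x$scheme$n_splits, x$n_failed))
  if (!is.null(x$permutation_p))
    cat(sprintf("  permutation p = %g (corrected %g)\n",
                x$permutation_p, x$corrected_p %||% NA_real_))
  invisible(x)
}

#' Apply a fitted model to an external cohort
#'
#' Applies a full-sample fitted `cpm_model` (coefficients and selected
#' features untouched) to an independent target sample sharing the same
#' parcellation, and reports the Pearson correlation between predicted and
#' observed outcomes with its two-sided parametric p-value.
#'
#' @param model A `cpm_model` fitted on the source cohort.
#' @param target_edges m x E edge matrix of the target cohort.
#' @param target_y Observed target outcomes (m >= 4).
#' @return `list(r, p, n, predicted)`.
#' @export
external_validate <- function(model, target_edges, target_y) {
  if (inherits(target_edges, "connectome_set")) target_edges <- target_edges$edges
  n <- nrow(target_edges)
  if (n < 4L) stop("external validation needs at least 4 target subjects")
  if (length(target_y) != n) stop("target_y length mismatch")
  pred <- predict(model, target_edges)
  r <- stats::cor(pred, target_y)
  list(r = r, p = .r_to_p(r, n), n = n, predicted = pred)
}

#' Serialize / deserialize a fitted CPM
#'
#' Writes a `cpm_model` as structured key-value text (coefficients at full
#' precision, explicit edge-index lists) so a model fitted on one cohort
#' can be shipped and applied to another.
#'
#' @param model A `cpm_model`.
#' @param path Output file.
#' @export
write_cpm_model <- function(model, path) {
  lines <- c(
    paste0("score_mode: ", model$score_mode),
    paste0("p_threshold: ", .fmt_num(model$mask$p_threshold)),
    paste0("slope: ", .fmt_num(model$slope)),
    paste0("intercept: ", .fmt_num(model$intercept)),
    paste0("train_n: ", model$train_n),
    paste0("n_edges: ", model$n_edges),
    paste0("positive_edges: ", paste(model$mask$positive, collapse = " ")),
    paste0("negative_edges: ", paste(model$mask$negative, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cpm_model
#' @return `read_cpm_model` returns the reconstructed `cpm_model`.
#' @export
read_cpm_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(x) if (length(x) > 1L) x[[2L]] else "", ""),
    vapply(kv, `[[`, "", 1L))
  ints <- function(s) if (nzchar(s)) as.integer(strsplit(s, " ")[[1L]]) else integer(0)
  mask <- structure(list(positive = ints(vals[["positive_edges"]]),
                         negative = ints(vals[["negative_edges"]]),
                         p_threshold = as.numeric(vals[["p_threshold"]])),
                    class = "feature_mask")
  structure(list(mask = mask, score_mode = vals[["score_mode"]],
                 slope = as.numeric(vals[["slope"]]),
                 intercept = as.numeric(vals[["intercept"]]),
                 train_n = as.integer(vals[["train_n"]]),
                 n_edges = as.integer(vals[["n_edges"]])),
            class = "cpm_model")
}
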