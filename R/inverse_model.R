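#' Inverted-model experiment on mispredicted subjects
#'
#' Fits a full-sample CPM on the correctly classified subjects
#' (MI < `train_cut`), applies it unchanged to the frequently misclassified
#' subjects (MI > `test_cut`), and reports the direct accuracy `r_direct`
#' alongside `r_inverted` — the accuracy of the same fixed model after
#' negating every summary score before the fitted coefficients are applied.
#' Negating the scalar input of a fixed linear map negates the Pearson
#' correlation between predictions and observations exactly, so
#' `r_inverted = -r_direct` to machine precision; both are computed
#' explicitly rather than by that identity. Refitting the model on the
#' negated scores instead (which breaks the exact antisymmetry) is
#' available with `refit_inverted = TRUE`.
#'
#' @inheritParams run_cpm
#' @param mi_profile An `mi_profile` from [run_misclassification()] aligned
#'   with the rows of `edges`.
#' @param train_cut Train on subjects with MI below this value (default 0.4).
#' @param test_cut Test on subjects with MI above this value (default 0.5).
#' @param refit_inverted Refit coefficients on the training set after
#'   negating scores instead of reusing the fixed map.
#' @return An `inverse_model_result`: `r_direct`, `r_inverted`, `n_train`,
#'   `n_test`, the fitted model, predictions.
#' @export
run_inverse_experiment <- function(edges, y, mi_profile, train_cut = 0.4,
                                   test_cut = 0.5, p_threshold = 0.01,
                                   score_mode = c("combined", "positive_only", "negative_only"),
                                   outcome_name = NULL, refit_inverted = FALSE) {
  score_mode <- match.arg(score_mode)
  if (inherits(edges, "connectome_set")) edges <- edges$edges
  if (nrow(mi_profile) != nrow(edges)) stop("MI profile / edge matrix size mismatch")
  tr <- which(mi_profile$mi < train_cut)
  te <- which(mi_profile$mi > test_cut)
  if (length(tr) < 4L || length(te) < 4L)
    stop(sprintf("insufficient subgroup sizes: %d train (MI < %g), %d test (MI > %g); need >= 4 each",
                 length(tr), train_cut, length(te), test_cut))
  model <- fit_cpm(edges[tr, , drop = FALSE], y[tr], p_threshold, score_mode)
  pred_direct <- predict(model, edges[te, , drop = FALSE])
  r_direct <- stats::cor(pred_direct, y[te])
  if (refit_inverted) {
    s_tr <- -summary_score(edges[tr, , drop = FALSE], model$mask, score_mode)
    v <- stats::var(s_tr)
    slope <- stats::cov(s_tr, y[tr]) / v
    intercept <- mean(y[tr]) - slope * mean(s_tr)
    s_te <- -summary_score(edges[te, , drop = FALSE], model$mask, score_mode)
    pred_inv <- intercept + slope * s_te
  } else {
    pred_inv <- predict(model, edges[te, , drop = FALSE], invert_scores = TRUE)
  }
  r_inverted <- stats::cor(pred_inv, y[te])
  structure(list(outcome_name = outcome_name, r_direct = r_direct,
                 r_inverted = r_inverted, n_train = length(tr),
                 n_test = length(te), model = model,
                 predicted_direct = pred_direct, predicted_inverted = pred_inv,
                 train_cut = train_cut, test_cut = test_cut,
                 refit_inverted = refit_inverted),
            class = "inverse_model_result")
}

#' @export
print.inverse_model_result <- function(x, ...) {
  cat(sprintf("<inverse_model_result>%s r_direct = %.3f, r_inverted = %.3f (train n=%d, test n=%d)\n",
              if (is.null(x$outcome_name)) "" else paste0(" ", x$outcome_name, ":"),
              x$r_direct, x$r_inverted, x$n_train, x$n_test))
  invisible(x)
}
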