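#' Median-split scorer classes
#'
#' Dichotomizes a continuous outcome into low vs high scorers at the
#' sample median. Subjects exactly at the median go to the low class
#' (deterministic tie rule), so with distinct values the class sizes
#' differ by at most one.
#'
#' @param y Real-valued outcome.
#' @return Factor with levels `low`, `high`.
#' @export
binarize_outcome <- function(y) {
  if (length(unique(y)) < 2L) stop("outcome is constant; cannot median-split")
  med <- stats::median(y)
  factor(ifelse(y <= med, "low", "high"), levels = c("low", "high"))
}

# Standardize classifier features with training statistics; constant
# columns are left centered only.
.std_train_apply <- function(xtr, xnew) {
  mu <- colMeans(xtr)
  sg <- apply(xtr, 2L, stats::sd)
  sg[sg == 0] <- 1
  list(tr = sweep(sweep(xtr, 2L, mu), 2L, sg, "/"),
       new = sweep(sweep(xnew, 2L, mu, check.margin = FALSE), 2L, sg, "/"))
}

#' Misclassification index via repeated subsampled classification
#'
#' For every subject in turn (leave-one-out), the remaining subjects are
#' randomly subsampled `n_iterations` times; within each subsample, edges
#' are selected against the binary scorer class (point-biserial correlation
#' at `p_threshold`), positive and negative network-strength summary
#' scores are computed, and a linear-kernel support-vector classifier is
#' trained on that two-dimensional score representation and applied to the
#' left-out subject. The misclassification index (MI) of a subject is the
#' fraction of iterations in which its class was predicted wrongly.
#'
#' An empty feature side contributes a zero score column; when no feature
#' separates the classes at all (both score columns constant) or the
#' subsample contains one class only, the iteration falls back to a
#' training-majority-class vote (ties go to `low`).
#'
#' @param edges N x E edge matrix or [connectome_set()].
#' @param classes Factor from [binarize_outcome()] (levels low/high), or a
#'   numeric outcome which is binarized first.
#' @param n_iterations Iterations per left-out subject (default 100).
#' @param subsample_fraction Fraction of the remaining N-1 subjects drawn
#'   per iteration (default 0.8).
#' @param p_threshold Feature-selection threshold for the binary stage
#'   (default 0.05, the lenient selection threshold: point-biserial
#'   correlations against a median-split class are attenuated relative to
#'   correlations with the continuous outcome, so the stricter continuous
#'   default would starve the classifier of features).
#' @param seed Master seed.
#' @param svm_cost Cost parameter of the linear SVM (default 1).
#' @param input `"scores"` (default: 2-D summary-score representation) or
#'   `"edges"` (raw selected edges as classifier features).
#' @param subject_ids Optional ids for the output (taken from a
#'   `connectome_set` automatically).
#' @return An `mi_profile` data.frame: `subject_id`, `scorer_class`, `mi`,
#'   with `n_iterations` as an attribute.
#' @export
run_misclassification <- function(edges, classes, n_iterations = 100L,
                                  subsample_fraction = 0.8, p_threshold = 0.05,
                                  seed = 1L, svm_cost = 1,
                                  input = c("scores", "edges"),
                                  subject_ids = NULL) {
  input <- match.arg(input)
  if (inherits(edges, "connectome_set")) {
    subject_ids <- subject_ids %||% edges$subject_ids
    edges <- edges$edges
  }
  .assert_numeric_matrix(edges)
  n <- nrow(edges)
  subject_ids <- subject_ids %||% as.character(seq_len(n))
  if (is.numeric(classes)) classes <- binarize_outcome(classes)
  classes <- factor(classes, levels = c("low", "high"))
  if (any(table(classes) == 0L)) stop("both scorer classes must be non-empty")
  ybin <- as.integer(classes == "high")
  n_sub <- floor(subsample_fraction * (n - 1L))
  if (n_sub < 10L) stop("subsample of ", n_sub, " subjects is too small for feature selection")
  sq <- edges^2                    # once: per-iteration column stats become crossprods
  rc <- .r_crit(p_threshold, n_sub)
  mis <- integer(n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    xi <- edges[i, , drop = FALSE]
    for (it in seq_len(n_iterations)) {
      set.seed(.derive_seed(seed, 4L, (i - 1L) * n_iterations + it))
      sub <- rest[sample.int(n - 1L, n_sub)]
      ys <- ybin[sub]
      if (length(unique(ys)) < 2L) {        # single-class subsample: majority vote
        pred_high <- mean(ys) > 0.5
      } else {
        ind <- numeric(n); ind[sub] <- 1
        csum <- as.vector(crossprod(ind, edges))
        css <- as.vector(crossprod(ind, sq)) - csum^2 / n_sub
        yfull <- numeric(n); yfull[sub] <- ys - mean(ys)
        r <- as.vector(crossprod(yfull, edges)) / sqrt(css * sum(yfull^2))
        r[css <= 0] <- 0
        pos <- which(r > rc)                 # p < thr  <=>  |r| > r_crit
        neg <- which(r < -rc)
        if (input == "scores") {
          xs <- edges[sub, c(pos, neg), drop = FALSE]
          np <- length(pos)
          ftr <- cbind(pos = if (np) rowSums(xs[, seq_len(np), drop = FALSE]) else rep(0, n_sub),
                       neg = if (length(neg)) rowSums(xs[, np + seq_along(neg), drop = FALSE]) else rep(0, n_sub))
          fte <- cbind(pos = if (np) sum(xi[, pos]) else 0,
                       neg = if (length(neg)) sum(xi[, neg]) else 0)
        } else {
          sel <- c(pos, neg)
          ftr <- if (length(sel)) edges[sub, sel, drop = FALSE] else matrix(0, n_sub, 1L)
          fte <- if (length(sel)) xi[, sel, drop = FALSE] else matrix(0, 1L, 1L)
        }
        keep <- colSums((ftr - rep(colMeans(ftr), each = n_sub))^2) > 0
        if (!any(keep)) {                   # nothing discriminative: majority vote
          pred_high <- mean(ys) > 0.5
        } else {
          z <- .std_train_apply(ftr[, keep, drop = FALSE], fte[, keep, drop = FALSE])
          fit <- e1071::svm(x = z$tr, y = factor(ys, levels = c(0L, 1L)),
                            kernel = "linear", cost = svm_cost, scale = FALSE)
          pred_high <- predict(fit, z$new) == "1"
        }
      }
      if (pred_high != (ybin[i] == 1L)) mis[i] <- mis[i] + 1L
    }
  }
  out <- data.frame(subject_id = subject_ids, scorer_class = classes,
                    mi = mis / n_iterations)
  attr(out, "n_iterations") <- as.integer(n_iterations)
  class(out) <- c("mi_profile", "data.frame")
  out
}

.encode_covariate <- function(x, name = "covariate") {
  if (is.numeric(x)) return(x)
  f <- factor(x)
  if (nlevels(f) < 2L) return(rep(0, length(x)))
  if (nlevels(f) == 2L) return(as.integer(f) - 1L)
  # >2 categories: indicator of the modal category
  modal <- names(which.max(table(f)))
  as.integer(f == modal)
}

#' Dissect misclassification by covariates
#'
#' Two complementary correlation analyses around the misclassification
#' index:
#' \describe{
#'   \item{MI ~ covariate}{Pearson r between MI and each covariate,
#'     separately within low and high scorers.}
#'   \item{covariate ~ outcome}{Pearson r between each covariate and the
#'     continuous outcome, separately within correctly classified
#'     (MI < `mi_cut`) and frequently misclassified (MI > `mi_cut`)
#'     subjects.}
#' }
#' Two-level categorical covariates are encoded 0/1; covariates with more
#' levels as an indicator of the modal category. Strata with fewer than 4
#' usable subjects are flagged not-computed (`computed = FALSE`). Subjects
#' with MI exactly at `mi_cut` belong to neither classification stratum.
#'
#' @param mi_profile An `mi_profile` from [run_misclassification()].
#' @param behavior Behavior data.frame aligned to the same subjects
#'   (matched on `subject_id`).
#' @param outcome Name of the continuous outcome column.
#' @param covariates Character vector of covariate column names.
#' @param mi_cut MI threshold separating correct from misclassified
#'   subjects (default 0.5).
#' @return Data.frame with columns `covariate`, `analysis`, `stratum`,
#'   `r`, `p`, `n`, `computed`.
#' @export
mi_covariate_dissection <- function(mi_profile, behavior, outcome, covariates,
                                    mi_cut = 0.5) {
  beh <- behavior[match(mi_profile$subject_id, behavior$subject_id), , drop = FALSE]
  if (anyNA(beh$subject_id)) stop("behavior table is missing subjects in the MI profile")
  miss <- setdiff(c(outcome, covariates), names(beh))
  if (length(miss)) stop("column(s) missing from behavior: ", paste(miss, collapse = ", "))
  rows <- list()
  strata <- list(
    list(analysis = "mi_vs_covariate", stratum = "low_scorers",
         idx = which(mi_profile$scorer_class == "low"), xvar = "mi"),
    list(analysis = "mi_vs_covariate", stratum = "high_scorers",
         idx = which(mi_profile$scorer_class == "high"), xvar = "mi"),
    list(analysis = "covariate_vs_outcome", stratum = "correct",
         idx = which(mi_profile$mi < mi_cut), xvar = "outcome"),
    list(analysis = "covariate_vs_outcome", stratum = "misclassified",
         idx = which(mi_profile$mi > mi_cut), xvar = "outcome"))
  for (cv in covariates) {
    enc <- .encode_covariate(beh[[cv]], cv)
    for (st in strata) {
      xv <- if (st$xvar == "mi") mi_profile$mi[st$idx] else beh[[outcome]][st$idx]
      yv <- enc[st$idx]
      ok <- stats::complete.cases(xv, yv)
      xv <- xv[ok]; yv <- yv[ok]
      usable <- length(xv) >= 4L && stats::sd(xv) > 0 && stats::sd(yv) > 0
      if (usable) {
        ct <- stats::cor.test(xv, yv)
        rows[[length(rows) + 1L]] <-
          data.frame(covariate = cv, analysis = st$analysis, stratum = st$stratum,
                     r = unname(ct$estimate), p = ct$p.value, n = length(xv),
                     computed = TRUE)
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(covariate = cv, analysis = st$analysis, stratum = st$stratum,
                     r = NA_real_, p = NA_real_, n = length(xv), computed = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate-controlled prediction accuracy
#'
#' Identical to [run_cpm()] except that the per-split accuracy is the
#' partial Pearson correlation between predicted and observed outcomes
#' controlling for the covariate within the test set. Splits where the
#' test-set covariate is constant use the raw correlation; splits where
#' the partial correlation is undefined (covariate collinear with
#' predictions or outcomes) are recorded missing with a warning.
#' Significance can be assessed with [permutation_test()] passing the same
#' `covariate`.
#'
#' @inheritParams run_cpm
#' @param covariate Covariate vector, one value per subject, no missing
#'   values among modeled subjects.
#' @return A `prediction_result` of partial accuracies.
#' @export
covaried_prediction <- function(edges, y, covariate, scheme, p_threshold = 0.01,
                                score_mode = c("combined", "positive_only", "negative_only"),
                                outcome_name = NULL) {
  score_mode <- match.arg(score_mode)
  if (inherits(edges, "connectome_set")) edges <- edges$edges
  if (anyNA(covariate)) stop("covariate has missing values among modeled subjects")
  if (length(covariate) != nrow(edges)) stop("covariate length mismatch")
  run_cpm(edges, y, scheme, p_threshold, score_mode,
          outcome_name = outcome_name, covariate = covariate)
}
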