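#' Virtually lesion one network and rerun the pipeline
#'
#' Removes every edge incident to the named network from the input edge
#' matrix, reruns the full cross-validated pipeline (feature selection
#' included) under the same split scheme, and quantifies the change in
#' per-split prediction accuracy relative to the intact run. Because the
#' splits are matched (same seed), each delta is a paired difference:
#' `delta_r = r_lesioned - r_full` over splits with valid accuracy in both
#' conditions.
#'
#' Significance of the mean delta uses a matched-split sign-flip
#' permutation (default 10,000 flips, two-sided, (k+1)/(n+1) estimator);
#' a paired t-test is available via `test = "t"`.
#'
#' With edge-wise feature selection, removing columns before selection
#' (`mode = "reselect"`) and pruning lesioned edges from masks selected on
#' the full edge set (`mode = "prune"`) yield identical per-split results,
#' because each edge's selection p-value does not depend on other edges;
#' both modes are kept for interface completeness.
#'
#' @inheritParams run_cpm
#' @param atlas A [network_atlas()] matching the connectome parcellation.
#' @param label Network to lesion (one of [gordon_networks]).
#' @param full Optional `prediction_result` of the intact run under the
#'   same scheme (recomputed if absent).
#' @param mode `"reselect"` or `"prune"` (see Details).
#' @param n_flips Sign-flip permutations for the paired test.
#' @param test `"signflip"` or `"t"`.
#' @return A `lesion_result`: `delta_r`, `mean_delta`, `se_delta`,
#'   `p_value`, per-condition accuracies.
#' @export
lesion_and_rerun <- function(edges, y, atlas, label, scheme,
                             p_threshold = 0.01,
                             score_mode = c("combined", "positive_only", "negative_only"),
                             full = NULL, mode = c("reselect", "prune"),
                             n_flips = 10000L, test = c("signflip", "t")) {
  score_mode <- match.arg(score_mode)
  mode <- match.arg(mode)
  test <- match.arg(test)
  if (inherits(edges, "connectome_set")) edges <- edges$edges
  lesion_idx <- edges_of_network(atlas, label)
  if (length(lesion_idx) >= ncol(edges))
    stop("lesioning ", label, " would remove every edge")
  if (is.null(full))
    full <- run_cpm(edges, y, scheme, p_threshold, score_mode)
  les <- if (mode == "reselect") {
    kept <- setdiff(seq_len(ncol(edges)), lesion_idx)
    run_cpm(edges[, kept, drop = FALSE], y, scheme, p_threshold, score_mode)
  } else {
    run_cpm(edges, y, scheme, p_threshold, score_mode, mask_exclude = lesion_idx)
  }
  ok <- !is.na(full$per_split_r) & !is.na(les$per_split_r)
  delta <- les$per_split_r[ok] - full$per_split_r[ok]
  m <- length(delta)
  if (m < 3L) stop("fewer than 3 matched splits with valid accuracy")
  mean_delta <- mean(delta)
  se_delta <- stats::sd(delta) / sqrt(m)
  if (test == "signflip") {
    set.seed(.derive_seed(scheme$seed, 3L, match(label, gordon_networks)))
    flips <- matrix(sample(c(-1, 1), n_flips * m, replace = TRUE), nrow = n_flips)
    null_means <- as.vector(flips %*% delta) / m
    p <- (sum(abs(null_means) >= abs(mean_delta)) + 1) / (n_flips + 1)
  } else {
    p <- stats::t.test(delta)$p.value
  }
  structure(list(network = label, score_mode = score_mode, mode = mode,
                 delta_r = delta, mean_delta = mean_delta, se_delta = se_delta,
                 p_value = p, p_corrected = NA_real_,
                 full_mean_r = full$mean_r, lesioned_mean_r = les$mean_r,
                 n_matched = m),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat(sprintf("<lesion_result> %s (%s): mean delta r = %.4f (SE %.4f), p = %.4g\n",
              x$network, x$score_mode, x$mean_delta, x$se_delta, x$p_value))
  invisible(x)
}

#' Lesion every network in turn
#'
#' Runs [lesion_and_rerun()] for each of the 12 canonical networks present
#' in the atlas, under one intact reference run, and Bonferroni-corrects
#' the sign-flip p-values over the networks tested (one family per
#' outcome/score-mode combination, following the published table layout).
#'
#' @inheritParams lesion_and_rerun
#' @param labels Networks to lesion (default: all canonical networks
#'   present in the atlas).
#' @return A data.frame with one row per network: `mean_delta`, `se_delta`,
#'   `p_value`, `p_corrected`, accuracies; the `lesion_result` objects are
#'   attached as the `"results"` attribute.
#' @export
lesion_sweep <- function(edges, y, atlas, scheme, p_threshold = 0.01,
                         score_mode = c("combined", "positive_only", "negative_only"),
                         labels = NULL, mode = c("reselect", "prune"),
                         n_flips = 10000L, test = c("signflip", "t")) {
  score_mode <- match.arg(score_mode)
  mode <- match.arg(mode)
  test <- match.arg(test)
  if (inherits(edges, "connectome_set")) edges <- edges$edges
  labels <- labels %||% intersect(gordon_networks, unique(atlas$network))
  full <- run_cpm(edges, y, scheme, p_threshold, score_mode)
  res <- lapply(labels, function(lb)
    lesion_and_rerun(edges, y, atlas, lb, scheme, p_threshold, score_mode,
                     full = full, mode = mode, n_flips = n_flips, test = test))
  p <- vapply(res, `[[`, 0, "p_value")
  p_corr <- bonferroni(p, m = length(labels))
  for (k in seq_along(res)) res[[k]]$p_corrected <- p_corr[k]
  out <- data.frame(network = labels,
                    mean_delta = vapply(res, `[[`, 0, "mean_delta"),
                    se_delta = vapply(res, `[[`, 0, "se_delta"),
                    p_value = p, p_corrected = p_corr,
                    full_mean_r = vapply(res, `[[`, 0, "full_mean_r"),
                    lesioned_mean_r = vapply(res, `[[`, 0, "lesioned_mean_r"),
                    n_matched = vapply(res, `[[`, 0L, "n_matched"))
  attr(out, "results") <- res
  attr(out, "score_mode") <- score_mode
  out
}

#' Network-pair selection-fraction matrices
#'
#' For a cross-validation run with stored per-split feature masks,
#' computes, for each pair of networks (A, B), the mean over splits of the
#' fraction of possible A-B edges that were selected — separately for the
#' positive and negative feature sets. These are the summary matrices of
#' how concentrated the predictive features are in particular network
#' couplings.
#'
#' @param result A `prediction_result` from `run_cpm(..., return_masks = TRUE)`.
#' @param atlas A [network_atlas()] for the same parcellation.
#' @return `list(positive, negative)`: symmetric K x K matrices over the
#'   network labels present in the atlas (UNASSIGNED included as its own
#'   stratum when present).
#' @export
selection_fraction_matrix <- function(result, atlas) {
  if (is.null(result$masks))
    stop("run_cpm must be called with return_masks = TRUE")
  p <- nrow(atlas)
  ep <- edge_pairs(p)
  labs <- c(intersect(gordon_networks, unique(atlas$network)),
            intersect("UNASSIGNED", unique(atlas$network)))
  k <- length(labs)
  net_i <- match(atlas$network[ep$i + 1L], labs)
  net_j <- match(atlas$network[ep$j + 1L], labs)
  # order pair so (min, max) indexes the upper triangle of the K x K matrix
  a <- pmin(net_i, net_j); b <- pmax(net_i, net_j)
  pair_id <- (a - 1L) * k + b
  possible <- tabulate(pair_id, nbins = k * k)
  acc <- list(positive = numeric(k * k), negative = numeric(k * k))
  n_used <- 0L
  for (msk in result$masks) {
    if (is.null(msk)) next
    n_used <- n_used + 1L
    for (side in c("positive", "negative")) {
      sel <- msk[[side]]
      if (length(sel))
        acc[[side]] <- acc[[side]] + tabulate(pair_id[sel], nbins = k * k)
    }
  }
  if (n_used == 0L) stop("no splits with stored masks")
  shape <- function(v) {
    frac <- ifelse(possible > 0, v / (n_used * possible), 0)
    m <- matrix(frac, nrow = k, byrow = TRUE, dimnames = list(labs, labs))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  list(positive = shape(acc$positive), negative = shape(acc$negative))
}
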