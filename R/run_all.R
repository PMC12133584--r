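.default_run_config <- function() {
  list(preset = NA, fixture_dir = NA, connectome_source = NA, atlas_path = NA,
       behavior_path = NA, outcomes = "total,fluid,crystallized",
       p_threshold = 0.01, score_mode = "combined", n_splits = 100L,
       train_fraction = 0.7, n_permutations = 1000L, perm_splits = NA,
       mi_iterations = 100L, mi_subsample = 0.8, mi_cut = 0.5,
       mi_p_threshold = 0.05,
       inverse_train_cut = 0.4, inverse_test_cut = 0.5,
       covariates = "age,SES,antipsychotic_exposure,PANSS_pos,PANSS_neg,head_motion,sex,race",
       lesion = TRUE, seed = 1L)
}

#' Read / write a run configuration
#'
#' Run configurations are flat `key = value` text files. Every [run_all()]
#' invocation writes a fully resolved `config_echo.txt` into its output
#' directory; reloading that file reproduces the run bit-for-bit.
#'
#' @param path Config file.
#' @return A named list with typed values.
#' @export
read_run_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- .default_run_config()
  for (x in kv) {
    key <- trimws(x[[1L]])
    val <- trimws(paste(x[-1L], collapse = "="))
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    proto <- cfg[[key]]
    cfg[[key]] <- if (is.logical(proto)) as.logical(val)
                  else if (is.integer(proto)) as.integer(val)
                  else if (is.numeric(proto)) as.numeric(val)
                  else val
  }
  cfg
}

#' @rdname read_run_config
#' @param config Named list of configuration values (missing keys take the
#'   documented defaults).
#' @export
write_run_config <- function(config, path) {
  cfg <- utils::modifyList(.default_run_config(), config)
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v)
                       if (is.double(v) && !is.na(v)) .fmt_num(v) else as.character(v),
                       "")), path)
  invisible(path)
}

.split_csv <- function(x) trimws(strsplit(x, ",")[[1L]])

#' Run the full analysis chain
#'
#' Executes the complete pipeline on one dataset: cross-validated
#' prediction for each outcome, permutation inference with Bonferroni
#' correction over outcomes, virtual lesioning sweeps (positive and
#' negative feature sets), the misclassification-index analysis with
#' covariate dissection, and the inverted-model experiment. Every stage
#' writes a delimited-text table into `out_dir`, together with a config
#' echo that reproduces the run.
#'
#' The dataset comes from (in order of precedence) the `preset` name
#' (generated via [synthetic_preset()]), a `fixture_dir` (read via
#' [read_fixture()]), or the three explicit input paths.
#'
#' @param config Named list of settings (see [read_run_config()] for keys
#'   and defaults) or the path to a config file.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with all stage results.
#' @export
run_all <- function(config = list(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(.default_run_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(cfg, file.path(out_dir, "config_echo.txt"))
  tsv <- function(d, f) utils::write.table(d, file.path(out_dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  stage <- function(name, expr) {
    message("run_all: stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", out_dir, ")", call. = FALSE))
  }

  data <- stage("inputs", {
    if (!is.na(cfg$preset)) {
      ds <- generate_synthetic(synthetic_preset(cfg$preset, seed = cfg$seed))
      list(connectomes = ds$connectomes,
           atlas = ds$ground_truth$config$atlas, behavior = ds$behavior)
    } else if (!is.na(cfg$fixture_dir)) {
      read_fixture(cfg$fixture_dir)
    } else {
      read_inputs(cfg$connectome_source, cfg$atlas_path, cfg$behavior_path)
    }
  })
  outcomes <- intersect(.split_csv(cfg$outcomes), names(data$behavior))
  if (!length(outcomes)) stop("no requested outcome column found in behavior table")
  covs <- intersect(.split_csv(cfg$covariates), names(data$behavior))
  scheme <- split_scheme(cfg$n_splits, cfg$train_fraction, cfg$seed)
  edges <- data$connectomes$edges
  results <- list(config = cfg)

  perms <- stage("fit+permute", lapply(outcomes, function(o)
    permutation_test(edges, data$behavior[[o]], scheme, cfg$p_threshold,
                     cfg$score_mode, n_permutations = cfg$n_permutations,
                     perm_splits = if (is.na(cfg$perm_splits)) NULL else cfg$perm_splits)))
  names(perms) <- outcomes
  pred_tab <- data.frame(outcome = outcomes,
                         mean_r = vapply(perms, `[[`, 0, "observed_mean_r"),
                         permutation_p = vapply(perms, `[[`, 0, "p_value"),
                         corrected_p = bonferroni(vapply(perms, `[[`, 0, "p_value"),
                                                  m = length(outcomes)))
  tsv(pred_tab, "predictions.tsv")
  tsv(do.call(data.frame, c(list(split = seq_len(cfg$n_splits)),
                            lapply(perms, `[[`, "per_split_r"))),
      "per_split_r.tsv")
  results$predictions <- perms

  if (isTRUE(cfg$lesion)) {
    results$lesions <- stage("lesion", {
      out <- list()
      for (o in outcomes) for (sm in c("positive_only", "negative_only")) {
        sw <- lesion_sweep(edges, data$behavior[[o]], data$atlas, scheme,
                           cfg$p_threshold, sm)
        tsv(sw, sprintf("lesion_%s_%s.tsv", o, sm))
        out[[paste(o, sm, sep = ".")]] <- sw
      }
      out
    })
  }

  results$mi <- stage("misclassify", {
    out <- list()
    for (o in outcomes) {
      mi <- run_misclassification(edges, binarize_outcome(data$behavior[[o]]),
                                  n_iterations = cfg$mi_iterations,
                                  subsample_fraction = cfg$mi_subsample,
                                  p_threshold = cfg$mi_p_threshold, seed = cfg$seed,
                                  subject_ids = data$connectomes$subject_ids)
      tsv(mi, sprintf("mi_%s.tsv", o))
      hist_tab <- as.data.frame(table(cut(mi$mi, seq(0, 1, 0.1),
                                          include.lowest = TRUE)))
      names(hist_tab) <- c("mi_bin", "count")
      tsv(hist_tab, sprintf("mi_hist_%s.tsv", o))
      frac_high <- mean(mi$mi > cfg$mi_cut)
      message(sprintf("misclassify[%s]: %.1f%% of subjects with MI > %g",
                      o, 100 * frac_high, cfg$mi_cut))
      tsv(data.frame(outcome = o, mi_cut = cfg$mi_cut,
                     fraction_above_cut = frac_high, mean_mi = mean(mi$mi)),
          sprintf("mi_summary_%s.tsv", o))
      if (length(covs)) {
        dis <- mi_covariate_dissection(mi, data$behavior, o, covs, cfg$mi_cut)
        tsv(dis, sprintf("dissection_%s.tsv", o))
        out[[o]] <- list(mi = mi, dissection = dis)
      } else out[[o]] <- list(mi = mi)
    }
    out
  })

  results$inverse <- stage("inverse", {
    out <- list()
    for (o in outcomes) {
      inv <- tryCatch(
        run_inverse_experiment(edges, data$behavior[[o]], results$mi[[o]]$mi,
                               cfg$inverse_train_cut, cfg$inverse_test_cut,
                               cfg$p_threshold, cfg$score_mode, outcome_name = o),
        error = function(e) e)
      if (inherits(inv, "error")) {
        message("inverse model skipped for ", o, ": ", conditionMessage(inv))
      } else {
        tsv(data.frame(outcome = o, r_direct = inv$r_direct,
                       r_inverted = inv$r_inverted, n_train = inv$n_train,
                       n_test = inv$n_test),
            sprintf("inverse_%s.tsv", o))
        out[[o]] <- inv
      }
    }
    out
  })

  message("run_all: complete; outputs in ", out_dir)
  invisible(results)
}
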