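# Gordon-atlas network sizes (12 cortical networks + unassigned parcels),
# used as the default full-scale parcellation profile.
.gordon_sizes <- c(AUD = 24L, CO = 40L, CP = 5L, DAN = 32L, DMN = 41L,
                   FPN = 24L, RSP = 8L, SAL = 4L, SM = 38L, SML = 8L,
                   VAN = 23L, VIS = 39L, UNASSIGNED = 47L)

.atlas_from_sizes <- function(sizes) {
  network_atlas(parcel_id = seq_len(sum(sizes)) - 1L,
                network = rep(names(sizes), sizes))
}

# Resolve a planted-edge specification: an explicit vector of edge
# positions, or list(networks = c(A, B), n = k) drawing k distinct edges
# whose endpoints fall one in A and one in B (within-network when A == B).
.resolve_planted <- function(spec, atlas, seed, stream, exclude = integer(0)) {
  if (is.null(spec)) return(integer(0))
  if (is.numeric(spec)) return(sort(as.integer(spec)))
  stopifnot(is.list(spec), !is.null(spec$networks), !is.null(spec$n))
  nets <- spec$networks
  if (length(nets) == 1L) nets <- c(nets, nets)
  ep <- edge_pairs(nrow(atlas))
  li <- atlas$network[ep$i + 1L]
  lj <- atlas$network[ep$j + 1L]
  cand <- which((li == nets[1L] & lj == nets[2L]) | (li == nets[2L] & lj == nets[1L]))
  cand <- setdiff(cand, exclude)
  if (length(cand) < spec$n)
    stop(sprintf("only %d candidate %s-%s edges for %d planted",
                 length(cand), nets[1L], nets[2L], spec$n))
  set.seed(.derive_seed(seed, 5L, stream))
  sort(cand[sample.int(length(cand), spec$n)])
}

#' Configuration for the synthetic connectome generator
#'
#' Defines a simulated study: a latent cognitive trait drives a set of
#' planted positive and negative edges, the observed outcomes, and
#' stereotypically coupled covariates; a discordant subgroup has the
#' edge-trait coupling sign flipped, emulating subjects whose
#' brain-behavior relationship opposes the majority pattern.
#'
#' Defaults describe the emulated study conditions: 92 subjects on a
#' Gordon-sized 333-parcel atlas; edge-trait coupling `effect_beta = 0.5`
#' against unit edge noise; outcome reliability 0.8
#' (`outcome_loading = 0.8`, `outcome_noise_sd = 0.6`) on a
#' NIH-Toolbox-like scale (mean 100, sd 15); SES coupled at +0.75 and
#' antipsychotic exposure at -0.5 to the trait — values chosen so the
#' population covariate-outcome correlations among concordant subjects
#' match the reported stereotype magnitudes (about +0.48 and -0.37).
#'
#' @param n_subjects Number of subjects (default 92).
#' @param atlas Either a [network_atlas()] or a named vector of
#'   network sizes; default is the Gordon-sized 13-stratum profile
#'   (333 parcels including 47 UNASSIGNED).
#' @param planted_positive,planted_negative Planted edge sets: explicit
#'   1-based edge positions, or `list(networks = c("A","B"), n = k)`.
#'   The two sets must be disjoint.
#' @param effect_beta Edge-trait coupling strength (edge units per trait
#'   SD; default 0.5). 0 gives a null generator.
#' @param edge_noise_sd Edge noise SD (default 1).
#' @param baseline_mean,baseline_sd Per-edge baseline connectivity drawn
#'   once per edge (default N(0.25, 0.1)); edges are not constrained to
#'   \[-1, 1\] unless `squash = TRUE` (tanh), since CPM is scale-free in
#'   the edges.
#' @param outcome_loading,outcome_noise_sd Trait loading and noise of the
#'   observed outcomes.
#' @param outcome_mean,outcome_sd Output scale (default 100 / 15).
#' @param outcomes Outcome column names; each gets an independent noise
#'   realization of the same trait (default total, fluid, crystallized).
#' @param covariate_couplings Named numeric couplings of continuous
#'   covariates to the trait (default SES +0.75, antipsychotic_exposure
#'   -0.5, age / PANSS_pos / PANSS_neg / head_motion 0); each covariate is
#'   `coupling * trait + N(0, 1)` before rescaling to its nominal units.
#' @param stereotype_breaking When TRUE (default), covariate couplings
#'   apply to concordant subjects only, so discordant subjects break the
#'   covariate-outcome stereotype as well.
#' @param discordant_fraction Fraction of subjects (in \[0, 1)) whose
#'   edge-trait coupling sign is inverted (default 0).
#' @param squash Apply tanh to the generated edges.
#' @param seed Master seed of the generator.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 92L, atlas = NULL,
                             planted_positive = NULL, planted_negative = NULL,
                             effect_beta = 0.5, edge_noise_sd = 1,
                             baseline_mean = 0.25, baseline_sd = 0.1,
                             outcome_loading = 0.8, outcome_noise_sd = 0.6,
                             outcome_mean = 100, outcome_sd = 15,
                             outcomes = c("total", "fluid", "crystallized"),
                             covariate_couplings = c(SES = 0.75,
                                                     antipsychotic_exposure = -0.5,
                                                     age = 0, PANSS_pos = 0,
                                                     PANSS_neg = 0, head_motion = 0),
                             stereotype_breaking = TRUE,
                             discordant_fraction = 0, squash = FALSE, seed = 1L) {
  if (is.null(atlas)) atlas <- .atlas_from_sizes(.gordon_sizes)
  else if (!inherits(atlas, "network_atlas")) atlas <- .atlas_from_sizes(atlas)
  if (!(discordant_fraction >= 0 && discordant_fraction < 1))
    stop("discordant_fraction must lie in [0, 1)")
  if (outcome_loading^2 + outcome_noise_sd^2 <= 0)
    stop("outcome loading and noise cannot both be zero (outcome would be constant)")
  p <- nrow(atlas)
  e <- p * (p - 1L) / 2L
  pos <- .resolve_planted(planted_positive, atlas, seed, 1L)
  neg <- .resolve_planted(planted_negative, atlas, seed, 2L, exclude = pos)
  if (length(intersect(pos, neg))) stop("planted positive and negative sets overlap")
  if (length(c(pos, neg)) && max(c(pos, neg)) > e)
    stop("planted edge index exceeds the edge count E=", e)
  structure(list(n_subjects = as.integer(n_subjects), atlas = atlas,
                 n_parcels = p, n_edges = e,
                 planted_positive = pos, planted_negative = neg,
                 effect_beta = effect_beta, edge_noise_sd = edge_noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 outcome_loading = outcome_loading,
                 outcome_noise_sd = outcome_noise_sd,
                 outcome_mean = outcome_mean, outcome_sd = outcome_sd,
                 outcomes = outcomes,
                 covariate_couplings = covariate_couplings,
                 stereotype_breaking = isTRUE(stereotype_breaking),
                 discordant_fraction = discordant_fraction,
                 squash = isTRUE(squash), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Preset generator configurations
#'
#' `"tiny"` — 24 subjects, 20 parcels in 4 networks, 3 + 3 planted edges;
#' runs the whole pipeline in seconds. `"full-scale"` — 92 subjects on the
#' Gordon-sized 333-parcel atlas with 1% of edges planted (half positive
#' in DMN-VIS, half negative in SM-RSP couplings). `"null"` — 92 subjects
#' on a 45-parcel 12-network atlas (E = 990) with `effect_beta = 0`.
#' `"signal"` — 92 subjects, 100 parcels (E = 4950), 1% planted edges
#' (25 positive DMN-VIS, 25 negative SM-RSP): the signal-recovery
#' condition. `"lesion"` — 92 subjects, 61 parcels, all 10 planted edges
#' strictly within DMN at an overwhelming coupling (`effect_beta = 2`), so
#' a DMN lesion removes the entire signal, every other network is
#' signal-free, and selection is dominated by the true edges.
#' `"discordant"` — 92 subjects, 25
#' parcels (E = 300), widespread planted signal (25 + 25 edges) and a 30%
#' sign-inverted discordant subgroup with stereotype-breaking covariates:
#' the misclassification condition.
#'
#' @param name Preset name (see Details).
#' @param seed Master seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(name = c("tiny", "full-scale", "null",
                                      "signal", "lesion", "discordant"),
                             seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    tiny = list(n_subjects = 24L,
                atlas = c(DMN = 5L, FPN = 5L, SM = 5L, VIS = 5L),
                planted_positive = list(networks = c("DMN", "FPN"), n = 3L),
                planted_negative = list(networks = c("SM", "VIS"), n = 3L)),
    `full-scale` = list(n_subjects = 92L,
                         planted_positive = list(networks = c("DMN", "VIS"), n = 276L),
                         planted_negative = list(networks = c("SM", "RSP"), n = 276L)),
    signal = list(n_subjects = 92L,
                  atlas = c(AUD = 8L, CO = 10L, CP = 6L, DAN = 10L, DMN = 12L,
                            FPN = 8L, RSP = 6L, SAL = 6L, SM = 10L, SML = 6L,
                            VAN = 8L, VIS = 10L),
                  planted_positive = list(networks = c("DMN", "VIS"), n = 25L),
                  planted_negative = list(networks = c("SM", "RSP"), n = 25L)),
    lesion = list(n_subjects = 92L,
                  atlas = c(AUD = 5L, CO = 5L, CP = 5L, DAN = 5L, DMN = 6L,
                            FPN = 5L, RSP = 5L, SAL = 5L, SM = 5L, SML = 5L,
                            VAN = 5L, VIS = 5L),
                  planted_positive = list(networks = "DMN", n = 5L),
                  planted_negative = list(networks = "DMN", n = 5L),
                  effect_beta = 2),
    discordant = list(n_subjects = 92L,
                      atlas = c(DMN = 7L, FPN = 6L, SM = 6L, VIS = 6L),
                      planted_positive = list(networks = c("DMN", "FPN"), n = 25L),
                      planted_negative = list(networks = c("SM", "VIS"), n = 25L),
                      discordant_fraction = 0.3),
    null = list(n_subjects = 92L,
                atlas = c(AUD = 4L, CO = 4L, CP = 4L, DAN = 4L, DMN = 4L,
                          FPN = 4L, RSP = 4L, SAL = 4L, SM = 3L, SML = 3L,
                          VAN = 3L, VIS = 4L),
                effect_beta = 0))
  over <- list(...)
  args[names(over)] <- over
  args$seed <- seed
  do.call(synthetic_config, args)
}

#' Generate a synthetic connectome study
#'
#' Draws a standard-normal latent trait per subject; planted positive
#' edges are `baseline + effect_beta * trait + noise` (sign flipped for
#' discordant subjects and for the negative set), non-planted edges are
#' baseline plus noise; outcomes are rescaled noisy loadings of the trait;
#' continuous covariates couple to the trait (concordant subjects only
#' under stereotype breaking) and sex/race are random categories. Fully
#' reproducible from the config seed.
#'
#' @param config A [synthetic_config()].
#' @return `list(connectomes, behavior, ground_truth)` where
#'   `ground_truth` records the planted edge sets, per-subject concordance
#'   flags, the latent trait and the config.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_subjects
  e <- config$n_edges
  set.seed(.derive_seed(config$seed, 6L, 0L))
  baseline <- stats::rnorm(e, config$baseline_mean, config$baseline_sd)
  trait <- stats::rnorm(n)
  n_disc <- floor(config$discordant_fraction * n)
  disc <- rep(FALSE, n)
  if (n_disc > 0L) disc[sample.int(n, n_disc)] <- TRUE
  sgn <- ifelse(disc, -1, 1)
  edges <- matrix(stats::rnorm(n * e, sd = config$edge_noise_sd), n, e)
  edges <- edges + rep(baseline, each = n)
  if (length(config$planted_positive))
    edges[, config$planted_positive] <- edges[, config$planted_positive] +
      (sgn * config$effect_beta * trait)
  if (length(config$planted_negative))
    edges[, config$planted_negative] <- edges[, config$planted_negative] -
      (sgn * config$effect_beta * trait)
  if (config$squash) edges <- tanh(edges)
  ids <- sprintf("S%03d", seq_len(n))
  cs <- connectome_set(edges, ids, config$n_parcels)

  osd <- sqrt(config$outcome_loading^2 + config$outcome_noise_sd^2)
  beh <- data.frame(subject_id = ids)
  for (o in config$outcomes) {
    raw <- config$outcome_loading * trait + stats::rnorm(n, sd = config$outcome_noise_sd)
    beh[[o]] <- config$outcome_mean + config$outcome_sd * raw / osd
  }
  cc <- config$covariate_couplings
  couple_to <- if (config$stereotype_breaking) as.numeric(!disc) else rep(1, n)
  zcov <- function(coupling) coupling * trait * couple_to + stats::rnorm(n)
  # nominal units: linear rescalings of the coupled z-scores
  units <- list(SES = c(50, 12), antipsychotic_exposure = c(18, 10),
                age = c(23, 3.5), PANSS_pos = c(15, 5), PANSS_neg = c(15, 5),
                head_motion = c(0.15, 0.05))
  for (nm in names(cc)) {
    u <- units[[nm]] %||% c(0, 1)
    beh[[nm]] <- u[1L] + u[2L] * zcov(cc[[nm]])
  }
  beh$sex <- sample(c("F", "M"), n, replace = TRUE)
  beh$race <- sample(c("white", "black", "asian", "other"), n,
                     replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
  gt <- list(planted_positive = config$planted_positive,
             planted_negative = config$planted_negative,
             concordant = !disc, trait = trait, config = config)
  list(connectomes = cs, behavior = beh, ground_truth = gt)
}

#' Write / read a synthetic dataset as an on-disk fixture
#'
#' Writes the connectomes (edge-table format by default), atlas, behavior
#' table and plain-text ground-truth sidecars (planted edges by parcel
#' pair; per-subject concordance and trait) into a directory, such that
#' [read_fixture()] (or [read_inputs()] for the three modeling artifacts)
#' reproduces the dataset exactly.
#'
#' @param dataset Output of [generate_synthetic()].
#' @param dir Target directory (created if needed).
#' @param format Connectome layout, `"edges"` or `"matrix"`.
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(dataset, dir, format = c("edges", "matrix")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- dataset$ground_truth$config
  con_path <- file.path(dir, if (format == "edges") "connectomes.tsv" else "matrices")
  write_connectomes(dataset$connectomes, con_path, format = format)
  write_atlas(cfg$atlas, file.path(dir, "atlas.tsv"))
  write_behavior(dataset$behavior, file.path(dir, "behavior.tsv"))
  ep <- edge_pairs(cfg$n_parcels)
  gt <- dataset$ground_truth
  ge <- data.frame(
    side = rep(c("positive", "negative"),
               c(length(gt$planted_positive), length(gt$planted_negative))),
    edge = c(gt$planted_positive, gt$planted_negative))
  ge$i <- ep$i[ge$edge]; ge$j <- ep$j[ge$edge]
  utils::write.table(ge, file.path(dir, "ground_truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gs <- data.frame(subject_id = dataset$behavior$subject_id,
                   concordant = gt$concordant, trait = .fmt_num(gt$trait))
  utils::write.table(gs, file.path(dir, "ground_truth_subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_fixture
#' @return `read_fixture` returns
#'   `list(connectomes, atlas, behavior, ground_truth)`.
#' @export
read_fixture <- function(dir) {
  con_path <- file.path(dir, "connectomes.tsv")
  if (!file.exists(con_path)) con_path <- file.path(dir, "matrices")
  inputs <- read_inputs(con_path, file.path(dir, "atlas.tsv"),
                        file.path(dir, "behavior.tsv"))
  ge <- .read_delim(file.path(dir, "ground_truth_edges.tsv"))
  gs <- .read_delim(file.path(dir, "ground_truth_subjects.tsv"))
  inputs$ground_truth <- list(
    planted_positive = ge$edge[ge$side == "positive"],
    planted_negative = ge$edge[ge$side == "negative"],
    concordant = as.logical(gs$concordant),
    trait = as.numeric(gs$trait))
  inputs
}
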