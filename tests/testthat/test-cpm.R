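test_that("edge-wise correlations match a brute-force per-column oracle", {
  toy <- toy_dataset()
  ce <- correlate_edges(toy$edges, toy$y)
  for (e in seq_len(toy$n_edges)) {
    ct <- cor.test(toy$edges[, e], toy$y)
    expect_equal(ce$r[e], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(ce$p[e], ct$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate correlation inputs are handled explicitly", {
  toy <- toy_dataset()
  x <- toy$edges
  x[, 2] <- toy$y                      # edge identical to the outcome
  x[, 3] <- 5                          # constant edge
  expect_warning(ce <- correlate_edges(x, toy$y), "constant edge")
  expect_equal(ce$r[2], 1)
  expect_lt(ce$p[2], 1e-12)
  expect_equal(ce$r[3], 0)
  expect_equal(ce$p[3], 1)
  expect_error(correlate_edges(x, rep(1, toy$n)), "constant")
  expect_error(correlate_edges(x[1:3, ], toy$y[1:3]), "at least 4")
})

test_that("feature selection applies the threshold-and-sign rule", {
  m <- select_features(r = c(0.4, 0.4, -0.4), p = c(0.001, 0.5, 0.001),
                       p_threshold = 0.01)
  expect_equal(m$positive, 1L)
  expect_equal(m$negative, 3L)
  m0 <- select_features(r = runif(5), p = rep(1, 5))
  expect_length(m0$positive, 0)
  expect_length(m0$negative, 0)
})

test_that("summary scores obey the combined identity and emptiness rules", {
  mask <- structure(list(positive = 1L, negative = 2L, p_threshold = 0.01),
                    class = "feature_mask")
  v <- c(2, 0.5, 99)
  expect_equal(summary_score(v, mask, "combined"), 1.5)
  empty_neg <- structure(list(positive = 1L, negative = integer(0)),
                         class = "feature_mask")
  expect_error(summary_score(v, empty_neg, "combined"), "negative feature set is empty")
  expect_equal(summary_score(v, empty_neg, "positive_only"), 2)
  set.seed(3)
  x <- matrix(rnorm(40), 4, 10)
  mask2 <- structure(list(positive = c(1L, 4L, 7L), negative = c(2L, 9L)),
                     class = "feature_mask")
  expect_identical(summary_score(x, mask2, "combined"),
                   summary_score(x, mask2, "positive_only") -
                     summary_score(x, mask2, "negative_only"))
})

test_that("an exactly linear outcome is recovered to numerical precision", {
  dl <- exact_linear_dataset()
  model <- fit_cpm(dl$edges, dl$y, p_threshold = 0.01, score_mode = "positive_only")
  expect_equal(model$mask$positive, 1L)
  expect_equal(model$slope, dl$slope, tolerance = 1e-10)
  expect_equal(model$intercept, dl$intercept, tolerance = 1e-10)
  expect_equal(predict(model, dl$edges), dl$y, tolerance = 1e-10)
})

test_that("toy OLS fit equals the closed-form least-squares oracle", {
  set.seed(21)
  z <- rnorm(5)
  y <- 1.2 * z + rnorm(5, sd = 0.3)
  edges <- orthogonalized_edges(5, 6, y, seed = 22)
  edges[, 4] <- z
  model <- fit_cpm(edges, y, p_threshold = 0.5, score_mode = "positive_only")
  s <- summary_score(edges, model$mask, "positive_only")
  co <- coef(lm(y ~ s))
  expect_equal(model$intercept, unname(co[1]), tolerance = 1e-10)
  expect_equal(model$slope, unname(co[2]), tolerance = 1e-10)
})

test_that("predictions depend only on masked edges", {
  dl <- exact_linear_dataset()
  model <- fit_cpm(dl$edges, dl$y, score_mode = "positive_only")
  perturbed <- dl$edges
  perturbed[, setdiff(seq_len(ncol(perturbed)), model$mask$positive)] <- 99
  expect_identical(predict(model, perturbed), predict(model, dl$edges))
  zeros <- matrix(0, 3, ncol(dl$edges))
  expect_equal(predict(model, zeros), rep(model$intercept, 3))
  expect_error(predict(model, matrix(0, 2, 5)), "mismatch")
})

test_that("cross-validated accuracy is near 1 in the perfect-signal limit", {
  dl <- exact_linear_dataset(n = 40L, e = 12L)
  res <- run_cpm(dl$edges, dl$y, split_scheme(25, 0.7, 5),
                 score_mode = "positive_only")
  expect_equal(res$n_failed, 0L)
  expect_gte(res$mean_r, 0.99)
})

test_that("pure-noise outcomes give accuracy centered on zero", {
  # single-dataset mean r fluctuates at the +/- 0.1 scale because spurious
  # edges recur across overlapping splits; the null-centering property is
  # an ensemble statement, so average over replicate null datasets
  means <- vapply(1:6, function(s) {
    set.seed(30 + s)
    edges <- matrix(rnorm(92 * 600), 92, 600)
    y <- rnorm(92)
    suppressWarnings(run_cpm(edges, y, split_scheme(50, 0.7, s))$mean_r)
  }, 0)
  expect_lt(abs(mean(means)), 0.1)
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)) + 0.05)
})

test_that("splits are unique and reproducible from the seed", {
  sch <- split_scheme(50, 0.7, 9)
  idx <- conncpm:::.split_indices(10, sch)
  keys <- vapply(idx, paste, "", collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(idx, conncpm:::.split_indices(10, sch))
  dl <- exact_linear_dataset(n = 30L)
  r1 <- run_cpm(dl$edges, dl$y, sch, score_mode = "positive_only")
  r2 <- run_cpm(dl$edges, dl$y, sch, score_mode = "positive_only")
  expect_identical(r1$per_split_r, r2$per_split_r)
})

test_that("runs abort with guidance when selection fails on most splits", {
  set.seed(12)
  edges <- matrix(rnorm(30 * 20), 30, 20)
  y <- rnorm(30)
  expect_error(suppressWarnings(
    run_cpm(edges, y, split_scheme(20, 0.7, 2), p_threshold = 1e-12)),
    "relax")
})

test_that("external validation applies a frozen model without refitting", {
  dl <- exact_linear_dataset(n = 50L, e = 8L)
  model <- fit_cpm(dl$edges, dl$y, score_mode = "positive_only")
  # on its own training data the transfer equals the in-sample correlation
  ev <- external_validate(model, dl$edges, dl$y)
  expect_equal(ev$r, cor(predict(model, dl$edges), dl$y), tolerance = 1e-12)
  expect_equal(ev$n, 50L)
  # a permuted target outcome destroys the transfer
  set.seed(13)
  ev0 <- external_validate(model, dl$edges, sample(dl$y))
  expect_lt(abs(ev0$r), 0.5)
  expect_error(external_validate(model, dl$edges[1:3, ], dl$y[1:3]), "at least 4")
})

test_that("a full-sample model transfers to an unseen cohort with signal", {
  # one generative population, split into a source cohort and a smaller
  # external cohort that the model never sees
  ds <- generate_synthetic(synthetic_preset("discordant", seed = 33,
                                            n_subjects = 120L,
                                            discordant_fraction = 0))
  x <- ds$connectomes$edges
  y <- ds$behavior$fluid
  src <- 1:92; ext <- 93:120
  model <- fit_cpm(x[src, ], y[src], p_threshold = 0.01)
  ev <- external_validate(model, x[ext, ], y[ext])
  expect_gt(ev$r, 0.3)
  expect_lt(ev$p, 0.05)
  expect_length(ev$predicted, 28L)
})

test_that("model serialization round-trips coefficients and masks exactly", {
  toy <- toy_dataset()
  model <- fit_cpm(toy$edges, toy$y, p_threshold = 0.6)
  f <- withr::local_tempfile(fileext = ".txt")
  write_cpm_model(model, f)
  back <- read_cpm_model(f)
  expect_identical(back$slope, model$slope)
  expect_identical(back$intercept, model$intercept)
  expect_identical(back$mask$positive, model$mask$positive)
  expect_identical(back$mask$negative, model$mask$negative)
  expect_identical(predict(back, toy$edges), predict(model, toy$edges))
})

test_that("full-sample estimators are invariant to subject order", {
  toy <- toy_dataset()
  set.seed(17)
  perm <- sample(toy$n)
  ce1 <- correlate_edges(toy$edges, toy$y)
  ce2 <- correlate_edges(toy$edges[perm, ], toy$y[perm])
  expect_equal(ce1$r, ce2$r, tolerance = 1e-14)
  m1 <- fit_cpm(toy$edges, toy$y, p_threshold = 0.6)
  m2 <- fit_cpm(toy$edges[perm, ], toy$y[perm], p_threshold = 0.6)
  expect_equal(m1$slope, m2$slope, tolerance = 1e-12)
  expect_equal(m1$intercept, m2$intercept, tolerance = 1e-12)
})
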