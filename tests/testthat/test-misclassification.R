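test_that("median split assigns at-median subjects to the low class", {
  cl <- binarize_outcome(c(1, 2, 3, 4))
  expect_identical(as.character(cl), c("low", "low", "high", "high"))
  cl3 <- binarize_outcome(c(10, 20, 30))
  expect_identical(as.character(cl3), c("low", "low", "high"))
  set.seed(2)
  y <- rnorm(41)
  tab <- table(binarize_outcome(y))
  expect_lte(abs(tab[["low"]] - tab[["high"]]), 1L)
  expect_error(binarize_outcome(rep(3, 5)), "constant")
})

test_that("a perfectly separable subject is never misclassified", {
  set.seed(1)
  n <- 40L
  cls <- factor(rep(c("low", "high"), each = 20), levels = c("low", "high"))
  x <- matrix(rnorm(n * 50), n)
  x[, 1] <- ifelse(cls == "high", 4, -4) + rnorm(n, sd = 0.01)
  mi <- run_misclassification(x, cls, n_iterations = 20, p_threshold = 0.01,
                              seed = 2)
  expect_lte(max(mi$mi), 0.1)
  expect_equal(mi$mi[1], 0)
  expect_identical(attr(mi, "n_iterations"), 20L)
})

test_that("misclassification is reproducible and near chance under label noise", {
  set.seed(5)
  n <- 40L
  x <- matrix(rnorm(n * 60), n)
  cls <- factor(sample(rep(c("low", "high"), each = 20)), levels = c("low", "high"))
  mi1 <- run_misclassification(x, cls, n_iterations = 25, seed = 3)
  mi2 <- run_misclassification(x, cls, n_iterations = 25, seed = 3)
  expect_identical(mi1$mi, mi2$mi)
  expect_gt(mean(mi1$mi), 0.3)
  expect_lt(mean(mi1$mi), 0.7)
})

test_that("discordant subjects are misclassified more often than concordant", {
  ds <- generate_synthetic(synthetic_preset("discordant", seed = 5, n_subjects = 60L))
  mi <- run_misclassification(ds$connectomes,
                              binarize_outcome(ds$behavior$total),
                              n_iterations = 40, seed = 5)
  conc <- ds$ground_truth$concordant
  expect_gt(mean(mi$mi[!conc]), mean(mi$mi[conc]))
})

test_that("covariate dissection recovers exact and degenerate relationships", {
  set.seed(6)
  n <- 40L
  mi <- data.frame(subject_id = sprintf("S%02d", 1:n),
                   scorer_class = factor(rep(c("low", "high"), each = 20),
                                         levels = c("low", "high")),
                   mi = runif(n))
  class(mi) <- c("mi_profile", "data.frame")
  beh <- data.frame(subject_id = mi$subject_id, total = rnorm(n),
                    SES = mi$mi + c(rnorm(n, sd = 1e-9)),   # exact copy of MI
                    sex = sample(c("F", "M"), n, TRUE))
  dis <- mi_covariate_dissection(mi, beh, "total", c("SES", "sex"))
  ses_low <- dis[dis$covariate == "SES" & dis$stratum == "low_scorers", ]
  ses_high <- dis[dis$covariate == "SES" & dis$stratum == "high_scorers", ]
  expect_equal(ses_low$r, 1, tolerance = 1e-6)
  expect_equal(ses_high$r, 1, tolerance = 1e-6)
  expect_true(all(dis$analysis %in% c("mi_vs_covariate", "covariate_vs_outcome")))
  # a stratum with < 4 subjects is flagged, not silently computed
  mi2 <- mi; mi2$mi <- c(rep(0.1, n - 2), 0.9, 0.95)
  dis2 <- mi_covariate_dissection(mi2, beh, "total", "SES")
  mis_row <- dis2[dis2$stratum == "misclassified", ]
  expect_false(mis_row$computed)
  expect_true(is.na(mis_row$r))
  expect_error(mi_covariate_dissection(mi, beh, "total", "nope"), "missing")
})

test_that("partial correlation matches the closed-form three-variable oracle", {
  set.seed(8)
  x <- rnorm(30); y <- rnorm(30); z <- 0.5 * x + 0.3 * y + rnorm(30)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(conncpm:::.partial_cor(x, y, z), oracle, tolerance = 1e-12)
  # orthogonal covariate leaves the correlation untouched
  z0 <- resid(lm(rnorm(30) ~ x + y))
  expect_equal(conncpm:::.partial_cor(x, y, z0), rxy, tolerance = 1e-10)
  # covariate identical to one variable: undefined
  expect_true(is.na(conncpm:::.partial_cor(x, y, y)))
})

test_that("covaried accuracy equals raw accuracy for a neutral covariate", {
  dl <- exact_linear_dataset(n = 40L, e = 12L)
  sch <- split_scheme(15, 0.7, 9)
  raw <- run_cpm(dl$edges, dl$y, sch, score_mode = "positive_only")
  cov_const <- covaried_prediction(dl$edges, dl$y, rep(2, 40), sch,
                                   score_mode = "positive_only")
  expect_equal(cov_const$per_split_r, raw$per_split_r, tolerance = 1e-12)
  # covarying for the outcome itself is degenerate on every split
  expect_error(suppressWarnings(
    covaried_prediction(dl$edges, dl$y, dl$y, sch, score_mode = "positive_only")),
    "failed|relax")
  expect_error(covaried_prediction(dl$edges, dl$y, c(NA, rnorm(39)), sch),
               "missing values")
})
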