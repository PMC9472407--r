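# aggressiveness classification, ROC/AUC, DeLong tests, percentile groups,
# covariate-adjusted odds ratios, evaluation report.

test_that("aggressiveness classifiers follow the T4 / Gleason-8 rules", {
  expect_true(classify_aggressive("T4", 6L, "stage"))
  expect_false(classify_aggressive("T2", 7L, "gleason"))
  expect_true(classify_aggressive(NA, 9L, "gleason"))
  expect_true(is.na(classify_aggressive(NA, 9L, "stage")))
  expect_false(classify_aggressive("T3", 8L, "stage"))
  expect_true(classify_aggressive("T1", 8L, "gleason"))
  expect_error(classify_aggressive("T5", 7L, "stage"), "stage")
  expect_error(classify_aggressive("T1", 11L, "gleason"), "Gleason")
})

test_that("AUC identities hold exactly", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1)
  # pairwise win/tie enumeration: cases {2,3}, controls {1,2}
  expect_equal(roc_auc(c(2, 3, 1, 2), c(T, T, F, F))$auc, 0.875,
               tolerance = 1e-12)
  # complement identity, exact
  set.seed(30)
  s <- rnorm(200); y <- rbinom(200, 1, 0.4) == 1
  expect_equal(roc_auc(s, y)$auc + roc_auc(-s, y)$auc, 1, tolerance = 1e-12)
  # invariance under strictly increasing transforms
  expect_equal(roc_auc(exp(s / 2), y)$auc, roc_auc(s, y)$auc,
               tolerance = 1e-12)
  # CI contains the AUC; variance nonnegative
  r <- roc_auc(s, y)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  expect_gte(r$var, 0)
  logit_ci <- roc_auc(s, y, ci_method = "logit")$ci
  expect_true(logit_ci[1] > 0 && logit_ci[2] < 1)
  expect_error(roc_auc(s, rep(TRUE, 200)), "both cases and controls")
})

test_that("DeLong tests behave on identities", {
  set.seed(31)
  s <- rnorm(100); y <- rep(c(TRUE, FALSE), 50)
  r <- roc_auc(s, y)
  self <- delong_test(r, r, paired = TRUE)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)
  # paired variance of a score against itself is exactly zero
  expect_equal(self$var, 0)
  # unpaired with equal AUCs
  r2 <- roc_auc(s + 100, y)  # monotone shift: same AUC, same components
  un <- delong_test(r, r2, paired = FALSE)
  expect_equal(un$z, 0)
  # mismatched samples rejected for paired tests
  r3 <- roc_auc(rnorm(80), rep(c(TRUE, FALSE), 40))
  expect_error(delong_test(r, r3, paired = TRUE), "same samples")
})

test_that("DeLong variance is consistent with a bootstrap oracle", {
  # moderately sized fixed dataset; the full 10,000-draw comparison runs in
  # the acceptance suite, this is a quick guard at 3,000 draws
  set.seed(32)
  n <- 200
  y <- rep(c(TRUE, FALSE), each = n / 2)
  s <- rnorm(n) + y * 0.8
  v_delong <- roc_auc(s, y)$var
  cs <- s[y]; ct <- s[!y]
  boot <- replicate(3000, {
    roc_auc(c(sample(cs, replace = TRUE), sample(ct, replace = TRUE)), y)$auc
  })
  expect_lt(abs(v_delong / var(boot) - 1), 0.15)
})

test_that("percentile groups use the stated boundary conventions", {
  g <- percentile_groups(seq_len(100))
  expect_identical(sum(g == "high"), 10L)
  expect_identical(sum(g == "mid"), 21L)
  # rank invariance under monotone transforms
  z <- rnorm(100)
  expect_identical(percentile_groups(z), percentile_groups(exp(z)))
  expect_error(percentile_groups(rep(1, 50)), "degenerate")
})

test_that("covariate-adjusted OR reduces to the cross-product without covariates", {
  g <- factor(rep(c("high", "mid"), c(40, 40)), levels = c("high", "mid", "other"))
  y <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 20), rep(FALSE, 20))
  res <- covariate_adjusted_or(g, y)
  expect_equal(res$or, 3.0, tolerance = 1e-6)
  expect_true(res$ci[1] <= res$or && res$or <= res$ci[2])
  # independence: OR near 1 at large n
  set.seed(33)
  z <- rnorm(5000)
  y2 <- rbinom(5000, 1, 0.4) == 1
  res2 <- covariate_adjusted_or(percentile_groups(z), y2)
  expect_lt(abs(log(res2$or)), 0.35)
  # with covariates: runs, median-fills missing ages
  age <- rnorm(5000, 65, 8); age[1:50] <- NA
  pcs <- matrix(rnorm(5000 * 10), 5000)
  res3 <- covariate_adjusted_or(percentile_groups(z), y2, age = age, pcs = pcs)
  expect_identical(res3$covariates, c("age", paste0("PC", 1:10)))
  # empty cell errors
  g4 <- factor(rep(c("high", "mid"), each = 10), levels = levels(g))
  y4 <- rep(c(TRUE, FALSE), each = 10)
  expect_error(covariate_adjusted_or(g4, y4), "empty cell")
})

test_that("covariate-adjusted AUC separates PRS and covariate signal", {
  set.seed(34)
  n <- 2000
  prs <- rnorm(n)
  # constant covariates: model AUC equals PRS-only AUC (rank invariance)
  y <- rbinom(n, 1, plogis(prs)) == 1
  res <- covariate_adjusted_auc(prs, y, age = rep(60, n))
  expect_equal(res$model_auc$auc, res$prs_auc$auc, tolerance = 1e-10)
  # null PRS with informative age: model AUC from age alone
  age <- rnorm(n, 65, 8)
  y2 <- rbinom(n, 1, plogis((age - 65) / 8)) == 1
  res2 <- covariate_adjusted_auc(rnorm(n), y2, age = age)
  expect_gt(res2$model_auc$auc, 0.6)
  expect_lt(abs(res2$prs_auc$auc - 0.5), 0.05)
})

test_that("evaluation reports have one row per combination", {
  set.seed(35)
  mk <- function(n) {
    z <- rnorm(n)
    list(scores = data.frame(z_EUR = z, z_AFR = z + rnorm(n, 0, 0.3)),
         status = rbinom(n, 1, plogis(z)) == 1,
         age = rnorm(n, 65, 5), pcs = matrix(rnorm(n * 2), n),
         stage = sample(c(paste0("T", 1:4), NA), n, replace = TRUE),
         gleason = sample(c(4:10, NA), n, replace = TRUE))
  }
  cohorts <- list(one = mk(400), two = mk(400))
  # stage/gleason must be case-only in spirit; here every sample is scored
  for (nm in names(cohorts)) {
    cohorts[[nm]]$stage[!cohorts[[nm]]$status] <- NA
    cohorts[[nm]]$gleason[!cohorts[[nm]]$status] <- NA
  }
  rep1 <- build_evaluation_report(cohorts, c("EUR", "AFR"))
  expect_identical(nrow(rep1), 4L)
  expect_true(all(rep1$outcome == "case_control"))
  rep2 <- build_evaluation_report(cohorts, "EUR",
                                  classifiers = c("stage", "gleason"))
  expect_identical(nrow(rep2), 6L)
  expect_setequal(unique(rep2$outcome),
                  c("case_control", "aggressive_stage", "aggressive_gleason"))
  # missing score column flagged, not fatal
  rep3 <- build_evaluation_report(cohorts, c("EUR", "XXX"))
  expect_identical(sum(rep3$note == "missing score column"), 2L)
  # serialization
  tsv <- tempfile(); json <- tempfile()
  write_evaluation_report(rep2, tsv, json)
  expect_true(file.exists(tsv) && file.exists(json))
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(nrow(back), nrow(rep2))
})
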