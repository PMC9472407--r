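# ROC/AUC with DeLong variance and tests, covariate-adjusted odds ratios
# for percentile groups, aggressiveness classification, and the evaluation
# report assembling all of it.

#' Classify a case as aggressive prostate cancer
#'
#' Two separate classifiers: `"stage"` calls a case aggressive when the
#' tumour stage is T4 (vs T1-T3); `"gleason"` when the Gleason score is at
#' least 8 (vs <= 7). A missing value for the active classifier makes the
#' case not evaluable (`NA`).
#'
#' @param stage character vector in `"T1".."T4"` (`NA` allowed).
#' @param gleason integer Gleason scores 2-10 (`NA` allowed).
#' @param classifier `"stage"` or `"gleason"`.
#' @return logical vector: `TRUE` aggressive, `FALSE` non-aggressive, `NA`
#'   not evaluable.
#' @export
classify_aggressive <- function(stage, gleason, classifier = c("stage", "gleason")) {
  classifier <- match.arg(classifier)
  bad_stage <- !is.na(stage) & !stage %in% paste0("T", 1:4)
  if (any(bad_stage)) stopf("unknown tumour stage code '%s'", stage[bad_stage][1])
  bad_gl <- !is.na(gleason) & !(gleason %in% 2:10)
  if (any(bad_gl)) stopf("Gleason score out of range: %s", gleason[bad_gl][1])
  if (classifier == "stage") stage == "T4" else gleason >= 8
}

delong_components <- function(scores, labels) {
  # structural components of the Mann-Whitney AUC (DeLong et al.)
  cs <- scores[labels]; ct <- scores[!labels]
  m <- length(cs); n <- length(ct)
  r_all <- rank(c(cs, ct), ties.method = "average")
  r_case <- rank(cs, ties.method = "average")
  r_ctrl <- rank(ct, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_case) / n          # per-case components
  v01 <- 1 - (r_all[m + seq_len(n)] - r_ctrl) / m  # per-control components
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC AUC with DeLong variance and confidence interval
#'
#' AUC by Mann-Whitney counting (ties worth 1/2); variance from DeLong's
#' structural components `var(V10)/m + var(V01)/n`; 95% CI by normal theory
#' on the AUC scale (truncated to `[0, 1]`), or on the logit scale with
#' `ci_method = "logit"`.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels logical case flags (both classes present).
#' @param ci_method `"auc"` (default, pROC-style normal CI) or `"logit"`.
#' @param conf_level confidence level (default 0.95).
#' @return a `roc_result`: `auc`, `var`, `ci`, `n_cases`, `n_controls`,
#'   plus the DeLong components for paired tests.
#' @export
roc_auc <- function(scores, labels, ci_method = c("auc", "logit"),
                    conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (!is.logical(labels)) labels <- as.logical(labels)
  keep <- !is.na(labels) & !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels))
    stopf("need both cases and controls to compute an ROC")
  dc <- delong_components(scores, labels)
  v <- var(dc$v10) / dc$m + var(dc$v01) / dc$n
  if (!is.finite(v)) v <- 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "auc") {
    ci <- pmin(pmax(dc$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  } else {
    if (dc$auc <= 0 || dc$auc >= 1) {
      ci <- c(dc$auc, dc$auc)
    } else {
      lg <- qlogis(dc$auc)
      se_lg <- sqrt(v) / (dc$auc * (1 - dc$auc))
      ci <- plogis(lg + c(-1, 1) * z * se_lg)
    }
  }
  structure(list(auc = dc$auc, var = v, ci = ci, conf_level = conf_level,
                 ci_method = ci_method, n_cases = dc$m, n_controls = dc$n,
                 v10 = dc$v10, v01 = dc$v01, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, 100 * x$conf_level, x$ci[1], x$ci[2],
              x$n_cases, x$n_controls))
  invisible(x)
}

#' DeLong test comparing two AUCs
#'
#' Paired (same individuals scored twice; the covariance of the structural
#' components enters) or unpaired (independent cohorts; variances add).
#' Two-sided normal p-value.
#'
#' @param roc_1,roc_2 [roc_auc()] results.
#' @param paired logical; `TRUE` requires identical case/control label
#'   vectors (same samples in the same order).
#' @return list: `z`, `p_value`, `delta_auc`, `var`, `paired`.
#' @export
delong_test <- function(roc_1, roc_2, paired) {
  check_flag(paired, "paired")
  stopifnot(inherits(roc_1, "roc_result"), inherits(roc_2, "roc_result"))
  d <- roc_1$auc - roc_2$auc
  if (paired) {
    if (roc_1$n_cases != roc_2$n_cases || roc_1$n_controls != roc_2$n_controls ||
        !identical(roc_1$labels, roc_2$labels))
      stopf("paired DeLong test requires the same samples scored twice")
    v <- var(roc_1$v10 - roc_2$v10) / roc_1$n_cases +
      var(roc_1$v01 - roc_2$v01) / roc_1$n_controls
  } else {
    v <- roc_1$var + roc_2$var
  }
  z <- if (v <= 0) { if (d == 0) 0 else sign(d) * Inf } else d / sqrt(v)
  list(z = z, p_value = 2 * pnorm(-abs(z)), delta_auc = d, var = v,
       paired = paired)
}

#' Label samples into top-decile and middle-20% percentile groups
#'
#' Percentile ranks are average ranks divided by n (population-specific: the
#' caller passes one cohort's scores at a time). `"high"` is a rank fraction
#' strictly above `high[1]`; `"mid"` lies inclusively within `mid`. With 100
#' distinct scores this yields 10 high and 21 mid samples. Grouping is
#' invariant under strictly increasing transforms of the scores.
#'
#' @param standardized_scores numeric scores from one population.
#' @param high upper group boundaries `(lo, hi]` (default `(0.90, 1]`).
#' @param mid middle group boundaries `[lo, hi]` (default `[0.40, 0.60]`).
#' @return factor with levels `high`, `mid`, `other`.
#' @export
percentile_groups <- function(standardized_scores, high = c(0.90, 1.00),
                              mid = c(0.40, 0.60)) {
  n <- length(standardized_scores)
  pr <- rank(standardized_scores, ties.method = "average") / n
  out <- rep("other", n)
  out[pr > high[1] & pr <= high[2]] <- "high"
  out[pr >= mid[1] & pr <= mid[2]] <- "mid"
  if (!any(out == "high") || !any(out == "mid"))
    stopf("degenerate percentile groups (too few distinct scores)")
  factor(out, levels = c("high", "mid", "other"))
}

#' Covariate-adjusted odds ratio for high vs mid percentile groups
#'
#' Logistic regression of case status on the high-vs-mid indicator plus age
#' and principal components, restricted to samples in the two groups.
#' Missing ages are filled with the cohort median before fitting. The OR is
#' `exp` of the indicator coefficient with a 95% Wald CI. With no
#' covariates this equals the 2x2 contingency-table cross-product exactly.
#'
#' @param group_labels factor from [percentile_groups()].
#' @param labels logical case flags.
#' @param age optional numeric ages (median-filled).
#' @param pcs optional matrix of principal components.
#' @param conf_level confidence level.
#' @return an `or_result`: `or`, `ci`, `n_high`, `n_mid`, `covariates`.
#' @export
covariate_adjusted_or <- function(group_labels, labels, age = NULL,
                                  pcs = NULL, conf_level = 0.95) {
  keep <- group_labels %in% c("high", "mid")
  g <- droplevels(factor(group_labels[keep], levels = c("mid", "high")))
  y <- as.logical(labels)[keep]
  tab <- table(g, y)
  if (any(tab == 0))
    stopf("empty cell in the high/mid x case/control table; use exact methods")
  dat <- data.frame(y = y, high = as.integer(g == "high"))
  covars <- character(0)
  if (!is.null(age)) {
    a <- age[keep]
    a[is.na(a)] <- median(a, na.rm = TRUE)
    dat$age <- a
    covars <- c(covars, "age")
  }
  if (!is.null(pcs)) {
    p <- as.matrix(pcs)[keep, , drop = FALSE]
    colnames(p) <- paste0("PC", seq_len(ncol(p)))
    dat <- cbind(dat, p)
    covars <- c(covars, colnames(p))
  }
  fit <- glm(y ~ ., data = dat, family = binomial())
  if (!fit$converged) stopf("logistic model did not converge")
  est <- coef(fit)["high"]
  se <- sqrt(vcov(fit)["high", "high"])
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(or = exp(unname(est)), ci = exp(unname(est) + c(-1, 1) * z * se),
                 log_or = unname(est), se = unname(se),
                 n_high = sum(g == "high"), n_mid = sum(g == "mid"),
                 covariates = covars, conf_level = conf_level),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (%.0f%% CI %.2f-%.2f), high n=%d vs mid n=%d%s\n",
              x$or, 100 * x$conf_level, x$ci[1], x$ci[2], x$n_high, x$n_mid,
              if (length(x$covariates))
                paste0(", adjusted for ", paste(x$covariates, collapse = "+"))
              else ""))
  invisible(x)
}

#' AUC after covariate adjustment
#'
#' Fits `status ~ PRS + age + PCs` by maximum likelihood and computes the
#' AUC of the fitted probabilities; the PRS-only AUC is always reported
#' alongside, since "AUC after correcting for covariates" is ambiguous
#' between the two.
#'
#' @param scores PRS values.
#' @param labels logical case flags.
#' @param age optional ages (median-filled).
#' @param pcs optional PC matrix.
#' @return list: `model_auc` ([roc_auc()] of fitted probabilities),
#'   `prs_auc` (PRS only), `coefficients`.
#' @export
covariate_adjusted_auc <- function(scores, labels, age = NULL, pcs = NULL) {
  y <- as.logical(labels)
  dat <- data.frame(y = y, prs = scores)
  if (!is.null(age)) {
    age[is.na(age)] <- median(age, na.rm = TRUE)
    dat$age <- age
  }
  if (!is.null(pcs)) {
    p <- as.matrix(pcs)
    colnames(p) <- paste0("PC", seq_len(ncol(p)))
    dat <- cbind(dat, p)
  }
  fit <- glm(y ~ ., data = dat, family = binomial())
  if (!fit$converged)
    stopf("logistic model did not converge (separation?)")
  list(model_auc = roc_auc(fit$fitted.values, y),
       prs_auc = roc_auc(scores, y),
       coefficients = coef(fit))
}

#' Build the evaluation report table
#'
#' One row per (score weight column, cohort) for case/control
#' discrimination — AUC with CI and top-decile vs middle-20%
#' covariate-adjusted OR with CI — plus one row per (weight column, cohort,
#' classifier) for case-only aggressiveness discrimination. Failures in a
#' combination are recorded in the row's `note` rather than aborting.
#'
#' @param cohorts named list; each element needs `scores` (data.frame with
#'   `z_<ancestry>` columns), `status` (logical), and optionally `age`,
#'   `pcs`, `stage`, `gleason`.
#' @param ancestries weight columns to evaluate.
#' @param classifiers aggressiveness classifiers to run (subset of
#'   `c("stage", "gleason")`, possibly empty).
#' @return data.frame report (class `evaluation_report`).
#' @export
build_evaluation_report <- function(cohorts, ancestries,
                                    classifiers = character(0)) {
  rows <- list()
  add_row <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (cn in names(cohorts)) {
    ch <- cohorts[[cn]]
    for (a in ancestries) {
      z <- ch$scores[[paste0("z_", a)]]
      if (is.null(z)) {
        add_row(cohort = cn, ancestry = a, outcome = "case_control",
                auc = NA, auc_lo = NA, auc_hi = NA, or = NA, or_lo = NA,
                or_hi = NA, n = NA, note = "missing score column")
        next
      }
      res <- tryCatch({
        rr <- roc_auc(z, ch$status)
        gr <- percentile_groups(z)
        orr <- covariate_adjusted_or(gr, ch$status, age = ch$age, pcs = ch$pcs)
        add_row(cohort = cn, ancestry = a, outcome = "case_control",
                auc = rr$auc, auc_lo = rr$ci[1], auc_hi = rr$ci[2],
                or = orr$or, or_lo = orr$ci[1], or_hi = orr$ci[2],
                n = length(z), note = "")
      }, error = function(e) {
        add_row(cohort = cn, ancestry = a, outcome = "case_control",
                auc = NA, auc_lo = NA, auc_hi = NA, or = NA, or_lo = NA,
                or_hi = NA, n = length(z), note = conditionMessage(e))
      })
      for (cl in classifiers) {
        res <- tryCatch({
          cases <- which(ch$status)
          agg <- classify_aggressive(ch$stage[cases], ch$gleason[cases], cl)
          ok <- !is.na(agg)
          rr <- roc_auc(z[cases][ok], agg[ok])
          zc <- z[cases][ok]
          gr <- percentile_groups(zc)
          orr <- covariate_adjusted_or(gr, agg[ok],
                                       age = if (is.null(ch$age)) NULL else
                                         ch$age[cases][ok],
                                       pcs = if (is.null(ch$pcs)) NULL else
                                         ch$pcs[cases, , drop = FALSE][ok, , drop = FALSE])
          add_row(cohort = cn, ancestry = a,
                  outcome = paste0("aggressive_", cl),
                  auc = rr$auc, auc_lo = rr$ci[1], auc_hi = rr$ci[2],
                  or = orr$or, or_lo = orr$ci[1], or_hi = orr$ci[2],
                  n = sum(ok), note = "")
        }, error = function(e) {
          add_row(cohort = cn, ancestry = a,
                  outcome = paste0("aggressive_", cl),
                  auc = NA, auc_lo = NA, auc_hi = NA, or = NA, or_lo = NA,
                  or_hi = NA, n = NA, note = conditionMessage(e))
        })
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Serialize an evaluation report to TSV and JSON
#'
#' @param report from [build_evaluation_report()].
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @export
write_evaluation_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(report, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(report), json_path, digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
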