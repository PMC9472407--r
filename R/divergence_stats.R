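# Joint site-frequency-spectrum informativeness ("bow-tie") classification
# and binomial test, plus Mann-Whitney comparisons of PRS distributions.

#' Classify variants into bow-tie regions of the joint SFS
#'
#' Per-SNP heritability is maximized at intermediate allele frequencies, so
#' a variant is more informative in whichever population has the larger
#' folded minor allele frequency. Classification uses folded MAF
#' (`min(f, 1 - f)`), making it invariant to risk/other allele orientation.
#'
#' @param f_a,f_b risk-allele frequencies in populations A and B, in
#'   `[0, 1]` (vectorized).
#' @return factor with levels `A_more_informative`, `B_more_informative`,
#'   `tie`.
#' @export
classify_bowtie <- function(f_a, f_b) {
  check_number(f_a, "f_a", 0, 1)
  check_number(f_b, "f_b", 0, 1)
  maf_a <- pmin(f_a, 1 - f_a)
  maf_b <- pmin(f_b, 1 - f_b)
  # folding introduces float noise (1 - 0.7 != 0.3 exactly): tie within eps
  tie <- abs(maf_a - maf_b) < 1e-12
  out <- ifelse(!tie & maf_a > maf_b, "A_more_informative",
                ifelse(!tie & maf_b > maf_a, "B_more_informative", "tie"))
  factor(out, levels = c("A_more_informative", "B_more_informative", "tie"))
}

#' Build a joint frequency table with bow-tie labels
#'
#' @param f_a,f_b per-variant risk-allele frequencies.
#' @param variant_id optional IDs.
#' @return data.frame `variant_id`, `f_a`, `f_b`, `region`.
#' @export
joint_frequency_table <- function(f_a, f_b, variant_id = NULL) {
  region <- classify_bowtie(f_a, f_b)
  data.frame(variant_id = variant_id %||% sprintf("v%d", seq_along(f_a)),
             f_a = f_a, f_b = f_b, region = region,
             stringsAsFactors = FALSE)
}

#' Two-sided binomial bow-tie test
#'
#' Tests whether score variants fall more often into one population's
#' more-informative region than the other's: exact two-sided binomial test
#' of `n_a_more` successes in `n_a_more + n_b_more` trials against a null
#' proportion of 0.5 (two-sidedness by summing all outcome probabilities not
#' exceeding the observed outcome's, which at p0 = 0.5 equals tail
#' doubling). Ties (equal folded MAF) are excluded by default — the
#' conservative conditional test; `tie_policy = "split"` assigns half of the
#' ties to each side (rounded down).
#'
#' @param n_a_more,n_b_more counts of variants in each region.
#' @param tie_policy `"exclude"` (default) or `"split"`.
#' @param n_tie number of tied variants (used by `"split"`).
#' @return list: `p_value`, `n`, `k_a`, `estimate`, `tie_policy`.
#' @export
bowtie_binomial_test <- function(n_a_more, n_b_more,
                                 tie_policy = c("exclude", "split"),
                                 n_tie = 0) {
  tie_policy <- match.arg(tie_policy)
  if (any(c(n_a_more, n_b_more, n_tie) < 0)) stopf("counts must be nonnegative")
  k_a <- n_a_more; k_b <- n_b_more
  if (tie_policy == "split" && n_tie > 0) {
    k_a <- k_a + n_tie %/% 2
    k_b <- k_b + n_tie %/% 2
  }
  n <- k_a + k_b
  if (n == 0) stopf("no variants to test after tie handling")
  bt <- binom.test(k_a, n, p = 0.5, alternative = "two.sided")
  list(p_value = bt$p.value, n = n, k_a = k_a,
       estimate = k_a / n, tie_policy = tie_policy)
}

#' Mann-Whitney U comparison of two score distributions
#'
#' Exact p-value when the combined sample size is at most 20 and there are
#' no ties; otherwise the normal approximation with continuity and tie
#' correction. U is reported for the first sample.
#'
#' @param scores_a,scores_b numeric vectors (nonempty).
#' @param exact_max combined-n switch point for the exact test.
#' @return list: `u`, `p_value`, `exact`.
#' @export
mann_whitney_shift <- function(scores_a, scores_b, exact_max = 20L) {
  if (!length(scores_a) || !length(scores_b)) stopf("both samples must be nonempty")
  if (length(unique(c(scores_a, scores_b))) == 1L) {
    warnf("all values tied across both samples; p = 1")
    return(list(u = length(scores_a) * length(scores_b) / 2, p_value = 1,
                exact = FALSE))
  }
  has_ties <- anyDuplicated(c(scores_a, scores_b)) > 0
  use_exact <- (length(scores_a) + length(scores_b)) <= exact_max && !has_ties
  wt <- suppressWarnings(
    wilcox.test(scores_a, scores_b, exact = use_exact, correct = TRUE))
  list(u = unname(wt$statistic), p_value = wt$p.value, exact = use_exact)
}

#' Per-population medians of standardized scores
#'
#' @param scores numeric vector of (standardized) scores.
#' @param population per-score population labels.
#' @return data.frame `population`, `median`, `rank` (1 = highest median).
#' @export
population_medians <- function(scores, population) {
  if (length(scores) != length(population))
    stopf("scores and population must have equal length")
  groups <- split(scores, population)
  if (any(!lengths(groups))) stopf("empty population group")
  med <- vapply(groups, median, 0.0)
  data.frame(population = names(med), median = unname(med),
             rank = rank(-med, ties.method = "min"),
             stringsAsFactors = FALSE, row.names = NULL)
}
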