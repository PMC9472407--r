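#' Expected AUC of a score under the liability-threshold model
#'
#' Disease is modelled with a latent Gaussian liability `L` with unit
#' variance; an individual is a case when `L` exceeds the threshold
#' `qnorm(1 - prevalence)`. A (standardized) risk score `S` is jointly
#' Gaussian with `L` at correlation `rho`. The AUC of `S` for case/control
#' discrimination is then
#' \deqn{AUC = E[\Phi(\rho (L_1 - L_2) / \sqrt{2 - 2\rho^2})]}
#' over independent truncated liabilities `L_1 | L_1 > t` (a case) and
#' `L_2 | L_2 <= t` (a control). The expectation is evaluated by quadrature
#' on equal-probability grids of the two truncated normals; with
#' `n_grid = 2000` the result is accurate to well under 1e-4.
#'
#' Note that case/control ascertainment does not change this AUC: it is a
#' within-class rank probability, so a 1:1 case/control sample estimates the
#' same quantity as the full population.
#'
#' @param rho correlation between the score and liability, in `[0, 1)`.
#' @param prevalence disease prevalence `K` in `(0, 1)`.
#' @param n_grid quadrature nodes per truncated normal.
#' @return expected AUC in `[0.5, 1)`.
#' @export
liability_auc <- function(rho, prevalence, n_grid = 2000) {
  check_number(rho, "rho", 0, 1, open_upper = TRUE)
  check_number(prevalence, "prevalence", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (rho == 0) return(0.5)
  K <- prevalence
  q <- (seq_len(n_grid) - 0.5) / n_grid
  l_case <- qnorm(1 - K + q * K)      # quantiles of L | L > t
  l_ctrl <- qnorm(q * (1 - K))        # quantiles of L | L <= t
  d <- outer(l_case, l_ctrl, "-")
  mean(pnorm(rho * d / sqrt(2 - 2 * rho^2)))
}

#' Score-liability correlation needed for a target AUC
#'
#' Inverts [liability_auc()] by root finding. Used to engineer synthetic
#' worlds whose true-score AUC equals a stated target.
#'
#' @param target_auc AUC in `(0.5, 1)`.
#' @param prevalence disease prevalence in `(0, 1)`.
#' @return correlation `rho` in `(0, 1)`.
#' @export
liability_rho_for_auc <- function(target_auc, prevalence) {
  check_number(target_auc, "target_auc", 0.5, 1, open_lower = TRUE, open_upper = TRUE)
  uniroot(function(r) liability_auc(r, prevalence) - target_auc,
          c(1e-6, 1 - 1e-6), tol = 1e-9)$root
}
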