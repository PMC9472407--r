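# Synthetic cohort generator: Balding-Nichols drifted allele frequencies,
# Hardy-Weinberg genotypes, liability-threshold disease, tumour
# stage / Gleason labels for cases, missingness, and planted-sweep
# haplotype panels for selection statistics.

FREQ_EPS <- 1e-6  # clamp keeping drifted frequencies off exact 0/1

#' Describe one continental population of a simulated study
#'
#' @param name population label, e.g. `"EUR"`.
#' @param fst Balding-Nichols drift parameter `F` in `[0, 1)` relative to the
#'   shared ancestral population.
#' @param sites named integer vector: per-study-site sample counts.
#' @param case_fraction target fraction of cases per site, in `(0, 1)`.
#' @return a `population_spec` list.
#' @export
population_spec <- function(name, fst, sites, case_fraction = 0.5) {
  if (!is.character(name) || length(name) != 1L) stopf("name must be a string")
  check_number(fst, "fst", 0, 1, open_upper = TRUE)
  if (is.null(names(sites)) || any(!nzchar(names(sites))))
    stopf("sites must be a named vector of sample counts")
  if (any(sites <= 0) || any(sites != round(sites)))
    stopf("site sample counts must be positive integers")
  check_number(case_fraction, "case_fraction", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  structure(list(name = name, fst = fst, sites = as.integer(round(sites)),
                 site_names = names(sites), case_fraction = case_fraction),
            class = "population_spec")
}

#' Genetic architecture of the simulated trait
#'
#' Effects are on the liability scale, per population (columns of
#' `true_log_or`); `prs_liability_variance` is per population as well, so the
#' same causal variants can explain less liability variance in a drifted
#' population.
#'
#' @param ancestral_freqs per-variant ancestral frequencies, strictly in (0,1).
#' @param true_log_or matrix `n_variants x n_populations` of per-population
#'   effects (interpreted as log odds ratios when written to scoring files).
#' @param prevalence disease prevalence `K` in (0,1).
#' @param prs_liability_variance named per-population proportion of liability
#'   variance explained by the scored variants, each in `[0, 1]`.
#' @return a `genetic_architecture` list.
#' @export
genetic_architecture <- function(ancestral_freqs, true_log_or, prevalence,
                                 prs_liability_variance) {
  check_number(ancestral_freqs, "ancestral_freqs", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  true_log_or <- as.matrix(true_log_or)
  if (nrow(true_log_or) != length(ancestral_freqs))
    stopf("true_log_or must have one row per variant")
  if (any(!is.finite(true_log_or))) stopf("true_log_or must be finite")
  check_number(prevalence, "prevalence", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(prs_liability_variance, "prs_liability_variance", 0, 1)
  structure(list(n_variants = length(ancestral_freqs),
                 ancestral_freqs = ancestral_freqs,
                 true_log_or = true_log_or,
                 prevalence = prevalence,
                 prs_liability_variance = prs_liability_variance),
            class = "genetic_architecture")
}

#' Draw drifted population allele frequencies (Balding-Nichols)
#'
#' For ancestral frequency `p` and drift `F > 0`, the population frequency is
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, so `E = p` and
#' `Var = F p (1 - p)`. With `F = 0` frequencies are returned unchanged.
#' Draws are clamped to `[eps, 1 - eps]` (default `1e-6`) so downstream
#' binomial sampling never degenerates.
#'
#' @param ancestral_freqs per-variant ancestral frequencies in (0,1).
#' @param fst drift parameter in `[0, 1)`.
#' @param seed integer seed.
#' @param eps clamp distance from the 0/1 boundary.
#' @return numeric vector of drifted frequencies.
#' @export
draw_population_frequencies <- function(ancestral_freqs, fst, seed,
                                        eps = FREQ_EPS) {
  check_number(ancestral_freqs, "ancestral_freqs", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(fst, "fst", 0, 1, open_upper = TRUE)
  if (fst == 0) return(ancestral_freqs)
  set.seed(seed)
  shape_scale <- (1 - fst) / fst
  f <- stats::rbeta(length(ancestral_freqs),
                    ancestral_freqs * shape_scale,
                    (1 - ancestral_freqs) * shape_scale)
  pmin(pmax(f, eps), 1 - eps)
}

#' Simulate Hardy-Weinberg genotype doses
#'
#' Each dose is an independent `Binomial(2, f)` draw, individuals in rows.
#'
#' @param pop_freqs per-variant allele frequencies in (0,1).
#' @param n_individuals number of individuals (> 0).
#' @param seed integer seed.
#' @return integer matrix `n_individuals x n_variants`.
#' @export
simulate_genotypes <- function(pop_freqs, n_individuals, seed) {
  check_number(pop_freqs, "pop_freqs", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (!is.numeric(n_individuals) || n_individuals <= 0)
    stopf("n_individuals must be positive")
  set.seed(seed)
  m <- length(pop_freqs)
  matrix(rbinom(n_individuals * m, 2L, rep(pop_freqs, each = n_individuals)),
         nrow = n_individuals, ncol = m)
}

#' Simulate case/control status under the liability-threshold model
#'
#' The genetic score `sum(doses %*% effects)` is standardized in-sample and
#' scaled to explain `prs_liability_variance` of the liability; an independent
#' standard-normal residual supplies the remainder. Cases are individuals
#' whose liability exceeds `qnorm(1 - prevalence)`.
#'
#' @param dosages dose matrix, individuals in rows (no missing values).
#' @param architecture a [genetic_architecture()].
#' @param seed integer seed.
#' @param population population name or column index into the effect matrix
#'   and `prs_liability_variance`.
#' @return list with `status` (logical case flag), `liability`,
#'   `genetic` (scaled genetic liability component) and `threshold`.
#' @export
simulate_phenotypes <- function(dosages, architecture, seed, population = 1L) {
  stopifnot(inherits(architecture, "genetic_architecture"))
  b <- architecture$true_log_or[, population]
  v <- architecture$prs_liability_variance[[population]]
  if (all(b == 0) && v > 0)
    stopf("degenerate architecture: all effects zero with prs_liability_variance > 0")
  set.seed(seed)
  n <- nrow(dosages)
  if (v > 0) {
    g_raw <- as.numeric(dosages %*% b)
    g <- sqrt(v) * sample_scale(g_raw)
  } else {
    g <- numeric(n)
  }
  liability <- g + sqrt(1 - v) * rnorm(n)
  threshold <- qnorm(1 - architecture$prevalence)
  list(status = liability > threshold, liability = liability,
       genetic = g, threshold = threshold)
}

#' Default aggressiveness parameters
#'
#' Marginals follow the MADCaP case characteristics: tumour stages
#' T1/T2/T3/T4 at 37.4/44.6/10.2/7.8 percent and Gleason bands <=6 / 7 / >=8
#' at 17.1/43.6/39.2 percent. Stage was recorded for 1002 of 1298 cases and
#' Gleason for 1068 of 1298, giving the default missingness rates.
#'
#' @return list of stage probabilities, Gleason band probabilities,
#'   missingness rates and the liability coupling (0 = independent of risk).
#' @export
aggressiveness_params <- function() {
  # published marginals are rounded (Gleason bands sum to 0.999); renormalize
  list(stage_probs = c(T1 = 0.374, T2 = 0.446, T3 = 0.102, T4 = 0.078),
       gleason_probs = c(le6 = 0.171, g7 = 0.436, ge8 = 0.392) / 0.999,
       stage_missing = 1 - 1002 / 1298,
       gleason_missing = 1 - 1068 / 1298,
       liability_effect = 0)
}

draw_ordered <- function(n, probs, liability, effect) {
  # proportional-odds draw: shift cumulative logits by effect * liability
  cum <- cumsum(probs)[-length(probs)]
  if (effect == 0 || is.null(liability)) {
    cuts <- matrix(rep(cum, each = n), nrow = n)
  } else {
    cuts <- plogis(outer(-effect * liability, qlogis(cum), "+"))
  }
  u <- runif(n)
  1L + rowSums(u > cuts)
}

#' Simulate tumour stage and Gleason score labels for cases
#'
#' Stage (T1-T4) and Gleason score (integer, 4-10 here) are drawn
#' independently of each other from the configured marginals, optionally
#' coupled to the case's latent liability via a proportional-odds shift
#' (`liability_effect > 0` makes high-liability cases more aggressive).
#' Missingness is applied at the configured per-label rates.
#'
#' @param n_cases number of cases.
#' @param params parameter list as from [aggressiveness_params()].
#' @param seed integer seed.
#' @param liability optional per-case liability (used when
#'   `params$liability_effect != 0`).
#' @return data.frame with character `stage` ("T1".."T4") and integer
#'   `gleason`, `NA` where missing.
#' @export
simulate_aggressiveness <- function(n_cases, params = aggressiveness_params(),
                                    seed = 1L, liability = NULL) {
  for (nm in c("stage_probs", "gleason_probs")) {
    p <- params[[nm]]
    if (abs(sum(p) - 1) > 1e-8) stopf("%s must sum to 1", nm)
    if (any(p < 0)) stopf("%s must be nonnegative", nm)
  }
  set.seed(seed)
  eff <- params$liability_effect %||% 0
  stage_idx <- draw_ordered(n_cases, params$stage_probs, liability, eff)
  gleason_band <- draw_ordered(n_cases, params$gleason_probs, liability, eff)
  stage <- paste0("T", stage_idx)
  gleason <- integer(n_cases)
  gleason[gleason_band == 1L] <- sample(4:6, sum(gleason_band == 1L), replace = TRUE)
  gleason[gleason_band == 2L] <- 7L
  gleason[gleason_band == 3L] <- sample(8:10, sum(gleason_band == 3L), replace = TRUE)
  stage[runif(n_cases) < (params$stage_missing %||% 0)] <- NA
  gleason[runif(n_cases) < (params$gleason_missing %||% 0)] <- NA
  data.frame(stage = stage, gleason = gleason, stringsAsFactors = FALSE)
}

#' Set dosage entries missing completely at random
#'
#' @param dosages dose matrix.
#' @param rate per-entry missingness probability in `[0, 1)`; the study-wide
#'   average in the motivating data was 0.67 percent.
#' @param seed integer seed.
#' @return the matrix with missing entries set to `NA`.
#' @export
inject_missingness <- function(dosages, rate = 0.0067, seed = 1L) {
  check_number(rate, "rate", 0, 1, open_upper = TRUE)
  if (rate == 0) return(dosages)
  set.seed(seed)
  miss <- runif(length(dosages)) < rate
  dosages[miss] <- NA
  dosages
}

#' Simulate ages from study-matched age bands
#'
#' Ages are drawn uniformly within three recruitment bands (40-69, 70-79,
#' 80-95 years) with band probabilities matched to the motivating study's
#' case and control marginals; cases skew slightly older. A small fraction
#' (default 2 percent) is set missing, to exercise median-fill handling.
#'
#' @param status logical case flags.
#' @param seed integer seed.
#' @param missing_rate fraction of missing ages.
#' @return numeric ages with `NA` for missing.
#' @export
simulate_ages <- function(status, seed = 1L, missing_rate = 0.02) {
  set.seed(seed)
  n <- length(status)
  band_probs_case <- c(0.245, 0.302, 0.453)
  band_probs_ctrl <- c(0.243, 0.392, 0.365)
  lo <- c(40, 70, 80); hi <- c(69, 79, 95)
  band <- integer(n)
  band[status]  <- sample.int(3L, sum(status), replace = TRUE, prob = band_probs_case)
  band[!status] <- sample.int(3L, sum(!status), replace = TRUE, prob = band_probs_ctrl)
  age <- runif(n, lo[band], hi[band])
  age[runif(n) < missing_rate] <- NA
  age
}

#' Simulate a haplotype panel with an optional planted sweep
#'
#' Neutral sites are independent Bernoulli draws per haplotype at uniform
#' frequencies. With `sweep_strength > 0`, haplotypes carrying the derived
#' allele at the core site copy a shared template over a flanking window
#' whose one-sided length (in sites) is drawn `1 + rexp(sweep_strength)` per
#' carrier, producing the extended shared haplotypes a recent hard sweep
#' leaves behind (elevated EHH/iHS at the core).
#'
#' @param n_haplotypes number of haplotypes (>= 4).
#' @param n_sites number of sites.
#' @param core_index index of the core site.
#' @param sweep_strength mean one-sided shared-segment length in sites; 0 for
#'   neutral.
#' @param seed integer seed.
#' @param core_freq derived-allele frequency at the core.
#' @param positions optional bp positions (default 10 kb spacing).
#' @return a [haplotype_panel()].
#' @export
simulate_sweep_haplotypes <- function(n_haplotypes, n_sites, core_index,
                                      sweep_strength = 0, seed = 1L,
                                      core_freq = 0.5, positions = NULL) {
  if (n_haplotypes < 4) stopf("need at least 4 haplotypes for EHH")
  if (core_index < 1 || core_index > n_sites) stopf("core_index out of range")
  if (sweep_strength < 0) stopf("sweep_strength must be >= 0")
  set.seed(seed)
  freqs <- runif(n_sites, 0.1, 0.9)
  h <- matrix(rbinom(n_haplotypes * n_sites, 1L, rep(freqs, each = n_haplotypes)),
              nrow = n_haplotypes)
  # fix the core-allele split deterministically so both alleles have carriers
  n_derived <- max(2L, min(n_haplotypes - 2L, round(core_freq * n_haplotypes)))
  h[, core_index] <- rep(0L, n_haplotypes)
  derived_rows <- sample.int(n_haplotypes, n_derived)
  h[derived_rows, core_index] <- 1L
  if (sweep_strength > 0) {
    template <- rbinom(n_sites, 1L, freqs)
    for (row in derived_rows) {
      w <- 1 + stats::rexp(1, 1 / sweep_strength)
      span <- seq(max(1L, core_index - as.integer(w)),
                  min(n_sites, core_index + as.integer(w)))
      h[row, span] <- template[span]
      h[row, core_index] <- 1L
    }
  }
  if (is.null(positions)) positions <- seq_len(n_sites) * 10000L
  haplotype_panel(h, positions, core_index)
}

#' Generate proxy haplotypes tagging a causal allele at a target r-squared
#'
#' Each proxy haplotype allele copies the causal allele with probability `r`
#' and is otherwise an independent Bernoulli draw at the same frequency, so
#' the haplotype correlation is `r` and the squared correlation `r^2`
#' (frequency is preserved in expectation).
#'
#' @param causal binary haplotype vector (or matrix, sites in columns).
#' @param r target haplotype correlation in `[0, 1]` (scalar or per column).
#' @param freq allele frequency (scalar or per column) used for redraws.
#' @param seed integer seed.
#' @return binary proxy haplotypes, same shape as `causal`.
#' @export
simulate_proxy_haplotypes <- function(causal, r, freq, seed = 1L) {
  check_number(r, "r", 0, 1)
  set.seed(seed)
  causal <- as.matrix(causal)
  n <- nrow(causal); m <- ncol(causal)
  keep <- matrix(runif(n * m) < rep(r, each = n), n, m)
  redraw <- matrix(rbinom(n * m, 1L, rep(freq, each = n)), n, m)
  out <- ifelse(keep, causal, redraw)
  storage.mode(out) <- "integer"
  out
}
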