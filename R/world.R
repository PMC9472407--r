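# A self-contained two-population study design whose true-score AUCs are
# engineered to stated targets, emulating the structure of a European
# biobank cohort plus a multi-site sub-Saharan African case/control study:
# drifted allele frequencies, ancestry-specific effect sizes, imperfect
# proxy tagging in the non-ascertainment population, and clinical labels
# for cases.

#' Analytic score-liability correlation implied by a tagging design
#'
#' For liability effects `b`, per-variant dose variances `tau = 2 f (1-f)`,
#' haplotype tagging correlations `r` (0 for variants absent from the
#' genotyped set, 1 for direct genotypes) and PRS-explained liability
#' variance `v`, the correlation between the r-squared-weighted PRS
#' (`weights b * r^2`) and the liability is
#' \deqn{\rho = \sqrt{v} \, \frac{\sum b^2 r^3 \tau}
#'   {\sigma_g \sqrt{\sum b^2 r^4 \tau}}, \quad \sigma_g^2 = \sum b^2 \tau.}
#'
#' @param b per-variant liability effects.
#' @param r per-variant haplotype tagging correlation (absolute value).
#' @param tau per-variant dose variance `2 f (1 - f)`.
#' @param v PRS-explained liability variance.
#' @return implied correlation in `[0, 1]`.
#' @export
implied_score_correlation <- function(b, r, tau, v) {
  sg2 <- sum(b^2 * tau)
  num <- sum(b^2 * r^3 * tau)
  den <- sqrt(sg2 * sum(b^2 * r^4 * tau))
  if (den == 0) return(0)
  sqrt(v) * num / den
}

#' Design a calibrated two-population PRS portability world
#'
#' Builds the complete generating design for a synthetic study of PRS
#' transferability: an "ascertainment" population (default `EUR`) where most
#' score variants are directly genotyped, and a drifted population (default
#' `AFR`) where fewer variants are genotyped, proxies tag them at lower
#' r-squared, and effect sizes are attenuated by an across-population genetic
#' correlation. The per-population PRS-explained liability variance is then
#' solved in closed form (via [implied_score_correlation()] and
#' [liability_rho_for_auc()]) so that the expected AUC of the pipeline's PRS
#' equals the stated per-population targets.
#'
#' @param seed integer seed for the design draws.
#' @param n_variants number of score variants.
#' @param target_auc named AUC targets per population.
#' @param prevalence liability-threshold disease prevalence.
#' @param fst named Balding-Nichols drift per population.
#' @param genetic_correlation correlation of per-variant effects across the
#'   two populations.
#' @param direct_fraction named fraction of variants directly genotyped.
#' @param proxy_fraction named fraction tagged by a proxy (the remainder has
#'   no proxy and is dropped by score resolution).
#' @param proxy_r2_range named list of `c(lo, hi)` uniform ranges for proxy
#'   r-squared (lower bound should respect the resolution threshold).
#' @param flip_fraction fraction of proxies whose counted allele tags the
#'   source variant's other allele (`same_direction = FALSE`).
#' @return a `prs_world` list: `architecture`, `pop_specs`, `score`
#'   (a [score_definition()]), `proxy_map`, per-population `tagging`
#'   (`r`, `genotyped_id`, flip flags), calibrated `v` and implied `rho`,
#'   and the genotyped-marker `variant_index`.
#' @export
design_prs_world <- function(seed = 1L,
                             n_variants = 147L,
                             target_auc = c(EUR = 0.70, AFR = 0.58),
                             prevalence = 0.10,
                             fst = c(EUR = 0.05, AFR = 0.10),
                             genetic_correlation = 0.8,
                             direct_fraction = c(EUR = 0.80, AFR = 0.60),
                             proxy_fraction = c(EUR = 0.12, AFR = 0.25),
                             proxy_r2_range = list(EUR = c(0.6, 1), AFR = c(0.4, 1)),
                             flip_fraction = 0.1) {
  pops <- names(target_auc)
  stopifnot(length(pops) == 2L, !is.null(pops))
  set.seed(fanout_seed(seed, "world"))

  # ancestral frequencies; ascertainment keeps pop-1 MAF intermediate
  p_anc <- runif(n_variants, 0.05, 0.95)
  f <- sapply(seq_along(pops), function(k)
    draw_population_frequencies(p_anc, fst[[pops[k]]],
                                fanout_seed(seed, 1L) + k))
  colnames(f) <- pops
  maf1 <- pmin(f[, 1], 1 - f[, 1])
  redo <- maf1 < 0.10  # GWAS-array style ascertainment in population 1
  while (any(redo)) {
    p_anc[redo] <- runif(sum(redo), 0.05, 0.95)
    for (k in seq_along(pops))
      f[redo, k] <- draw_population_frequencies(p_anc[redo], fst[[pops[k]]],
                                                sample.int(2^31 - 2, 1))
    redo <- pmin(f[, 1], 1 - f[, 1]) < 0.10
  }

  # ancestry-specific liability effects with stated genetic correlation
  b1 <- rnorm(n_variants, 0, 0.05)
  b2 <- genetic_correlation * b1 +
    sqrt(1 - genetic_correlation^2) * rnorm(n_variants, 0, 0.05)
  b <- cbind(b1, b2); colnames(b) <- pops

  # tagging design per population
  tagging <- list()
  for (k in seq_along(pops)) {
    pop <- pops[k]
    n_direct <- round(direct_fraction[[pop]] * n_variants)
    n_proxy <- round(proxy_fraction[[pop]] * n_variants)
    cls <- rep("dropped", n_variants)
    ord <- sample.int(n_variants)
    cls[ord[seq_len(n_direct)]] <- "direct"
    cls[ord[n_direct + seq_len(n_proxy)]] <- "proxy"
    r2 <- ifelse(cls == "direct", 1,
                 ifelse(cls == "proxy",
                        runif(n_variants, proxy_r2_range[[pop]][1],
                              proxy_r2_range[[pop]][2]), 0))
    flip <- cls == "proxy" & runif(n_variants) < flip_fraction
    tagging[[pop]] <- list(class = cls, r = sqrt(r2), r2 = r2, flip = flip)
  }

  # calibrate per-population PRS liability variance to the AUC targets
  v <- rho <- setNames(numeric(2), pops)
  for (pop in pops) {
    tau <- 2 * f[, pop] * (1 - f[, pop])
    rt <- liability_rho_for_auc(target_auc[[pop]], prevalence)
    rho1 <- implied_score_correlation(b[, pop], tagging[[pop]]$r, tau, 1)
    v[pop] <- (rt / rho1)^2
    if (v[pop] >= 1)
      stopf("population %s cannot reach AUC %.3f with its tagging design",
            pop, target_auc[[pop]])
    rho[pop] <- rt
  }

  architecture <- genetic_architecture(p_anc, b, prevalence, v)

  source_ids <- sprintf("rs%05d", seq_len(n_variants))
  chrom <- rep(1:22, length.out = n_variants)
  pos <- 100000L + 5000L * seq_len(n_variants)
  score <- score_definition(
    score_name = "synthetic_prs",
    variants = data.frame(variant_id = source_ids, chrom = chrom, pos = pos,
                          effect_allele = "A", other_allele = "G",
                          stringsAsFactors = FALSE),
    weights = setNames(as.data.frame(b), pops))

  # proxy map covering both populations' proxies
  pm <- list()
  for (pop in pops) {
    tg <- tagging[[pop]]
    idx <- which(tg$class == "proxy")
    if (length(idx))
      pm[[pop]] <- data.frame(
        source_id = source_ids[idx],
        proxy_id = sprintf("%s_tag%s", source_ids[idx], pop),
        r2 = tg$r2[idx],
        same_direction = !tg$flip[idx],
        rule = "single", stringsAsFactors = FALSE)
  }
  proxy_map <- do.call(rbind, pm)
  rownames(proxy_map) <- NULL

  # genotyped marker id per variant per population (NA when dropped)
  for (pop in pops) {
    tg <- tagging[[pop]]
    tagging[[pop]]$genotyped_id <- ifelse(
      tg$class == "direct", source_ids,
      ifelse(tg$class == "proxy", sprintf("%s_tag%s", source_ids, pop), NA))
  }

  structure(list(seed = seed, populations = pops, architecture = architecture,
                 pop_freqs = f, score = score, proxy_map = proxy_map,
                 tagging = tagging, v = v, rho = rho,
                 target_auc = target_auc, prevalence = prevalence,
                 source_ids = source_ids, chrom = chrom, pos = pos,
                 pop_specs = list(
                   EURlike = population_spec(pops[1], fst[[pops[1]]],
                                             c(BIOBANK = 5387L), 0.5),
                   AFRlike = population_spec(pops[2], fst[[pops[2]]],
                                             c(HOGGY = 281L, MIL37 = 278L, KBTH = 280L,
                                               UCH = 265L, UATH = 179L, WITS = 1113L,
                                               SU = 235L), 0.49))),
            class = "prs_world")
}

#' Simulate an ascertained case/control cohort from a designed world
#'
#' Draws causal haplotypes at the population's drifted frequencies, forms
#' liabilities under the calibrated architecture, ascertains the requested
#' numbers of cases and controls, and genotypes each individual at the
#' population's genotyped markers (direct variants and proxy tags, with
#' allele flips where the design says so). Missing genotypes, ages, study
#' sites and case-only stage/Gleason labels complete the cohort.
#'
#' @param world a `prs_world` from [design_prs_world()].
#' @param population population name in `world$populations`.
#' @param n_cases,n_controls ascertained sample sizes.
#' @param seed integer seed.
#' @param missing_rate per-entry genotype missingness (default 0.0067).
#' @param aggressiveness_coupling liability coupling for stage/Gleason draws.
#' @return a [cohort_data()] with a `truth` attribute (liabilities, design
#'   parameters, expected AUC).
#' @export
simulate_study_cohort <- function(world, population, n_cases, n_controls,
                                  seed = 1L, missing_rate = 0.0067,
                                  aggressiveness_coupling = 0) {
  stopifnot(inherits(world, "prs_world"))
  pop_idx <- match(population, world$populations)
  if (is.na(pop_idx)) stopf("unknown population '%s'", population)
  f <- world$pop_freqs[, population]
  b <- world$architecture$true_log_or[, population]
  K <- world$prevalence
  tg <- world$tagging[[population]]
  m <- length(f)

  # draw a liability pool large enough to ascertain from
  n_pool <- ceiling(max(n_cases / K, n_controls / (1 - K)) * 1.3) + 200
  set.seed(fanout_seed(seed, "genotypes"))
  h1 <- matrix(rbinom(n_pool * m, 1L, rep(f, each = n_pool)), n_pool, m)
  h2 <- matrix(rbinom(n_pool * m, 1L, rep(f, each = n_pool)), n_pool, m)
  x <- h1 + h2
  phen <- simulate_phenotypes(x, world$architecture,
                              fanout_seed(seed, "phenotypes"), population)
  case_idx <- which(phen$status); ctrl_idx <- which(!phen$status)
  if (length(case_idx) < n_cases || length(ctrl_idx) < n_controls)
    stopf("liability pool too small: got %d cases / %d controls",
          length(case_idx), length(ctrl_idx))
  set.seed(fanout_seed(seed, "downsample"))
  keep <- c(sample(case_idx, n_cases), sample(ctrl_idx, n_controls))
  status <- rep(c(TRUE, FALSE), c(n_cases, n_controls))

  # genotyped markers: direct copies or proxy haplotypes at design r
  genotyped <- which(!is.na(tg$genotyped_id))
  set.seed(fanout_seed(seed, "proxies"))
  doses <- matrix(0L, length(keep), length(genotyped))
  for (j in seq_along(genotyped)) {
    i <- genotyped[j]
    if (tg$class[i] == "direct") {
      doses[, j] <- x[keep, i]
    } else {
      p1 <- simulate_proxy_haplotypes(h1[keep, i], tg$r[i], f[i],
                                      seed = fanout_seed(seed, 100L + i))
      p2 <- simulate_proxy_haplotypes(h2[keep, i], tg$r[i], f[i],
                                      seed = fanout_seed(seed, 100000L + i))
      d <- as.integer(p1 + p2)
      if (tg$flip[i]) d <- 2L - d
      doses[, j] <- d
    }
  }
  doses <- inject_missingness(doses, missing_rate,
                              fanout_seed(seed, "missingness"))

  # metadata: sites proportional to the population spec, ages, clinical labels
  spec <- if (pop_idx == 1L) world$pop_specs[[1]] else world$pop_specs[[2]]
  site <- sample(rep(spec$site_names,
                     ceiling(length(keep) * spec$sites / sum(spec$sites)))[
                       seq_along(keep)])
  age <- simulate_ages(status, fanout_seed(seed, "ages"))
  params <- aggressiveness_params()
  params$liability_effect <- aggressiveness_coupling
  agg <- simulate_aggressiveness(n_cases, params,
                                 fanout_seed(seed, "aggressiveness"),
                                 liability = phen$liability[keep[seq_len(n_cases)]])
  stage <- rep(NA_character_, length(keep)); gleason <- rep(NA_integer_, length(keep))
  stage[seq_len(n_cases)] <- agg$stage
  gleason[seq_len(n_cases)] <- agg$gleason

  ids <- sprintf("%s%06d", population, seq_along(keep))
  variant_index <- data.frame(
    variant_id = tg$genotyped_id[genotyped],
    chrom = world$chrom[genotyped],
    pos = world$pos[genotyped] + ifelse(tg$class[genotyped] == "proxy", 250L, 0L),
    ref = "G", alt = "A", stringsAsFactors = FALSE)

  cohort <- cohort_data(
    dosages = doses,
    variants = variant_index,
    metadata = data.frame(sample = ids, site = site, status = status,
                          age = age, stage = stage, gleason = gleason,
                          ancestry = population, stringsAsFactors = FALSE))
  attr(cohort, "truth") <- list(
    liability = phen$liability[keep], genetic = phen$genetic[keep],
    v = world$v[[population]], rho = world$rho[[population]],
    expected_auc = world$target_auc[[population]], seed = seed)
  cohort
}
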