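# synthetic-data generator: drift model, HWE genotypes, liability
# phenotypes, clinical labels, missingness, sweep haplotypes.

test_that("Balding-Nichols draws have the stated moments and limits", {
  # F = 0: identity
  expect_identical(draw_population_frequencies(c(0.3, 0.7), 0, seed = 1),
                   c(0.3, 0.7))
  # moments: E = p, Var = F p (1 - p), Monte Carlo at n = 1e5, 3 SE
  p <- 0.5; F <- 0.1; n <- 1e5
  f <- draw_population_frequencies(rep(p, n), F, seed = 7)
  v_true <- F * p * (1 - p)
  expect_lt(abs(mean(f) - p), 3 * sqrt(v_true / n))
  # SE of the sample variance of a Beta via 4th moment bound (normal approx)
  expect_lt(abs(var(f) - v_true), 4 * v_true / sqrt(n))
  # F -> 1: U-shaped, mass near the boundaries
  f99 <- draw_population_frequencies(rep(0.5, 1e4), 0.99, seed = 8)
  expect_gt(mean(f99 < 0.05 | f99 > 0.95), 0.85)
  expect_true(all(f99 >= 1e-6 & f99 <= 1 - 1e-6))
  # validation
  expect_error(draw_population_frequencies(c(0, 0.5), 0.1, 1), "ancestral")
  expect_error(draw_population_frequencies(0.5, 1, 1), "fst")
  expect_error(draw_population_frequencies(NaN, 0.1, 1), "finite")
})

test_that("genotype simulation is HWE binomial", {
  expect_error(simulate_genotypes(0.5, 0, 1), "positive")
  # clamped ceiling: nearly all doses 2
  g <- simulate_genotypes(rep(1 - 1e-6, 50), 200, seed = 1)
  expect_gt(mean(g == 2), 0.999)
  # mean dose 2f within 3 SE
  g <- simulate_genotypes(0.5, 1e4, seed = 2)
  expect_lt(abs(mean(g) - 1), 3 * sqrt(0.5 / 1e4))
  # HWE genotype proportions at f = 0.2, chi-square alpha = 0.01
  g <- simulate_genotypes(0.2, 1e4, seed = 3)
  obs <- tabulate(g + 1L, 3L)
  chi <- suppressWarnings(
    chisq.test(obs, p = c(0.64, 0.32, 0.04)))
  expect_gt(chi$p.value, 0.01)
})

test_that("liability phenotypes honour prevalence and explained variance", {
  arch0 <- genetic_architecture(rep(0.5, 3), matrix(0, 3, 1), 0.5, c(P = 0))
  d <- simulate_genotypes(rep(0.5, 3), 4000, 1)
  ph <- simulate_phenotypes(d, arch0, seed = 2)
  # K = 0.5, null effects: about half cases, status independent of doses
  expect_lt(abs(mean(ph$status) - 0.5), 3 * sqrt(0.25 / 4000))
  expect_error(
    simulate_phenotypes(d, genetic_architecture(rep(0.5, 3), matrix(0, 3, 1),
                                                0.5, c(P = 0.2)), 1),
    "degenerate")
  # v = 0 with nonzero effects: dosages carry no signal, AUC near 0.5
  arch <- genetic_architecture(rep(0.5, 3), matrix(1, 3, 1), 0.3, c(P = 0))
  ph0 <- simulate_phenotypes(d, arch, seed = 3)
  s <- as.numeric(d %*% rep(1, 3))
  expect_lt(abs(roc_auc(s, ph0$status)$auc - 0.5), 0.03)
})

test_that("true-score AUC matches the quadrature oracle", {
  # 200 variants, v = 0.3, K = 0.1: simulate 20,000 individuals and compare
  # the genetic score's AUC with the numerical-integration oracle
  m <- 200; v <- 0.3; K <- 0.1; n <- 20000
  f <- runif(m, 0.1, 0.9)  # seeded by the preceding set.seed
  set.seed(11)
  d <- simulate_genotypes(f, n, seed = 11)
  b <- rnorm(m, 0, 1)
  arch <- genetic_architecture(f, cbind(P = b), K, c(P = v))
  ph <- simulate_phenotypes(d, arch, seed = 12)
  auc_hat <- roc_auc(ph$genetic, ph$status)$auc
  auc_oracle <- liability_auc(sqrt(v), K)
  # MC tolerance: AUC SE with ~n*K cases is well under 0.01
  expect_lt(abs(auc_hat - auc_oracle), 0.02)
})

test_that("aggressiveness labels reproduce study marginals", {
  n <- 1e4
  agg <- simulate_aggressiveness(n, seed = 5)
  p <- aggressiveness_params()
  # stage marginals within 3 SE (missingness is independent of category)
  stage_obs <- prop.table(table(factor(agg$stage, paste0("T", 1:4))))
  for (k in 1:4) {
    se <- sqrt(p$stage_probs[k] * (1 - p$stage_probs[k]) / sum(!is.na(agg$stage)))
    expect_lt(abs(stage_obs[k] - p$stage_probs[k]), 3 * se)
  }
  # gleason >= 8 band
  ge8 <- mean(agg$gleason >= 8, na.rm = TRUE)
  expect_lt(abs(ge8 - p$gleason_probs[["ge8"]]),
            3 * sqrt(0.39 * 0.61 / sum(!is.na(agg$gleason))))
  # missingness close to configured rates
  expect_lt(abs(mean(is.na(agg$stage)) - p$stage_missing), 0.02)
  # all mass on T4: every evaluable case aggressive under the stage rule
  p4 <- p; p4$stage_probs <- c(T1 = 0, T2 = 0, T3 = 0, T4 = 1)
  a4 <- simulate_aggressiveness(500, p4, seed = 6)
  cls <- classify_aggressive(a4$stage, a4$gleason, "stage")
  expect_true(all(cls[!is.na(cls)]))
  # invalid probabilities rejected
  pbad <- p; pbad$stage_probs <- c(T1 = 0.5, T2 = 0.5, T3 = 0.5, T4 = 0.5)
  expect_error(simulate_aggressiveness(10, pbad), "sum to 1")
})

test_that("missingness injection hits the stated rate", {
  d <- matrix(1L, 100, 100)
  expect_identical(inject_missingness(d, 0, 1), d)
  expect_error(inject_missingness(d, 1, 1), "rate")
  big <- matrix(1L, 1000, 149)
  out <- inject_missingness(big, 0.0067, seed = 3)
  rate <- mean(rowMeans(is.na(out)))
  expect_lt(abs(rate - 0.0067), 3 * sqrt(0.0067 * (1 - 0.0067) / length(big)))
  half <- inject_missingness(matrix(0L, 100, 100), 0.5, seed = 4)
  expect_lt(abs(sum(is.na(half)) - 5000), 3 * sqrt(1e4 * 0.25))
})

test_that("sweep haplotypes plant an extended-homozygosity signal", {
  expect_error(simulate_sweep_haplotypes(3, 10, 5), "4 haplotypes")
  # neutral: unstandardized core iHS centred at 0 over replicates
  neu <- vapply(1:10, function(s) {
    pan <- simulate_sweep_haplotypes(60, 61, 31, 0, seed = s)
    compute_ihs_unstandardized(pan)$ihs_unstd
  }, 0.0)
  expect_lt(abs(mean(neu)), 0.12)
  # strong sweep: |unstandardized iHS| at the core in the top 5% of the same
  # run's neutral sites, in most replicates
  hits <- vapply(1:6, function(s) {
    pan <- simulate_sweep_haplotypes(80, 101, 51, sweep_strength = 15,
                                     seed = 100 + s)
    scan <- suppressMessages(ihs_scan(pan))
    core <- scan$ihs_unstd[scan$site == 51]
    neutral <- scan$ihs_unstd[scan$site != 51 & scan$reliable]
    length(core) == 1 && mean(abs(neutral) <= abs(core)) >= 0.95
  }, NA)
  expect_gte(mean(hits), 5 / 6)
  # identical haplotypes: EHH exactly 1 everywhere
  h <- matrix(rep(c(1L, 0L, 1L, 0L, 1L), each = 6), nrow = 6)
  pan <- haplotype_panel(h, (1:5) * 100, 3L)
  expect_true(all(compute_ehh(pan, 1)$ehh == 1))
})

test_that("proxy haplotypes hit their target r-squared", {
  set.seed(1)
  f <- 0.4; r <- 0.8; n <- 2e4
  causal <- rbinom(n, 1L, f)
  proxy <- simulate_proxy_haplotypes(causal, r, f, seed = 2)
  expect_lt(abs(cor(causal, proxy) - r), 0.02)
  expect_lt(abs(mean(proxy) - f), 0.02)
})

test_that("generators are fully reproducible under a fixed seed", {
  w <- shared_world()
  a <- simulate_study_cohort(w, "EUR", 50, 50, seed = 31)
  b <- simulate_study_cohort(w, "EUR", 50, 50, seed = 31)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$metadata, b$metadata)
  expect_identical(attr(a, "truth")$liability, attr(b, "truth")$liability)
  # different stage seeds differ
  expect_false(identical(fanout_seed(1, "freqs"), fanout_seed(1, "genotypes")))
  expect_identical(fanout_seed(1, "freqs"), fanout_seed(1, 1L))
})

test_that("cohort metadata honours its invariants", {
  w <- shared_world()
  ch <- simulate_study_cohort(w, "AFR", 80, 80, seed = 13)
  md <- ch$metadata
  expect_true(all(is.na(md$stage[!md$status])))
  expect_true(all(is.na(md$gleason[!md$status])))
  expect_true(all(ch$dosages[!is.na(ch$dosages)] %in% 0:2))
  expect_true(all(md$age >= 40 & md$age <= 95, na.rm = TRUE))
  expect_setequal(unique(md$site), w$pop_specs[[2]]$site_names)
})
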