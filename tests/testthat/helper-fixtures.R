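# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; extdata holds only the packaged score-file
# fixtures.

extdata <- function(...) {
  system.file("extdata", ..., package = "prsport", mustWork = TRUE)
}

# small cohort with known structure, used across io/engine/structure tests
make_tiny_cohort <- function(n = 12L, m = 5L, seed = 42L, miss = 0) {
  set.seed(seed)
  doses <- matrix(rbinom(n * m, 2L, 0.4), n, m)
  if (miss > 0) doses[runif(n * m) < miss] <- NA
  cohort_data(
    doses,
    data.frame(variant_id = sprintf("v%02d", seq_len(m)),
               chrom = seq_len(m), pos = 1000L * seq_len(m),
               ref = "G", alt = "A", stringsAsFactors = FALSE),
    data.frame(sample = sprintf("s%02d", seq_len(n)),
               site = rep(c("siteA", "siteB"), length.out = n),
               status = rep(c(TRUE, FALSE), length.out = n),
               age = 60 + seq_len(n),
               stage = ifelse(rep(c(TRUE, FALSE), length.out = n), "T2", NA),
               gleason = ifelse(rep(c(TRUE, FALSE), length.out = n), 7L, NA),
               stringsAsFactors = FALSE))
}

# a minimal two-ancestry score over the tiny cohort's variants
make_tiny_score <- function(m = 5L) {
  score_definition(
    "tiny",
    data.frame(variant_id = sprintf("v%02d", seq_len(m)),
               chrom = seq_len(m), pos = 1000L * seq_len(m),
               effect_allele = "A", other_allele = "G",
               stringsAsFactors = FALSE),
    data.frame(EUR = seq_len(m) / 10, AFR = rev(seq_len(m)) / 10))
}

# exact two-sided binomial p at p0 = 0.5 by direct probability enumeration
enum_binom_p <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1L] + 1e-12])
}

# exact two-sided Mann-Whitney p by enumerating all assignments (no ties)
enum_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_stat(a, b)
  mu <- na * length(b) / 2
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# one small designed world shared by slow-ish tests (cached per session)
shared_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- design_prs_world(seed = 20240902L)
    w
  }
})
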