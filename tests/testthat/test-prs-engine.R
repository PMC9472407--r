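# score resolution, weight adjustment, imputation, scoring,
# standardization.

test_that("adjust_weight is ln(OR) scaled by r-squared", {
  expect_equal(adjust_weight(2, 1), log(2), tolerance = 1e-12)
  expect_identical(adjust_weight(1, 0.7), 0)
  expect_equal(adjust_weight(1.5, 0.5), log(1.5) * 0.5, tolerance = 1e-12)
  expect_equal(adjust_weight(1.5, 0.5), 0.2027326, tolerance = 1e-6)
  expect_error(adjust_weight(0, 1), "positive")
  expect_error(adjust_weight(2, 1.2), "r_squared")
})

test_that("resolution prefers direct genotypes and thresholded proxies", {
  score <- make_tiny_score()
  # all direct
  res <- resolve_variants(score, sprintf("v%02d", 1:5))
  expect_true(all(res$table$status == "used"))
  expect_true(all(res$table$r_squared == 1))
  expect_equal(res$weights[, "EUR"], score$weights$EUR,
               ignore_attr = TRUE, tolerance = 1e-12)
  # proxy below threshold -> dropped with reason
  pm <- data.frame(source_id = "v01", proxy_id = "p1", r2 = 0.3,
                   same_direction = TRUE, rule = "single")
  res <- resolve_variants(score, c("p1", sprintf("v%02d", 2:5)), pm)
  row <- res$table[res$table$source_id == "v01", ]
  expect_identical(row$status, "dropped")
  expect_match(row$reason, "lacked proxies")
  # proxy above threshold used with adjusted weight
  pm$r2 <- 0.8
  res <- resolve_variants(score, c("p1", sprintf("v%02d", 2:5)), pm)
  row <- res$table[res$table$source_id == "v01", ]
  expect_identical(row$used_id, "p1")
  expect_equal(res$weights["p1", "EUR"], 0.1 * 0.8, tolerance = 1e-12)
  # opposite-direction proxy gets a negated weight
  pm$same_direction <- FALSE
  res <- resolve_variants(score, c("p1", sprintf("v%02d", 2:5)), pm)
  expect_equal(res$weights["p1", "EUR"], -0.1 * 0.8, tolerance = 1e-12)
})

test_that("proxy ties break by distance then ID, and shared mode intersects", {
  score <- make_tiny_score(1)
  pm <- data.frame(source_id = "v01", proxy_id = c("pFar", "pNear"),
                   r2 = 0.9, same_direction = TRUE, rule = "single")
  pos <- c(v01 = 1000, pNear = 1200, pFar = 9000)
  res <- resolve_variants(score, c("pFar", "pNear"), pm, positions = pos)
  expect_identical(res$table$used_id, "pNear")
  # no positions: lexicographic
  res <- resolve_variants(score, c("pFar", "pNear"), pm)
  expect_identical(res$table$used_id, "pFar")
  # shared mode: proxy genotyped here but not in the other dataset
  expect_warning(
    res <- resolve_variants(score, c("pFar", "pNear"), pm, mode = "shared",
                            genotyped_ids_other = "somethingElse"),
    "not genotyped")
  expect_identical(res$table$status, "dropped")
})

test_that("packaged fixtures reproduce the published marker counts", {
  # 147-variant score with a dictionary-absent indel resolves to 146 markers
  sch <- read_score_file(extdata("schumacher_like_score.tsv"))
  dict <- readLines(extdata("schumacher_dictionary.txt"))
  res <- resolve_variants(sch, genotyped_ids = sch$variants$variant_id,
                          variant_dictionary = dict)
  expect_identical(res$n_markers, 146L)
  expect_identical(res$table$reason[res$table$status == "dropped"], "unmatched")
  # 269-variant score with one two-marker expansion resolves to 270 markers
  conti <- read_score_file(extdata("conti_like_score.tsv"))
  pm <- read_proxy_map(extdata("conti_proxy_map.tsv"))
  ew <- read.table(extdata("conti_expansion_weights.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  genotyped <- c(setdiff(conti$variants$variant_id, "rsC00042"),
                 "rsPAIR001", "rsPAIR002")
  res <- resolve_variants(conti, genotyped, pm,
                          expansion_weights = list(rsC00042 = ew))
  expect_identical(res$n_markers, 270L)
  expect_identical(sum(res$table$status == "expanded"), 2L)
  expect_equal(res$weights["rsPAIR001", "African"],
               ew$African[ew$marker_id == "rsPAIR001"], tolerance = 1e-12)
})

test_that("missing doses are filled with per-site means", {
  d <- matrix(c(0, 1, 2, NA), 4, 1)
  imp <- impute_missing_doses(d, rep("s1", 4))
  expect_equal(imp$dosages[4, 1], 1.0)
  expect_equal(imp$fill_counts, c(0, 0, 0, 1))
  # site mean, not pooled: A = [0, NA], B = [2, 2] -> fill 0
  d <- matrix(c(0, NA, 2, 2), 4, 1)
  imp <- impute_missing_doses(d, c("A", "A", "B", "B"))
  expect_equal(imp$dosages[2, 1], 0.0)
  # site with no data falls back to the cohort-wide mean
  d <- matrix(c(NA, NA, 2, 1), 4, 1)
  imp <- impute_missing_doses(d, c("A", "A", "B", "B"))
  expect_equal(imp$dosages[1, 1], 1.5)
  # complete matrix unchanged
  d <- matrix(0:3 %% 3, 4, 2)
  imp <- impute_missing_doses(d, rep("x", 4))
  expect_equal(imp$dosages, d, ignore_attr = TRUE)
  expect_true(all(imp$fill_counts == 0))
  # variant with no data anywhere is flagged
  d <- matrix(c(NA, NA, 1, 2), 2, 2)
  expect_warning(imp <- impute_missing_doses(d, c("A", "B")), "excluded")
  expect_identical(imp$excluded_variants, 1L)
})

test_that("raw PRS is the weighted dose sum; standardization is exact", {
  d <- matrix(c(2, 1), 1, 2, dimnames = list("s", c("a", "b")))
  res <- structure(list(
    table = NULL, ancestries = "X",
    weights = matrix(c(0.5, -0.2), 2, 1, dimnames = list(c("a", "b"), "X"))),
    class = "resolved_score")
  expect_equal(compute_raw_prs(d, res, "X"), 0.8, tolerance = 1e-12)
  expect_error(compute_raw_prs(d, res, "nope"), "available: X")
  # all-zero weights give all-zero scores
  res$weights[] <- 0
  expect_equal(compute_raw_prs(d, res, "X"), 0)
  # 3x3 brute-force oracle
  set.seed(9)
  dd <- matrix(rbinom(9, 2, 0.5), 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  w <- rnorm(3)
  res3 <- structure(list(ancestries = "X",
                         weights = matrix(w, 3, 1,
                                          dimnames = list(c("a", "b", "c"), "X"))),
                    class = "resolved_score")
  brute <- sapply(1:3, function(i) sum(dd[i, ] * w))
  expect_equal(compute_raw_prs(dd, res3, "X"), brute, tolerance = 1e-12)
  # standardization
  expect_equal(standardize_scores(c(1, 2, 3)), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(standardize_scores(c(1, 2, 3) + 100), c(-1, 0, 1),
               tolerance = 1e-12)
  z <- standardize_scores(rnorm(50))
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_error(standardize_scores(rep(2, 5)), "variance")
  expect_error(standardize_scores(3), "at least 2")
})

test_that("scoring is permutation-invariant and monotone", {
  ch <- make_tiny_cohort(n = 20, m = 6, miss = 0.1)
  score <- make_tiny_score(6)
  sc <- score_cohort(ch, score)
  # permute samples
  perm <- sample(20)
  ch_p <- cohort_data(ch$dosages[perm, ], ch$variants, ch$metadata[perm, ])
  sc_p <- score_cohort(ch_p, score)
  expect_equal(sc_p$scores$raw_EUR[order(perm)], sc$scores$raw_EUR,
               tolerance = 1e-12)
  # permute variants
  vperm <- c(3, 1, 6, 2, 5, 4)
  ch_v <- cohort_data(ch$dosages[, vperm], ch$variants[vperm, ], ch$metadata)
  score_v <- score_definition("tiny", score$variants[vperm, ],
                              score$weights[vperm, ])
  sc_v <- score_cohort(ch_v, score_v)
  expect_equal(sc_v$scores$raw_EUR, sc$scores$raw_EUR, tolerance = 1e-12)
  # monotonicity: raising a dose at a positive-weight variant never lowers PRS
  d2 <- ch$dosages
  j <- which(score$weights$EUR > 0)[1]
  i <- which(!is.na(d2[, j]) & d2[, j] < 2)[1]
  d2[i, j] <- d2[i, j] + 1L
  ch2 <- cohort_data(d2, ch$variants, ch$metadata)
  sc2 <- score_cohort(ch2, score)
  expect_gte(sc2$scores$raw_EUR[i], sc$scores$raw_EUR[i])
})

test_that("mean-fill imputation is neutral for complete samples", {
  ch <- make_tiny_cohort(n = 10, m = 4)
  score <- make_tiny_score(4)
  base <- score_cohort(ch, score)$scores$raw_EUR
  # blank one dose, rescore: only that sample's score changes, to the value
  # obtained by plugging in the site mean
  d <- ch$dosages
  d[3, 2] <- NA
  chm <- cohort_data(d, ch$variants, ch$metadata)
  site3 <- ch$metadata$site[3]
  site_mean <- mean(ch$dosages[ch$metadata$site == site3 &
                                 seq_len(10) != 3, 2])
  manual <- ch$dosages + 0
  manual[3, 2] <- site_mean
  expected <- as.numeric(manual %*% as.matrix(score$weights$EUR))
  got <- score_cohort(chm, score)$scores$raw_EUR
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got[-3], base[-3], tolerance = 1e-12)
})

test_that("r-squared-1 proxies reproduce direct scoring exactly", {
  ch <- make_tiny_cohort(n = 8, m = 3)
  score <- make_tiny_score(3)
  direct <- score_cohort(ch, score)$scores$raw_EUR
  # rename the genotyped markers and route every variant through an r2=1 proxy
  ch2 <- ch
  ch2$variants$variant_id <- paste0("proxy_", ch$variants$variant_id)
  colnames(ch2$dosages) <- ch2$variants$variant_id
  pm <- data.frame(source_id = score$variants$variant_id,
                   proxy_id = ch2$variants$variant_id,
                   r2 = 1, same_direction = TRUE, rule = "single")
  via_proxy <- score_cohort(ch2, score, proxy_map = pm)$scores$raw_EUR
  expect_equal(via_proxy, direct, tolerance = 1e-12)
})
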