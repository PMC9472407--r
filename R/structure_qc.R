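# Sample QC (missingness, PCA outliers), genotype PCA for covariates,
# classical MDS on allele-sharing distances, and case:control ratio-matched
# downsampling.

#' Flag samples by genotype missingness
#'
#' A sample is excluded when its fraction of missing doses strictly exceeds
#' `max_rate` ("exceeded" is strict, so a sample at exactly the threshold is
#' kept).
#'
#' @param dosages matrix individuals x variants with `NA` for missing.
#' @param max_rate maximum tolerated missingness, in (0,1); default 0.05.
#' @return data.frame `sample` (row index or name), `missing_rate`,
#'   `included`.
#' @export
filter_sample_missingness <- function(dosages, max_rate = 0.05) {
  check_number(max_rate, "max_rate", 0, 1, open_lower = TRUE, open_upper = TRUE)
  rate <- rowMeans(is.na(dosages))
  data.frame(sample = rownames(dosages) %||% seq_len(nrow(dosages)),
             missing_rate = rate, included = rate <= max_rate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genotype principal components
#'
#' Doses are centered at `2 f` and scaled by `sqrt(2 f (1 - f))` (the
#' standard genotype-PCA normalization), monomorphic variants are dropped,
#' and PCs are taken from the SVD of the normalized matrix. Sign convention:
#' each PC's largest-magnitude variant loading is made positive, so results
#' are deterministic and permutation-equivariant.
#'
#' @param dosages complete dose matrix (individuals x variants).
#' @param k number of components (default 10).
#' @return list: `scores` (n x k), `eigenvalues` (of the sample
#'   covariance), `loadings`, `k`.
#' @export
genotype_pca <- function(dosages, k = 10L) {
  if (any(is.na(dosages))) stopf("dosage matrix must be complete (impute first)")
  n <- nrow(dosages)
  if (n < 2L) stopf("need at least 2 samples")
  f <- colMeans(dosages) / 2
  poly <- f > 0 & f < 1
  x <- sweep(dosages[, poly, drop = FALSE], 2, 2 * f[poly])
  x <- sweep(x, 2, sqrt(2 * f[poly] * (1 - f[poly])), "/")
  k_eff <- as.integer(min(k, n - 1L, ncol(x)))
  if (k_eff < k) warnf("rank limits PCA to %d component(s)", k_eff)
  sv <- svd(x, nu = k_eff, nv = k_eff)
  flip <- vapply(seq_len(k_eff), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0.0)
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k_eff)], k_eff), 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(k_eff))
  rownames(scores) <- rownames(dosages)
  list(scores = scores, eigenvalues = sv$d^2 / (n - 1),
       loadings = sweep(sv$v, 2, flip, "*"), k = k_eff)
}

#' Flag PCA outliers on the first two components
#'
#' A sample is excluded when it lies more than `sd_limit` standard
#' deviations from the mean on PC1 or PC2.
#'
#' @param pc_coords matrix with at least two PC columns.
#' @param sd_limit default 2.
#' @return logical inclusion flags.
#' @export
pca_outlier_filter <- function(pc_coords, sd_limit = 2) {
  pc_coords <- as.matrix(pc_coords)
  if (ncol(pc_coords) < 2L) stopf("need at least two PC columns")
  ok <- rep(TRUE, nrow(pc_coords))
  for (j in 1:2) {
    v <- pc_coords[, j]
    s <- sd(v)
    if (s == 0) next  # all identical: zero deviation, all included
    ok <- ok & abs(v - mean(v)) <= sd_limit * s
  }
  ok
}

#' Allele-sharing distance matrix (1 - IBS)
#'
#' Identity-by-state proportion between two samples is
#' `1 - |d_i - d_j| / 2` averaged over variants complete in both; the
#' returned distance is one minus that. Computed via a Manhattan distance,
#' with missing-pair rescaling as in [stats::dist()].
#'
#' @param dosages dose matrix (individuals x variants), `NA` allowed.
#' @return symmetric distance matrix with zero diagonal.
#' @export
ibs_distance <- function(dosages) {
  d <- as.matrix(dist(dosages, method = "manhattan")) / (2 * ncol(dosages))
  diag(d) <- 0
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and embeds on the top
#' eigenvectors (via [stats::cmdscale()]); the same largest-magnitude sign
#' convention as [genotype_pca()] makes axes deterministic.
#'
#' @param distance_matrix symmetric matrix with zero diagonal.
#' @param dims embedding dimension (default 2).
#' @return list: `coords` (n x dims), `eigenvalues`.
#' @export
classical_mds <- function(distance_matrix, dims = 2L) {
  distance_matrix <- as.matrix(distance_matrix)
  if (!isSymmetric(unname(distance_matrix), tol = 1e-8))
    stopf("distance matrix must be symmetric")
  if (any(abs(diag(distance_matrix)) > 1e-12))
    stopf("distance matrix must have zero diagonal")
  fit <- suppressWarnings(cmdscale(distance_matrix, k = dims, eig = TRUE))
  coords <- fit$points
  if (ncol(coords) < dims) {  # degenerate geometry: pad zero columns
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  }
  for (j in seq_len(ncol(coords))) {
    v <- coords[, j]
    if (length(v) && v[which.max(abs(v))] < 0) coords[, j] <- -v
  }
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  list(coords = coords, eigenvalues = fit$eig)
}

#' Downsample to a target case:control ratio
#'
#' Keeps as many samples as possible while matching `target_ratio`
#' (cases : controls): whichever class is in excess relative to the target
#' is randomly downsampled (seeded).
#'
#' @param metadata data.frame with logical `status`.
#' @param target_ratio cases per control (e.g. `1` for 1:1, or
#'   `1298 / 1333`).
#' @param seed integer seed.
#' @param tolerance allowed relative deviation of the achieved ratio.
#' @return integer row indices of the retained subset.
#' @export
ratio_matched_downsample <- function(metadata, target_ratio, seed,
                                     tolerance = 0.01) {
  check_number(target_ratio, "target_ratio", 0, Inf, open_lower = TRUE)
  cases <- which(metadata$status); ctrls <- which(!metadata$status)
  n_case <- length(cases); n_ctrl <- length(ctrls)
  if (!n_case || !n_ctrl) stopf("need both cases and controls")
  set.seed(seed)
  if (n_case / n_ctrl > target_ratio) {
    keep_case <- round(n_ctrl * target_ratio)
    if (keep_case < 1) stopf("unattainable ratio: max achievable %.4g with >=1 case",
                             1 / n_ctrl)
    cases <- sort(sample(cases, keep_case))
  } else {
    keep_ctrl <- round(n_case / target_ratio)
    if (keep_ctrl < 1) stopf("unattainable ratio: min achievable %.4g with >=1 control",
                             n_case)
    ctrls <- sort(sample(ctrls, keep_ctrl))
  }
  achieved <- length(cases) / length(ctrls)
  if (abs(achieved / target_ratio - 1) > tolerance)
    warnf("achieved ratio %.4g deviates from target %.4g by more than %.2g",
          achieved, target_ratio, tolerance)
  sort(c(cases, ctrls))
}
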