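# Score resolution against a genotyped marker set, r-squared weight
# adjustment, per-site mean imputation, and PRS computation/standardization.

#' Adjust a published effect size for proxy tagging quality
#'
#' The per-locus weight is `beta = ln(OR) * r^2`: directly genotyped
#' variants keep their full log odds ratio (`r^2 = 1`), proxies are shrunk
#' by how well they tag the score variant.
#'
#' @param odds_ratio odds ratio (> 0), vectorized.
#' @param r_squared squared correlation between proxy and score variant,
#'   in `[0, 1]`.
#' @return adjusted weight `ln(OR) * r^2`.
#' @export
adjust_weight <- function(odds_ratio, r_squared) {
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0))
    stopf("odds_ratio must be positive")
  check_number(r_squared, "r_squared", 0, 1)
  log(odds_ratio) * r_squared
}

#' Resolve score variants against a genotyped marker set
#'
#' Every score variant ends up in exactly one of four states:
#' \describe{
#'   \item{used (direct)}{genotyped under its own ID; `r2 = 1`.}
#'   \item{used (proxy)}{best genotyped proxy with `r2 >= r2_threshold`;
#'     ties broken by smaller genomic distance then lexicographic ID.}
#'   \item{expanded}{replaced by the markers of a `two_marker` proxy-map
#'     rule (each with caller-supplied weights), growing the marker count.}
#'   \item{dropped}{absent from the variant dictionary, no proxy at
#'     threshold, or proxy not genotyped.}
#' }
#' Proxies whose counted allele tags the score variant's other allele
#' (`same_direction = FALSE`) get negated weights; the constant offset this
#' induces is absorbed by score standardization.
#'
#' @param score a [score_definition()].
#' @param genotyped_ids IDs genotyped in the target dataset.
#' @param proxy_map optional data.frame from [read_proxy_map()].
#' @param r2_threshold minimum proxy r-squared (default 0.4; proxies below
#'   it are treated as absent).
#' @param variant_dictionary optional vector of known variant IDs (dbSNP
#'   stand-in); score variants outside it are dropped as `unmatched`.
#' @param expansion_weights named list: for each `two_marker` source, a
#'   data.frame `marker_id` + one log-OR column per ancestry.
#' @param mode `"optimal"` resolves against this dataset only; `"shared"`
#'   restricts usable markers to the intersection with
#'   `genotyped_ids_other`.
#' @param genotyped_ids_other marker IDs of the other dataset (for
#'   `mode = "shared"`).
#' @param positions optional named bp positions used for distance
#'   tie-breaks.
#' @return a `resolved_score`: `table` (source_id, used_id, r_squared,
#'   status, reason, same_direction), `weights` (used marker x ancestry
#'   adjusted weights), `n_markers`.
#' @export
resolve_variants <- function(score, genotyped_ids, proxy_map = NULL,
                             r2_threshold = 0.4, variant_dictionary = NULL,
                             expansion_weights = NULL,
                             mode = c("optimal", "shared"),
                             genotyped_ids_other = NULL, positions = NULL) {
  mode <- match.arg(mode)
  check_number(r2_threshold, "r2_threshold", 0, 1, open_lower = TRUE)
  usable <- genotyped_ids
  if (mode == "shared") {
    if (is.null(genotyped_ids_other))
      stopf("mode 'shared' needs genotyped_ids_other")
    usable <- intersect(genotyped_ids, genotyped_ids_other)
  }
  src <- score$variants$variant_id
  anc <- score$ancestries
  rows <- list(); weights <- list()
  for (i in seq_along(src)) {
    sid <- src[i]
    w_full <- as.numeric(score$weights[i, ])
    if (!is.null(variant_dictionary) && !sid %in% variant_dictionary) {
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = sid, used_id = NA, r_squared = NA_real_,
        status = "dropped", reason = "unmatched", same_direction = NA)
      next
    }
    pm_i <- if (is.null(proxy_map)) NULL else
      proxy_map[proxy_map$source_id == sid, , drop = FALSE]
    two <- if (is.null(pm_i)) NULL else pm_i[pm_i$rule == "two_marker", , drop = FALSE]
    if (!is.null(two) && nrow(two)) {
      markers <- strsplit(two$proxy_id[1], ",")[[1]]
      ew <- expansion_weights[[sid]]
      if (is.null(ew))
        stopf("two-marker rule for %s needs expansion_weights", sid)
      for (mk in markers) {
        wk <- as.numeric(ew[ew$marker_id == mk, anc])
        genotyped <- mk %in% usable
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = sid, used_id = mk, r_squared = 1,
          status = if (genotyped) "expanded" else "dropped",
          reason = if (genotyped) "two_marker" else "expansion marker not genotyped",
          same_direction = TRUE)
        if (genotyped) weights[[mk]] <- wk
      }
      next
    }
    if (sid %in% usable) {
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = sid, used_id = sid, r_squared = 1, status = "used",
        reason = "direct", same_direction = TRUE)
      weights[[sid]] <- w_full
      next
    }
    # proxy route
    cand <- if (is.null(pm_i)) pm_i else
      pm_i[pm_i$rule == "single" & pm_i$r2 >= r2_threshold &
             pm_i$proxy_id %in% usable, , drop = FALSE]
    not_genotyped <- !is.null(pm_i) && nrow(pm_i) > 0 &&
      (is.null(cand) || nrow(cand) == 0) &&
      any(pm_i$r2 >= r2_threshold & !pm_i$proxy_id %in% usable)
    if (!is.null(cand) && nrow(cand)) {
      best_r2 <- max(cand$r2)
      cand <- cand[cand$r2 == best_r2, , drop = FALSE]
      if (nrow(cand) > 1L && !is.null(positions)) {
        dist <- abs(positions[cand$proxy_id] - positions[sid])
        dist[is.na(dist)] <- Inf
        cand <- cand[order(dist, cand$proxy_id), , drop = FALSE]
      } else {
        cand <- cand[order(cand$proxy_id), , drop = FALSE]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = sid, used_id = cand$proxy_id[1], r_squared = cand$r2[1],
        status = "used", reason = "proxy",
        same_direction = cand$same_direction[1])
      sgn <- if (isFALSE(cand$same_direction[1])) -1 else 1
      weights[[cand$proxy_id[1]]] <- sgn * w_full * cand$r2[1]
      next
    }
    reason <- if (not_genotyped) "proxy not genotyped"
      else "lacked proxies (r2 < threshold)"
    if (not_genotyped)
      warnf("score variant %s: proxy exists but is not genotyped", sid)
    rows[[length(rows) + 1L]] <- data.frame(
      source_id = sid, used_id = NA, r_squared = NA_real_,
      status = "dropped", reason = reason, same_direction = NA)
  }
  table <- do.call(rbind, rows)
  wm <- do.call(rbind, weights)
  if (!is.null(wm)) colnames(wm) <- anc
  n_markers <- sum(table$status %in% c("used", "expanded")) +
    sum(table$status == "dropped" &
          table$reason %in% c("lacked proxies (r2 < threshold)",
                              "proxy not genotyped",
                              "expansion marker not genotyped"))
  structure(list(table = table, weights = wm, ancestries = anc,
                 n_markers = n_markers, r2_threshold = r2_threshold,
                 mode = mode, score_name = score$score_name),
            class = "resolved_score")
}

#' @export
print.resolved_score <- function(x, ...) {
  cat(sprintf("<resolved_score> %s: %d markers (%d used, %d dropped), mode=%s\n",
              x$score_name, x$n_markers,
              sum(x$table$status %in% c("used", "expanded")),
              sum(x$table$status == "dropped"), x$mode))
  invisible(x)
}

#' Fill missing doses with per-site mean counts
#'
#' Each missing dose is replaced by the mean dose of non-missing samples at
#' that variant within the same study site; when a site has no data for a
#' variant, the cohort-wide mean is used. Variants missing everywhere are
#' flagged for exclusion.
#'
#' @param dosages matrix individuals x variants with `NA` for missing.
#' @param site_labels per-sample site labels.
#' @return list: `dosages` (complete), `fill_counts` per sample,
#'   `excluded_variants` (column indices with no data anywhere).
#' @export
impute_missing_doses <- function(dosages, site_labels) {
  if (length(site_labels) != nrow(dosages))
    stopf("site_labels must match dosage rows")
  fill_counts <- rowSums(is.na(dosages))
  excluded <- which(colSums(!is.na(dosages)) == 0L)
  if (length(excluded))
    warnf("%d variant(s) missing in every sample; excluded from scoring",
          length(excluded))
  out <- dosages
  storage.mode(out) <- "double"
  global_mean <- colMeans(dosages, na.rm = TRUE)
  for (s in unique(site_labels)) {
    idx <- which(site_labels == s)
    block <- dosages[idx, , drop = FALSE]
    na_block <- is.na(block)
    if (!any(na_block)) next
    site_mean <- colMeans(block, na.rm = TRUE)
    site_mean[is.nan(site_mean)] <- global_mean[is.nan(site_mean)]
    fill <- matrix(rep(site_mean, each = length(idx)), nrow = length(idx))
    block[na_block] <- fill[na_block]
    out[idx, ] <- block
  }
  list(dosages = out, fill_counts = fill_counts,
       excluded_variants = excluded)
}

#' Compute raw polygenic risk scores
#'
#' `PRS_j = sum_i d_ij * beta_i` over the resolved, used markers, in variant
#' index order. Markers excluded at imputation (no data anywhere) are
#' skipped.
#'
#' @param dosages complete dose matrix (individuals x variants) with marker
#'   IDs as column names.
#' @param resolved a `resolved_score` from [resolve_variants()].
#' @param ancestry_label which weight column to use.
#' @return per-sample raw scores (named numeric).
#' @export
compute_raw_prs <- function(dosages, resolved, ancestry_label) {
  if (!ancestry_label %in% resolved$ancestries)
    stopf("unknown ancestry '%s'; available: %s", ancestry_label,
          paste(resolved$ancestries, collapse = ", "))
  if (any(is.na(dosages))) stopf("dosage matrix must be complete (impute first)")
  used <- intersect(colnames(dosages), rownames(resolved$weights))
  if (!length(used)) stopf("no resolved markers present in dosage matrix")
  b <- resolved$weights[used, ancestry_label]
  as.numeric(dosages[, used, drop = FALSE] %*% b)
}

#' Standardize raw scores to z-units
#'
#' `z = (raw - mean) / sd` with the sample standard deviation (n - 1
#' denominator), so `c(1, 2, 3)` maps exactly to `c(-1, 0, 1)`.
#'
#' @param raw_scores numeric vector (>= 2 values, nonzero variance).
#' @return standardized scores with mean 0 and sample SD 1.
#' @export
standardize_scores <- function(raw_scores) {
  if (length(raw_scores) < 2L) stopf("need at least 2 scores to standardize")
  if (any(!is.finite(raw_scores))) stopf("raw scores must be finite")
  sample_scale(raw_scores)
}

#' Score a cohort end to end
#'
#' Convenience wrapper: resolve the score against the cohort's markers,
#' impute missing doses per site, compute raw PRS for each requested
#' ancestry column and standardize within the cohort.
#'
#' @param cohort a [cohort_data()].
#' @param score a [score_definition()].
#' @param proxy_map optional proxy map.
#' @param ancestries weight columns to score (default: all).
#' @param ... passed to [resolve_variants()].
#' @return list: `scores` (data.frame sample, n_filled, then
#'   `raw_<anc>` / `z_<anc>` per ancestry), `resolved`.
#' @export
score_cohort <- function(cohort, score, proxy_map = NULL,
                         ancestries = score$ancestries, ...) {
  resolved <- resolve_variants(score, cohort$variants$variant_id,
                               proxy_map = proxy_map, ...)
  imp <- impute_missing_doses(cohort$dosages, cohort$metadata$site)
  d <- imp$dosages
  if (length(imp$excluded_variants))
    d <- d[, -imp$excluded_variants, drop = FALSE]
  out <- data.frame(sample = cohort$metadata$sample,
                    n_filled = imp$fill_counts, stringsAsFactors = FALSE)
  for (a in ancestries) {
    raw <- compute_raw_prs(d, resolved, a)
    out[[paste0("raw_", a)]] <- raw
    out[[paste0("z_", a)]] <- standardize_scores(raw)
  }
  list(scores = out, resolved = resolved)
}
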