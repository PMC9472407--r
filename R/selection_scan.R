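# Extended haplotype homozygosity (EHH), integrated haplotype scores (iHS),
# percentile placement against a genome-wide reference, and the one-sample
# Kolmogorov-Smirnov uniformity test.

#' Construct a haplotype panel
#'
#' @param haplotypes binary matrix, haplotypes in rows, sites in columns;
#'   1 is the derived allele.
#' @param positions strictly increasing bp positions, one per site.
#' @param core_index column index of the core site.
#' @return a `haplotype_panel` object.
#' @export
haplotype_panel <- function(haplotypes, positions, core_index) {
  haplotypes <- as.matrix(haplotypes)
  if (!all(haplotypes %in% c(0L, 1L))) stopf("haplotype entries must be 0/1")
  if (length(positions) != ncol(haplotypes))
    stopf("positions must match the number of sites")
  if (any(diff(positions) <= 0)) stopf("positions must be strictly increasing")
  if (core_index < 1 || core_index > ncol(haplotypes))
    stopf("core_index out of range")
  storage.mode(haplotypes) <- "integer"
  structure(list(haplotypes = haplotypes, positions = as.numeric(positions),
                 core_index = as.integer(core_index)),
            class = "haplotype_panel")
}

#' Extended haplotype homozygosity around the core site
#'
#' `EHH(x)` is the probability that two distinct, randomly drawn carrier
#' haplotypes of `core_allele` are identical at every site from the core out
#' to `x`: with extended-haplotype group sizes `n_h`,
#' `EHH = sum n_h (n_h - 1) / (n (n - 1))`. It is 1 at the core and
#' non-increasing with distance.
#'
#' @param panel a [haplotype_panel()].
#' @param core_allele 0 (ancestral) or 1 (derived).
#' @return data.frame `site`, `position`, `ehh`, ordered by site; includes
#'   the core.
#' @export
compute_ehh <- function(panel, core_allele) {
  stopifnot(inherits(panel, "haplotype_panel"))
  carriers <- which(panel$haplotypes[, panel$core_index] == core_allele)
  n <- length(carriers)
  if (n < 2L) stopf("EHH undefined with fewer than 2 carrier haplotypes")
  h <- panel$haplotypes[carriers, , drop = FALSE]
  m <- ncol(h)
  ehh <- numeric(m)
  homozygosity <- function(groups) {
    cnt <- table(groups)
    sum(cnt * (cnt - 1)) / (n * (n - 1))
  }
  for (dir in c(-1L, 1L)) {
    groups <- rep(1L, n)
    j <- panel$core_index
    while (j >= 1L && j <= m) {
      groups <- as.integer(interaction(groups, h[, j], drop = TRUE))
      ehh[j] <- homozygosity(groups)
      j <- j + dir
    }
  }
  ehh[panel$core_index] <- 1
  data.frame(site = seq_len(m), position = panel$positions, ehh = ehh)
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

integrate_ehh_side <- function(pos, ehh, truncation) {
  # pos/ehh ordered outward from the core (first element = core, EHH 1);
  # integrate until EHH drops below the truncation threshold, interpolating
  # the crossing point linearly.
  if (length(pos) < 2L) return(list(ihh = 0, decayed = TRUE))
  below <- which(ehh < truncation)
  if (!length(below))
    return(list(ihh = trapezoid(abs(pos - pos[1]), ehh), decayed = FALSE))
  k <- below[1]
  x <- abs(pos[seq_len(k)] - pos[1])
  y <- ehh[seq_len(k)]
  # clip the last trapezoid at the threshold crossing
  frac <- (y[k - 1] - truncation) / (y[k - 1] - y[k])
  x[k] <- x[k - 1] + frac * (x[k] - x[k - 1])
  y[k] <- truncation
  list(ihh = trapezoid(x, y), decayed = TRUE)
}

#' Unstandardized iHS at the core site
#'
#' Integrates EHH over physical distance (trapezoid rule) separately for
#' ancestral- and derived-allele carriers, truncating each flank where EHH
#' decays below `truncation`, and returns `ln(iHH_A / iHH_D)`. Negative
#' values mean the derived allele sits on longer shared haplotypes (a
#' sweep-like signal). When EHH never decays below the threshold on some
#' flank, the value is flagged unreliable.
#'
#' @param panel a [haplotype_panel()].
#' @param truncation EHH truncation threshold (default 0.05).
#' @return list: `ihs_unstd`, `ihh_a`, `ihh_d`, `reliable`,
#'   `derived_freq`.
#' @export
compute_ihs_unstandardized <- function(panel, truncation = 0.05) {
  stopifnot(inherits(panel, "haplotype_panel"))
  core <- panel$core_index
  counts <- table(factor(panel$haplotypes[, core], levels = 0:1))
  if (any(counts < 2L)) stopf("both core alleles need >= 2 carriers")
  out <- list()
  for (allele in 0:1) {
    ehh <- compute_ehh(panel, allele)
    left <- seq(core, 1L)
    right <- seq(core, nrow(ehh))
    l <- integrate_ehh_side(ehh$position[left], ehh$ehh[left], truncation)
    r <- integrate_ehh_side(ehh$position[right], ehh$ehh[right], truncation)
    out[[allele + 1L]] <- list(ihh = l$ihh + r$ihh,
                               decayed = l$decayed && r$decayed)
  }
  ihh_a <- out[[1]]$ihh; ihh_d <- out[[2]]$ihh
  list(ihs_unstd = log(ihh_a / ihh_d), ihh_a = ihh_a, ihh_d = ihh_d,
       reliable = out[[1]]$decayed && out[[2]]$decayed,
       derived_freq = unname(counts[2] / sum(counts)))
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Within each of `n_bins` equal-width frequency bins on `bin_range`,
#' subtracts the bin mean and divides by the bin (sample) SD. Bins with
#' fewer than 2 values are merged with their nearest nonempty neighbour
#' (and a message logged). A bin with zero SD is an error.
#'
#' @param values unstandardized iHS values.
#' @param derived_freqs per-value derived allele frequencies.
#' @param n_bins number of bins (default 20).
#' @param bin_range frequency range covered by the bins.
#' @return standardized iHS values (same order as input).
#' @export
standardize_ihs <- function(values, derived_freqs, n_bins = 20L,
                            bin_range = c(0.05, 0.95)) {
  if (length(values) != length(derived_freqs))
    stopf("values and derived_freqs must have equal length")
  breaks <- seq(bin_range[1], bin_range[2], length.out = n_bins + 1L)
  bin <- findInterval(derived_freqs, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  # merge undersized bins into the nearest populated neighbour
  repeat {
    sizes <- tabulate(bin, nbins = n_bins)
    small <- which(sizes > 0L & sizes < 2L)
    if (!length(small)) break
    b <- small[1]
    others <- which(sizes >= 2L)
    if (!length(others)) stopf("too few values to form any frequency bin")
    target <- others[which.min(abs(others - b))]
    message(sprintf("standardize_ihs: merging bin %d (n=%d) into bin %d",
                    b, sizes[b], target))
    bin[bin == b] <- target
  }
  out <- numeric(length(values))
  for (b in unique(bin)) {
    idx <- bin == b
    s <- sd(values[idx])
    if (s == 0) stopf("zero SD in frequency bin %d; cannot standardize", b)
    out[idx] <- (values[idx] - mean(values[idx])) / s
  }
  out
}

#' Percentiles of target iHS values against a genome-wide reference
#'
#' Percentile of a target is the fraction of reference values whose |iHS|
#' does not exceed the target's |iHS| (two-sided magnitude convention, since
#' enrichment concerns extreme scores of either sign).
#'
#' @param target_values iHS at the score variants.
#' @param reference_values genome-wide iHS reference (nonempty).
#' @return data.frame `ihs`, `percentile` (in `[0, 1]`).
#' @export
percentile_against_reference <- function(target_values, reference_values) {
  if (!length(reference_values)) stopf("reference must be nonempty")
  if (!length(target_values))
    return(data.frame(ihs = numeric(0), percentile = numeric(0)))
  ref <- sort(abs(reference_values))
  pct <- findInterval(abs(target_values), ref) / length(ref)
  data.frame(ihs = target_values, percentile = pct)
}

#' One-sample Kolmogorov-Smirnov test of percentile uniformity
#'
#' `D = sup |ECDF - U(0,1)|`; p-value exact for `n < 100` (the stats::ks.test
#' default switch) and asymptotic otherwise.
#'
#' @param percentiles values in `[0, 1]`.
#' @return list: `d`, `p_value`, `n`.
#' @export
ks_uniform_test <- function(percentiles) {
  if (!length(percentiles)) stopf("need at least one percentile")
  check_number(percentiles, "percentiles", 0, 1)
  kt <- suppressWarnings(ks.test(percentiles, "punif"))
  list(d = unname(kt$statistic), p_value = kt$p.value,
       n = length(percentiles))
}

#' iHS for every eligible site of a panel
#'
#' Treats each site in turn as the core and computes unstandardized iHS
#' (sites where either allele has fewer than 2 carriers, or where EHH never
#' decays, are skipped or flagged), then standardizes within
#' derived-frequency bins.
#'
#' @param panel a [haplotype_panel()].
#' @param truncation EHH truncation threshold.
#' @param n_bins frequency bins for standardization.
#' @return data.frame `site`, `position`, `derived_freq`, `ihs_unstd`,
#'   `reliable`, `ihs` (standardized; `NA` for unreliable sites).
#' @export
ihs_scan <- function(panel, truncation = 0.05, n_bins = 20L) {
  m <- ncol(panel$haplotypes)
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    counts <- table(factor(panel$haplotypes[, j], levels = 0:1))
    if (any(counts < 2L)) next
    p <- haplotype_panel(panel$haplotypes, panel$positions, j)
    r <- compute_ihs_unstandardized(p, truncation)
    rows[[j]] <- data.frame(site = j, position = panel$positions[j],
                            derived_freq = r$derived_freq,
                            ihs_unstd = r$ihs_unstd, reliable = r$reliable)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no site with both alleles at >= 2 carriers")
  ok <- out$reliable & is.finite(out$ihs_unstd)
  out$ihs <- NA_real_
  if (sum(ok) >= 2L)
    out$ihs[ok] <- standardize_ihs(out$ihs_unstd[ok], out$derived_freq[ok],
                                   n_bins = n_bins)
  out
}
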