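# Readers and writers for the study's file formats. Scoring, proxy-map,
# metadata and iHS tables are tab-separated with documented headers
# (PGS-Catalog-style '#key=value' preamble for scores); genotypes travel as
# VCF 4.2 and haplotypes as plain 0/1 matrices. Gzipped input is handled
# transparently by the readers (data.table/connections).

#' Construct a score definition
#'
#' @param score_name label of the published score.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`.
#' @param weights data.frame/matrix, one column per ancestry label, of
#'   per-variant log odds ratios `ln(OR)`.
#' @return a `score_definition` object.
#' @export
score_definition <- function(score_name, variants, weights) {
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(need %in% names(variants)))
    stopf("variants must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(variants$variant_id))
    stopf("duplicate variant IDs in score definition")
  weights <- as.data.frame(weights)
  if (nrow(weights) != nrow(variants))
    stopf("weights must have one row per variant")
  if (any(!is.finite(as.matrix(weights))))
    stopf("weights must be finite (ln OR scale)")
  structure(list(score_name = score_name,
                 variants = as.data.frame(variants),
                 weights = weights,
                 ancestries = names(weights)),
            class = "score_definition")
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score_definition> %s: %d variants, ancestries: %s\n",
              x$score_name, nrow(x$variants),
              paste(x$ancestries, collapse = ", ")))
  invisible(x)
}

#' Construct a cohort container
#'
#' @param dosages matrix individuals x variants with entries in
#'   `{0, 1, 2, NA}`.
#' @param variants data.frame `variant_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param metadata data.frame with at least `sample`, `site`, `status`
#'   (logical case flag); optionally `age`, `stage`, `gleason`, `ancestry`.
#' @return a `cohort_data` object.
#' @export
cohort_data <- function(dosages, variants, metadata) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != nrow(metadata))
    stopf("dosage rows (%d) != metadata rows (%d)", nrow(dosages), nrow(metadata))
  if (ncol(dosages) != nrow(variants))
    stopf("dosage columns (%d) != variant rows (%d)", ncol(dosages), nrow(variants))
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stopf("doses must be 0, 1, 2 or missing")
  if (!all(c("sample", "site", "status") %in% names(metadata)))
    stopf("metadata needs sample, site, status columns")
  if (!is.logical(metadata$status)) stopf("metadata$status must be logical")
  ok_case <- metadata$status
  for (cl in intersect(c("stage", "gleason"), names(metadata))) {
    if (any(!is.na(metadata[[cl]][!ok_case])))
      stopf("%s must be missing for controls", cl)
  }
  rownames(dosages) <- metadata$sample
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages, variants = as.data.frame(variants),
                 metadata = as.data.frame(metadata)),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %d samples (%d cases) x %d variants, %.2f%% missing\n",
              nrow(x$dosages), sum(x$metadata$status), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

# ---- scoring files ---------------------------------------------------------

#' Write a scoring file
#'
#' Tab-separated with a `#key=value` preamble (`score_name`, `weight_scale`)
#' followed by `variant_id chrom pos effect_allele other_allele <ancestry...>`.
#'
#' @param score a [score_definition()].
#' @param path output path.
#' @param weight_scale `"logOR"` (default) or `"OR"` for the written columns.
#' @export
write_score_file <- function(score, path, weight_scale = c("logOR", "OR")) {
  weight_scale <- match.arg(weight_scale)
  w <- score$weights
  if (weight_scale == "OR") w <- exp(w)
  tab <- cbind(score$variants[c("variant_id", "chrom", "pos",
                                "effect_allele", "other_allele")], w)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#score_name=%s", score$score_name),
               sprintf("#weight_scale=%s", weight_scale)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scoring file
#'
#' Odds-ratio columns are converted to `ln(OR)` once at parse time; the
#' returned definition always carries log-odds weights.
#'
#' @param path scoring file (see [write_score_file()] for the layout).
#' @return a [score_definition()].
#' @export
read_score_file <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#", "", hdr)
  keys <- sub("=.*", "", kv); vals <- sub("^[^=]*=", "", kv)
  meta <- setNames(as.list(vals), keys)
  scale <- meta$weight_scale
  if (is.null(scale) || !scale %in% c("OR", "logOR"))
    stopf("line %d: header must declare weight_scale=OR or logOR",
          length(hdr))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stopf("line %d: empty variant section", length(lines))
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(need %in% names(tab)))
    stopf("scoring file must have columns: %s", paste(need, collapse = ", "))
  dup <- which(duplicated(tab$variant_id))
  if (length(dup))
    stopf("line %d: duplicate variant ID '%s'",
          dup[1] + 1L + length(hdr), tab$variant_id[dup[1]])
  anc <- setdiff(names(tab), need)
  if (!length(anc)) stopf("no ancestry weight columns found")
  w <- tab[anc]
  if (scale == "OR") {
    bad <- which(as.matrix(w) <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stopf("line %d: non-positive odds ratio in column '%s'",
            bad[1, 1] + 1L + length(hdr), anc[bad[1, 2]])
    w <- log(w)
  }
  score_definition(meta$score_name %||% "unnamed", tab[need], w)
}

# ---- proxy maps ------------------------------------------------------------

#' Write a proxy map
#'
#' Columns: `source_id`, `proxy_id` (comma-separated marker list for
#' `rule = "two_marker"` rows), `r2`, `same_direction`, `rule`.
#'
#' @param proxy_map data.frame as above.
#' @param path output path.
#' @export
write_proxy_map <- function(proxy_map, path) {
  utils::write.table(proxy_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a proxy map
#'
#' @param path tab-separated proxy map (see [write_proxy_map()]).
#' @return validated data.frame.
#' @export
read_proxy_map <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("source_id", "proxy_id", "r2", "same_direction")
  if (!all(need %in% names(pm)))
    stopf("proxy map must have columns: %s", paste(need, collapse = ", "))
  if (is.null(pm$rule)) pm$rule <- "single"
  check_number(pm$r2, "r2", 0, 1)
  self <- pm$source_id == pm$proxy_id & pm$r2 < 1
  if (any(self)) stopf("source '%s' maps to itself with r2 < 1",
                       pm$source_id[which(self)[1]])
  pm$same_direction <- as.logical(pm$same_direction)
  pm
}

# ---- VCF -------------------------------------------------------------------

#' Write a cohort's genotypes as VCF 4.2
#'
#' Unphased diploid GT fields; missing doses become `./.`. The dose is the
#' ALT-allele count, so ALT is the counted allele on write.
#'
#' @param cohort a [cohort_data()].
#' @param path output path (`.vcf`).
#' @export
write_genotypes_vcf <- function(cohort, path) {
  v <- cohort$variants
  d <- t(cohort$dosages)  # variants x samples
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  body <- cbind(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=prsport",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", cohort$metadata$sample),
                     collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes from a VCF into a cohort container
#'
#' Parses diploid GT fields and counts copies of the requested effect allele
#' per variant. When the effect allele equals ALT the dose is the ALT count;
#' when it equals REF the orientation is flipped (`dose = 2 - ALT count`);
#' when neither allele matches, the variant is flagged unmatched and its
#' doses set missing (not fatal). `./.` becomes `NA`.
#'
#' @param path VCF file (plain or gzipped).
#' @param variant_subset optional IDs to keep.
#' @param effect_alleles optional named character vector `variant_id ->
#'   effect allele`; default counts ALT.
#' @param metadata optional per-sample metadata to attach (default: minimal
#'   metadata with unknown site/status).
#' @return a [cohort_data()]; unmatched variant IDs in
#'   `attr(, "unmatched")`.
#' @export
read_genotypes_vcf <- function(path, variant_subset = NULL,
                               effect_alleles = NULL, metadata = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "synthetic"),
    error = function(e) stopf("malformed VCF '%s': %s", path, conditionMessage(e)))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stopf("VCF '%s' has no GT field", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- names(rr)
  ref <- as.character(rr$REF)
  alt <- vapply(rr$ALT, function(a) as.character(a)[1], "")
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  keep <- if (is.null(variant_subset)) seq_along(ids) else
    which(ids %in% variant_subset)
  gt <- gt[keep, , drop = FALSE]
  ids <- ids[keep]; ref <- ref[keep]; alt <- alt[keep]
  chrom <- chrom[keep]; pos <- pos[keep]
  alt_count <- matrix(NA_real_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  alt_count[clean == "0/0"] <- 0
  alt_count[clean %in% c("0/1", "1/0")] <- 1
  alt_count[clean == "1/1"] <- 2
  doses <- alt_count
  unmatched <- character(0)
  if (!is.null(effect_alleles)) {
    for (i in seq_along(ids)) {
      ea <- effect_alleles[ids[i]]
      if (is.na(ea)) next
      if (ea == alt[i]) {
        # already ALT-oriented
      } else if (ea == ref[i]) {
        doses[i, ] <- 2 - alt_count[i, ]
      } else {
        doses[i, ] <- NA_real_
        unmatched <- c(unmatched, ids[i])
      }
    }
  }
  samples <- colnames(gt)
  if (is.null(metadata))
    metadata <- data.frame(sample = samples, site = "unknown",
                           status = NA, stringsAsFactors = FALSE)
  metadata$status <- as.logical(metadata$status)
  out <- cohort_data(t(doses),
                     data.frame(variant_id = ids, chrom = chrom, pos = pos,
                                ref = ref, alt = alt, stringsAsFactors = FALSE),
                     metadata)
  attr(out, "unmatched") <- unmatched
  out
}

# ---- iHS tables ------------------------------------------------------------

#' Read a table of standardized iHS values
#'
#' Tab-separated `variant_id`, `freq` (derived or minor allele frequency),
#' `ihs` (standardized). Rows whose minor allele frequency is not strictly
#' above `maf_min` are flagged `excluded = TRUE` (the availability rule for
#' genome-wide iHS panels); the boundary itself is excluded.
#'
#' @param path input file.
#' @param maf_min strict lower MAF bound (default 0.05).
#' @return data.frame with `variant_id`, `freq`, `maf`, `ihs`, `excluded`.
#' @export
read_ihs_table <- function(path, maf_min = 0.05) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("variant_id", "freq", "ihs")
  if (!all(need %in% names(tab)))
    stopf("iHS table must have columns: %s", paste(need, collapse = ", "))
  if (!is.numeric(tab$ihs) || any(is.na(tab$ihs)))
    stopf("non-numeric iHS value in %s", path)
  check_number(tab$freq, "freq", 0, 1)
  tab$maf <- pmin(tab$freq, 1 - tab$freq)
  # strict "> maf_min" with an epsilon so the folded boundary (freq 0.95)
  # lands on the excluded side despite float noise
  tab$excluded <- !(tab$maf > maf_min + 1e-12)
  tab[c("variant_id", "freq", "maf", "ihs", "excluded")]
}

#' Write an iHS table
#' @param tab data.frame with `variant_id`, `freq`, `ihs`.
#' @param path output path.
#' @export
write_ihs_table <- function(tab, path) {
  utils::write.table(tab[c("variant_id", "freq", "ihs")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- metadata and haplotypes ----------------------------------------------

#' Write per-sample metadata
#' @param metadata data.frame (`sample`, `site`, `status`, ...).
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read per-sample metadata
#' @param path tab-separated metadata file.
#' @return data.frame with logical `status`.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (!all(c("sample", "site", "status") %in% names(md)))
    stopf("metadata needs sample, site, status columns")
  md$status <- as.logical(md$status)
  md
}

#' Write a haplotype panel as a plain 0/1 matrix
#'
#' First line `#positions=` comma-separated bp, second `#core_index=`, then
#' one row of 0/1 (no separators) per haplotype.
#'
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @export
write_haplotypes <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#positions=%s", paste(panel$positions, collapse = ",")),
               sprintf("#core_index=%d", panel$core_index)), con)
  writeLines(apply(panel$haplotypes, 1, paste, collapse = ""), con)
  invisible(path)
}

#' Read a haplotype panel written by [write_haplotypes()]
#' @param path input path.
#' @return a [haplotype_panel()].
#' @export
read_haplotypes <- function(path) {
  lines <- readLines(path)
  pos_line <- grep("^#positions=", lines, value = TRUE)
  core_line <- grep("^#core_index=", lines, value = TRUE)
  if (!length(pos_line) || !length(core_line))
    stopf("haplotype file missing #positions/#core_index header")
  positions <- as.numeric(strsplit(sub("^#positions=", "", pos_line), ",")[[1]])
  core <- as.integer(sub("^#core_index=", "", core_line))
  body <- lines[!grepl("^#", lines)]
  mat <- do.call(rbind, lapply(strsplit(body, ""), as.integer))
  haplotype_panel(mat, positions, core)
}
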