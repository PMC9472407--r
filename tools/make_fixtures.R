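# Regenerates the plain-text fixtures under inst/extdata (deterministic).
# Run from the package root: Rscript tools/make_fixtures.R
suppressPackageStartupMessages(library(prsport))
set.seed(20240901)
out <- file.path("inst", "extdata")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

alleles <- c("A", "C", "G", "T")
rand_alleles <- function(n) {
  ea <- sample(alleles, n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), "")
  list(ea = ea, oa = unname(oa))
}

# 147-marker European-style score; one indel-style ID absent from the
# variant dictionary, so resolution shrinks it to 146 markers.
n1 <- 147L
ids1 <- sprintf("rsS%05d", seq_len(n1))
ids1[77] <- "chr10_ins_77"  # dbSNP-absent indel stand-in
al1 <- rand_alleles(n1)
sch <- score_definition(
  "schumacher_like",
  data.frame(variant_id = ids1, chrom = rep(1:22, length.out = n1),
             pos = 1000000L + 137L * seq_len(n1),
             effect_allele = al1$ea, other_allele = al1$oa,
             stringsAsFactors = FALSE),
  data.frame(European = log(exp(rnorm(n1, 0, 0.08)))))
write_score_file(sch, file.path(out, "schumacher_like_score.tsv"),
                 weight_scale = "OR")
writeLines(c(ids1[ids1 != "chr10_ins_77"],
             sprintf("rsX%05d", 1:25)),  # extra known ids, not in the score
           file.path(out, "schumacher_dictionary.txt"))

# 269-marker multi-ancestry score; one source variant is replaced by a
# two-marker inference rule, expanding resolution to 270 markers.
n2 <- 269L
ids2 <- sprintf("rsC%05d", seq_len(n2))
al2 <- rand_alleles(n2)
anc <- c("Multi", "European", "African", "Asian", "Hispanic")
wts <- as.data.frame(setNames(lapply(anc, function(a) rnorm(n2, 0, 0.07)), anc))
conti <- score_definition(
  "conti_like",
  data.frame(variant_id = ids2, chrom = rep(1:22, length.out = n2),
             pos = 2000000L + 211L * seq_len(n2),
             effect_allele = al2$ea, other_allele = al2$oa,
             stringsAsFactors = FALSE),
  wts)
write_score_file(conti, file.path(out, "conti_like_score.tsv"),
                 weight_scale = "OR")

two_marker_source <- "rsC00042"
pm <- rbind(
  data.frame(source_id = two_marker_source,
             proxy_id = "rsPAIR001,rsPAIR002", r2 = 1,
             same_direction = TRUE, rule = "two_marker"),
  data.frame(source_id = c("rsC00007", "rsC00019"),
             proxy_id = c("rsC00007_tag", "rsC00019_tag"),
             r2 = c(0.91, 0.55), same_direction = c(TRUE, FALSE),
             rule = "single"))
write_proxy_map(pm, file.path(out, "conti_proxy_map.tsv"))

ew <- data.frame(marker_id = c("rsPAIR001", "rsPAIR002"))
for (a in anc) ew[[a]] <- rnorm(2, 0, 0.07)
utils::write.table(ew, file.path(out, "conti_expansion_weights.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("fixtures written to", out, "\n")
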