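# End-to-end orchestration: simulate -> QC -> structure -> score ->
# divergence/selection -> evaluate, from a single validated config, with a
# provenance manifest. Every stage seed derives from config$seed via
# fanout_seed(), so a config fully determines its outputs.

#' Default pipeline configuration
#'
#' Cohort sizes default to the motivating study's scale (2700/2687 European
#' cases/controls after downsampling; 1298/1333 African). Thresholds carry
#' the analysis defaults: proxy r-squared 0.4, sample missingness 5%, PCA
#' outliers at 2 SD, MAF availability > 0.05.
#'
#' @return a config list (see [validate_config()] for the fields).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_variants = 147L,
    populations = c("EUR", "AFR"),
    target_auc = c(EUR = 0.70, AFR = 0.58),
    prevalence = 0.10,
    n_cases = c(EUR = 2700L, AFR = 1298L),
    n_controls = c(EUR = 2687L, AFR = 1333L),
    r2_threshold = 0.4,
    missingness_max = 0.05,
    pca_sd = 2,
    maf_min = 0.05,
    n_pcs = 10L,
    high_group = c(0.90, 1.00),
    mid_group = c(0.40, 0.60),
    classifiers = c("stage", "gleason"),
    selection_scan = TRUE,
    aggressiveness_coupling = 0,
    out_dir = "prsport_run"
  )
}

#' Validate and normalize a pipeline config
#'
#' Missing fields are filled from [default_config()]; constraint violations
#' are returned (not raised) as a character vector naming the field.
#'
#' @param config partial config list.
#' @return list: `config` (normalized) and `errors` (character, empty when
#'   valid).
#' @export
validate_config <- function(config = list()) {
  full <- utils::modifyList(default_config(), config)
  errors <- character(0)
  chk <- function(ok, msg) if (!ok) errors <<- c(errors, msg)
  chk(is.numeric(full$seed) && length(full$seed) == 1,
      "seed: must be a single number")
  chk(full$n_variants >= 2, "n_variants: must be >= 2")
  chk(length(full$populations) == 2, "populations: exactly two required")
  chk(all(full$target_auc > 0.5 & full$target_auc < 1),
      "target_auc: must be in (0.5, 1)")
  chk(full$prevalence > 0 && full$prevalence < 1,
      "prevalence: must be in (0, 1)")
  chk(full$r2_threshold > 0 && full$r2_threshold <= 1,
      "r2_threshold: must be in (0, 1]")
  chk(full$missingness_max > 0 && full$missingness_max < 1,
      "missingness_max: must be in (0, 1)")
  chk(full$pca_sd > 0, "pca_sd: must be positive")
  chk(full$maf_min >= 0 && full$maf_min < 0.5, "maf_min: must be in [0, 0.5)")
  chk(all(full$n_cases > 0) && all(full$n_controls > 0),
      "n_cases/n_controls: must be positive")
  chk(all(full$classifiers %in% c("stage", "gleason")),
      "classifiers: must be a subset of stage, gleason")
  list(config = full, errors = errors)
}

#' Run the full synthetic PRS portability pipeline
#'
#' Stages: design the calibrated two-population world; simulate both
#' cohorts; sample QC (missingness filter, PCA outlier filter); genotype
#' PCA and MDS; score resolution and PRS computation per ancestry weight
#' column; bow-tie divergence test on directly genotyped shared variants;
#' Mann-Whitney comparison of the pooled-standardized PRS distributions;
#' optional selection scan on planted-sweep haplotype fixtures (failure of
#' this stage is logged, not fatal); AUC / DeLong / odds-ratio evaluation.
#' Tables are written as TSV + JSON under `config$out_dir` along with a
#' provenance manifest.
#'
#' @param config config list (validated via [validate_config()]).
#' @return (invisibly) a list with the report, per-cohort scores, bow-tie
#'   and KS results, DeLong comparisons, and the manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  vc <- validate_config(config)
  if (length(vc$errors))
    stopf("invalid config:\n  %s", paste(vc$errors, collapse = "\n  "))
  cfg <- vc$config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  counts <- list()

  say("stage world: designing %d-variant two-population study", cfg$n_variants)
  world <- design_prs_world(
    seed = cfg$seed, n_variants = cfg$n_variants,
    target_auc = cfg$target_auc, prevalence = cfg$prevalence)
  pops <- world$populations

  cohorts <- list()
  for (i in seq_along(pops)) {
    pop <- pops[i]
    say("stage simulate[%s]: %d cases / %d controls", pop,
        cfg$n_cases[[pop]], cfg$n_controls[[pop]])
    ch <- simulate_study_cohort(world, pop, cfg$n_cases[[pop]],
                                cfg$n_controls[[pop]],
                                seed = fanout_seed(cfg$seed, 20L + i),
                                aggressiveness_coupling = cfg$aggressiveness_coupling)
    qc <- filter_sample_missingness(ch$dosages, cfg$missingness_max)
    imp <- impute_missing_doses(ch$dosages[qc$included, , drop = FALSE],
                                ch$metadata$site[qc$included])
    pca <- genotype_pca(imp$dosages, cfg$n_pcs)
    keep_pca <- pca_outlier_filter(pca$scores[, 1:2], cfg$pca_sd)
    say("stage qc[%s]: %d excluded for missingness, %d PCA outliers", pop,
        sum(!qc$included), sum(!keep_pca))
    idx <- which(qc$included)[keep_pca]
    cohorts[[pop]] <- list(
      cohort = cohort_data(ch$dosages[idx, , drop = FALSE],
                           ch$variants, ch$metadata[idx, , drop = FALSE]),
      pcs = pca$scores[keep_pca, , drop = FALSE],
      truth = attr(ch, "truth"))
    counts[[paste0("samples_", pop)]] <- length(idx)
  }

  say("stage score: resolving and scoring both cohorts")
  scores <- list()
  for (pop in pops) {
    ch <- cohorts[[pop]]$cohort
    sc <- score_cohort(ch, world$score, proxy_map = world$proxy_map,
                       r2_threshold = cfg$r2_threshold)
    scores[[pop]] <- sc
    utils::write.table(
      sc$scores, file.path(cfg$out_dir, sprintf("scores_%s.tsv", pop)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    counts[[paste0("markers_", pop)]] <- sc$resolved$n_markers
  }

  say("stage divergence: bow-tie binomial test on shared direct variants")
  direct_both <- world$source_ids[
    world$tagging[[pops[1]]]$class == "direct" &
      world$tagging[[pops[2]]]$class == "direct"]
  fa <- colMeans(cohorts[[pops[1]]]$cohort$dosages[, direct_both, drop = FALSE],
                 na.rm = TRUE) / 2
  fb <- colMeans(cohorts[[pops[2]]]$cohort$dosages[, direct_both, drop = FALSE],
                 na.rm = TRUE) / 2
  jft <- joint_frequency_table(fa, fb, direct_both)
  tabs <- table(jft$region)
  bow <- bowtie_binomial_test(tabs[["A_more_informative"]],
                              tabs[["B_more_informative"]],
                              n_tie = tabs[["tie"]])
  z_pool <- standardize_scores(c(scores[[pops[1]]]$scores[[paste0("raw_", pops[1])]],
                                 scores[[pops[2]]]$scores[[paste0("raw_", pops[2])]]))
  n1 <- nrow(scores[[pops[1]]]$scores)
  mw <- mann_whitney_shift(z_pool[seq_len(n1)], z_pool[-seq_len(n1)])
  jsonlite::write_json(
    list(counts = as.list(tabs), p_value = bow$p_value, policy = bow$tie_policy,
         mann_whitney_p = mw$p_value),
    file.path(cfg$out_dir, "bowtie.json"), auto_unbox = TRUE, digits = NA)

  ks <- NULL
  if (isTRUE(cfg$selection_scan)) {
    ks <- tryCatch({
      say("stage selection: iHS scan on synthetic haplotype panel")
      panel <- simulate_sweep_haplotypes(
        n_haplotypes = 120, n_sites = 151, core_index = 76,
        sweep_strength = 0, seed = fanout_seed(cfg$seed, 30L))
      scan <- ihs_scan(panel)
      ok <- !is.na(scan$ihs)
      prs_like <- which(ok)[seq_len(min(25L, sum(ok)))]
      pct <- percentile_against_reference(scan$ihs[prs_like],
                                          scan$ihs[ok])
      res <- ks_uniform_test(pct$percentile)
      jsonlite::write_json(list(d = res$d, p_value = res$p_value, n = res$n),
                           file.path(cfg$out_dir, "ks.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    }, error = function(e) {
      say("stage selection FAILED (continuing): %s", conditionMessage(e))
      NULL
    })
  }

  say("stage evaluate: AUC / OR / DeLong")
  eval_in <- list()
  for (pop in pops) {
    md <- cohorts[[pop]]$cohort$metadata
    eval_in[[pop]] <- list(scores = scores[[pop]]$scores, status = md$status,
                           age = md$age, pcs = cohorts[[pop]]$pcs,
                           stage = md$stage, gleason = md$gleason)
  }
  report <- build_evaluation_report(eval_in, ancestries = pops,
                                    classifiers = cfg$classifiers)
  write_evaluation_report(report,
                          tsv_path = file.path(cfg$out_dir, "report.tsv"),
                          json_path = file.path(cfg$out_dir, "report.json"))
  delong <- list()
  for (a in pops) {
    r1 <- roc_auc(eval_in[[pops[1]]]$scores[[paste0("z_", a)]],
                  eval_in[[pops[1]]]$status)
    r2 <- roc_auc(eval_in[[pops[2]]]$scores[[paste0("z_", a)]],
                  eval_in[[pops[2]]]$status)
    dt <- delong_test(r1, r2, paired = FALSE)
    delong[[a]] <- list(ancestry = a, auc_1 = r1$auc, auc_2 = r2$auc,
                        z = dt$z, p_value = dt$p_value)
  }
  jsonlite::write_json(delong, file.path(cfg$out_dir, "delong.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    package = "prsport",
    version = as.character(utils::packageVersion("prsport")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    counts = counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(list(report = report, scores = scores, bowtie = bow,
                 mann_whitney = mw, ks = ks, delong = delong,
                 manifest = manifest, world = world, cohorts = cohorts))
}
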