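# End-to-end orchestration: ingest -> filter -> classify under one or both
# profiles -> per-gene TESE evidence -> cohort statistics -> report files.
# The function surface is the entry point; `scripts/acceptance.R` shows a
# complete scripted run.

#' Run the full panel-diagnosis pipeline
#'
#' Accepts either in-memory objects or file paths (YAML config via
#' `config_path`), applies the filtration cascade, classifies the
#' candidates under the selected profiles, aggregates per-gene TESE
#' evidence from the cohort's carriers, and computes the cohort
#' association statistics. When `output_dir` is given, writes per-variant
#' filter decisions, per-profile classification tables, a per-patient
#' carrier summary, the gene-level TESE report and a JSON statistics
#' bundle plus a run manifest.
#'
#' @param panel `panel_index` or path to a panel TSV.
#' @param variants Variant table or path (TSV/VCF).
#' @param patients Phenotype table or path.
#' @param profiles Character vector of profile ids, subset of
#'   `c("I", "II")`; both by default.
#' @param thresholds `filter_thresholds` or path to a YAML override.
#' @param cnvs Optional CNV table.
#' @param output_dir Optional directory for report files.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the caller generated inputs).
#' @return List: `filter` (from [run_filters()]), `classifications`
#'   (combined table over profiles), `carriers` (per patient x profile),
#'   `tese` (per-gene evidence per profile), `stats`
#'   ([cohort_summary()]), `manifest`.
#' @export
run_pipeline <- function(panel, variants, patients,
                         profiles = c("I", "II"),
                         thresholds = filter_thresholds(),
                         cnvs = NULL, output_dir = NULL, seed = NULL) {
  if (length(profiles) == 0)
    stop_noa("at least one classification profile must be selected")
  check_enum(profiles, c("I", "II"), "profile")
  if (is.character(panel)) panel <- load_panel(panel)
  if (is.character(patients)) patients <- read_phenotypes(patients)
  if (is.character(variants)) variants <- read_variants(variants, panel)
  if (is.character(thresholds)) thresholds <- read_thresholds(thresholds)

  filt <- run_filters(variants, panel, patients, thresholds, cnvs = cnvs)

  classifications <- do.call(rbind, lapply(profiles, function(p) {
    classify_variants(filt$candidates, panel, rule_profile(p))
  }))

  carrier_rows <- unique(classifications[
    classifications$tier %in% c("P", "LP"),
    c("patient_id", "gene", "profile_id")])
  pidx <- match(carrier_rows$patient_id, patients$patient_id)
  tese_carriers <- data.frame(
    gene = carrier_rows$gene, carrier_id = carrier_rows$patient_id,
    source = "cohort", outcome = patients$tese_outcome[pidx],
    profile = carrier_rows$profile_id, stringsAsFactors = FALSE)
  tese <- lapply(stats::setNames(profiles, profiles), function(p) {
    tese_evidence_table(tese_carriers, profile = p)
  })

  stats_out <- cohort_summary(patients, classifications)

  manifest <- list(
    n_patients = nrow(patients), n_variants = nrow(variants),
    n_candidates = nrow(filt$candidates), profiles = profiles,
    thresholds = unclass(thresholds), seed = seed,
    package_version = as.character(utils::packageVersion("noapanel")))

  result <- list(filter = filt, classifications = classifications,
                 carriers = tese_carriers, tese = tese,
                 stats = stats_out, manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    ok <- FALSE
    on.exit(if (!ok) unlink(file.path(output_dir,
                                      c("filter_decisions.tsv",
                                        "classifications.tsv",
                                        "carriers.tsv", "tese_report.tsv",
                                        "stats.json", "manifest.json"))))
    write_tsv(filt$decisions, file.path(output_dir, "filter_decisions.tsv"))
    write_tsv(classifications, file.path(output_dir, "classifications.tsv"))
    write_tsv(tese_carriers, file.path(output_dir, "carriers.tsv"))
    write_tsv(do.call(rbind, lapply(profiles, function(p) {
      cbind(profile = p, tese[[p]])
    })), file.path(output_dir, "tese_report.tsv"))
    jsonlite::write_json(summarise_stats(stats_out),
                         file.path(output_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    ok <- TRUE
  }
  result
}

# Flatten a cohort summary into plain lists for JSON output.
summarise_stats <- function(s) {
  out <- list(n_patients = s$n_patients,
              retrieval_rate_pct = s$retrieval_rate_pct)
  for (nm in grep("^profile_", names(s), value = TRUE)) {
    p <- s[[nm]]
    out[[nm]] <- list(
      n_carriers = p$n_carriers,
      yield_overall_pct = p$yield_overall_pct,
      yield_negative_pct = p$yield_negative_pct,
      yield_positive_pct = p$yield_positive_pct,
      odds_ratio = p$odds_ratio$or,
      or_ci = c(p$odds_ratio$ci_low, p$odds_ratio$ci_high),
      p_binomial = p$p_binomial,
      histology = p$histology,
      histology_chisq = p$histology_chisq)
  }
  out
}
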