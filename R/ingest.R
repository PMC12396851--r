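# Variant and phenotype ingestion. Variants live in a plain data.frame with
# one row per patient-allele ("variant table"); the same columns are used by
# the filtering engine, the classifier and the simulator.

#' Controlled consequence vocabulary
#'
#' Internal consequence terms used throughout the package. Annotation-tool
#' terms (e.g. Ensembl VEP strings) are translated into this vocabulary via
#' the `consequence_map` argument of [read_variants()].
#' @export
CONSEQUENCES <- c("missense", "stop_gain", "frameshift", "splice_region",
                  "synonymous", "start_loss", "inframe_indel", "other")

ZYGOSITIES <- c("het", "hom", "hemi")
VARIANT_CLASSES <- c("SNV", "indel", "CNV_del")
HISTOLOGIES <- c("SCO", "MA", "HSG", "TS", "unknown")
TESE_OUTCOMES <- c("positive", "negative")

VARIANT_COLUMNS <- c("patient_id", "gene", "chrom", "pos", "ref", "alt",
                     "variant_class", "consequence", "splice_offset",
                     "zygosity", "depth", "alt_fraction", "popmax_af",
                     "revel", "spliceai", "phase_group", "off_panel")

#' Build a validated variant table
#'
#' Assembles per-patient variant calls into the canonical variant table.
#' Missing optional annotations are filled with `NA`; an absent population
#' allele frequency is stored as 0 (absent from the reference population is
#' treated as maximally rare, the standard clinical-filtering convention).
#'
#' @param df data.frame with at least `patient_id`, `gene`, `consequence`,
#'   `zygosity`; remaining columns of `VARIANT_COLUMNS` optional.
#' @param panel Optional `panel_index`; when given, rows in genes absent
#'   from the panel are flagged `off_panel = TRUE` (they are retained, not
#'   dropped).
#' @return data.frame with the full `VARIANT_COLUMNS` set.
#' @export
variant_table <- function(df, panel = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("patient_id", "gene", "consequence", "zygosity")) {
    if (!col %in% names(df)) stop_noa("variant table: missing column ", col)
  }
  defaults <- list(
    chrom = NA_character_, pos = NA_integer_, ref = NA_character_,
    alt = NA_character_, variant_class = "SNV", splice_offset = NA_integer_,
    depth = NA_real_, alt_fraction = NA_real_, popmax_af = 0,
    revel = NA_real_, spliceai = NA_real_, phase_group = NA_character_,
    off_panel = FALSE
  )
  for (col in names(defaults)) {
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  }
  for (col in c("patient_id", "gene", "chrom", "ref", "alt",
                "variant_class", "consequence", "zygosity", "phase_group"))
    df[[col]] <- as.character(df[[col]])
  for (col in c("pos", "splice_offset"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("depth", "alt_fraction", "popmax_af", "revel", "spliceai"))
    df[[col]] <- as.numeric(df[[col]])
  df$off_panel <- as_logical_flag(df$off_panel, "off_panel")
  df$popmax_af[is.na(df$popmax_af)] <- 0
  check_enum(df$consequence, CONSEQUENCES, "consequence")
  check_enum(df$zygosity, ZYGOSITIES, "zygosity")
  check_enum(df$variant_class, VARIANT_CLASSES, "variant_class")
  if (any(df$depth < 0, na.rm = TRUE)) stop_noa("negative depth")
  if (any(df$alt_fraction < 0 | df$alt_fraction > 1, na.rm = TRUE))
    stop_noa("alt_fraction outside [0, 1]")
  if (any(df$popmax_af < 0 | df$popmax_af > 1, na.rm = TRUE))
    stop_noa("popmax_af outside [0, 1]")
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "panel_index"))
    df$off_panel <- !(df$gene %in% panel$genes$symbol)
  }
  df <- df[, VARIANT_COLUMNS]
  rownames(df) <- NULL
  df
}

#' Read variant calls from an annotated TSV or a VCF
#'
#' The annotated-TSV dialect has one row per patient-allele with the
#' `VARIANT_COLUMNS` headers (`off_panel` is recomputed, not read). A VCF
#' (4.2+) is read through the vcfR package when available; genotype depth is
#' taken from FORMAT `DP` and the alternate-allele fraction from FORMAT
#' `AD`, the gene symbol from an INFO key (default `GENE`), and records with
#' several ALT alleles are decomposed into one row per alternate allele.
#'
#' @param path Input file; `.vcf` is dispatched to the VCF reader, anything
#'   else to the TSV reader.
#' @param panel `panel_index` used to flag off-panel genes.
#' @param consequence_map Optional named character vector translating
#'   annotation-tool consequence terms to the internal [CONSEQUENCES]
#'   vocabulary; terms already in the vocabulary pass through.
#' @param info_gene_key INFO key holding the gene symbol (VCF input).
#' @param info_csq_key INFO key holding the consequence term (VCF input).
#' @return Variant table (see [variant_table()]).
#' @export
read_variants <- function(path, panel, consequence_map = NULL,
                          info_gene_key = "GENE", info_csq_key = "CSQ") {
  if (!file.exists(path)) stop_noa("file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    df <- read_variants_vcf(path, info_gene_key, info_csq_key)
  } else {
    df <- read_tsv_checked(path, required = c("patient_id", "gene",
                                              "consequence", "zygosity"))
  }
  if (!is.null(consequence_map)) {
    hit <- df$consequence %in% names(consequence_map)
    df$consequence[hit] <- unname(consequence_map[df$consequence[hit]])
  }
  variant_table(df, panel = panel)
}

read_variants_vcf <- function(path, info_gene_key, info_csq_key) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_noa("VCF input requires the vcfR package; supply an annotated TSV instead")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  info_field <- function(key) {
    vapply(vcf@fix[, "INFO"], function(s) {
      m <- regmatches(s, regexpr(paste0("(^|;)", key, "=[^;]*"), s))
      if (length(m) == 0) return(NA_character_)
      sub(paste0("^(;)?", key, "="), "", sub("^;", "", m))
    }, character(1), USE.NAMES = FALSE)
  }
  gene <- info_field(info_gene_key)
  csq <- info_field(info_csq_key)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c("./.", ".")) next
      alleles <- as.integer(strsplit(gsub("\\|", "/", g), "/")[[1]])
      alleles <- alleles[!is.na(alleles)]
      ad_i <- suppressWarnings(as.numeric(strsplit(ad[i, s] %||% NA_character_,
                                                   ",")[[1]]))
      for (ai in seq_along(alts)) {
        n_alt <- sum(alleles == ai)
        if (n_alt == 0) next
        zyg <- if (length(alleles) == 1) "hemi"
               else if (n_alt == length(alleles)) "hom" else "het"
        depth_i <- dp[i, s]
        if (is.na(depth_i) && length(ad_i) && !anyNA(ad_i))
          depth_i <- sum(ad_i)
        af <- if (length(ad_i) > ai && !is.na(ad_i[ai + 1]) &&
                  !is.na(depth_i) && depth_i > 0)
          ad_i[ai + 1] / depth_i else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = s, gene = gene[i], chrom = fix$CHROM[i],
          pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[ai],
          variant_class = if (nchar(fix$REF[i]) == nchar(alts[ai])) "SNV" else "indel",
          consequence = csq[i] %||% "other",
          zygosity = zyg, depth = depth_i, alt_fraction = af,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(), gene = character(),
                      consequence = character(), zygosity = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write a variant table to TSV
#'
#' Inverse of the TSV branch of [read_variants()]: re-reading the written
#' file yields an identical table.
#' @param variants Variant table.
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  write_tsv(variants[, VARIANT_COLUMNS], path)
}

#' Read the patient phenotype table
#'
#' Expects a TSV with header `patient_id sex_chromosomes tese_outcome
#' histology centre consanguinity_region`. Histology uses the closed set
#' SCO (Sertoli-cell-only), MA (maturation arrest), HSG
#' (hypospermatogenesis), TS (tubular shadows) or `unknown`; the TESE
#' outcome (`positive`/`negative`) is mandatory for every patient.
#'
#' @param path Phenotype TSV.
#' @return data.frame, one row per patient.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_checked(path, required = c("patient_id", "sex_chromosomes",
                                            "tese_outcome", "histology"))
  if (!"centre" %in% names(df)) df$centre <- NA_character_
  if (!"consanguinity_region" %in% names(df))
    df$consanguinity_region <- FALSE
  if (nrow(df) == 0) return(df)
  df$patient_id <- as.character(df$patient_id)
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup))
    stop_noa("duplicate patient_id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(df$tese_outcome))
    stop_noa("tese_outcome is mandatory for every patient")
  check_enum(df$tese_outcome, TESE_OUTCOMES, "tese_outcome")
  df$histology[is.na(df$histology)] <- "unknown"
  check_enum(df$histology, HISTOLOGIES, "histology")
  check_enum(df$sex_chromosomes, c("XY", "other"), "sex_chromosomes")
  df$consanguinity_region <- as_logical_flag(df$consanguinity_region,
                                             "consanguinity_region")
  rownames(df) <- NULL
  df
}

#' Build a validated CNV-deletion call table
#'
#' Copy-number deletions are handled separately from sequence variants
#' because their filters differ (breakpoint recurrence and SV-panel
#' frequency instead of depth/allele-fraction QC).
#'
#' @param df data.frame with columns `patient_id`, `gene`, `copy_state`
#'   (`het_del`/`hom_del`), `breakpoint_start`, `breakpoint_end`,
#'   `n_unrelated_carriers_same_breakpoints` (includes the patient; >= 1),
#'   optional `sv_af` (absent = 0).
#' @return Validated data.frame.
#' @export
cnv_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("patient_id", "gene", "copy_state",
                "n_unrelated_carriers_same_breakpoints")) {
    if (!col %in% names(df)) stop_noa("cnv table: missing column ", col)
  }
  if (!"sv_af" %in% names(df)) df$sv_af <- 0
  df$sv_af[is.na(df$sv_af)] <- 0
  if (!"breakpoint_start" %in% names(df)) df$breakpoint_start <- NA_integer_
  if (!"breakpoint_end" %in% names(df)) df$breakpoint_end <- NA_integer_
  check_enum(df$copy_state, c("het_del", "hom_del"), "copy_state")
  if (any(df$n_unrelated_carriers_same_breakpoints < 1))
    stop_noa("carrier count must include the patient (>= 1)")
  bad <- !is.na(df$breakpoint_start) & !is.na(df$breakpoint_end) &
    df$breakpoint_start > df$breakpoint_end
  if (any(bad)) stop_noa("breakpoint_start > breakpoint_end")
  rownames(df) <- NULL
  df
}
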