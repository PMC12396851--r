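# Shared fixture builders and independent oracles. Oracles re-state the
# scientific rules in plain, unoptimised code so they stay independent of
# the package's implementation paths.

toy_panel_df <- function() {
  data.frame(
    symbol = c("GENE_AR1", "GENE_AR2", "GENE_XL1", "GENE_AD1", "GENE_YL1"),
    inheritance_mode = c("AR", "AR", "XL", "AD", "YL"),
    chromosome_class = c("autosome", "autosome", "X", "autosome", "Y"),
    gdr_level = c("moderate", "limited", "strong", "moderate", "limited"),
    tese_class = c("negative_only", "unknown", "negative_only",
                   "compatible_positive", "unknown"),
    poi_linked = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    notes = NA_character_,
    stringsAsFactors = FALSE
  )
}

write_panel <- function(df = toy_panel_df(), path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

toy_panel <- function() load_panel(write_panel())

partial_panel <- function() {
  load_panel(system.file("extdata", "noa_panel_partial.tsv",
                         package = "noapanel"))
}

xy_patients <- function(ids) {
  data.frame(patient_id = ids, sex_chromosomes = "XY",
             tese_outcome = "negative", histology = "unknown",
             centre = NA_character_, consanguinity_region = FALSE,
             stringsAsFactors = FALSE)
}

# Randomised variant generator for property tests: every rule of the
# filtration cascade is exercised (consequence classes, splice offsets,
# frequency around both ceilings, depth and allele-fraction around the QC
# cutoffs, zygosities per inheritance mode).
random_variants <- function(n, panel, seed) {
  set.seed(seed)
  gi <- sample.int(nrow(panel$genes), n, replace = TRUE)
  gene <- panel$genes$symbol[gi]
  mode <- panel$genes$inheritance_mode[gi]
  csq <- sample(CONSEQUENCES, n, replace = TRUE)
  splice_offset <- ifelse(csq == "splice_region",
                          sample(-6:6, n, replace = TRUE), NA_integer_)
  zyg <- ifelse(mode %in% c("XL", "YL"),
                sample(c("hemi", "het"), n, replace = TRUE,
                       prob = c(0.8, 0.2)),
                sample(c("het", "hom"), n, replace = TRUE,
                       prob = c(0.7, 0.3)))
  data.frame(
    patient_id = sprintf("R%03d", sample.int(max(2L, n %/% 4L), n,
                                             replace = TRUE)),
    gene = gene, chrom = NA_character_,
    pos = sample.int(1e6, n, replace = TRUE), ref = "A", alt = "G",
    variant_class = "SNV", consequence = csq,
    splice_offset = splice_offset, zygosity = zyg,
    depth = sample(c(5:15, 30, 100), n, replace = TRUE),
    alt_fraction = round(stats::runif(n, 0.05, 1), 3),
    popmax_af = sample(c(0, 1e-4, 5e-4, 1e-3, 2e-3, 9e-3, 1e-2, 2e-2, 0.1),
                       n, replace = TRUE),
    revel = ifelse(stats::runif(n) < 0.5, round(stats::runif(n), 3),
                   NA_real_),
    spliceai = ifelse(stats::runif(n) < 0.3, round(stats::runif(n), 3),
                      NA_real_),
    phase_group = NA_character_, off_panel = FALSE,
    stringsAsFactors = FALSE
  )
}

# Brute-force filtration oracle: evaluates every rule predicate
# independently, then the group-level inheritance rule, mirroring the
# documented filtering semantics without sharing code with run_filters().
oracle_filter_kept <- function(variants, panel, thresholds = filter_thresholds()) {
  mode <- panel$genes$inheritance_mode[match(variants$gene,
                                             panel$genes$symbol)]
  n <- nrow(variants)
  csq_ok <- logical(n); frq_ok <- logical(n); qc_ok <- logical(n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    csq_ok[i] <- if (v$consequence == "splice_region") {
      abs(v$splice_offset) <= thresholds$splice_window
    } else {
      v$consequence %in% c("missense", "stop_gain", "frameshift",
                           "start_loss", "inframe_indel")
    }
    ceiling_i <- if (mode[i] == "AR") thresholds$maf_recessive
                 else thresholds$maf_dominant_sexlinked
    frq_ok[i] <- v$popmax_af <= ceiling_i
    qc_ok[i] <- v$depth >= thresholds$min_depth &&
      v$alt_fraction >= thresholds$min_alt_fraction
  }
  local_ok <- csq_ok & frq_ok & qc_ok
  kept <- rep(FALSE, n)
  keys <- paste(variants$patient_id, variants$gene)
  for (key in unique(keys)) {
    grp <- which(keys == key & local_ok)
    if (length(grp) == 0) next
    m <- mode[grp[1]]
    zyg <- variants$zygosity[grp]
    if (m == "AD") {
      kept[grp] <- TRUE
    } else if (m %in% c("XL", "YL")) {
      kept[grp] <- zyg %in% c("hemi", "hom")
    } else {
      hom_like <- zyg %in% c("hom", "hemi")
      kept[grp[hom_like]] <- TRUE
      if (sum(zyg == "het") >= 2) kept[grp[zyg == "het"]] <- TRUE
    }
  }
  kept
}
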