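# Candidate-variant filtration. Rules mirror standard clinical panel
# practice for azoospermia: a consequence window (non-synonymous exonic plus
# near-splice), inheritance-mode-specific population-frequency ceilings,
# sequencing QC on depth and allele fraction, inheritance-consistency within
# each patient-gene group, and recurrence/frequency filters for copy-number
# deletions.

#' Filtering thresholds
#'
#' Defaults: variants in autosomal-recessive genes are kept up to a maximum
#' population allele frequency of 0.01, dominant and sex-linked genes up to
#' 0.001 (both boundaries inclusive); sites need >= 10x depth and an
#' alternate-read fraction >= 0.15; splice variants are kept within +/- 3
#' bases of the exon boundary; deletions recurring in more than 10 unrelated
#' carriers with similar breakpoints, or with SV-panel frequency >= 0.01
#' (recessive) / >= 0.001 (sex-linked), are removed.
#'
#' @param maf_recessive,maf_dominant_sexlinked Population-frequency ceilings.
#' @param min_depth Minimum read depth (x).
#' @param min_alt_fraction Minimum mutated/all-reads ratio.
#' @param splice_window Maximum absolute distance (bases) from the splice
#'   junction for splice-region variants.
#' @param cnv_max_carriers Maximum unrelated carriers sharing breakpoints.
#' @param cnv_maf_recessive,cnv_maf_sexlinked SV-frequency ceilings
#'   (exclusive: a deletion at the ceiling is removed).
#' @return List of class `filter_thresholds`.
#' @export
filter_thresholds <- function(maf_recessive = 0.01,
                              maf_dominant_sexlinked = 0.001,
                              min_depth = 10,
                              min_alt_fraction = 0.15,
                              splice_window = 3L,
                              cnv_max_carriers = 10L,
                              cnv_maf_recessive = 0.01,
                              cnv_maf_sexlinked = 0.001) {
  t <- list(maf_recessive = maf_recessive,
            maf_dominant_sexlinked = maf_dominant_sexlinked,
            min_depth = min_depth, min_alt_fraction = min_alt_fraction,
            splice_window = splice_window, cnv_max_carriers = cnv_max_carriers,
            cnv_maf_recessive = cnv_maf_recessive,
            cnv_maf_sexlinked = cnv_maf_sexlinked)
  if (any(unlist(t) <= 0)) stop_noa("all thresholds must be positive")
  if (t$maf_dominant_sexlinked > t$maf_recessive)
    stop_noa("dominant/sex-linked frequency ceiling cannot exceed the recessive one")
  structure(t, class = "filter_thresholds")
}

#' Load filtering thresholds from a YAML config
#'
#' The YAML keys mirror the [filter_thresholds()] argument names; absent
#' keys keep their defaults.
#' @param path YAML file.
#' @return `filter_thresholds`.
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(filter_thresholds))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_noa("unknown threshold key(s): ", paste(unknown, collapse = ", "))
  do.call(filter_thresholds, cfg)
}

exonic_keep <- c("missense", "stop_gain", "frameshift", "start_loss",
                 "inframe_indel")

#' Consequence filter
#'
#' Keeps non-synonymous exonic variants (missense, stop gain, frameshift,
#' start loss, in-frame indel) and splice-region variants within the splice
#' window (default +/- 3 bases of the junction, junction base included);
#' synonymous and `other` consequences are dropped.
#'
#' @param variants Variant table.
#' @param thresholds `filter_thresholds`.
#' @return Logical vector: keep each row?
#' @export
consequence_filter <- function(variants, thresholds = filter_thresholds()) {
  is_splice <- variants$consequence == "splice_region"
  if (any(is_splice & is.na(variants$splice_offset)))
    stop_noa("splice_region variant without splice_offset")
  keep <- variants$consequence %in% exonic_keep
  keep[is_splice] <- abs(variants$splice_offset[is_splice]) <=
    thresholds$splice_window
  keep
}

#' Population-frequency filter
#'
#' Keeps variants whose maximum population allele frequency does not exceed
#' the inheritance-mode ceiling: 0.01 for autosomal-recessive genes, 0.001
#' for dominant and sex-linked genes (inclusive boundaries). An absent
#' frequency counts as 0 and always passes.
#'
#' @param variants Variant table (absent `popmax_af` already stored as 0).
#' @param mode Inheritance mode per row (`AR`, `AD`, `XL`, `YL`).
#' @param thresholds `filter_thresholds`.
#' @return Logical keep vector.
#' @export
frequency_filter <- function(variants, mode,
                             thresholds = filter_thresholds()) {
  check_enum(mode, INHERITANCE_MODES, "inheritance mode")
  ceiling_af <- ifelse(mode == "AR", thresholds$maf_recessive,
                       thresholds$maf_dominant_sexlinked)
  af <- variants$popmax_af
  af[is.na(af)] <- 0
  af <= ceiling_af
}

#' Sequencing-QC filter
#'
#' Keeps variants with depth >= 10x and mutated/all-reads ratio >= 0.15
#' (defaults). Copy-number deletions bypass this filter (their evidence does
#' not come from site-level read counts). Returns, per row, which of the two
#' QC rules failed.
#'
#' @param variants Variant table.
#' @param thresholds `filter_thresholds`.
#' @return data.frame with logical columns `depth_ok`, `alt_fraction_ok`.
#' @export
qc_filter <- function(variants, thresholds = filter_thresholds()) {
  cnv <- variants$variant_class == "CNV_del"
  depth_ok <- cnv | (!is.na(variants$depth) &
                       variants$depth >= thresholds$min_depth)
  af_ok <- cnv | (!is.na(variants$alt_fraction) &
                    variants$alt_fraction >= thresholds$min_alt_fraction)
  data.frame(depth_ok = depth_ok, alt_fraction_ok = af_ok)
}

#' Inheritance-consistency check for one patient-gene group
#'
#' Applies the expected-mode-of-inheritance rule to the variants of one
#' patient in one gene (all assumed to have passed the record-local
#' filters):
#' * `AR`: homozygous variants kept; heterozygous variants kept only when
#'   at least two are present in the gene (or a heterozygous-deletion
#'   partner is supplied), giving a candidate compound heterozygote;
#'   the configuration is `confirmed_cHET` when two variants share a
#'   `phase_group` marking them in trans, `candidate_cHET` otherwise.
#'   A single unpartnered heterozygous variant is dropped.
#' * `XL`/`YL` in an XY patient: hemizygous (or homozygous-called) variants
#'   kept; a heterozygous call on the X in an XY patient is inconsistent
#'   and dropped with a warning. A `YL` gene in a non-XY patient is an
#'   error.
#' * `AD`: heterozygous and homozygous variants kept (two copies of a
#'   dominant allele remain consistent).
#'
#' @param variants Variant rows of one patient in one gene.
#' @param mode Inheritance mode of the gene.
#' @param sex_chromosomes `"XY"` or `"other"` for the patient.
#' @param n_cnv_partners Number of surviving heterozygous-deletion partners
#'   in the same gene (counts toward compound-heterozygous pairing in AR
#'   genes).
#' @return List with `keep` (logical vector over rows) and `configuration`
#'   (one of `hom`, `hemi`, `het_dominant`, `candidate_cHET`,
#'   `confirmed_cHET`, `inconsistent`, `none`).
#' @export
inheritance_consistency <- function(variants, mode, sex_chromosomes = "XY",
                                    n_cnv_partners = 0L) {
  check_enum(mode, INHERITANCE_MODES, "inheritance mode")
  n <- nrow(variants)
  if (n == 0) return(list(keep = logical(0), configuration = "none"))
  zyg <- variants$zygosity
  if (mode == "AD") {
    return(list(keep = rep(TRUE, n), configuration = "het_dominant"))
  }
  if (mode %in% c("XL", "YL")) {
    if (mode == "YL" && !identical(sex_chromosomes, "XY"))
      stop_noa("Y-linked gene variant in a patient without a Y chromosome")
    keep <- zyg %in% c("hemi", "hom")
    if (any(!keep)) {
      warning("heterozygous call on a sex-linked gene in an XY patient; ",
              "dropped as inconsistent", call. = FALSE)
    }
    cfg <- if (any(keep)) "hemi" else "inconsistent"
    return(list(keep = keep, configuration = cfg))
  }
  # AR
  hom <- zyg == "hom" | zyg == "hemi"  # hemi on an autosome should not occur
  hets <- zyg == "het"
  n_het_units <- sum(hets) + n_cnv_partners
  keep <- hom
  cfg <- if (any(hom)) "hom" else "none"
  if (n_het_units >= 2 && sum(hets) >= 1) {
    keep <- keep | hets
    pg <- variants$phase_group[hets]
    trans_confirmed <- (sum(hets) >= 2 &&
                          any(duplicated(pg[!is.na(pg)]))) ||
      (n_cnv_partners >= 1 && sum(hets) >= 1)
    cfg <- if (any(hom)) "hom"
           else if (trans_confirmed) "confirmed_cHET" else "candidate_cHET"
  }
  if (!any(keep)) cfg <- "none"
  list(keep = keep, configuration = cfg)
}

#' Copy-number deletion filter
#'
#' Keeps homozygous deletions; keeps heterozygous deletions only as
#' compound-heterozygous candidates in autosomal-recessive genes (a partner
#' sequence variant or second deletion in the same gene must exist). Drops
#' deletions with similar breakpoints seen in more than `cnv_max_carriers`
#' unrelated carriers, and deletions whose SV-panel frequency reaches the
#' recessive (0.01) or sex-linked (0.001) ceiling.
#'
#' @param cnvs CNV table ([cnv_table()]).
#' @param mode Inheritance mode per row.
#' @param has_partner Logical per row: surviving partner variant in the
#'   same gene and patient?
#' @param thresholds `filter_thresholds`.
#' @return data.frame with `kept` and `failed_rules` (comma-separated).
#' @export
cnv_filter <- function(cnvs, mode, has_partner = FALSE,
                       thresholds = filter_thresholds()) {
  check_enum(mode, INHERITANCE_MODES, "inheritance mode")
  n <- nrow(cnvs)
  has_partner <- rep_len(has_partner, n)
  af_ceiling <- ifelse(mode == "AR", thresholds$cnv_maf_recessive,
                       thresholds$cnv_maf_sexlinked)
  recur_fail <- cnvs$n_unrelated_carriers_same_breakpoints >
    thresholds$cnv_max_carriers
  freq_fail <- cnvs$sv_af >= af_ceiling
  zyg_fail <- cnvs$copy_state == "het_del" & !(mode == "AR" & has_partner)
  failed <- mapply(function(r, f, z) {
    paste(c(if (r) "cnv_recurrence", if (f) "cnv_frequency",
            if (z) "inheritance"), collapse = ",")
  }, recur_fail, freq_fail, zyg_fail)
  data.frame(kept = !(recur_fail | freq_fail | zyg_fail),
             failed_rules = failed, stringsAsFactors = FALSE)
}

#' Run the full filtration cascade
#'
#' Applies, in order, the consequence, population-frequency and QC filters
#' to every variant, then the inheritance-consistency rule within each
#' patient-gene group of the survivors (counting surviving
#' heterozygous-deletion partners toward compound-heterozygous pairing),
#' and the deletion-specific filters to the CNV calls. Off-panel variants
#' are set aside (tallied, not silently discarded). The cascade is
#' deterministic and idempotent.
#'
#' @param variants Variant table.
#' @param panel `panel_index`.
#' @param patients Phenotype table ([read_phenotypes()]); used for
#'   sex-chromosome context.
#' @param thresholds `filter_thresholds`.
#' @param cnvs Optional CNV table.
#' @return List with:
#'   * `decisions`: per input variant, `kept`, comma-separated
#'     `failed_rules` and the patient-gene `configuration`;
#'   * `candidates`: the kept variant rows with `configuration` attached;
#'   * `cnv_decisions` / `cnv_candidates`: same for deletions;
#'   * `tally`: named drop counts per rule plus `off_panel` and `kept`.
#' @export
run_filters <- function(variants, panel, patients = NULL,
                        thresholds = filter_thresholds(), cnvs = NULL) {
  stopifnot(inherits(panel, "panel_index"))
  variants <- variant_table(variants, panel = panel)
  n <- nrow(variants)
  failed <- vector("list", n)
  on_panel <- !variants$off_panel

  mode <- rep(NA_character_, n)
  idx <- match(variants$gene, panel$genes$symbol)
  mode[on_panel] <- panel$genes$inheritance_mode[idx[on_panel]]

  sexchr <- rep("XY", n)
  if (!is.null(patients) && nrow(variants)) {
    pidx <- match(variants$patient_id, patients$patient_id)
    if (anyNA(pidx)) {
      orphan <- unique(variants$patient_id[is.na(pidx)])
      stop_noa("variant patient(s) missing from phenotype table: ",
               paste(orphan, collapse = ", "))
    }
    sexchr <- patients$sex_chromosomes[pidx]
  }

  keep_local <- rep(FALSE, n)
  if (any(on_panel)) {
    v_on <- variants[on_panel, , drop = FALSE]
    csq_ok <- consequence_filter(v_on, thresholds)
    frq_ok <- frequency_filter(v_on, mode[on_panel], thresholds)
    qc <- qc_filter(v_on, thresholds)
    local_ok <- csq_ok & frq_ok & qc$depth_ok & qc$alt_fraction_ok
    keep_local[on_panel] <- local_ok
    fails <- character(sum(on_panel))
    fails <- mapply(function(c_, f_, d_, a_) {
      paste(c(if (!c_) "consequence", if (!f_) "frequency",
              if (!d_) "depth", if (!a_) "alt_fraction"), collapse = ",")
    }, csq_ok, frq_ok, qc$depth_ok, qc$alt_fraction_ok)
    failed[on_panel] <- as.list(fails)
  }
  failed[!on_panel] <- list("off_panel")

  # CNV candidates by patient-gene, used for cHET pairing and filtered below
  cnv_partner_key <- character(0)
  if (!is.null(cnvs) && nrow(cnvs)) {
    cnvs <- cnv_table(cnvs)
    cnv_partner_key <- paste(cnvs$patient_id, cnvs$gene, sep = "\r")
  }

  # Inheritance consistency among record-local survivors
  keep_final <- keep_local
  configuration <- rep(NA_character_, n)
  surv <- which(keep_local)
  if (length(surv)) {
    key <- paste(variants$patient_id[surv], variants$gene[surv], sep = "\r")
    for (grp in split(surv, key)) {
      g_mode <- mode[grp[1]]
      g_key <- paste(variants$patient_id[grp[1]], variants$gene[grp[1]],
                     sep = "\r")
      n_partners <- if (g_mode == "AR")
        sum(cnv_partner_key == g_key) else 0L
      res <- inheritance_consistency(variants[grp, , drop = FALSE], g_mode,
                                     sex_chromosomes = sexchr[grp[1]],
                                     n_cnv_partners = n_partners)
      keep_final[grp] <- res$keep
      configuration[grp] <- res$configuration
      dropped <- grp[!res$keep]
      for (i in dropped) failed[[i]] <- "inheritance"
    }
  }

  failed_chr <- vapply(failed, function(f) paste(f, collapse = ","),
                       character(1))
  failed_chr[keep_final] <- ""
  decisions <- data.frame(variants[, c("patient_id", "gene")],
                          kept = keep_final, failed_rules = failed_chr,
                          configuration = configuration,
                          stringsAsFactors = FALSE)
  candidates <- cbind(variants[keep_final, , drop = FALSE],
                      configuration = configuration[keep_final])
  rownames(candidates) <- NULL

  # CNV filtering: partner = kept het SNV/indel in same AR gene, or a second
  # deletion in the same gene
  cnv_decisions <- NULL
  cnv_candidates <- NULL
  if (!is.null(cnvs) && nrow(cnvs)) {
    cnv_mode <- panel$genes$inheritance_mode[match(cnvs$gene,
                                                   panel$genes$symbol)]
    if (anyNA(cnv_mode))
      stop_noa("CNV in gene absent from the panel: ",
               paste(unique(cnvs$gene[is.na(cnv_mode)]), collapse = ", "))
    cand_key <- paste(candidates$patient_id, candidates$gene, sep = "\r")
    het_snv_partner <- cnv_partner_key %in%
      cand_key[candidates$zygosity == "het"]
    second_del <- vapply(seq_len(nrow(cnvs)), function(i) {
      sum(cnv_partner_key == cnv_partner_key[i]) > 1
    }, logical(1))
    cnv_decisions <- cnv_filter(cnvs, cnv_mode,
                                has_partner = het_snv_partner | second_del,
                                thresholds = thresholds)
    cnv_decisions <- cbind(cnvs[, c("patient_id", "gene", "copy_state")],
                           cnv_decisions)
    cnv_candidates <- cnvs[cnv_decisions$kept, , drop = FALSE]
    rownames(cnv_candidates) <- NULL
  }

  all_failed <- unlist(strsplit(failed_chr[!keep_final], ","))
  if (!is.null(cnv_decisions)) {
    all_failed <- c(all_failed,
                    unlist(strsplit(
                      cnv_decisions$failed_rules[!cnv_decisions$kept], ",")))
  }
  rule_names <- c("consequence", "frequency", "depth", "alt_fraction",
                  "inheritance", "cnv_recurrence", "cnv_frequency",
                  "off_panel")
  tally <- vapply(rule_names, function(r) sum(all_failed == r), integer(1))
  tally <- c(tally, kept = sum(keep_final) +
               if (is.null(cnv_decisions)) 0L else sum(cnv_decisions$kept))

  list(decisions = decisions, candidates = candidates,
       cnv_decisions = cnv_decisions, cnv_candidates = cnv_candidates,
       tally = tally)
}
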