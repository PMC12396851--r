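# ACMG/AMP evidence engine for NOA gene-panel variants. Two rule profiles
# are shipped: profile "I" follows the adaptations common in the male
# infertility literature (PM2 at moderate strength); profile "II" is the
# diagnostics-grade refinement (PM2 demoted to supporting, in line with
# current recommendations on allele-rarity evidence). Both use
# disease-specific frequency thresholds derived from the prevalence of
# azoospermia and its genetic/allelic heterogeneity, and the scaled point
# system mapping summed evidence strengths to the five classification
# tiers.

STRENGTHS <- c(supporting = 1L, moderate = 2L, strong = 4L, very_strong = 8L)
TIERS <- c("P", "LP", "VUS", "LB", "B")

#' Point value of one evidence strength
#'
#' Scaled point system: supporting = 1, moderate = 2, strong = 4,
#' very strong = 8; benign-direction criteria count negatively. The
#' stand-alone benign criterion (BA1) has no point value: it short-circuits
#' classification to benign.
#'
#' @param strength One of `supporting`, `moderate`, `strong`, `very_strong`.
#' @param direction `"pathogenic"` or `"benign"`.
#' @return Signed integer point value.
#' @examples
#' strength_points("very_strong", "pathogenic")  # +8
#' strength_points("supporting", "benign")       # -1
#' @export
strength_points <- function(strength, direction = "pathogenic") {
  if (any(strength == "stand_alone"))
    stop_noa("stand_alone (BA1) has no point value; it is handled categorically")
  check_enum(strength, names(STRENGTHS), "strength")
  check_enum(direction, c("pathogenic", "benign"), "direction")
  pts <- unname(STRENGTHS[strength])
  sign <- ifelse(direction == "benign", -1L, 1L)
  pts * rep_len(sign, length(pts))
}

#' Five-tier classification from total evidence points
#'
#' Bands: >= 10 pathogenic (P); 6 to 9 likely pathogenic (LP); 0 to 5
#' uncertain significance (VUS); -6 to -1 likely benign (LB); <= -7
#' benign (B). Total, exhaustive and mutually exclusive over the integers.
#'
#' @param points Integer vector of summed evidence points.
#' @return Character vector of tiers.
#' @export
classify_points <- function(points) {
  if (any(points != round(points))) stop_noa("points must be integers")
  ifelse(points >= 10, "P",
         ifelse(points >= 6, "LP",
                ifelse(points >= 0, "VUS",
                       ifelse(points >= -6, "LB", "B"))))
}

#' Maximum credible population allele frequency
#'
#' Converts disease prevalence and the share of cases attributable to one
#' gene/allele (combined genetic and allelic heterogeneity) into the
#' highest allele frequency a fully penetrant causal variant could credibly
#' reach in the reference population:
#' * dominant: `prevalence * heterogeneity / (2 * penetrance)` (two alleles
#'   per affected individual);
#' * X-/Y-linked (male-limited expression): `prevalence * heterogeneity /
#'   penetrance`;
#' * recessive: `sqrt(prevalence * heterogeneity / penetrance)` (carriers
#'   vastly outnumber affected homozygotes).
#'
#' With the default azoospermia parameters (prevalence 1%, heterogeneity 5%
#' for the stand-alone benign ceiling and 1% for the rarity criteria) these
#' formulas populate the BA1, BS1 and PM2 thresholds per inheritance mode.
#'
#' @param prevalence Disease prevalence in (0, 1].
#' @param heterogeneity Combined genetic and allelic heterogeneity in
#'   (0, 1].
#' @param mode Inheritance mode (`AR`, `AD`, `XL`, `YL`).
#' @param penetrance Penetrance in (0, 1], default 1.
#' @return Allele-frequency threshold.
#' @examples
#' max_credible_af(0.01, 0.05, "AR")        # ~0.0224
#' max_credible_af(0.01, 0.01, "AD")        # 5e-05
#' @export
max_credible_af <- function(prevalence, heterogeneity, mode,
                            penetrance = 1) {
  for (p in c(prevalence, heterogeneity, penetrance)) {
    if (!is.numeric(p) || any(p <= 0) || any(p > 1))
      stop_noa("prevalence, heterogeneity and penetrance must lie in (0, 1]")
  }
  check_enum(mode, INHERITANCE_MODES, "mode")
  core <- prevalence * heterogeneity / penetrance
  ifelse(mode == "AR", sqrt(core),
         ifelse(mode == "AD", core / 2, core))
}

#' Construct a classification rule profile
#'
#' @param profile_id `"I"` (literature-adapted: PM2 at moderate strength)
#'   or `"II"` (NOA diagnostics refinement: PM2 at supporting strength).
#' @param pm2_strength Strength of the rarity criterion; defaults by
#'   profile.
#' @param prevalence Azoospermia prevalence (default 0.01).
#' @param heterogeneity_ba1 Heterogeneity for the stand-alone benign
#'   frequency ceiling (default 0.05).
#' @param heterogeneity_pm2 Heterogeneity for the PM2/BS1/BS2 thresholds
#'   (default 0.01).
#' @param revel_pathogenic REVEL cutoff above which the in-silico
#'   criterion supports pathogenicity (strict inequality; default 0.644).
#' @param spliceai_high SpliceAI delta-score cutoff (inclusive; default
#'   0.9).
#' @param revel_benign,spliceai_benign Cutoffs below which both scores
#'   jointly support a benign interpretation (defaults 0.29 and 0.1).
#' @param bs2_min_controls Minimum count of healthy adults (or
#'   normozoospermic controls) with the disease-consistent genotype
#'   (homozygous for AR, hemizygous male for XL) for BS2 (default 1).
#' @param penetrance Assumed penetrance for the frequency thresholds.
#' @return List of class `rule_profile`, including the per-mode derived
#'   thresholds `ba1_af` and `pm2_af`.
#' @export
rule_profile <- function(profile_id = c("II", "I"),
                         pm2_strength = NULL,
                         prevalence = 0.01,
                         heterogeneity_ba1 = 0.05,
                         heterogeneity_pm2 = 0.01,
                         revel_pathogenic = 0.644,
                         spliceai_high = 0.9,
                         revel_benign = 0.29,
                         spliceai_benign = 0.1,
                         bs2_min_controls = 1L,
                         penetrance = 1) {
  profile_id <- match.arg(profile_id)
  if (is.null(pm2_strength))
    pm2_strength <- if (profile_id == "I") "moderate" else "supporting"
  check_enum(pm2_strength, names(STRENGTHS), "pm2_strength")
  modes <- INHERITANCE_MODES
  p <- list(
    profile_id = profile_id,
    pm2_strength = pm2_strength,
    prevalence = prevalence,
    heterogeneity_ba1 = heterogeneity_ba1,
    heterogeneity_pm2 = heterogeneity_pm2,
    revel_pathogenic = revel_pathogenic,
    spliceai_high = spliceai_high,
    revel_benign = revel_benign,
    spliceai_benign = spliceai_benign,
    bs2_min_controls = bs2_min_controls,
    penetrance = penetrance,
    ba1_af = stats::setNames(
      max_credible_af(prevalence, heterogeneity_ba1, modes, penetrance),
      modes),
    pm2_af = stats::setNames(
      max_credible_af(prevalence, heterogeneity_pm2, modes, penetrance),
      modes)
  )
  structure(p, class = "rule_profile")
}

#' Load a rule profile from a YAML rule table
#'
#' Keys mirror the [rule_profile()] arguments. The two shipped defaults
#' live in `inst/extdata/profile_I.yaml` and `profile_II.yaml`.
#' @param path YAML file.
#' @return `rule_profile`.
#' @export
read_rule_profile <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(rule_profile))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_noa("unknown rule-profile key(s): ", paste(unknown, collapse = ", "))
  do.call(rule_profile, cfg)
}

as_rule_profile <- function(profile) {
  if (inherits(profile, "rule_profile")) return(profile)
  rule_profile(profile)
}

# Vectorised evidence evaluation over a candidate table. `ctx` is a
# data.frame aligned with `v` carrying lof_mechanism, last_exon,
# in_trans_pathogenic, control_genotype_count. Returns a data.frame of
# per-criterion points (0 = not applied) plus the BA1 indicator.
evidence_batch <- function(v, mode, profile, ctx) {
  af <- v$popmax_af
  af[is.na(af)] <- 0
  ba1_thr <- unname(profile$ba1_af[mode])
  pm2_thr <- unname(profile$pm2_af[mode])

  lof <- v$consequence %in% c("stop_gain", "frameshift", "start_loss") |
    (v$consequence == "splice_region" & !is.na(v$splice_offset) &
       abs(v$splice_offset) <= 2)
  pvs1 <- ifelse(lof & ctx$lof_mechanism,
                 ifelse(ctx$last_exon, STRENGTHS[["strong"]],
                        STRENGTHS[["very_strong"]]), 0L)
  ba1 <- af >= ba1_thr
  bs1 <- !ba1 & af >= pm2_thr
  pm2 <- ifelse(af < pm2_thr, STRENGTHS[[profile$pm2_strength]], 0L)
  pm3 <- ifelse(ctx$in_trans_pathogenic & mode == "AR",
                STRENGTHS[["moderate"]], 0L)
  bs2 <- ctx$control_genotype_count >= profile$bs2_min_controls
  pp3 <- (!is.na(v$revel) & v$revel > profile$revel_pathogenic) |
    (!is.na(v$spliceai) & v$spliceai >= profile$spliceai_high)
  bp4 <- !pp3 &
    (!is.na(v$revel) & v$revel < profile$revel_benign) &
    (!is.na(v$spliceai) & v$spliceai < profile$spliceai_benign)

  data.frame(
    PVS1 = as.integer(pvs1),
    PM2 = as.integer(pm2),
    PM3 = as.integer(pm3),
    PP3 = ifelse(pp3, STRENGTHS[["supporting"]], 0L),
    BS1 = ifelse(bs1, -STRENGTHS[["strong"]], 0L),
    BS2 = ifelse(bs2, -STRENGTHS[["strong"]], 0L),
    BP4 = ifelse(bp4, -STRENGTHS[["supporting"]], 0L),
    BA1 = ba1
  )
}

default_context <- function(n, ctx = NULL) {
  base <- data.frame(
    lof_mechanism = rep(TRUE, n),
    last_exon = rep(FALSE, n),
    in_trans_pathogenic = rep(FALSE, n),
    control_genotype_count = rep(0L, n)
  )
  if (!is.null(ctx)) {
    for (col in intersect(names(ctx), names(base))) base[[col]] <- ctx[[col]]
  }
  base
}

strength_label <- function(points) {
  names(STRENGTHS)[match(abs(points), STRENGTHS)]
}

#' Assign ACMG/AMP evidence criteria to one candidate variant
#'
#' Deterministic rule evaluation of the implemented triggers:
#' * `PVS1` for predicted loss-of-function consequences (stop gain,
#'   frameshift, start loss, canonical +/- 2 splice) in genes where
#'   loss of function is the established disease mechanism; truncation in
#'   the last exon is downgraded to strong;
#' * `PM2` when the population frequency is below the mode-specific
#'   maximum-credible threshold, at the profile's strength;
#' * `BA1` (stand-alone) / `BS1` above the corresponding thresholds;
#' * `BS2` when the disease-consistent genotype is observed in healthy
#'   adults or normozoospermic controls (genotype-aware count supplied via
#'   context);
#' * `PM3` for recessive-gene variants confirmed in trans with a
#'   pathogenic partner;
#' * `PP3` / `BP4` from REVEL and SpliceAI scores.
#'
#' All other codes (PS1, PM1, PM5, PP1, PS4, ...) enter only through
#' `context$extra`, a data.frame with columns `code`, `strength`,
#' `direction`. At most one very-strong pathogenic criterion is allowed:
#' further very-strong entries are capped to strong with a warning.
#'
#' @param v One-row variant table.
#' @param gene One-row panel entry for the variant's gene (see
#'   [panel_gene()]).
#' @param profile `rule_profile` or profile id.
#' @param context List: `lof_mechanism` (default TRUE), `last_exon`
#'   (default FALSE), `in_trans_pathogenic` (default FALSE),
#'   `control_genotype_count` (default 0), optional `extra` data.frame.
#' @return data.frame with one row per applied criterion: `code`,
#'   `direction`, `strength`, `points` (0 rows when nothing applies; BA1 is
#'   reported with strength `stand_alone` and 0 points).
#' @export
assign_evidence <- function(v, gene, profile, context = list()) {
  profile <- as_rule_profile(profile)
  stopifnot(nrow(v) == 1)
  mode <- gene$inheritance_mode
  if (isTRUE(context$in_trans_pathogenic) && mode != "AR") {
    warning("in_trans_pathogenic context on a non-recessive gene; ",
            "PM3 not applied", call. = FALSE)
    context$in_trans_pathogenic <- FALSE
  }
  ctx <- default_context(1, as.data.frame(
    context[setdiff(names(context), "extra")], stringsAsFactors = FALSE))
  ev <- evidence_batch(v, mode, profile, ctx)
  rows <- list()
  add <- function(code, points) {
    rows[[length(rows) + 1L]] <<- data.frame(
      code = code,
      direction = if (points >= 0) "pathogenic" else "benign",
      strength = strength_label(points), points = points,
      stringsAsFactors = FALSE)
  }
  if (ev$BA1) {
    rows[[1]] <- data.frame(code = "BA1", direction = "benign",
                            strength = "stand_alone", points = 0L,
                            stringsAsFactors = FALSE)
  } else {
    for (code in c("PVS1", "PM2", "PM3", "PP3", "BS1", "BS2", "BP4")) {
      if (ev[[code]] != 0) add(code, ev[[code]])
    }
    if (!is.null(context$extra) && nrow(context$extra)) {
      extra <- context$extra
      have_vs <- any(vapply(rows, function(r)
        r$points == STRENGTHS[["very_strong"]], logical(1)))
      for (i in seq_len(nrow(extra))) {
        pts <- strength_points(extra$strength[i], extra$direction[i])
        if (pts == STRENGTHS[["very_strong"]] && have_vs) {
          warning("second very-strong pathogenic criterion capped to strong",
                  call. = FALSE)
          pts <- STRENGTHS[["strong"]]
        }
        if (pts == STRENGTHS[["very_strong"]]) have_vs <- TRUE
        add(extra$code[i], pts)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(code = character(), direction = character(),
                      strength = character(), points = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$code))
    stop_noa("criterion applied more than once: ",
             paste(out$code[duplicated(out$code)], collapse = ", "))
  out
}

#' Classify one candidate variant
#'
#' Composes [assign_evidence()], the point sum and [classify_points()].
#' A stand-alone benign frequency (BA1) short-circuits to tier `B`
#' regardless of pathogenic evidence.
#'
#' @inheritParams assign_evidence
#' @return List of class `classification_result`: `applied` (criterion
#'   data.frame), `points`, `tier`, `profile_id`, `vus_priority_flag`.
#' @export
classify_variant <- function(v, gene, profile, context = list()) {
  profile <- as_rule_profile(profile)
  applied <- assign_evidence(v, gene, profile, context)
  ba1 <- "BA1" %in% applied$code
  points <- sum(applied$points)
  tier <- if (ba1) "B" else classify_points(points)
  res <- structure(list(applied = applied, points = points, tier = tier,
                        profile_id = profile$profile_id,
                        vus_priority_flag = FALSE),
                   class = "classification_result")
  res$vus_priority_flag <- flag_priority_vus(res, v, profile = profile)
  res
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("profile %s: %s (%+d points)\n", x$profile_id, x$tier,
              x$points))
  if (nrow(x$applied))
    cat("  applied:", paste(sprintf("%s_%s", x$applied$code,
                                    x$applied$strength), collapse = " "), "\n")
  if (x$vus_priority_flag) cat("  flagged: priority VUS for follow-up\n")
  invisible(x)
}

#' Flag variants of uncertain significance worth functional follow-up
#'
#' Among VUS, four categories are of particular interest for reassessment:
#' splice-region variants (even with SpliceAI below the high-confidence
#' cutoff), stop gains, frameshifts removing less than 10% of the protein
#' without hitting a known domain, and missense variants with REVEL above
#' the pathogenic-support cutoff.
#'
#' @param r `classification_result` (or a tier string).
#' @param v One-row variant table.
#' @param protein_fraction_removed For frameshifts: fraction of the protein
#'   removed (NA = unknown, not flagged).
#' @param affects_domain For frameshifts: does the truncation hit a known
#'   domain? (NA treated as TRUE, i.e. not flagged.)
#' @param profile `rule_profile` supplying the REVEL cutoff.
#' @return Logical.
#' @export
flag_priority_vus <- function(r, v, protein_fraction_removed = NA,
                              affects_domain = NA,
                              profile = rule_profile("II")) {
  tier <- if (inherits(r, "classification_result")) r$tier else r
  if (!identical(tier, "VUS")) return(FALSE)
  csq <- v$consequence
  if (csq == "splice_region" || csq == "stop_gain") return(TRUE)
  if (csq == "frameshift") {
    return(!is.na(protein_fraction_removed) &&
             protein_fraction_removed < 0.10 &&
             identical(affects_domain, FALSE))
  }
  if (csq == "missense") {
    return(!is.na(v$revel) && v$revel > profile$revel_pathogenic)
  }
  FALSE
}

#' Classify a table of candidate variants under one profile
#'
#' Vectorised batch interface over the same rule evaluation as
#' [classify_variant()]. Context columns (`lof_mechanism`, `last_exon`,
#' `in_trans_pathogenic`, `control_genotype_count`) are read from
#' `candidates` when present, otherwise defaulted. When `candidates`
#' carries a `configuration` column (from [run_filters()]), confirmed
#' compound-heterozygous variants whose partner in the gene is predicted
#' loss-of-function receive the in-trans criterion automatically.
#'
#' @param candidates Variant table (typically `run_filters()$candidates`).
#' @param panel `panel_index`.
#' @param profile `rule_profile` or profile id (`"I"`/`"II"`).
#' @return data.frame: one row per variant with `profile_id`,
#'   `applied` (space-separated `CODE_strength` labels), `points`, `tier`,
#'   `vus_priority_flag`.
#' @export
classify_variants <- function(candidates, panel, profile) {
  profile <- as_rule_profile(profile)
  stopifnot(inherits(panel, "panel_index"))
  n <- nrow(candidates)
  if (n == 0) {
    return(data.frame(patient_id = character(), gene = character(),
                      profile_id = character(), applied = character(),
                      points = integer(), tier = character(),
                      vus_priority_flag = logical(),
                      stringsAsFactors = FALSE))
  }
  idx <- match(candidates$gene, panel$genes$symbol)
  if (anyNA(idx))
    stop_noa("candidate in gene absent from the panel: ",
             paste(unique(candidates$gene[is.na(idx)]), collapse = ", "))
  mode <- panel$genes$inheritance_mode[idx]
  ctx <- default_context(n, candidates)
  if ("configuration" %in% names(candidates) &&
      !"in_trans_pathogenic" %in% names(candidates)) {
    chet <- !is.na(candidates$configuration) &
      candidates$configuration == "confirmed_cHET"
    if (any(chet)) {
      lof <- candidates$consequence %in%
        c("stop_gain", "frameshift", "start_loss") |
        (candidates$consequence == "splice_region" &
           !is.na(candidates$splice_offset) &
           abs(candidates$splice_offset) <= 2)
      key <- paste(candidates$patient_id, candidates$gene, sep = "\r")
      lof_per_key <- tapply(lof, key, sum)
      partner_lof <- unname(lof_per_key[key]) - as.integer(lof) > 0
      ctx$in_trans_pathogenic <- chet & partner_lof
    }
  }
  ev <- evidence_batch(candidates, mode, profile, ctx)
  score_cols <- c("PVS1", "PM2", "PM3", "PP3", "BS1", "BS2", "BP4")
  pts <- as.integer(rowSums(ev[score_cols]))
  tier <- ifelse(ev$BA1, "B", classify_points(pts))
  labels <- lapply(score_cols, function(code) {
    ifelse(ev[[code]] != 0,
           paste0(code, "_", strength_label(ev[[code]])), "")
  })
  applied <- trimws(gsub(" +", " ", do.call(paste, labels)))
  applied[ev$BA1] <- "BA1_stand_alone"
  prio <- tier == "VUS" &
    (candidates$consequence %in% c("splice_region", "stop_gain") |
       (candidates$consequence == "missense" & !is.na(candidates$revel) &
          candidates$revel > profile$revel_pathogenic))
  data.frame(patient_id = candidates$patient_id, gene = candidates$gene,
             chrom = candidates$chrom, pos = candidates$pos,
             ref = candidates$ref, alt = candidates$alt,
             profile_id = profile$profile_id, applied = applied,
             points = pts, tier = tier, vus_priority_flag = prio,
             stringsAsFactors = FALSE)
}

#' Export likely-pathogenic/pathogenic rows as a submission-style TSV
#'
#' Writes the LP/P rows of a classification table in a minimal
#' ClinVar-submission-like layout (gene, coordinates, alleles,
#' classification, applied criteria).
#'
#' @param classified Output of [classify_variants()].
#' @param path Output TSV path.
#' @export
export_submission_tsv <- function(classified, path) {
  lp <- classified[classified$tier %in% c("P", "LP"), , drop = FALSE]
  out <- data.frame(
    gene_symbol = lp$gene, chromosome = lp$chrom, position = lp$pos,
    reference_allele = lp$ref, alternate_allele = lp$alt,
    clinical_significance = ifelse(lp$tier == "P", "Pathogenic",
                                   "Likely pathogenic"),
    assertion_criteria = lp$applied, stringsAsFactors = FALSE)
  write_tsv(out, path)
}
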