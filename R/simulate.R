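# Seeded synthetic NOA cohorts. The generator emulates the study
# conditions of a multicentre TESE cohort: 571 men, a 42.4% sperm-retrieval
# rate, the observed histology mix, planted loss-of-function LP/P variants
# enriched among TESE-negative patients at a configurable odds ratio, and
# non-causal variant noise with realistic frequency, depth and
# allele-fraction distributions so that every filter rule is exercised.

#' Simulation configuration
#'
#' Defaults reflect the cohort the package models: 571 patients, sperm
#' retrieval in 42.4%, histology mixed 238:171:143:6 over SCO, MA
#' (maturation arrest), HSG and tubular shadows, a carrier rate of about 2%
#' among TESE-positive men and a planted carrier-versus-outcome odds ratio
#' of 4.
#'
#' @param n_patients Cohort size.
#' @param tese_positive_rate Probability of a positive TESE outcome.
#' @param histology_mix Named probabilities over SCO/MA/HSG/TS (normalised
#'   internally).
#' @param carrier_rate_tese_positive Probability that a TESE-positive
#'   patient carries a planted causal variant.
#' @param planted_or Target odds ratio of carrier status for TESE-negative
#'   versus TESE-positive patients.
#' @param chet_fraction Fraction of recessive-gene carriers planted as
#'   phased compound heterozygotes (two variants sharing a phase group)
#'   rather than homozygotes.
#' @param noise_variants_per_patient Poisson mean of non-causal panel
#'   variants per patient.
#' @param depth_mu,depth_size Negative-binomial read-depth parameters.
#' @param af_zero_mass Probability that a non-causal variant is absent
#'   from the reference population (frequency 0); the remainder draw a
#'   Beta(`af_beta_shape1`, `af_beta_shape2`) tail so that both
#'   rarity-criterion-eligible and frequency-filtered variants arise.
#' @param af_beta_shape1,af_beta_shape2 Beta tail parameters.
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 571L,
                       tese_positive_rate = 0.424,
                       histology_mix = c(SCO = 238, MA = 171,
                                         HSG = 143, TS = 6),
                       carrier_rate_tese_positive = 0.021,
                       planted_or = 4,
                       chet_fraction = 0.15,
                       noise_variants_per_patient = 6,
                       depth_mu = 80, depth_size = 8,
                       af_zero_mass = 0.4,
                       af_beta_shape1 = 0.5, af_beta_shape2 = 60,
                       seed) {
  if (missing(seed) || is.null(seed)) stop_noa("seed is mandatory")
  if (tese_positive_rate < 0 || tese_positive_rate > 1)
    stop_noa("tese_positive_rate must lie in [0, 1]")
  if (any(histology_mix < 0) || sum(histology_mix) <= 0)
    stop_noa("histology_mix must be non-negative with positive sum")
  histology_mix <- histology_mix / sum(histology_mix)
  odds_pos <- carrier_rate_tese_positive / (1 - carrier_rate_tese_positive)
  p_neg <- planted_or * odds_pos / (1 + planted_or * odds_pos)
  if (carrier_rate_tese_positive >= 1 || p_neg >= 1)
    stop_noa(sprintf(
      "planted_or %.3g unreachable at carrier_rate_tese_positive %.3g ",
      planted_or, carrier_rate_tese_positive),
      "(implied TESE-negative carrier probability reaches 1)")
  structure(list(
    n_patients = as.integer(n_patients),
    tese_positive_rate = tese_positive_rate,
    histology_mix = histology_mix,
    carrier_rate_tese_positive = carrier_rate_tese_positive,
    carrier_rate_tese_negative = p_neg,
    planted_or = planted_or,
    chet_fraction = chet_fraction,
    noise_variants_per_patient = noise_variants_per_patient,
    depth_mu = depth_mu, depth_size = depth_size,
    af_zero_mass = af_zero_mass,
    af_beta_shape1 = af_beta_shape1, af_beta_shape2 = af_beta_shape2,
    seed = as.integer(seed)
  ), class = "sim_config")
}

chrom_for <- function(panel_genes, gene) {
  cls <- panel_genes$chromosome_class[match(gene, panel_genes$symbol)]
  ifelse(cls == "X", "X", ifelse(cls == "Y", "Y",
         as.character(1 + (match(gene, sort(unique(gene))) %% 22))))
}

planted_variant_rows <- function(patient_id, gene, mode, cfg, panel_genes) {
  # Guaranteed to pass every filter and to score as LP/P: predicted LoF,
  # absent from reference populations, adequate depth and allele fraction,
  # zygosity matching the gene's inheritance mode.
  n_units <- if (mode == "AR" &&
                 stats::runif(1) < cfg$chet_fraction) 2L else 1L
  zyg <- if (mode == "AR" && n_units == 1L) "hom"
         else if (mode == "AR") "het"
         else if (mode == "AD") "het" else "hemi"
  pos <- sample.int(2e6, n_units) + 1e6
  data.frame(
    patient_id = patient_id, gene = gene,
    chrom = chrom_for(panel_genes, rep(gene, n_units)),
    pos = pos, ref = "C", alt = "T",
    variant_class = "SNV",
    consequence = sample(c("stop_gain", "frameshift"), n_units,
                         replace = TRUE),
    splice_offset = NA_integer_,
    zygosity = zyg,
    depth = 15 + stats::rnbinom(n_units, size = cfg$depth_size,
                                mu = cfg$depth_mu - 15),
    alt_fraction = if (zyg == "het") stats::runif(n_units, 0.3, 0.6)
                   else stats::runif(n_units, 0.9, 1),
    popmax_af = 0, revel = NA_real_, spliceai = NA_real_,
    phase_group = if (n_units == 2L) paste0(patient_id, "_", gene, "_pg")
                  else NA_character_,
    off_panel = FALSE, stringsAsFactors = FALSE
  )
}

noise_variant_rows <- function(patient_ids, cfg, panel_genes) {
  n_per <- stats::rpois(length(patient_ids), cfg$noise_variants_per_patient)
  n <- sum(n_per)
  if (n == 0) return(NULL)
  pid <- rep(patient_ids, n_per)
  gi <- sample.int(nrow(panel_genes), n, replace = TRUE)
  gene <- panel_genes$symbol[gi]
  mode <- panel_genes$inheritance_mode[gi]
  csq <- sample(c("missense", "synonymous", "splice_region", "other",
                  "inframe_indel", "stop_gain", "frameshift"),
                n, replace = TRUE,
                prob = c(0.40, 0.25, 0.15, 0.10, 0.04, 0.04, 0.02))
  splice_offset <- rep(NA_integer_, n)
  is_splice <- csq == "splice_region"
  # offsets 3..8: exercises the splice window without creating canonical
  # (+/-2) loss-of-function sites, which only the planting path produces
  splice_offset[is_splice] <- sample(c(-(8:3), 3:8), sum(is_splice),
                                     replace = TRUE)
  af <- ifelse(stats::runif(n) < cfg$af_zero_mass, 0,
               stats::rbeta(n, cfg$af_beta_shape1, cfg$af_beta_shape2))
  # standing loss-of-function variation in these genes survives in the
  # population only at appreciable frequency; draw it above every ceiling
  is_lof <- csq %in% c("stop_gain", "frameshift")
  af[is_lof] <- stats::runif(sum(is_lof), 0.02, 0.2)
  sex_linked <- mode %in% c("XL", "YL")
  zyg <- ifelse(sex_linked,
                ifelse(stats::runif(n) < 0.95, "hemi", "het"),
                ifelse(stats::runif(n) < 0.92, "het", "hom"))
  depth <- stats::rnbinom(n, size = cfg$depth_size, mu = cfg$depth_mu)
  low_depth <- stats::runif(n) < 0.05
  depth[low_depth] <- sample(0:9, sum(low_depth), replace = TRUE)
  alt_fraction <- ifelse(zyg == "het", stats::rbeta(n, 20, 20),
                         stats::rbeta(n, 40, 3))
  low_af <- stats::runif(n) < 0.07
  alt_fraction[low_af] <- stats::rbeta(sum(low_af), 1.5, 15)
  revel <- ifelse(csq == "missense", stats::rbeta(n, 2, 2), NA_real_)
  spliceai <- ifelse(is_splice, stats::rbeta(n, 1, 10), NA_real_)
  data.frame(
    patient_id = pid, gene = gene,
    chrom = chrom_for(panel_genes, gene),
    pos = sample.int(2e6, n, replace = TRUE),
    ref = "G", alt = "A", variant_class = "SNV",
    consequence = csq, splice_offset = splice_offset, zygosity = zyg,
    depth = depth, alt_fraction = pmin(alt_fraction, 1),
    popmax_af = pmin(af, 1), revel = revel, spliceai = spliceai,
    phase_group = NA_character_, off_panel = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Generate a seeded synthetic NOA cohort
#'
#' Draws phenotypes, plants causal variants (predicted loss of function,
#' absent from reference populations, zygosity matched to the gene's
#' inheritance mode; compound heterozygotes carry a shared phase group)
#' with a TESE-outcome enrichment at the configured odds ratio, and adds
#' non-causal noise variants whose frequency, depth and allele-fraction
#' distributions make a fraction fail each filter rule. Identical seeds
#' give identical cohorts.
#'
#' @param cfg `sim_config`.
#' @param panel `panel_index`.
#' @return List: `patients` (phenotype table), `variants` (variant table),
#'   `truth` (one row per planted variant: `patient_id`, `gene`,
#'   `variant_key`, `planted_tier`), `config`.
#' @export
generate_cohort <- function(cfg, panel) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "panel_index"))
  if (nrow(panel$genes) == 0) stop_noa("panel is empty")
  set.seed(cfg$seed)
  n <- cfg$n_patients
  empty_truth <- data.frame(patient_id = character(), gene = character(),
                            variant_key = character(),
                            planted_tier = character(),
                            stringsAsFactors = FALSE)
  if (n == 0) {
    return(list(patients = data.frame(), variants = data.frame(),
                truth = empty_truth, config = cfg))
  }
  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    sex_chromosomes = "XY",
    tese_outcome = ifelse(stats::runif(n) < cfg$tese_positive_rate,
                          "positive", "negative"),
    histology = sample(names(cfg$histology_mix), n, replace = TRUE,
                       prob = cfg$histology_mix),
    centre = sample(c("Barcelona", "Newcastle_Nijmegen", "Doha"), n,
                    replace = TRUE),
    consanguinity_region = stats::runif(n) < 0.3,
    stringsAsFactors = FALSE
  )
  p_carrier <- ifelse(patients$tese_outcome == "positive",
                      cfg$carrier_rate_tese_positive,
                      cfg$carrier_rate_tese_negative)
  carrier <- stats::runif(n) < p_carrier
  planted <- NULL
  truth <- empty_truth
  if (any(carrier)) {
    ids <- patients$patient_id[carrier]
    genes <- sample(panel$genes$symbol, length(ids), replace = TRUE)
    modes <- panel$genes$inheritance_mode[match(genes, panel$genes$symbol)]
    planted <- do.call(rbind, lapply(seq_along(ids), function(i) {
      planted_variant_rows(ids[i], genes[i], modes[i], cfg, panel$genes)
    }))
    truth <- data.frame(
      patient_id = planted$patient_id, gene = planted$gene,
      variant_key = paste(planted$gene, planted$pos, sep = ":"),
      planted_tier = "LP", stringsAsFactors = FALSE)
  }
  noise <- noise_variant_rows(patients$patient_id, cfg, panel$genes)
  variants <- rbind(planted, noise)
  if (is.null(variants)) {
    variants <- variant_table(data.frame(
      patient_id = character(), gene = character(),
      consequence = character(), zygosity = character(),
      stringsAsFactors = FALSE))
  } else {
    variants <- variant_table(variants, panel = panel)
  }
  list(patients = patients, variants = variants, truth = truth,
       config = cfg)
}

#' Patient-level fixture reproducing the printed cohort contingency counts
#'
#' Builds, deterministically, a 571-patient table whose marginal counts
#' reproduce the published cohort summary exactly: TESE outcome split
#' 329 negative / 242 positive; LP/P carriers 53/11 (negative/positive)
#' under classification profile I and 30/5 under profile II; histology
#' strata of 238 SCO, 171 MA, 143 HSG, 6 TS and 13 unknown with profile
#' carriers 22/34/8 (I) and 11/20/4 (II) in SCO/MA/HSG. The joint
#' distribution of outcome, histology and carrier status within those
#' margins is not published; the expansion fixes one consistent assignment
#' (profile II carriers nested within profile I carriers). Re-tabulating
#' the expansion reproduces the contingency tables cell for cell.
#'
#' @return List: `patients` (phenotype table), `classifications`
#'   (`patient_id`, `profile_id`, `tier`), `tables` (named 2x2 matrices:
#'   `outcome_I`, `outcome_II` with rows negative/positive and columns
#'   carrier/non-carrier).
#' @export
make_table1_fixture <- function() {
  # per histology stratum: total, TESE-negative total, profile-I carriers
  # (neg, pos), profile-II carriers (neg, pos; nested in profile I)
  strata <- list(
    MA      = list(total = 171, neg = 100, cI = c(28, 6), cII = c(17, 3)),
    SCO     = list(total = 238, neg = 140, cI = c(18, 4), cII = c(10, 1)),
    HSG     = list(total = 143, neg = 75,  cI = c(7, 1),  cII = c(3, 1)),
    TS      = list(total = 6,   neg = 4,   cI = c(0, 0),  cII = c(0, 0)),
    unknown = list(total = 13,  neg = 10,  cI = c(0, 0),  cII = c(0, 0))
  )
  rows <- list()
  k <- 0L
  for (h in names(strata)) {
    s <- strata[[h]]
    for (outcome in c("negative", "positive")) {
      n_out <- if (outcome == "negative") s$neg else s$total - s$neg
      i_out <- if (outcome == "negative") 1L else 2L
      n_cII <- s$cII[i_out]
      n_cI <- s$cI[i_out]
      flags_I <- rep(c(TRUE, FALSE), c(n_cI, n_out - n_cI))
      flags_II <- rep(c(TRUE, FALSE), c(n_cII, n_out - n_cII))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("T1_%04d", k + seq_len(n_out)),
        sex_chromosomes = "XY", tese_outcome = outcome, histology = h,
        centre = NA_character_, consanguinity_region = FALSE,
        carrier_I = flags_I, carrier_II = flags_II,
        stringsAsFactors = FALSE)
      k <- k + n_out
    }
  }
  patients <- do.call(rbind, rows)
  classifications <- rbind(
    data.frame(patient_id = patients$patient_id[patients$carrier_I],
               profile_id = "I", tier = "LP", stringsAsFactors = FALSE),
    data.frame(patient_id = patients$patient_id[patients$carrier_II],
               profile_id = "II", tier = "LP", stringsAsFactors = FALSE)
  )
  tab <- function(flag) {
    neg <- patients$tese_outcome == "negative"
    matrix(c(sum(flag & neg), sum(!flag & neg),
             sum(flag & !neg), sum(!flag & !neg)),
           nrow = 2, byrow = TRUE,
           dimnames = list(c("negative", "positive"),
                           c("carrier", "non_carrier")))
  }
  list(
    patients = patients[, c("patient_id", "sex_chromosomes", "tese_outcome",
                            "histology", "centre", "consanguinity_region")],
    carrier_flags = patients[, c("patient_id", "carrier_I", "carrier_II")],
    classifications = classifications,
    tables = list(outcome_I = tab(patients$carrier_I),
                  outcome_II = tab(patients$carrier_II))
  )
}
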