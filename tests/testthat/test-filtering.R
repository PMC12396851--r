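mkvar <- function(patient, gene, csq, zyg, af = 0, depth = 30,
                  frac = 0.9, offset = NA_integer_, pg = NA_character_) {
  data.frame(patient_id = patient, gene = gene, chrom = NA_character_,
             pos = NA_integer_, ref = "A", alt = "G",
             variant_class = "SNV", consequence = csq,
             splice_offset = offset, zygosity = zyg, depth = depth,
             alt_fraction = frac, popmax_af = af, revel = NA_real_,
             spliceai = NA_real_, phase_group = pg, off_panel = FALSE,
             stringsAsFactors = FALSE)
}

test_that("consequence filter keeps the non-synonymous window", {
  t <- filter_thresholds()
  expect_false(consequence_filter(mkvar("P", "G", "synonymous", "hom"), t))
  expect_true(consequence_filter(mkvar("P", "G", "missense", "hom"), t))
  expect_true(consequence_filter(
    mkvar("P", "G", "splice_region", "hom", offset = 3L), t))
  expect_false(consequence_filter(
    mkvar("P", "G", "splice_region", "hom", offset = 4L), t))
  expect_true(consequence_filter(
    mkvar("P", "G", "splice_region", "hom", offset = -3L), t))
  expect_error(consequence_filter(
    mkvar("P", "G", "splice_region", "hom"), t), "splice_offset")
})

test_that("frequency filter applies mode-specific inclusive ceilings", {
  t <- filter_thresholds()
  v <- function(af) mkvar("P", "G", "missense", "hom", af = af)
  expect_true(frequency_filter(v(0.009), "AR", t))
  expect_false(frequency_filter(v(0.011), "AR", t))
  expect_true(frequency_filter(v(0.01), "AR", t))    # boundary kept
  expect_true(frequency_filter(v(0.0009), "XL", t))
  expect_false(frequency_filter(v(0.002), "XL", t))
  expect_true(frequency_filter(v(0.001), "AD", t))   # boundary kept
})

test_that("QC filter enforces depth and allele-fraction floors", {
  t <- filter_thresholds()
  qc <- qc_filter(rbind(
    mkvar("P", "G", "missense", "hom", depth = 9, frac = 0.5),
    mkvar("P", "G", "missense", "hom", depth = 30, frac = 0.14),
    mkvar("P", "G", "missense", "hom", depth = 10, frac = 0.15)), t)
  expect_equal(qc$depth_ok, c(FALSE, TRUE, TRUE))
  expect_equal(qc$alt_fraction_ok, c(TRUE, FALSE, TRUE))
})

test_that("inheritance consistency encodes mode expectations", {
  # single heterozygous variant in a recessive gene: no genotype consistent
  # with disease
  single <- mkvar("P", "GENE_AR1", "missense", "het")
  res <- inheritance_consistency(single, "AR")
  expect_false(any(res$keep))

  # two heterozygous variants sharing a phase group: confirmed in trans
  pair <- rbind(mkvar("P", "GENE_AR1", "missense", "het", pg = "pg1"),
                mkvar("P", "GENE_AR1", "frameshift", "het", pg = "pg1"))
  res <- inheritance_consistency(pair, "AR")
  expect_true(all(res$keep))
  expect_equal(res$configuration, "confirmed_cHET")

  # without shared phase: candidate compound heterozygote
  pair$phase_group <- NA_character_
  expect_equal(inheritance_consistency(pair, "AR")$configuration,
               "candidate_cHET")

  # a heterozygous-deletion partner rescues a lone recessive het
  res <- inheritance_consistency(single, "AR", n_cnv_partners = 1L)
  expect_true(all(res$keep))
  expect_equal(res$configuration, "confirmed_cHET")

  hemi <- mkvar("P", "GENE_XL1", "missense", "hemi")
  expect_true(inheritance_consistency(hemi, "XL")$keep)

  het_x <- mkvar("P", "GENE_XL1", "missense", "het")
  expect_warning(res <- inheritance_consistency(het_x, "XL"),
                 "inconsistent")
  expect_false(res$keep)

  expect_error(inheritance_consistency(
    mkvar("P", "GENE_YL1", "missense", "hemi"), "YL",
    sex_chromosomes = "other"), "without a Y chromosome")

  expect_true(all(inheritance_consistency(
    rbind(mkvar("P", "GENE_AD1", "missense", "het"),
          mkvar("P", "GENE_AD1", "missense", "hom")), "AD")$keep))
})

test_that("CNV deletions are filtered on zygosity, recurrence and frequency", {
  cnv <- function(state, carriers = 1, sv_af = 0) {
    cnv_table(data.frame(patient_id = "P", gene = "G", copy_state = state,
                         breakpoint_start = 1, breakpoint_end = 1000,
                         n_unrelated_carriers_same_breakpoints = carriers,
                         sv_af = sv_af, stringsAsFactors = FALSE))
  }
  expect_true(cnv_filter(cnv("hom_del", sv_af = 0.005), "AR")$kept)
  expect_true(cnv_filter(cnv("het_del"), "AR", has_partner = TRUE)$kept)
  expect_false(cnv_filter(cnv("het_del"), "AR", has_partner = FALSE)$kept)
  res <- cnv_filter(cnv("hom_del", carriers = 11), "AR")
  expect_false(res$kept)
  expect_match(res$failed_rules, "cnv_recurrence")
  expect_false(cnv_filter(cnv("hom_del", sv_af = 0.01), "AR")$kept)
  expect_true(cnv_filter(cnv("hom_del", sv_af = 0.005), "AR")$kept)
  expect_false(cnv_filter(cnv("hom_del", sv_af = 0.005), "XL")$kept)
})

# 20-variant fixture with the kept set derived by hand from the rule
# definitions (7 survivors).
twenty_variant_fixture <- function() {
  rbind(
    mkvar("P1", "GENE_AR1", "stop_gain", "hom"),                    # keep
    mkvar("P1", "GENE_AR1", "synonymous", "hom"),                   # consequence
    mkvar("P1", "GENE_XL1", "missense", "hemi"),                    # keep
    mkvar("P1", "GENE_XL1", "missense", "het"),                     # inheritance
    mkvar("P1", "GENE_AD1", "missense", "het", af = 0.0009),        # keep
    mkvar("P1", "GENE_AD1", "missense", "het", af = 0.002),         # frequency
    mkvar("P2", "GENE_AR1", "missense", "het", frac = 0.4,
          pg = "pg1"),                                              # keep (cHET)
    mkvar("P2", "GENE_AR1", "frameshift", "het", frac = 0.4,
          pg = "pg1"),                                              # keep (cHET)
    mkvar("P2", "GENE_AR2", "missense", "het"),                     # inheritance
    mkvar("P4", "GENE_AR1", "splice_region", "hom", offset = 3L),   # keep
    mkvar("P4", "GENE_AR1", "splice_region", "hom", offset = 4L),   # consequence
    mkvar("P3", "GENE_AR1", "missense", "hom", af = 0.009),         # keep
    mkvar("P3", "GENE_AR1", "missense", "hom", af = 0.011),         # frequency
    mkvar("P3", "GENE_AR1", "missense", "hom", depth = 9),          # depth
    mkvar("P3", "GENE_AR1", "missense", "hom", frac = 0.14),        # alt_fraction
    mkvar("P3", "GENE_YL1", "missense", "het"),                     # inheritance
    mkvar("P3", "GENE_AD1", "synonymous", "het"),                   # consequence
    mkvar("P4", "GENE_AR2", "other", "hom"),                        # consequence
    mkvar("P4", "GENE_XL1", "missense", "hemi", af = 0.002),        # frequency
    mkvar("P4", "GENE_AR1", "missense", "het", depth = 5,
          frac = 0.1)                                               # depth+frac
  )
}

test_that("the filtration cascade reproduces the hand-derived kept set", {
  panel <- toy_panel()
  v <- twenty_variant_fixture()
  res <- suppressWarnings(run_filters(v, panel))
  expect_equal(sum(res$decisions$kept), 7)
  expect_equal(unname(res$tally[c("consequence", "frequency", "depth",
                                  "alt_fraction", "inheritance", "kept")]),
               c(4L, 3L, 2L, 2L, 3L, 7L))
  # every dropped variant names at least one failed rule; kept name none
  expect_true(all(nzchar(res$decisions$failed_rules[!res$decisions$kept])))
  expect_true(all(!nzchar(res$decisions$failed_rules[res$decisions$kept])))
  # the compound-het pair is recognised as confirmed in trans
  chet <- res$candidates[res$candidates$patient_id == "P2", ]
  expect_equal(unique(chet$configuration), "confirmed_cHET")

  # idempotence / determinism
  res2 <- suppressWarnings(run_filters(v, panel))
  expect_identical(res$decisions, res2$decisions)
})

test_that("an empty variant set yields empty candidates and zero tallies", {
  panel <- toy_panel()
  v <- twenty_variant_fixture()[0, ]
  res <- run_filters(v, panel)
  expect_equal(nrow(res$candidates), 0)
  expect_true(all(res$tally == 0))
})

test_that("heterozygous deletions pair with sequence variants for cHET", {
  panel <- toy_panel()
  v <- mkvar("P1", "GENE_AR1", "missense", "het")
  cnvs <- data.frame(patient_id = "P1", gene = "GENE_AR1",
                     copy_state = "het_del", breakpoint_start = 1,
                     breakpoint_end = 5000,
                     n_unrelated_carriers_same_breakpoints = 1, sv_af = 0,
                     stringsAsFactors = FALSE)
  res <- run_filters(v, panel, cnvs = cnvs)
  expect_true(all(res$decisions$kept))
  expect_equal(res$decisions$configuration, "confirmed_cHET")
  expect_true(res$cnv_decisions$kept)
})

test_that("the cascade matches the brute-force oracle on random variants", {
  panel <- toy_panel()
  for (seed in 1:5) {
    v <- random_variants(200, panel, seed = seed)
    res <- suppressWarnings(run_filters(v, panel))
    expect_equal(res$decisions$kept, oracle_filter_kept(v, panel),
                 info = paste("seed", seed))
  }
})

test_that("tightening any threshold never increases the kept set", {
  panel <- toy_panel()
  v <- random_variants(300, panel, seed = 99)
  base <- sum(suppressWarnings(run_filters(v, panel))$decisions$kept)
  tighter <- list(
    filter_thresholds(maf_recessive = 0.001, maf_dominant_sexlinked = 1e-4),
    filter_thresholds(min_depth = 25),
    filter_thresholds(min_alt_fraction = 0.3),
    filter_thresholds(splice_window = 1)
  )
  for (t in tighter) {
    expect_lte(sum(suppressWarnings(
      run_filters(v, panel, thresholds = t))$decisions$kept), base)
  }
})

test_that("threshold configs reject inconsistent values", {
  expect_error(filter_thresholds(min_depth = -1), "positive")
  expect_error(filter_thresholds(maf_recessive = 0.0005),
               "cannot exceed")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("min_depth: 20", "min_alt_fraction: 0.2"), path)
  t <- read_thresholds(path)
  expect_equal(t$min_depth, 20)
  expect_equal(t$maf_recessive, 0.01)
  writeLines("not_a_key: 1", path)
  expect_error(read_thresholds(path), "unknown threshold key")
})
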