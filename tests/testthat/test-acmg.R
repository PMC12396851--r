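mk_candidate <- function(csq = "stop_gain", af = 0, revel = NA_real_,
                         spliceai = NA_real_, offset = NA_integer_,
                         zyg = "hom", gene = "GENE_AR1") {
  data.frame(patient_id = "P1", gene = gene, chrom = "1", pos = 100L,
             ref = "C", alt = "T", variant_class = "SNV",
             consequence = csq, splice_offset = offset, zygosity = zyg,
             depth = 50, alt_fraction = 0.5, popmax_af = af,
             revel = revel, spliceai = spliceai,
             phase_group = NA_character_, off_panel = FALSE,
             stringsAsFactors = FALSE)
}

ar_gene <- function() {
  g <- toy_panel()$genes
  g[g$symbol == "GENE_AR1", ]
}

test_that("strength points follow the scaled point system", {
  expect_equal(strength_points("very_strong", "pathogenic"), 8L)
  expect_equal(strength_points("strong", "pathogenic"), 4L)
  expect_equal(strength_points("moderate", "pathogenic"), 2L)
  expect_equal(strength_points("supporting", "pathogenic"), 1L)
  expect_equal(strength_points("supporting", "benign"), -1L)
  expect_equal(strength_points("strong", "benign"), -4L)
  expect_error(strength_points("stand_alone"), "categorically")
})

test_that("point bands assign the five printed tiers", {
  expect_equal(classify_points(10), "P")
  expect_equal(classify_points(9), "LP")
  expect_equal(classify_points(6), "LP")
  expect_equal(classify_points(5), "VUS")
  expect_equal(classify_points(0), "VUS")
  expect_equal(classify_points(-1), "LB")
  expect_equal(classify_points(-6), "LB")
  expect_equal(classify_points(-7), "B")
  expect_error(classify_points(1.5), "integers")
})

test_that("maximum credible allele frequency follows the closed forms", {
  expect_equal(max_credible_af(0.01, 0.05, "AR"), sqrt(5e-4),
               tolerance = 1e-12)
  expect_equal(max_credible_af(0.01, 0.01, "AD"), 5e-5, tolerance = 1e-12)
  expect_equal(max_credible_af(0.01, 0.01, "XL"), 1e-4, tolerance = 1e-12)
  # degenerate upper bound dominates any observable frequency
  expect_gte(max_credible_af(1, 1, "AR"), 1)
  expect_error(max_credible_af(0, 0.05, "AR"), "\\(0, 1\\]")
  # halving penetrance raises every threshold
  expect_gt(max_credible_af(0.01, 0.01, "AD", penetrance = 0.5),
            max_credible_af(0.01, 0.01, "AD"))
})

test_that("evidence assignment reproduces the canonical rule outcomes", {
  gene <- ar_gene()
  # rare loss of function under the stringent profile: PVS1 + PM2(supporting)
  res <- classify_variant(mk_candidate("stop_gain"), gene, "II")
  expect_setequal(res$applied$code, c("PVS1", "PM2"))
  expect_equal(res$points, 9L)
  expect_equal(res$tier, "LP")

  # same variant under the literature profile: PM2 at moderate -> P
  res_I <- classify_variant(mk_candidate("stop_gain"), gene, "I")
  expect_equal(res_I$points, 10L)
  expect_equal(res_I$tier, "P")

  # rare missense with high REVEL: PP3 + PM2 only -> VUS
  res <- classify_variant(mk_candidate("missense", revel = 0.7), gene, "II")
  expect_setequal(res$applied$code, c("PM2", "PP3"))
  expect_equal(res$points, 2L)
  expect_equal(res$tier, "VUS")

  # stand-alone benign frequency trumps everything
  res <- classify_variant(mk_candidate("stop_gain", af = 0.5), gene, "II")
  expect_equal(res$applied$code, "BA1")
  expect_equal(res$tier, "B")

  # frequency between the rarity and stand-alone ceilings: BS1
  thr <- rule_profile("II")
  af_mid <- mean(c(thr$pm2_af[["AR"]], thr$ba1_af[["AR"]]))
  res <- classify_variant(mk_candidate("missense", af = af_mid), gene, "II")
  expect_true("BS1" %in% res$applied$code)
  expect_false("PM2" %in% res$applied$code)

  # disease-consistent genotype in healthy controls: BS2
  res <- classify_variant(mk_candidate("missense"), gene, "II",
                          context = list(control_genotype_count = 2L))
  expect_true("BS2" %in% res$applied$code)

  # confirmed in-trans partner in a recessive gene: PM3
  res <- classify_variant(mk_candidate("frameshift", zyg = "het"), gene,
                          "II", context = list(in_trans_pathogenic = TRUE))
  expect_true("PM3" %in% res$applied$code)
  expect_equal(res$points, 11L)  # PVS1 8 + PM3 2 + PM2 1
  expect_equal(res$tier, "P")

  # PM3 context on a dominant gene is contradictory and reported
  ad_gene <- toy_panel()$genes[toy_panel()$genes$symbol == "GENE_AD1", ]
  expect_warning(
    classify_variant(mk_candidate("missense", gene = "GENE_AD1",
                                  zyg = "het"), ad_gene, "II",
                     context = list(in_trans_pathogenic = TRUE)),
    "non-recessive")

  # both in-silico scores low: BP4
  res <- classify_variant(mk_candidate("missense", revel = 0.1,
                                       spliceai = 0.05), gene, "II")
  expect_true("BP4" %in% res$applied$code)

  # last-exon truncation downgrades PVS1 to strong
  res <- classify_variant(mk_candidate("stop_gain"), gene, "II",
                          context = list(last_exon = TRUE))
  expect_equal(res$applied$points[res$applied$code == "PVS1"], 4L)
})

test_that("explicit context criteria combine with the point system", {
  gene <- ar_gene()
  # rare LoF plus strong in-trans evidence supplied via context:
  # PVS1 (8) + PM2 supporting (1) + PM3 at strong (4) -> 13 -> P
  res <- classify_variant(
    mk_candidate("stop_gain"), gene,
    rule_profile("II", pm2_strength = "supporting"),
    context = list(extra = data.frame(code = "PM3", strength = "strong",
                                      direction = "pathogenic")))
  expect_equal(res$points, 13L)  # 8 + 1 + 4
  expect_equal(res$tier, "P")

  # no evidence at all: 0 points, VUS
  res <- classify_variant(mk_candidate("other",
                                       af = rule_profile("II")$pm2_af[["AR"]]),
                          gene, "II")
  expect_equal(nrow(res$applied), 1)  # BS1 at the boundary
  res2 <- classify_variant(mk_candidate("other"), gene,
                           rule_profile("II", pm2_strength = "supporting"))
  expect_equal(res2$applied$code, "PM2")

  # a second very-strong criterion is capped to strong
  expect_warning(
    res <- classify_variant(
      mk_candidate("stop_gain"), gene, "II",
      context = list(extra = data.frame(code = "PS3",
                                        strength = "very_strong",
                                        direction = "pathogenic"))),
    "capped")
  expect_equal(res$points, 8L + 1L + 4L)
})

test_that("classification equals a subset-enumeration oracle", {
  # pool of context-supplied criteria; the variant itself triggers only PM2
  pool <- data.frame(
    code = c("PS1", "PM1", "PP1", "BS3", "BP7"),
    strength = c("strong", "moderate", "supporting", "strong", "supporting"),
    direction = c("pathogenic", "pathogenic", "pathogenic", "benign",
                  "benign"), stringsAsFactors = FALSE)
  value <- c(4L, 2L, 1L, -4L, -1L)  # oracle's own strength map
  gene <- ar_gene()
  profile <- rule_profile("II")
  pm2_pts <- 1L
  oracle_band <- function(p) {
    if (p >= 10) "P" else if (p >= 6) "LP" else if (p >= 0) "VUS"
    else if (p >= -6) "LB" else "B"
  }
  set.seed(42)
  for (size in 0:5) {
    combos <- utils::combn(5, max(size, 1), simplify = FALSE)
    if (size == 0) combos <- list(integer(0))
    for (sel in combos) {
      res <- classify_variant(mk_candidate("other"), gene, profile,
                              context = list(extra = pool[sel, , drop = FALSE]))
      expected_points <- sum(value[sel]) + pm2_pts
      expect_equal(res$points, expected_points)
      expect_equal(res$tier, oracle_band(expected_points))
    }
  }
})

test_that("evidence monotonicity: benign never raises, pathogenic never lowers", {
  gene <- ar_gene()
  profile <- rule_profile("II")
  tier_rank <- function(t) match(t, c("B", "LB", "VUS", "LP", "P"))
  base <- classify_variant(mk_candidate("stop_gain"), gene, profile)
  plus_benign <- classify_variant(
    mk_candidate("stop_gain"), gene, profile,
    context = list(extra = data.frame(code = "BS3", strength = "strong",
                                      direction = "benign")))
  expect_lte(tier_rank(plus_benign$tier), tier_rank(base$tier))
  plus_path <- classify_variant(
    mk_candidate("stop_gain"), gene, profile,
    context = list(extra = data.frame(code = "PM1", strength = "moderate",
                                      direction = "pathogenic")))
  expect_gte(tier_rank(plus_path$tier), tier_rank(base$tier))
})

test_that("priority VUS flagging covers the four follow-up categories", {
  gene <- ar_gene()
  v_mis <- mk_candidate("missense", revel = 0.65)
  expect_true(flag_priority_vus("VUS", v_mis))
  expect_false(flag_priority_vus("VUS", mk_candidate("missense",
                                                     revel = 0.2)))
  expect_true(flag_priority_vus("VUS", mk_candidate("stop_gain")))
  expect_true(flag_priority_vus("VUS", mk_candidate("splice_region",
                                                    offset = 5L)))
  expect_true(flag_priority_vus("VUS", mk_candidate("frameshift"),
                                protein_fraction_removed = 0.05,
                                affects_domain = FALSE))
  expect_false(flag_priority_vus("VUS", mk_candidate("frameshift"),
                                 protein_fraction_removed = 0.5,
                                 affects_domain = FALSE))
  expect_false(flag_priority_vus("VUS", mk_candidate("frameshift")))
  expect_false(flag_priority_vus("LP", v_mis))  # only VUS are flagged
})

test_that("batch classification agrees with the single-variant path", {
  panel <- toy_panel()
  v <- rbind(mk_candidate("stop_gain"),
             mk_candidate("missense", revel = 0.7),
             mk_candidate("missense", af = 0.5),
             mk_candidate("synonymous", revel = 0.1, spliceai = 0.01))
  for (pid in c("I", "II")) {
    batch <- classify_variants(v, panel, pid)
    for (i in seq_len(nrow(v))) {
      single <- classify_variant(v[i, ], ar_gene(), pid)
      expect_equal(batch$points[i], single$points)
      expect_equal(batch$tier[i], single$tier)
    }
  }
})

test_that("rule profiles load from the shipped YAML tables", {
  p1 <- read_rule_profile(system.file("extdata", "profile_I.yaml",
                                      package = "noapanel"))
  p2 <- read_rule_profile(system.file("extdata", "profile_II.yaml",
                                      package = "noapanel"))
  expect_equal(p1$pm2_strength, "moderate")
  expect_equal(p2$pm2_strength, "supporting")
  expect_identical(unclass(p1)[setdiff(names(p1),
                                       c("profile_id", "pm2_strength"))],
                   unclass(p2)[setdiff(names(p2),
                                       c("profile_id", "pm2_strength"))])
})
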