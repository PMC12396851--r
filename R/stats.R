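# Cohort-level genotype-phenotype association statistics: diagnostic
# yields, Wald odds ratios, exact binomial tests and Bonferroni-adjusted
# pairwise chi-square comparisons across TESE-outcome and histology strata.

#' Diagnostic yield as a percentage
#'
#' @param carriers Number of carriers (0 <= carriers <= total).
#' @param total Stratum size (> 0).
#' @param digits Decimals to report (default 2; prose summaries in the
#'   field typically use 1).
#' @return Percentage, rounded to `digits`.
#' @examples
#' diagnostic_yield(53, 329)      # 16.11
#' diagnostic_yield(35, 571, 1)   # 6.1
#' @export
diagnostic_yield <- function(carriers, total, digits = 2) {
  if (any(total <= 0)) stop_noa("total must be positive")
  if (any(carriers < 0 | carriers > total))
    stop_noa("carriers must lie in [0, total]")
  round(100 * carriers / total, digits)
}

#' Wald odds ratio with 95% confidence interval
#'
#' For a 2x2 table with cells `a`, `b` (row 1) and `c`, `d` (row 2), the
#' odds ratio is the cross product `(a*d)/(b*c)` and the confidence
#' interval is computed on the log scale as
#' `ln(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d)`.
#' Zero cells are an error unless the Haldane-Anscombe correction (adding
#' 0.5 to every cell) is explicitly requested — the correction is never
#' applied silently.
#'
#' @param a,b,c,d Cell counts, or `a` may be a 2x2 matrix.
#' @param haldane Apply the 0.5-per-cell correction (default FALSE).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `or`, `ci_low`, `ci_high`, `haldane`.
#' @examples
#' wald_or(53, 276, 11, 231)  # OR ~4.03
#' @export
wald_or <- function(a, b = NULL, c = NULL, d = NULL, haldane = FALSE,
                    conf_level = 0.95) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop_noa("cell counts must be non-negative")
  if (any(cells == 0) && !haldane)
    stop_noa("zero cell in 2x2 table; request the Haldane-Anscombe ",
             "correction explicitly (haldane = TRUE)")
  if (haldane) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se), haldane = haldane)
}

#' Exact binomial test (two-sided, minimum-likelihood method)
#'
#' Exact two-sided p-value: the sum of the probabilities of all outcomes no
#' more likely than the observed one under the null proportion `p0`. The
#' default null `p0 = 0.5` encodes "carriers are equally likely to be
#' TESE-positive or TESE-negative".
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null proportion in (0, 1).
#' @param alternative Only `"two_sided"` is offered (the study design is
#'   two-sided).
#' @return p-value.
#' @examples
#' binomial_exact(10, 10)  # ~0.00195
#' @export
binomial_exact <- function(k, n, p0 = 0.5, alternative = "two_sided") {
  if (p0 <= 0 || p0 >= 1) stop_noa("p0 must lie in (0, 1)")
  if (k < 0 || k > n) stop_noa("k must lie in [0, n]")
  stopifnot(identical(alternative, "two_sided"))
  stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}

#' Pairwise chi-square tests with Bonferroni adjustment
#'
#' One chi-square test (df = 1, Yates continuity correction on by default)
#' per 2x2 table, with p-values multiplied by the number of comparisons and
#' capped at 1. Emits a warning recommending an exact test when any
#' expected cell count falls below 1.
#'
#' @param tables Named list of 2x2 matrices (e.g. the three histology
#'   pairs MA/SCO, MA/HSG, SCO/HSG).
#' @param yates Continuity correction (default TRUE).
#' @param m Number of comparisons for the Bonferroni factor (default
#'   `length(tables)`).
#' @return data.frame: `comparison`, `statistic`, `p_raw`, `p_adjusted`.
#' @export
chisq_pairwise <- function(tables, yates = TRUE, m = length(tables)) {
  if (is.matrix(tables)) tables <- list(tables)
  res <- lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    stopifnot(is.matrix(tab), all(dim(tab) == 2))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1))
      warning("expected cell count below 1; an exact test is recommended",
              call. = FALSE)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
    data.frame(comparison = names(tables)[i] %||% paste0("pair", i),
               statistic = unname(ct$statistic), p_raw = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, m * out$p_raw)
  out
}

#' Cohort carrier summary with association statistics
#'
#' Tabulates carriers of likely-pathogenic/pathogenic variants against
#' TESE outcome and testis histology and computes, per classification
#' profile: diagnostic yields by stratum, the Wald odds ratio of carrying
#' an LP/P variant given a negative versus positive TESE outcome, the
#' two-sided exact binomial test on the carriers' outcome split, and
#' Bonferroni-adjusted pairwise chi-square comparisons across the MA, SCO
#' and HSG histology strata.
#'
#' @param patients Phenotype table (one row per patient; see
#'   [read_phenotypes()]).
#' @param classifications data.frame with columns `patient_id`,
#'   `profile_id`, `tier` (one row per classified variant; a patient is a
#'   carrier under a profile when at least one row has tier `P` or `LP`).
#' @param binomial_null `"half"` (default; carriers equally likely in
#'   either outcome) or `"cohort"` (null = the cohort's TESE-negative
#'   proportion).
#' @param haldane Apply the Haldane-Anscombe correction to the odds ratio
#'   when a cell is empty (opt-in, never silent).
#' @return List of class `noa_cohort_summary`: `retrieval_rate_pct`,
#'   `n_patients` and one entry per profile with the outcome table, yields,
#'   odds ratio, binomial p and the histology comparison table.
#' @export
cohort_summary <- function(patients, classifications,
                           binomial_null = c("half", "cohort"),
                           haldane = FALSE) {
  binomial_null <- match.arg(binomial_null)
  orphan <- setdiff(unique(classifications$patient_id), patients$patient_id)
  if (length(orphan))
    stop_noa("classification refers to patient(s) missing from the ",
             "phenotype table: ", paste(orphan, collapse = ", "))
  n <- nrow(patients)
  n_neg <- sum(patients$tese_outcome == "negative")
  n_pos <- n - n_neg
  out <- list(n_patients = n,
              retrieval_rate_pct = diagnostic_yield(n_pos, n, 1))

  for (pid in sort(unique(classifications$profile_id))) {
    cls <- classifications[classifications$profile_id == pid, , drop = FALSE]
    carrier_ids <- unique(cls$patient_id[cls$tier %in% c("P", "LP")])
    is_carrier <- patients$patient_id %in% carrier_ids
    neg <- patients$tese_outcome == "negative"
    a <- sum(is_carrier & neg); b <- sum(!is_carrier & neg)
    cc <- sum(is_carrier & !neg); dd <- sum(!is_carrier & !neg)
    outcome_table <- matrix(c(a, b, cc, dd), nrow = 2, byrow = TRUE,
                            dimnames = list(c("negative", "positive"),
                                            c("carrier", "non_carrier")))
    or <- if (all(outcome_table > 0) || haldane) {
      wald_or(a, b, cc, dd, haldane = haldane && any(outcome_table == 0))
    } else {
      list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           haldane = FALSE, note = "zero cell; odds ratio undefined")
    }
    n_carriers <- a + cc
    p0 <- if (binomial_null == "half") 0.5 else n_neg / n
    p_binom <- if (n_carriers > 0) binomial_exact(a, n_carriers, p0) else NA_real_

    hist_counts <- lapply(c(MA = "MA", SCO = "SCO", HSG = "HSG"),
                          function(h) {
      in_h <- patients$histology == h
      c(carriers = sum(is_carrier & in_h), total = sum(in_h))
    })
    pair_tabs <- list()
    for (pair in list(c("MA", "SCO"), c("MA", "HSG"), c("SCO", "HSG"))) {
      x <- hist_counts[[pair[1]]]; y <- hist_counts[[pair[2]]]
      pair_tabs[[paste(pair, collapse = "_vs_")]] <- matrix(
        c(x["carriers"], x["total"] - x["carriers"],
          y["carriers"], y["total"] - y["carriers"]),
        nrow = 2, byrow = TRUE,
        dimnames = list(pair, c("carrier", "non_carrier")))
    }
    hist_chisq <- suppressWarnings(chisq_pairwise(pair_tabs, m = 3))

    out[[paste0("profile_", pid)]] <- list(
      profile_id = pid,
      n_carriers = n_carriers,
      yield_overall_pct = diagnostic_yield(n_carriers, n),
      yield_negative_pct = diagnostic_yield(a, n_neg),
      yield_positive_pct = diagnostic_yield(cc, n_pos),
      outcome_table = outcome_table,
      odds_ratio = or,
      p_binomial = p_binom,
      histology = data.frame(
        stratum = names(hist_counts),
        carriers = vapply(hist_counts, `[[`, numeric(1), "carriers"),
        total = vapply(hist_counts, `[[`, numeric(1), "total"),
        yield_pct = vapply(hist_counts, function(x) {
          if (x["total"] > 0) diagnostic_yield(x["carriers"], x["total"])
          else NA_real_
        }, numeric(1)), row.names = NULL, stringsAsFactors = FALSE),
      histology_chisq = hist_chisq
    )
  }
  structure(out, class = "noa_cohort_summary")
}

#' @export
print.noa_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients; sperm retrieval rate %.1f%%\n",
              x$n_patients, x$retrieval_rate_pct))
  for (nm in grep("^profile_", names(x), value = TRUE)) {
    p <- x[[nm]]
    cat(sprintf("\nClassification profile %s: %d LP/P carriers (yield %.2f%%)\n",
                p$profile_id, p$n_carriers, p$yield_overall_pct))
    cat(sprintf("  TESE-negative %d/%d (%.2f%%) vs TESE-positive %d/%d (%.2f%%)\n",
                p$outcome_table["negative", "carrier"],
                sum(p$outcome_table["negative", ]), p$yield_negative_pct,
                p$outcome_table["positive", "carrier"],
                sum(p$outcome_table["positive", ]), p$yield_positive_pct))
    if (!is.na(p$odds_ratio$or))
      cat(sprintf("  Wald OR %.2f (95%% CI %.2f-%.2f), exact binomial p = %.3g\n",
                  p$odds_ratio$or, p$odds_ratio$ci_low, p$odds_ratio$ci_high,
                  p$p_binomial))
    for (i in seq_len(nrow(p$histology)))
      cat(sprintf("  %s: %d/%d (%.2f%%)\n", p$histology$stratum[i],
                  p$histology$carriers[i], p$histology$total[i],
                  p$histology$yield_pct[i]))
    for (i in seq_len(nrow(p$histology_chisq)))
      cat(sprintf("  chi-square %s: %.2f, adjusted p = %.3g\n",
                  p$histology_chisq$comparison[i],
                  p$histology_chisq$statistic[i],
                  p$histology_chisq$p_adjusted[i]))
  }
  invisible(x)
}
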