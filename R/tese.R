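# Per-gene aggregation of TESE outcomes in carriers of likely-pathogenic
# or pathogenic variants (cohort plus literature), yielding a prediction of
# whether mutations in a gene are compatible with testicular sperm
# production. By field convention, reported carriers with spermatozoa in
# the ejaculate (extreme or severe oligozoospermia) count as TESE-positive.

#' Aggregate carrier TESE outcomes for one gene
#'
#' @param gene Gene symbol.
#' @param outcomes Character vector of carrier outcomes
#'   (`"positive"`/`"negative"`); carriers with unknown outcome are
#'   excluded upstream.
#' @return One-row data.frame: `gene`, `n_carriers_known_outcome`,
#'   `n_tese_positive`, `prediction` (`negative_only` when every carrier
#'   was TESE-negative, `compatible_positive` when at least one had sperm
#'   retrieved, `insufficient` with no carriers), `confidence` (`high`
#'   with >= 10 known-outcome carriers, else `low`).
#' @export
aggregate_tese_evidence <- function(gene, outcomes) {
  check_enum(outcomes, TESE_OUTCOMES, "TESE outcome")
  n <- length(outcomes)
  n_pos <- sum(outcomes == "positive")
  data.frame(
    gene = gene,
    n_carriers_known_outcome = n,
    n_tese_positive = n_pos,
    prediction = if (n == 0) "insufficient"
                 else if (n_pos == 0) "negative_only" else "compatible_positive",
    confidence = if (n >= 10) "high" else "low",
    stringsAsFactors = FALSE
  )
}

#' Aggregate a carrier evidence table into per-gene predictions
#'
#' @param carriers data.frame with columns `gene`, `outcome` and optional
#'   `source` (`cohort`/`literature`) and `profile`; one row per carrier
#'   with known TESE outcome.
#' @param profile Optional: restrict to rows of one classification
#'   profile.
#' @return data.frame, one row per gene (see
#'   [aggregate_tese_evidence()]), ordered by symbol.
#' @export
tese_evidence_table <- function(carriers, profile = NULL) {
  if (!is.null(profile) && "profile" %in% names(carriers))
    carriers <- carriers[carriers$profile == profile, , drop = FALSE]
  if (nrow(carriers) == 0) {
    return(data.frame(gene = character(), n_carriers_known_outcome = integer(),
                      n_tese_positive = integer(), prediction = character(),
                      confidence = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(carriers$outcome, carriers$gene),
                               function(o) NULL))
  parts <- lapply(sort(unique(carriers$gene)), function(g) {
    aggregate_tese_evidence(g, carriers$outcome[carriers$gene == g])
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Partition genes by predicted TESE compatibility
#'
#' Splits genes with at least one known-outcome carrier into those where
#' sperm retrieval failed in every carrier (`negative_only`) and those
#' where sperm were recovered in at least one (`compatible`). Genes with
#' no known-outcome carriers are excluded. The two sets are disjoint and
#' cover all included genes.
#'
#' @param evidence Per-gene evidence table from [tese_evidence_table()].
#' @return List: `negative_only` and `compatible` (character vectors of
#'   gene symbols).
#' @export
partition_genes <- function(evidence) {
  evidence <- evidence[evidence$n_carriers_known_outcome > 0, , drop = FALSE]
  list(
    negative_only = evidence$gene[evidence$prediction == "negative_only"],
    compatible = evidence$gene[evidence$prediction == "compatible_positive"]
  )
}

#' Read a carrier TESE-evidence TSV
#'
#' Dialect: `gene carrier_id source outcome profile` with `source` in
#' `cohort`/`literature` and `outcome` in `positive`/`negative`.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tese_carriers <- function(path) {
  df <- read_tsv_checked(path, required = c("gene", "carrier_id", "source",
                                            "outcome", "profile"))
  check_enum(df$outcome, TESE_OUTCOMES, "outcome")
  check_enum(df$source, c("cohort", "literature"), "source")
  df
}
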