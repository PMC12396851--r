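# Panel registry: the virtual gene panel for non-obstructive azoospermia
# (NOA). Each entry carries the gene's inheritance mode, its curated
# gene-disease relationship (GDR) level and, where known, the class of TESE
# outcomes observed in carriers of pathogenic variants.

#' Inheritance modes recognised by the panel
#'
#' `AR` autosomal recessive, `AD` autosomal dominant, `XL` X-linked,
#' `YL` Y-linked.
#' @export
INHERITANCE_MODES <- c("AR", "AD", "XL", "YL")

#' Ordered gene-disease relationship levels
#'
#' Clinical-validity levels in increasing order of evidence. Comparisons
#' between levels use this ordering.
#' @export
GDR_LEVELS <- c("none", "limited", "moderate", "strong", "definitive")

TESE_CLASSES <- c("negative_only", "compatible_positive", "unknown")
CHROM_CLASSES <- c("autosome", "X", "Y")

gdr_rank <- function(level) match(level, GDR_LEVELS)

#' Load and validate a virtual gene panel
#'
#' Reads a tab-separated panel file with header columns
#' `symbol`, `inheritance_mode`, `chromosome_class`, `gdr_level`,
#' `tese_class`, `poi_linked` and an optional free-text `notes` column, and
#' returns a validated `panel_index` object. Loading is order-insensitive:
#' genes are indexed by symbol and per-mode counts are recomputed from the
#' rows.
#'
#' Structural rules enforced at load time:
#' * gene symbols must be unique;
#' * `XL` genes must sit on the X chromosome and `YL` genes on the Y;
#' * enumerated columns must use their closed vocabularies
#'   (see [INHERITANCE_MODES], [GDR_LEVELS]).
#'
#' @param path Path to the panel TSV.
#' @return A `panel_index`: list with `genes` (data.frame, one row per gene)
#'   and `mode_counts` (named integer vector over all inheritance modes).
#' @examples
#' panel <- load_panel(system.file("extdata", "noa_panel_partial.tsv",
#'                                 package = "noapanel"))
#' panel$mode_counts
#' @export
load_panel <- function(path) {
  df <- read_tsv_checked(path, required = c(
    "symbol", "inheritance_mode", "chromosome_class", "gdr_level",
    "tese_class", "poi_linked"
  ))
  if (!"notes" %in% names(df)) df$notes <- NA_character_
  if (nrow(df) == 0) {
    return(new_panel_index(df))
  }
  df$symbol <- as.character(df$symbol)
  for (i in seq_len(nrow(df))) {
    row_err <- function(msg) {
      stop_noa(sprintf("panel row %d (%s): %s", i + 1L,
                       df$symbol[i] %||% "?", msg))
    }
    if (is.na(df$symbol[i]) || !nzchar(df$symbol[i])) row_err("empty symbol")
    if (!df$inheritance_mode[i] %in% INHERITANCE_MODES)
      row_err(paste0("unknown inheritance_mode '", df$inheritance_mode[i], "'"))
    if (!df$chromosome_class[i] %in% CHROM_CLASSES)
      row_err(paste0("unknown chromosome_class '", df$chromosome_class[i], "'"))
    if (!df$gdr_level[i] %in% GDR_LEVELS)
      row_err(paste0("unknown gdr_level '", df$gdr_level[i], "'"))
    if (!df$tese_class[i] %in% TESE_CLASSES)
      row_err(paste0("unknown tese_class '", df$tese_class[i], "'"))
    if (df$inheritance_mode[i] == "XL" && df$chromosome_class[i] != "X")
      row_err("XL inheritance requires chromosome_class X")
    if (df$inheritance_mode[i] == "YL" && df$chromosome_class[i] != "Y")
      row_err("YL inheritance requires chromosome_class Y")
  }
  dup <- df$symbol[duplicated(df$symbol)]
  if (length(dup))
    stop_noa("duplicate gene symbol(s) in panel: ",
             paste(unique(dup), collapse = ", "))
  df$poi_linked <- as_logical_flag(df$poi_linked, "poi_linked")
  df <- df[order(df$symbol), , drop = FALSE]
  rownames(df) <- NULL
  new_panel_index(df)
}

new_panel_index <- function(genes) {
  counts <- vapply(INHERITANCE_MODES, function(m) {
    sum(genes$inheritance_mode == m)
  }, integer(1))
  structure(list(genes = genes, mode_counts = counts), class = "panel_index")
}

#' @export
print.panel_index <- function(x, ...) {
  cat(sprintf("NOA virtual gene panel: %d genes\n", nrow(x$genes)))
  cat("  by inheritance mode:",
      paste(sprintf("%s=%d", names(x$mode_counts), x$mode_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' Look up one panel gene
#'
#' @param panel A `panel_index` from [load_panel()].
#' @param symbol Gene symbol.
#' @return One-row data.frame, or `NULL` when the gene is off-panel.
#' @export
panel_gene <- function(panel, symbol) {
  stopifnot(inherits(panel, "panel_index"))
  hit <- panel$genes[panel$genes$symbol == symbol, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  hit
}

#' Panel inclusion test for a candidate gene
#'
#' A gene qualifies for the virtual panel when either (i) its curated
#' gene-disease relationship for azoospermia is at least `limited`, or
#' (ii) it has been reported mutated in more than one unrelated NOA patient.
#'
#' @param gdr_level One of [GDR_LEVELS].
#' @param n_unrelated_noa_carriers Count of unrelated reported NOA carriers
#'   (non-negative integer).
#' @return `TRUE` when the gene qualifies.
#' @examples
#' check_panel_inclusion("limited", 1)  # TRUE: criterion (i)
#' check_panel_inclusion("none", 2)     # TRUE: criterion (ii)
#' check_panel_inclusion("none", 1)     # FALSE
#' @export
check_panel_inclusion <- function(gdr_level, n_unrelated_noa_carriers) {
  check_enum(gdr_level, GDR_LEVELS, "gdr_level")
  if (length(n_unrelated_noa_carriers) != 1 ||
      is.na(n_unrelated_noa_carriers) || n_unrelated_noa_carriers < 0)
    stop_noa("n_unrelated_noa_carriers must be a non-negative count")
  gdr_rank(gdr_level) >= gdr_rank("limited") || n_unrelated_noa_carriers > 1
}

#' Default carrier-count rubric for GDR upgrades
#'
#' Maps cumulative unrelated-carrier counts to a minimum clinical-validity
#' level. The mapping is configurable because published scoring rubrics
#' weigh additional evidence (segregation, functional data) that a pure
#' carrier tally cannot capture; these defaults encode only the count-driven
#' part: three or more unrelated carriers support `moderate`, eight or more
#' support `strong`.
#'
#' @return Named integer vector: minimum carrier count per level.
#' @export
default_gdr_rubric <- function() {
  c(moderate = 3L, strong = 8L)
}

validate_rubric <- function(rubric) {
  if (length(rubric) == 0) return(invisible(rubric))
  check_enum(names(rubric), GDR_LEVELS, "rubric level")
  if (any(rubric < 0)) stop_noa("rubric thresholds must be non-negative")
  ord <- order(gdr_rank(names(rubric)))
  if (is.unsorted(rubric[ord], strictly = FALSE))
    stop_noa("rubric must be monotone: higher levels need at least as many carriers")
  invisible(rubric)
}

#' Suggest a gene-disease relationship upgrade from new carriers
#'
#' Combines a gene's prior clinical-validity level with newly observed
#' unrelated carriers under a carrier-count rubric. The suggestion never
#' falls below the prior level (evidence accumulates; it is not withdrawn).
#'
#' @param prior_level Current level, one of [GDR_LEVELS].
#' @param n_new_unrelated_carriers Newly observed unrelated carriers.
#' @param n_prior_carriers Carriers already counted toward `prior_level`
#'   (default 0; the rubric sees the cumulative total).
#' @param rubric Named vector mapping levels to minimum cumulative carrier
#'   counts; must be monotone in the level ordering. See
#'   [default_gdr_rubric()].
#' @return The suggested level (character scalar).
#' @export
flag_gdr_upgrade <- function(prior_level, n_new_unrelated_carriers,
                             n_prior_carriers = 0L,
                             rubric = default_gdr_rubric()) {
  check_enum(prior_level, GDR_LEVELS, "prior_level")
  if (n_new_unrelated_carriers < 0 || n_prior_carriers < 0)
    stop_noa("carrier counts must be non-negative")
  validate_rubric(rubric)
  total <- n_prior_carriers + n_new_unrelated_carriers
  rubric_level <- "none"
  if (length(rubric)) {
    reached <- names(rubric)[total >= rubric]
    if (length(reached))
      rubric_level <- reached[which.max(gdr_rank(reached))]
  }
  GDR_LEVELS[max(gdr_rank(prior_level), gdr_rank(rubric_level))]
}
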