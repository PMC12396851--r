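# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
stop_noa <- function(..., call. = FALSE) stop(..., call. = call.)

# Validate that all values of `x` belong to the closed vocabulary `allowed`;
# NA permitted only when `na_ok`.
check_enum <- function(x, allowed, what, na_ok = FALSE) {
  bad <- !(x %in% allowed)
  if (na_ok) bad <- bad & !is.na(x)
  if (any(bad)) {
    stop_noa(sprintf(
      "invalid %s value(s): %s (allowed: %s)",
      what, paste(unique(x[bad]), collapse = ", "),
      paste(allowed, collapse = ", ")
    ))
  }
  invisible(x)
}

read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop_noa("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE, quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_noa(sprintf("%s: missing required column(s): %s",
                     basename(path), paste(missing, collapse = ", ")))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

as_logical_flag <- function(x, what) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  out <- rep(FALSE, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  bad <- !(x %in% c("true", "t", "1", "yes", "false", "f", "0", "no", "", NA))
  bad[is.na(x)] <- FALSE
  if (any(bad)) stop_noa(sprintf("invalid boolean in %s: %s", what,
                                 paste(unique(x[bad]), collapse = ", ")))
  out
}
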