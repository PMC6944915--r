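#' Build and validate a screen readout table
#'
#' A screen table holds the well-level readouts of a multi-plate siRNA screen
#' in long format, one row per (plate, well, replicate, condition). The
#' readout is the fraction of mitosis-marker-positive cells
#' (phospho-histone H3 or MPM2); tables carrying raw `positive`/`total`
#' counts are converted to fractions on construction, and the original count
#' columns are retained.
#'
#' Required columns: `plate_id`, `well_id`, `gene`, `sirna_id`, `condition`
#' (`"treated"` or `"untreated"`), `replicate` (integer >= 1), `is_control`
#' (`"none"`, `"negative_control"` or `"positive_control"`), and either
#' `readout` (fraction in \[0, 1\]) or both `positive` and `total` counts.
#'
#' Invariants enforced: each (plate, well, replicate, condition) appears at
#' most once; every plate carries at least one negative-control well;
#' fractions lie in \[0, 1\].
#'
#' @param df data.frame with the columns above.
#' @return The validated data.frame with class `"screen_table"` prepended and
#'   a numeric `readout` column guaranteed.
#' @seealso [read_screen_table()], [compute_zscores()], [simulate_screen()]
#' @export
screen_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("plate_id", "well_id", "gene", "sirna_id", "condition",
            "replicate", "is_control")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("screen table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!("readout" %in% names(df))) {
    if (!all(c("positive", "total") %in% names(df))) {
      stop("screen table needs either 'readout' or both 'positive' and 'total'")
    }
    if (any(df$total <= 0)) stop("'total' must be positive to form fractions")
    if (any(df$positive < 0 | df$positive > df$total)) {
      stop("'positive' must lie in [0, total]")
    }
    df$readout <- df$positive / df$total
  }
  if (!all(df$condition %in% c("treated", "untreated"))) {
    stop("condition must be 'treated' or 'untreated'")
  }
  if (!all(df$is_control %in% c("none", "negative_control", "positive_control"))) {
    stop("is_control must be none, negative_control or positive_control")
  }
  if (!all(is.finite(df$readout))) stop("readouts must be finite")
  if (any(df$readout < 0 | df$readout > 1)) {
    stop("readout fractions must lie in [0, 1]")
  }
  key <- paste(df$plate_id, df$well_id, df$replicate, df$condition, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (plate_id, well_id, replicate, condition) rows")
  }
  has_neg <- tapply(df$is_control == "negative_control", df$plate_id, any)
  if (!all(has_neg)) {
    stop("plates without a negative-control well: ",
         paste(names(has_neg)[!has_neg], collapse = ", "))
  }
  class(df) <- unique(c("screen_table", class(df)))
  df
}

#' Read a screen table from CSV/TSV
#'
#' Reads a UTF-8 delimited file with the documented screen-table header
#' (see [screen_table()]) and validates it. The delimiter is inferred from
#' the file extension (`.tsv` -> tab) unless given.
#'
#' @param path file path.
#' @param sep field separator; default inferred from extension.
#' @return A `screen_table`.
#' @export
read_screen_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  screen_table(df)
}

#' @export
print.screen_table <- function(x, ...) {
  cat(sprintf(
    "screen_table: %d wells, %d plates, %d genes, %d replicate(s)\n",
    nrow(x), length(unique(x$plate_id)),
    length(unique(x$gene[x$is_control == "none"])),
    length(unique(x$replicate))))
  invisible(x)
}
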