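#' Standardize screen readouts to Z-scores
#'
#' For every non-control well the readout is standardized against the mean
#' and sample standard deviation (divisor n - 1) of its reference group:
#' either the other wells on the same plate (`scope = "per_plate"`, the
#' default, since plate effects dominate 96-well screens) or all wells of
#' the same replicate (`scope = "per_screen"`). Control wells are excluded
#' from the reference distribution unless `include_controls = TRUE`; they
#' never receive a Z-score of their own. Per-replicate Z-scores are then
#' aggregated per gene/oligo (mean by default, median optionally).
#'
#' A low Z-score means fewer mitosis-marker-positive cells than the bulk of
#' the library after irradiation (impaired checkpoint recovery); a high one
#' means more (enhanced recovery).
#'
#' @param table a [screen_table()]. Only `condition == "treated"` rows enter
#'   the statistic; untreated rows, if present, are ignored here (they feed
#'   [normalized_ratio()]).
#' @param scope reference population: `"per_plate"` or `"per_screen"`.
#' @param include_controls if `TRUE`, control wells enter the reference mean
#'   and SD (they are still not scored).
#' @param aggregate `"mean"` (default) or `"median"` across replicates.
#' @return data.frame with one row per (gene, sirna_id), ordered
#'   lexicographically: columns `gene`, `sirna_id`, `z_mean`,
#'   `n_replicates`, and a list column `z_per_replicate`.
#' @details Each scope group must contain at least 3 non-control wells. A
#'   reference group with zero standard deviation signals a degenerate plate
#'   and raises an error. Genes absent from some replicate are still
#'   reported, with reduced `n_replicates` and a warning.
#' @examples
#' sim <- simulate_screen(n_genes = 24, wells_per_plate = 16, seed = 1)
#' z <- compute_zscores(sim$table)
#' head(z)
#' @export
compute_zscores <- function(table,
                            scope = c("per_plate", "per_screen"),
                            include_controls = FALSE,
                            aggregate = c("mean", "median")) {
  scope <- match.arg(scope)
  aggregate <- match.arg(aggregate)
  table <- screen_table(as.data.frame(table))
  tab <- table[table$condition == "treated", , drop = FALSE]
  if (nrow(tab) == 0) stop("no treated wells in table")

  grp <- if (scope == "per_plate") {
    paste(tab$plate_id, tab$replicate, sep = "\r")
  } else {
    as.character(tab$replicate)
  }
  is_ctrl <- tab$is_control != "none"
  ref_idx <- if (include_controls) rep(TRUE, nrow(tab)) else !is_ctrl

  z <- rep(NA_real_, nrow(tab))
  for (g in unique(grp)) {
    in_g <- grp == g
    ref <- tab$readout[in_g & ref_idx]
    if (sum(in_g & !is_ctrl) < 3) {
      stop("scope group '", gsub("\r", "/", g),
           "' has fewer than 3 non-control wells")
    }
    m <- mean(ref)
    s <- stats::sd(ref)
    if (!is.finite(s) || s == 0) {
      stop("degenerate plate: zero reference standard deviation in group '",
           gsub("\r", "/", g), "'")
    }
    z[in_g] <- (tab$readout[in_g] - m) / s
  }

  sc <- tab[!is_ctrl, , drop = FALSE]
  zc <- z[!is_ctrl]
  key <- paste(sc$gene, sc$sirna_id, sep = "\r")
  split_z <- split(zc, key)
  split_rep <- split(sc$replicate, key)
  keys <- names(split_z)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[`, "", 1L),
    sirna_id = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  agg_fun <- if (aggregate == "mean") mean else stats::median
  # order each gene's z values by replicate so the list column is stable
  ord <- lapply(split_rep, order)
  out$z_per_replicate <- I(Map(function(v, o) unname(v[o]), split_z, ord))
  out$z_mean <- vapply(out$z_per_replicate, agg_fun, 0)
  out$n_replicates <- vapply(out$z_per_replicate, length, 0L)

  n_full <- max(out$n_replicates)
  if (any(out$n_replicates < n_full)) {
    short <- unique(out$gene[out$n_replicates < n_full])
    warning("genes with missing replicates (reported with reduced n): ",
            paste(utils::head(short, 5), collapse = ", "),
            if (length(short) > 5) ", ..." else "")
  }
  out <- out[order(out$gene, out$sirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
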