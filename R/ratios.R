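#' Treated/untreated ratios normalized to the negative control
#'
#' Computes the ratio of a treated readout to its untreated counterpart and
#' normalizes it to the same ratio of the negative-control (siLuciferase)
#' sample, which is thereby set to 1. This is the normalization behind the
#' relative mitotic entry (RME: mitotic cells after IR over mitotic cells
#' untreated), clonogenic survival (irradiated over untreated optical
#' density), and related readouts.
#'
#' @param treated nonnegative readout(s) under treatment (vectorized).
#' @param untreated positive readout(s) without treatment.
#' @param control_ratio the negative control's own treated/untreated ratio
#'   (scalar, > 0). Passing the control's ratio for `treated`/`untreated`
#'   therefore yields `normalized == 1` exactly.
#' @param kind one of `"RME"`, `"survival"`, `"repair_efficiency"` (label
#'   only).
#' @param gene optional gene label(s) carried through.
#' @return data.frame `gene`, `raw_ratio`, `normalized`, `kind`.
#' @examples
#' normalized_ratio(30, 60, control_ratio = 0.5, kind = "RME")  # normalized 1
#' @export
normalized_ratio <- function(treated, untreated, control_ratio,
                             kind = c("RME", "survival", "repair_efficiency"),
                             gene = NA_character_) {
  kind <- match.arg(kind)
  if (any(!is.finite(treated)) || any(treated < 0)) {
    stop("'treated' must be finite and nonnegative")
  }
  if (any(!is.finite(untreated)) || any(untreated <= 0)) {
    stop("empty untreated gate: 'untreated' must be positive")
  }
  if (!is.finite(control_ratio) || control_ratio <= 0) {
    stop("'control_ratio' must be positive")
  }
  raw <- treated / untreated
  data.frame(gene = gene, raw_ratio = raw, normalized = raw / control_ratio,
             kind = kind, stringsAsFactors = FALSE)
}

#' Reporter repair efficiency relative to the negative control
#'
#' For the chromosomal I-SceI reporters, repair efficiency is the fraction
#' of repair-marker-positive cells (CD4 for end joining, GFP for
#' homologous recombination) among transfection-marker-positive (mCherry+)
#' cells, expressed relative to the same fraction in the negative-control
#' knockdown.
#'
#' @param marker_pos_in_transfected count of marker+ cells among transfected
#'   cells.
#' @param transfected count of transfected (gated) cells, > 0.
#' @param control_fraction the negative control's marker+ fraction (> 0).
#' @param gene optional gene label(s).
#' @return data.frame as [normalized_ratio()] with `kind =
#'   "repair_efficiency"`; `raw_ratio` is the marker+ fraction.
#' @export
repair_efficiency <- function(marker_pos_in_transfected, transfected,
                              control_fraction, gene = NA_character_) {
  if (any(transfected <= 0)) stop("'transfected' must be positive")
  if (any(marker_pos_in_transfected < 0) ||
      any(marker_pos_in_transfected > transfected)) {
    stop("'marker_pos_in_transfected' must lie in [0, transfected]")
  }
  if (!is.finite(control_fraction) || control_fraction <= 0) {
    stop("'control_fraction' must be positive")
  }
  frac <- marker_pos_in_transfected / transfected
  data.frame(gene = gene, raw_ratio = frac,
             normalized = frac / control_fraction,
             kind = "repair_efficiency", stringsAsFactors = FALSE)
}

#' Two-tailed unpaired t-test
#'
#' The classical equal-variance two-sample t-test used for all pairwise
#' comparisons in this workflow, as a thin wrapper around
#' [stats::t.test()] with `var.equal = TRUE`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t` (statistic), `p` (two-tailed), `df`
#'   (`length(a) + length(b) - 2`).
#' @export
two_sample_ttest <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (!is.finite(pooled) || pooled <= 0) {
    stop("zero pooled variance: t statistic undefined")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = as.integer(unname(ht$parameter)))
}
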