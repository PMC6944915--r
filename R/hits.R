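#' Call screen hits from aggregated Z-scores
#'
#' Applies the asymmetric cutoff rule used for the primary screen: a
#' gene/oligo is called `increased` when its aggregated Z-score reaches
#' `up_cutoff` (default 2) and `decreased` when it falls to `-down_cutoff`
#' (default 1). Both boundaries are inclusive: a Z-score exactly at the
#' cutoff is a hit. The asymmetry reflects that losses of recovery were
#' screened for more liberally than gains.
#'
#' @param z data.frame from [compute_zscores()] (needs `gene`, `sirna_id`,
#'   `z_mean`).
#' @param up_cutoff positive cutoff for `increased` calls.
#' @param down_cutoff positive cutoff (applied on the negative side) for
#'   `decreased` calls.
#' @return data.frame `gene`, `sirna_id`, `z_mean`, `direction`
#'   (`"increased"`, `"decreased"` or `"none"`), row order preserved.
#' @export
call_hits <- function(z, up_cutoff = 2, down_cutoff = 1) {
  stopifnot(is.data.frame(z), all(c("gene", "z_mean") %in% names(z)))
  if (!(up_cutoff > 0 && down_cutoff > 0)) stop("cutoffs must be positive")
  direction <- rep("none", nrow(z))
  direction[z$z_mean >= up_cutoff] <- "increased"
  direction[z$z_mean <= -down_cutoff] <- "decreased"
  out <- data.frame(
    gene = z$gene,
    sirna_id = if ("sirna_id" %in% names(z)) z$sirna_id else "pool",
    z_mean = z$z_mean,
    direction = direction,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Deconvolve pooled hits with individual siRNA oligos
#'
#' Rescreening a pooled hit with its individual oligos guards against
#' off-target artifacts. An oligo is *altered* in one experiment when its
#' recovery readout deviates from the mean of that experiment's
#' negative-control wells by more than `sd_threshold` times the control
#' wells' sample standard deviation; it *validates* when altered in at
#' least `min_experiments` independent experiments; a gene validates when
#' at least `min_oligos` of its oligos validate (the "2 out of 4" rule).
#'
#' Control statistics are computed per (plate, replicate) from the
#' negative-control wells of that plate; an experiment with fewer than two
#' negative-control wells has no defined SD and raises an error.
#'
#' @param table a [screen_table()] of single-oligo wells; `replicate`
#'   indexes the independent experiments.
#' @param sd_threshold multiple of the negative-control SD beyond which a
#'   readout counts as altered (default 0.5).
#' @param min_oligos minimum number of validating oligos for a gene call.
#' @param min_experiments minimum number of experiments in which an oligo
#'   must be altered.
#' @return data.frame with one row per gene: `gene`, `n_oligos`,
#'   `n_oligos_altered`, `validated`, `direction` (sign of the mean
#'   deviation of the validating oligos; `"none"` if not validated).
#' @export
deconvolve <- function(table, sd_threshold = 0.5, min_oligos = 2,
                       min_experiments = 2) {
  stopifnot(sd_threshold > 0, min_oligos >= 1, min_experiments >= 1)
  table <- screen_table(as.data.frame(table))
  tab <- table[table$condition == "treated", , drop = FALSE]

  exp_key <- paste(tab$plate_id, tab$replicate, sep = "\r")
  ctrl <- tab$is_control == "negative_control"
  altered <- rep(NA, nrow(tab))
  deviation <- rep(NA_real_, nrow(tab))
  for (e in unique(exp_key)) {
    in_e <- exp_key == e
    cr <- tab$readout[in_e & ctrl]
    if (length(cr) < 2) {
      stop("experiment '", gsub("\r", "/", e),
           "' has fewer than 2 negative-control wells; control SD undefined")
    }
    m <- mean(cr)
    s <- stats::sd(cr)
    deviation[in_e] <- tab$readout[in_e] - m
    altered[in_e] <- abs(tab$readout[in_e] - m) > sd_threshold * s
  }

  sc <- tab[tab$is_control == "none", , drop = FALSE]
  sc$altered <- altered[tab$is_control == "none"]
  sc$deviation <- deviation[tab$is_control == "none"]

  okey <- paste(sc$gene, sc$sirna_id, sep = "\r")
  n_alt_exp <- tapply(sc$altered, okey, sum)
  oligo_validates <- n_alt_exp >= min_experiments
  oligo_gene <- vapply(strsplit(names(n_alt_exp), "\r", fixed = TRUE), `[`, "", 1L)
  oligo_dev <- tapply(sc$deviation, okey, mean)

  genes <- sort(unique(oligo_gene))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  out$n_oligos <- as.integer(table(oligo_gene)[genes])
  out$n_oligos_altered <- vapply(genes, function(g) {
    sum(oligo_validates[oligo_gene == g])
  }, 0L)
  out$validated <- out$n_oligos_altered >= min_oligos
  out$direction <- vapply(genes, function(g) {
    sel <- oligo_gene == g & oligo_validates
    if (!any(sel)) return("none")
    if (mean(oligo_dev[sel]) > 0) "increased" else "decreased"
  }, "")
  out$direction[!out$validated] <- "none"
  rownames(out) <- NULL
  out
}
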