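#' Simulate a ground-truthed multi-plate siRNA recovery screen
#'
#' Emulates the structure of the checkpoint-recovery screen: a library of
#' `n_genes` genes (529 by default) distributed over 96-well plates, each
#' plate carrying negative-control (luciferase) and positive-control
#' (PPM1D, BTRC) wells, read out as the fraction of mitosis-marker-positive
#' cells after irradiation across `n_replicates` independent screens. The
#' null readout is Gaussian on the mitotic fraction (truncated to \[0, 1\]);
#' planted hits shift their wells by `effect_size` null-SD units in the
#' stated direction. In the pooled mode each gene occupies one well
#' (`sirna_id = "pool"`); in the deconvolution mode each gene occupies
#' `oligos_per_gene` wells and only a fraction of oligos carries the
#' planted effect, emulating off-target-prone oligos.
#'
#' @param n_genes library size.
#' @param oligos_per_gene oligos per gene in deconvolution mode.
#' @param n_replicates independent screens (replicates).
#' @param wells_per_plate plate capacity including controls.
#' @param null_mean,null_sd mean and SD of the null mitotic fraction.
#' @param planted_hits `NULL`, or a data.frame with columns `gene`,
#'   `direction` (`"increased"`/`"decreased"`), `effect_size` (in null-SD
#'   units; default 5 when the column is absent), and optionally
#'   `fraction_effective_oligos` (default 1).
#' @param pooled if `TRUE` (default) one pooled well per gene; otherwise
#'   per-oligo wells.
#' @param counts if `TRUE`, also emit `positive`/`total` columns by
#'   binomial sampling of `cells_per_well` cells at the well's fraction
#'   (a normal-binomial readout; the fraction column then carries the
#'   realized positive fraction).
#' @param cells_per_well cells scored per well in counts mode.
#' @param seed integer seed; the generator uses a private RNG stream and
#'   leaves the global RNG state untouched.
#' @return list: `table` (a [screen_table()]), `truth` (data.frame of the
#'   planted effects: `gene`, `direction`, `effect_size`,
#'   `n_effective_oligos`).
#' @examples
#' sim <- simulate_screen(n_genes = 20, wells_per_plate = 24, seed = 1,
#'   planted_hits = data.frame(gene = "GENE003", direction = "decreased"))
#' call_hits(compute_zscores(sim$table))[1:4, ]
#' @export
simulate_screen <- function(n_genes = 529,
                            oligos_per_gene = 4,
                            n_replicates = 3,
                            wells_per_plate = 96,
                            null_mean = 0.30,
                            null_sd = 0.05,
                            planted_hits = NULL,
                            pooled = TRUE,
                            counts = FALSE,
                            cells_per_well = 1000,
                            seed = NULL) {
  stopifnot(n_genes >= 1, n_replicates >= 1, wells_per_plate >= 8,
            null_sd > 0, null_mean > 0, null_mean < 1)
  local_rng(seed, "screen")

  genes <- sprintf("GENE%03d", seq_len(n_genes))
  hits <- normalize_planted_hits(planted_hits, genes)

  ctrl <- data.frame(
    gene = c("Luciferase", "Luciferase", "PPM1D", "BTRC"),
    is_control = c("negative_control", "negative_control",
                   "positive_control", "positive_control"),
    effect = c(0, 0, -5, -5),  # known recovery regulators: strong decrease
    stringsAsFactors = FALSE
  )
  n_ctrl <- nrow(ctrl)
  sample_slots <- wells_per_plate - n_ctrl
  if (sample_slots < 1) stop("wells_per_plate too small for the control set")

  units <- if (pooled) {
    data.frame(gene = genes, sirna_id = "pool", stringsAsFactors = FALSE)
  } else {
    data.frame(gene = rep(genes, each = oligos_per_gene),
               sirna_id = rep(sprintf("oligo%d", seq_len(oligos_per_gene)),
                              times = n_genes),
               stringsAsFactors = FALSE)
  }
  # per-unit planted shift (0 for nulls); in per-oligo mode only the first
  # round(fraction * oligos) oligos of a hit gene are effective
  units$effect <- 0
  units$effective <- FALSE
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      sel <- units$gene == hits$gene[i]
      eff <- hits$effect_size[i] *
        if (hits$direction[i] == "decreased") -1 else 1
      if (pooled) {
        units$effect[sel] <- eff
        units$effective[sel] <- TRUE
      } else {
        k <- max(1L, round(hits$fraction_effective_oligos[i] * sum(sel)))
        pick <- which(sel)[seq_len(k)]
        units$effect[pick] <- eff
        units$effective[pick] <- TRUE
      }
    }
  }

  n_plates <- ceiling(nrow(units) / sample_slots)
  unit_plate <- rep(seq_len(n_plates), each = sample_slots)[seq_len(nrow(units))]

  rows <- vector("list", n_plates * n_replicates)
  ri <- 0L
  for (rep_i in seq_len(n_replicates)) {
    for (pl in seq_len(n_plates)) {
      u <- units[unit_plate == pl, , drop = FALSE]
      plate <- rbind(
        data.frame(gene = u$gene, sirna_id = u$sirna_id,
                   is_control = "none", effect = u$effect,
                   stringsAsFactors = FALSE),
        data.frame(gene = ctrl$gene, sirna_id = "pool",
                   is_control = ctrl$is_control, effect = ctrl$effect,
                   stringsAsFactors = FALSE)
      )
      nw <- nrow(plate)
      frac <- pmin(1, pmax(0, stats::rnorm(nw, null_mean + plate$effect * null_sd,
                                           null_sd)))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        plate_id = sprintf("P%02d", pl),
        well_id = well_names(wells_per_plate)[seq_len(nw)],
        gene = plate$gene,
        sirna_id = plate$sirna_id,
        condition = "treated",
        replicate = rep_i,
        readout = frac,
        is_control = plate$is_control,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  if (counts) {
    tab$total <- cells_per_well
    tab$positive <- stats::rbinom(nrow(tab), cells_per_well, tab$readout)
    tab$readout <- tab$positive / tab$total
  }
  truth <- if (nrow(hits) > 0) {
    data.frame(gene = hits$gene, direction = hits$direction,
               effect_size = hits$effect_size,
               n_effective_oligos = vapply(hits$gene, function(g) {
                 sum(units$effective[units$gene == g])
               }, 0L), stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), direction = character(),
               effect_size = numeric(), n_effective_oligos = integer())
  }
  list(table = screen_table(tab), truth = truth)
}

normalize_planted_hits <- function(planted_hits, genes) {
  if (is.null(planted_hits) || nrow(as.data.frame(planted_hits)) == 0) {
    return(data.frame(gene = character(), direction = character(),
                      effect_size = numeric(),
                      fraction_effective_oligos = numeric()))
  }
  hits <- as.data.frame(planted_hits, stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(hits))) {
    stop("planted_hits needs 'gene' and 'direction' columns")
  }
  bad <- setdiff(hits$gene, genes)
  if (length(bad)) {
    stop("planted hit gene(s) absent from the library: ",
         paste(bad, collapse = ", "))
  }
  if (!all(hits$direction %in% c("increased", "decreased"))) {
    stop("planted direction must be 'increased' or 'decreased'")
  }
  if (is.null(hits$effect_size)) hits$effect_size <- 5
  if (is.null(hits$fraction_effective_oligos)) hits$fraction_effective_oligos <- 1
  stopifnot(all(is.finite(hits$effect_size)))
  hits
}

well_names <- function(n) {
  ncols <- ceiling(n / 8)
  paste0(rep(LETTERS[1:8], times = ncols),
         sprintf("%02d", rep(seq_len(ncols), each = 8)))[seq_len(n)]
}

# Private, keyed RNG stream: seeds a stream derived from (seed, key) and
# restores the caller's RNG state when the caller exits, so regenerating
# one artifact never perturbs another.
local_rng <- function(seed, key, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  restore <- function() {
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
  do.call(on.exit,
          list(substitute(RESTORE(), list(RESTORE = restore)), add = TRUE),
          envir = envir)
  offset <- c(screen = 101L, images = 202L, junctions = 303L)[[key]]
  set.seed((as.integer(seed) * 7L + offset) %% .Machine$integer.max)
  invisible(NULL)
}
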