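#' Match detected foci to planted ground truth
#'
#' Greedy nearest-neighbour matching between planted focus centres and
#' detected centroids within the same nucleus: pairs are accepted in order
#' of increasing distance, each point used at most once, up to `max_dist`
#' pixels apart.
#'
#' @param truth data.frame with `nucleus_id`, `row`, `col` (0-based planted
#'   centres).
#' @param detected data.frame with `nucleus_id`, `centroid_row`,
#'   `centroid_col` (as in [detect_foci()] output).
#' @param max_dist matching radius in pixels.
#' @param by_nucleus require matches within the same nucleus label
#'   (default `TRUE`; set `FALSE` when segmentation labels and truth ids
#'   need not agree).
#' @return list: `n_matched`, `recall`, `precision`.
#' @export
match_foci <- function(truth, detected, max_dist = 3, by_nucleus = TRUE) {
  nt <- nrow(truth); nd <- nrow(detected)
  if (nt == 0 || nd == 0) {
    return(list(n_matched = 0L,
                recall = if (nt == 0) NA_real_ else 0,
                precision = if (nd == 0) NA_real_ else 0))
  }
  dmat <- outer(truth$row, detected$centroid_row, `-`)^2 +
    outer(truth$col, detected$centroid_col, `-`)^2
  dmat <- sqrt(dmat)
  if (by_nucleus) {
    same <- outer(truth$nucleus_id, detected$nucleus_id, `==`)
    dmat[!same] <- Inf
  }
  used_t <- logical(nt); used_d <- logical(nd)
  n <- 0L
  ord <- order(dmat)
  for (k in ord) {
    if (dmat[k] > max_dist) break
    i <- (k - 1) %% nt + 1
    j <- (k - 1) %/% nt + 1
    if (used_t[i] || used_d[j]) next
    used_t[i] <- used_d[j] <- TRUE
    n <- n + 1L
  }
  list(n_matched = n, recall = n / nt, precision = n / nd)
}

#' Score hit calls against planted screen truth
#'
#' @param hits data.frame from [call_hits()].
#' @param truth planted-hit truth from [simulate_screen()].
#' @return list: `sensitivity` (planted hits called, any direction),
#'   `direction_accuracy` (fraction of called planted hits with the planted
#'   direction), `n_false_positives`, `false_discovery_proportion`.
#' @export
score_screen_calls <- function(hits, truth) {
  called <- hits[hits$direction != "none", , drop = FALSE]
  planted <- truth$gene
  called_planted <- called[called$gene %in% planted, , drop = FALSE]
  sens <- if (length(planted)) {
    length(unique(called_planted$gene)) / length(planted)
  } else NA_real_
  dir_ok <- if (nrow(called_planted)) {
    mean(called_planted$direction ==
           truth$direction[match(called_planted$gene, truth$gene)])
  } else NA_real_
  fp <- sum(!called$gene %in% planted)
  list(sensitivity = sens,
       direction_accuracy = dir_ok,
       n_false_positives = fp,
       false_discovery_proportion = if (nrow(called)) fp / nrow(called) else 0)
}
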