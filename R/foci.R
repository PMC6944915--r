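#' Multi-channel image container
#'
#' @param channels named list of 2D matrices or 3D arrays (rows x cols x z);
#'   must include `"dapi"` plus at least one focus channel, all with equal
#'   spatial dimensions.
#' @param pixel_size optional pixel size in microns (metadata only).
#' @return list of class `"image_stack"`.
#' @export
image_stack <- function(channels, pixel_size = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  dims <- lapply(channels, function(a) dim(a)[1:2])
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("all channels must share identical spatial dimensions")
  }
  for (a in channels) {
    if (!all(is.finite(a)) || any(a < 0)) {
      stop("intensities must be finite and nonnegative")
    }
  }
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %s; %d x %d px, z = %s\n",
              paste(names(x$channels), collapse = ", "),
              d[1], d[2],
              paste(unique(vapply(x$channels,
                                  function(a) if (length(dim(a)) == 3) dim(a)[3] else 1L,
                                  1L)), collapse = "/")))
  invisible(x)
}

#' Maximum-intensity projection of one channel
#'
#' Collapses a z-stack to 2D by the per-pixel maximum over planes; a
#' single-plane channel is returned unchanged.
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @return 2D numeric matrix.
#' @export
max_project <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels)) {
    stop("unknown channel: '", channel, "'")
  }
  a <- stack$channels[[channel]]
  if (length(dim(a)) == 2) return(a)
  do.call(pmax, lapply(seq_len(dim(a)[3]), function(k) a[, , k]))
}

#' Difference-of-Gaussians background subtraction
#'
#' Band-pass filters a focus channel as the difference of two Gaussian
#' blurs, removing smooth nuclear background while preserving spot-sized
#' structure. The output may be negative; clamping is left to the detection
#' stage. A constant image maps to (numerically) zero.
#'
#' @param image 2D numeric matrix.
#' @param sigma_small,sigma_large blur sigmas in pixels, small < large.
#' @return 2D numeric matrix of the same size.
#' @export
dog_subtract <- function(image, sigma_small = 1, sigma_large = 3) {
  stopifnot(is.matrix(image), sigma_small < sigma_large, sigma_small > 0)
  g1 <- EBImage::imageData(EBImage::gblur(EBImage::Image(image), sigma_small))
  g2 <- EBImage::imageData(EBImage::gblur(EBImage::Image(image), sigma_large))
  matrix(g1 - g2, nrow = nrow(image))
}

#' Detect foci in a background-subtracted image
#'
#' Implements the adaptive two-criterion rule for radiation-induced foci.
#' For every nucleus the background median of its DoG values is estimated
#' (robustly, as median and 1.4826 x MAD, so bona fide foci do not inflate
#' the estimate); the image-wide reference SD is the *median over nuclei* of
#' those background SDs. A pixel belongs to a focus when its DoG value
#' exceeds its nucleus's background median by `k_sd` times the reference SD
#' *and* exceeds the absolute minimum `abs_min`. Connected components of
#' passing pixels (8- or 4-connectivity) that lie within a single nucleus
#' and reach `min_focus_area` pixels become foci.
#'
#' @param dog_image 2D matrix from [dog_subtract()].
#' @param nuclei a `"nucleus_label_map"` from [segment_nuclei()] with the
#'   same dimensions.
#' @param params a [foci_params()].
#' @return object of class `"foci_calls"`: list with
#'   \describe{
#'     \item{foci}{data.frame `nucleus_id`, `focus_id`, `centroid_row`,
#'       `centroid_col` (0-based pixel coordinates), `area`,
#'       `peak_intensity`, `total_intensity`}
#'     \item{nuclei}{data.frame `nucleus_id`, `area`, `background_median`,
#'       `background_sd`, `focus_count`, `mean_focus_intensity` (mean
#'       per-focus total intensity; `NA` when no foci)}
#'   }
#'   Nuclei smaller than 10 px are excluded from detection with a warning.
#' @export
detect_foci <- function(dog_image, nuclei, params = foci_params()) {
  stopifnot(inherits(nuclei, "nucleus_label_map"),
            identical(dim(dog_image), dim(nuclei$labels)),
            inherits(params, "foci_params"))
  labels <- nuclei$labels
  ids <- nuclei$nuclei$nucleus_id
  if (length(ids) == 0) {
    return(empty_foci_calls(params))
  }

  too_small <- nuclei$nuclei$area < 10
  if (any(too_small)) {
    warning(sum(too_small), " nucleus/nuclei below 10 px excluded from detection")
    ids <- ids[!too_small]
    if (length(ids) == 0) return(empty_foci_calls(params))
  }

  bg_median <- bg_sd <- numeric(length(ids))
  for (i in seq_along(ids)) {
    v <- dog_image[labels == ids[i]]
    bg_median[i] <- stats::median(v)
    bg_sd[i] <- if (params$robust_background) stats::mad(v) else stats::sd(v)
  }
  ref_sd <- stats::median(bg_sd)

  thr <- rep(Inf, max(labels))
  thr[ids] <- bg_median + params$k_sd * ref_sd
  pass <- labels > 0 & dog_image > thr[pmax(labels, 1L)] & dog_image > params$abs_min

  comp <- label_components(pass, labels, params$connectivity)
  foci_list <- list()
  k <- 0L
  if (max(comp) > 0) {
    idx <- which(comp > 0)
    rows0 <- (idx - 1L) %% nrow(comp)
    cols0 <- (idx - 1L) %/% nrow(comp)
    for (cid in seq_len(max(comp))) {
      sel <- comp[idx] == cid
      if (sum(sel) < params$min_focus_area) next
      k <- k + 1L
      vals <- dog_image[idx[sel]]
      foci_list[[k]] <- data.frame(
        nucleus_id = labels[idx[sel][1]],
        focus_id = k,
        centroid_row = mean(rows0[sel]),
        centroid_col = mean(cols0[sel]),
        area = sum(sel),
        peak_intensity = max(vals),
        total_intensity = sum(vals)
      )
    }
  }
  foci <- if (k > 0) do.call(rbind, foci_list) else empty_foci_df()
  if (k > 0) {
    foci <- foci[order(foci$nucleus_id, foci$centroid_row, foci$centroid_col), ]
    foci$focus_id <- seq_len(nrow(foci))
    rownames(foci) <- NULL
  }

  per_nuc <- data.frame(
    nucleus_id = ids,
    area = nuclei$nuclei$area[match(ids, nuclei$nuclei$nucleus_id)],
    background_median = bg_median,
    background_sd = bg_sd,
    focus_count = vapply(ids, function(i) sum(foci$nucleus_id == i), 0L),
    mean_focus_intensity = vapply(ids, function(i) {
      v <- foci$total_intensity[foci$nucleus_id == i]
      if (length(v)) mean(v) else NA_real_
    }, 0)
  )
  structure(list(foci = foci, nuclei = per_nuc, params = params,
                 reference_sd = ref_sd),
            class = "foci_calls")
}

empty_foci_df <- function() {
  data.frame(nucleus_id = integer(), focus_id = integer(),
             centroid_row = numeric(), centroid_col = numeric(),
             area = integer(), peak_intensity = numeric(),
             total_intensity = numeric())
}

empty_foci_calls <- function(params) {
  structure(list(
    foci = empty_foci_df(),
    nuclei = data.frame(nucleus_id = integer(), area = integer(),
                        background_median = numeric(), background_sd = numeric(),
                        focus_count = integer(), mean_focus_intensity = numeric()),
    params = params, reference_sd = NA_real_), class = "foci_calls")
}

#' @export
print.foci_calls <- function(x, ...) {
  cat(sprintf("foci_calls: %d foci across %d nuclei (median count %s)\n",
              nrow(x$foci), nrow(x$nuclei),
              if (nrow(x$nuclei)) format(stats::median(x$nuclei$focus_count)) else "-"))
  invisible(x)
}

# Connected components of `mask`, where two passing pixels connect only when
# adjacent (4/8-neighborhood) AND carry the same region label. Two-pass
# union-find over the passing pixels; returns an integer matrix.
label_components <- function(mask, regions, connectivity = 8) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0) return(out)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  pos <- match(seq_len(length(mask)), idx) # linear index -> pixel rank (NA if off)

  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- if (connectivity == 8) {
    list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(-1L, 1L))
  } else {
    list(c(-1L, 0L), c(0L, -1L))
  }
  for (p in seq_along(idx)) {
    for (o in offs) {
      rn <- r[p] + o[1]; cn <- c[p] + o[2]
      if (rn < 1 || rn > nr || cn < 1 || cn > ncol(mask)) next
      lin <- rn + (cn - 1L) * nr
      q <- pos[lin]
      if (!is.na(q) && regions[lin] == regions[idx[p]]) {
        rp <- find(p); rq <- find(q)
        if (rp != rq) parent[rp] <- rq
      }
    }
  }
  roots <- vapply(seq_along(idx), find, 1L)
  out[idx] <- match(roots, unique(roots))
  out
}

#' Run the full foci pipeline on an image stack
#'
#' Deterministic composition of the stages in acquisition order: project
#' the DAPI channel, segment nuclei, project the focus channel, subtract
#' background with a Difference-of-Gaussians filter, and detect foci.
#'
#' @param stack an [image_stack()] containing `"dapi"` and `channel`.
#' @param channel name of the focus channel (e.g. `"gH2AX"`, `"53BP1"`).
#' @param params a [foci_params()].
#' @return list of class `"irif_result"`: `nuclei` (per-nucleus table with
#'   `focus_count`, `mean_focus_intensity`, `area`), `foci` (per-focus
#'   table), `labels` (nucleus label matrix), `params`.
#' @examples
#' sim <- simulate_images(n_nuclei = 3, foci_per_nucleus = 5, seed = 7)
#' res <- run_irif_pipeline(sim$stack, "gH2AX")
#' res$nuclei[, c("nucleus_id", "area", "focus_count")]
#' @export
run_irif_pipeline <- function(stack, channel, params = foci_params()) {
  stopifnot(inherits(stack, "image_stack"))
  if (!"dapi" %in% names(stack$channels)) stop("stack has no 'dapi' channel")
  dapi <- max_project(stack, "dapi")
  seg <- segment_nuclei(dapi, params)
  img <- max_project(stack, channel)
  dog <- dog_subtract(img, params$dog_sigma_small, params$dog_sigma_large)
  calls <- detect_foci(dog, seg, params)
  structure(list(nuclei = calls$nuclei, foci = calls$foci,
                 labels = seg$labels, params = params),
            class = "irif_result")
}

#' @export
print.irif_result <- function(x, ...) {
  cat(sprintf("irif_result: %d nuclei, %d foci\n", nrow(x$nuclei), nrow(x$foci)))
  invisible(x)
}
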