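#' Segment nuclei from a DAPI image
#'
#' Reproduces the standard nucleus segmentation of high-content IRIF
#' analysis: the DAPI channel is median-filtered, thresholded (Otsu by
#' default), holes are filled, and touching nuclei are separated by a
#' watershed on the distance transform of the foreground mask (equivalently,
#' flooding the negated distance map from its local maxima). Objects smaller
#' than `min_nucleus_area` are removed, nuclei touching the image border are
#' optionally excluded, and surviving labels are renumbered 1..K in raster
#' (row-major) order of their first pixel.
#'
#' Intensities are rescaled to \[0, 1\] internally (EBImage's filters
#' operate on that range); an absolute `nucleus_threshold` is given on the
#' raw intensity scale and rescaled along with the image.
#'
#' @param dapi 2D numeric matrix of nonnegative intensities (project stacks
#'   with [max_project()] first).
#' @param params a [foci_params()] object.
#' @return object of class `"nucleus_label_map"`: list with `labels`
#'   (integer matrix, 0 = background) and `nuclei` (data.frame `nucleus_id`,
#'   `area`).
#' @examples
#' sim <- simulate_images(n_nuclei = 2, foci_per_nucleus = 0, seed = 3)
#' seg <- segment_nuclei(max_project(sim$stack, "dapi"), foci_params())
#' seg$nuclei
#' @export
segment_nuclei <- function(dapi, params = foci_params()) {
  stopifnot(is.matrix(dapi), all(is.finite(dapi)), all(dapi >= 0))
  stopifnot(inherits(params, "foci_params"), params$median_radius >= 1)

  top <- max(dapi)
  if (top == 0) {
    warning("empty foreground: DAPI image is all zero")
    return(empty_label_map(dim(dapi)))
  }
  norm <- dapi / top
  filt <- EBImage::medianFilter(norm, params$median_radius)
  thr <- if (identical(params$nucleus_threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(filt))
  } else {
    params$nucleus_threshold / top
  }
  mask <- filt > thr
  if (!any(mask)) {
    warning("empty foreground: no pixels above the nucleus threshold")
    return(empty_label_map(dim(dapi)))
  }
  mask <- EBImage::fillHull(EBImage::Image(mask))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::imageData(
    EBImage::watershed(dm, tolerance = params$watershed_tolerance, ext = 1))
  labels <- matrix(as.integer(labels), nrow = nrow(dapi))

  labels <- prune_labels(labels, params$min_nucleus_area, params$exclude_border)
  if (max(labels) == 0) {
    warning("empty foreground: no nuclei left after area/border filtering")
  }
  areas <- tabulate(labels[labels > 0], nbins = max(labels, 1L))
  nuclei <- data.frame(nucleus_id = seq_along(areas), area = areas)
  nuclei <- nuclei[nuclei$area > 0, , drop = FALSE]
  rownames(nuclei) <- NULL
  structure(list(labels = labels, nuclei = nuclei),
            class = "nucleus_label_map")
}

empty_label_map <- function(dims) {
  structure(list(labels = matrix(0L, dims[1], dims[2]),
                 nuclei = data.frame(nucleus_id = integer(), area = integer())),
            class = "nucleus_label_map")
}

# drop small/border objects and renumber 1..K by first pixel in row-major order
prune_labels <- function(labels, min_area, exclude_border) {
  if (max(labels) == 0) return(labels)
  areas <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- areas >= min_area
  if (exclude_border) {
    nr <- nrow(labels); nc <- ncol(labels)
    border <- unique(c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc]))
    keep[border[border > 0]] <- FALSE
  }
  lut <- integer(length(areas))
  idx <- which(labels > 0)
  if (any(keep)) {
    # raster (row-major) index of each object's first pixel
    rr <- (idx - 1L) %% nrow(labels)
    cc <- (idx - 1L) %/% nrow(labels)
    raster <- rr * ncol(labels) + cc
    first <- tapply(raster, labels[idx], min)
    kept <- as.integer(names(first))[keep[as.integer(names(first))]]
    kept <- kept[order(first[as.character(kept)])]
    lut[kept] <- seq_along(kept)
  }
  out <- labels
  out[idx] <- lut[labels[idx]]
  out
}

#' @export
print.nucleus_label_map <- function(x, ...) {
  cat(sprintf("nucleus_label_map: %d nuclei over a %d x %d image\n",
              nrow(x$nuclei), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}
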