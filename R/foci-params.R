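#' Parameters for nucleus segmentation and focus detection
#'
#' Bundles every tunable of the IRIF (ionizing-radiation-induced foci)
#' pipeline. Defaults target confocal images where nuclei span tens of
#' pixels and foci 3-6 pixels; in practice `k_sd` and `abs_min` are tuned
#' per experiment by comparing detections with the raw signal.
#'
#' @param median_radius radius (pixels) of the median filter applied to the
#'   DAPI channel before thresholding.
#' @param nucleus_threshold `"otsu"` (default) or an absolute intensity on
#'   the raw DAPI scale.
#' @param min_nucleus_area smallest object (pixels) kept as a nucleus.
#' @param dog_sigma_small,dog_sigma_large Gaussian sigmas (pixels) of the
#'   Difference-of-Gaussians band-pass; small < large.
#' @param k_sd the "set number of times" the image-wide median background SD
#'   a pixel must exceed its nucleus's background median (typical 2-4).
#' @param abs_min user-defined absolute minimum DoG value a focus pixel must
#'   also exceed.
#' @param min_focus_area minimum focus area in pixels (default 3, i.e.
#'   strictly larger than two pixels; set 2 for the inclusive reading).
#' @param connectivity 8 (default) or 4; pixel adjacency for foci.
#' @param robust_background if `TRUE` (default) the per-nucleus background
#'   SD is the MAD scaled to the normal (1.4826 x MAD); otherwise the plain
#'   sample SD, which true foci inflate.
#' @param exclude_border drop nuclei touching the image border (stand-in for
#'   manual curation of partial nuclei).
#' @param watershed_tolerance minimum object-separation depth handed to the
#'   watershed split of touching nuclei.
#' @return list of class `"foci_params"`.
#' @export
foci_params <- function(median_radius = 2,
                        nucleus_threshold = "otsu",
                        min_nucleus_area = 200,
                        dog_sigma_small = 1,
                        dog_sigma_large = 3,
                        k_sd = 3,
                        abs_min = 0,
                        min_focus_area = 3,
                        connectivity = 8,
                        robust_background = TRUE,
                        exclude_border = TRUE,
                        watershed_tolerance = 1) {
  if (!(is.numeric(dog_sigma_small) && is.numeric(dog_sigma_large) &&
        dog_sigma_small < dog_sigma_large)) {
    stop("dog_sigma_small must be smaller than dog_sigma_large")
  }
  if (!(k_sd > 0)) stop("k_sd must be positive")
  if (!(min_focus_area >= 1)) stop("min_focus_area must be >= 1")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (!(identical(nucleus_threshold, "otsu") ||
        (is.numeric(nucleus_threshold) && length(nucleus_threshold) == 1))) {
    stop("nucleus_threshold must be \"otsu\" or a single numeric value")
  }
  structure(list(
    median_radius = as.integer(median_radius),
    nucleus_threshold = nucleus_threshold,
    min_nucleus_area = min_nucleus_area,
    dog_sigma_small = dog_sigma_small,
    dog_sigma_large = dog_sigma_large,
    k_sd = k_sd,
    abs_min = abs_min,
    min_focus_area = min_focus_area,
    connectivity = as.integer(connectivity),
    robust_background = isTRUE(robust_background),
    exclude_border = isTRUE(exclude_border),
    watershed_tolerance = watershed_tolerance
  ), class = "foci_params")
}

#' @export
print.foci_params <- function(x, ...) {
  cat("foci_params:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
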