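#' Write a result table to CSV
#'
#' UTF-8, '.' decimal separator, no row names. List columns (such as
#' `z_per_replicate`) are flattened to semicolon-separated strings.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  x <- as.data.frame(x)
  for (nm in names(x)) {
    if (is.list(x[[nm]])) {
      x[[nm]] <- vapply(x[[nm]], function(v) {
        paste(format(v, digits = 10, trim = TRUE), collapse = ";")
      }, "")
    }
  }
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read image channels from TIFF files
#'
#' Builds an [image_stack()] from single- or multi-page TIFFs, one file per
#' channel; multi-page files become z-stacks.
#'
#' @param paths named character vector of TIFF paths; names are channel
#'   names and must include `"dapi"`.
#' @return an [image_stack()].
#' @export
read_image_channels <- function(paths) {
  stopifnot(!is.null(names(paths)), "dapi" %in% names(paths))
  channels <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(m) {
      if (length(dim(m)) == 3) m <- m[, , 1]  # collapse grayscale-as-RGB
      m
    })
    if (length(pages) == 1) pages[[1]]
    else array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  })
  image_stack(channels)
}

#' Write a channel or label map to TIFF
#'
#' Intensities are rescaled to the 16-bit range for storage; label maps are
#' written as-is (labels / 65535) so they can be audited in image viewers.
#'
#' @param x 2D matrix or 3D array.
#' @param path output path.
#' @param rescale divide by `max(x)` before writing (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path, rescale = TRUE) {
  top <- if (rescale && max(x) > 0) max(x) else 1
  img <- x / top
  if (length(dim(x)) == 3) {
    tiff::writeTIFF(lapply(seq_len(dim(x)[3]), function(k) img[, , k]),
                    path, bits.per.sample = 16)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 16)
  }
  invisible(path)
}
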