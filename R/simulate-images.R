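#' Simulate a ground-truthed microscopy scene
#'
#' Renders a two-channel confocal-like field: a DAPI channel of filled,
#' randomly oriented noisy ellipses (nuclei) and a focus channel of
#' isotropic 2D Gaussian spots planted inside the nuclei over a flat
#' background. Focus amplitudes are specified in units of the background
#' noise SD, so signal-to-noise-based acceptance thresholds are well
#' defined. With `z_planes > 1` each focus is placed in a single random
#' plane, exercising the maximum-intensity projection.
#'
#' Limits of realism: no point-spread function, no illumination gradients,
#' no chromatic aberration, no overlapping nuclei unless forced.
#'
#' @param width,height image size in pixels.
#' @param n_nuclei number of nuclei (placed non-overlapping, away from the
#'   border).
#' @param nucleus_axes range (min, max) of ellipse semi-axes in pixels.
#' @param foci_per_nucleus mean or fixed number of foci per nucleus.
#' @param foci_distribution `"fixed"` or `"poisson"` (mean
#'   `foci_per_nucleus`; Poisson draws whose placement cannot satisfy the
#'   separation constraint inside the nucleus are redrawn, i.e. counts are
#'   conditioned on geometric feasibility).
#' @param focus_amplitude peak height of a focus, in noise-SD units.
#' @param focus_sigma Gaussian sigma of a focus in pixels.
#' @param background flat background level (both channels).
#' @param noise_sd SD of the additive Gaussian noise.
#' @param noise `"gaussian"` (default) or `"poisson"` (shot noise on the
#'   noiseless intensity; `noise_sd` then only scales focus amplitudes).
#' @param dapi_level nucleus intensity in the DAPI channel.
#' @param z_planes number of z-planes in the focus channel.
#' @param min_focus_separation minimum distance between planted foci within
#'   a nucleus (pixels).
#' @param channel_name name of the focus channel (default `"gH2AX"`).
#' @param seed integer seed (private stream; global RNG untouched).
#' @return list: `stack` (an [image_stack()]), `truth` (list with `nuclei`:
#'   data.frame `nucleus_id`, `center_row`, `center_col`, `semi_a`,
#'   `semi_b`, `theta`, `n_foci`; and `foci`: data.frame `nucleus_id`,
#'   `row`, `col`, `amplitude`, `plane`, 0-based coordinates).
#' @export
simulate_images <- function(width = 256, height = 256,
                            n_nuclei = 5,
                            nucleus_axes = c(18, 26),
                            foci_per_nucleus = 10,
                            foci_distribution = c("fixed", "poisson"),
                            focus_amplitude = 8,
                            focus_sigma = 1.5,
                            background = 100,
                            noise_sd = 10,
                            noise = c("gaussian", "poisson"),
                            dapi_level = 150,
                            z_planes = 1,
                            min_focus_separation = 6,
                            channel_name = "gH2AX",
                            seed = NULL) {
  foci_distribution <- match.arg(foci_distribution)
  noise <- match.arg(noise)
  stopifnot(n_nuclei >= 0, focus_sigma > 0, noise_sd > 0, z_planes >= 1)
  local_rng(seed, "images")

  nr <- height; nc <- width
  margin <- nucleus_axes[2] + 3

  centers <- matrix(numeric(0), ncol = 2)
  nuclei <- vector("list", n_nuclei)
  tries <- 0L
  i <- 1L
  while (i <= n_nuclei) {
    tries <- tries + 1L
    if (tries > 200 * max(n_nuclei, 1)) {
      stop("infeasible placement: cannot fit ", n_nuclei,
           " non-overlapping nuclei of semi-axes ",
           paste(nucleus_axes, collapse = "-"), " in a ",
           nr, " x ", nc, " image")
    }
    cy <- stats::runif(1, margin, nr - margin)
    cx <- stats::runif(1, margin, nc - margin)
    if (nrow(centers) > 0 &&
        any(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) <
            2.2 * nucleus_axes[2])) next
    nuclei[[i]] <- list(
      cy = cy, cx = cx,
      a = stats::runif(1, nucleus_axes[1], nucleus_axes[2]),
      b = stats::runif(1, nucleus_axes[1], nucleus_axes[2]),
      theta = stats::runif(1, 0, pi)
    )
    centers <- rbind(centers, c(cy, cx))
    i <- i + 1L
  }

  dapi <- matrix(0, nr, nc)
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  masks <- vector("list", n_nuclei)
  for (i in seq_len(n_nuclei)) {
    nu <- nuclei[[i]]
    dy <- rowg - nu$cy; dx <- colg - nu$cx
    u <- dy * cos(nu$theta) + dx * sin(nu$theta)
    v <- -dy * sin(nu$theta) + dx * cos(nu$theta)
    masks[[i]] <- (u / nu$a)^2 + (v / nu$b)^2 <= 1
    dapi[masks[[i]]] <- dapi_level
  }

  # plant foci
  foci <- list(); fk <- 0L
  n_foci <- integer(n_nuclei)
  for (i in seq_len(n_nuclei)) {
    nu <- nuclei[[i]]
    place_k <- function(k) {
      pts <- matrix(numeric(0), ncol = 2)
      attempts <- 0L
      while (nrow(pts) < k) {
        attempts <- attempts + 1L
        if (attempts > 500 * max(k, 1)) return(NULL)
        # sample within 80% of the ellipse so foci sit clearly inside
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * 0.8
        u <- rad * cos(ang) * nu$a; v <- rad * sin(ang) * nu$b
        py <- nu$cy + u * cos(nu$theta) - v * sin(nu$theta)
        px <- nu$cx + u * sin(nu$theta) + v * cos(nu$theta)
        if (nrow(pts) > 0 &&
            any(sqrt((pts[, 1] - py)^2 + (pts[, 2] - px)^2) <
                min_focus_separation)) next
        pts <- rbind(pts, c(py, px))
      }
      pts
    }
    if (foci_distribution == "fixed") {
      k <- round(foci_per_nucleus)
      pts <- place_k(k)
      if (is.null(pts)) {
        stop("infeasible placement: cannot fit ", k, " foci separated by ",
             min_focus_separation, " px inside nucleus ", i)
      }
    } else {
      # Poisson counts conditioned on geometric feasibility: a draw whose
      # placement cannot satisfy the separation constraint is redrawn
      for (redraw in 1:20) {
        k <- stats::rpois(1, foci_per_nucleus)
        pts <- place_k(k)
        if (!is.null(pts)) break
      }
      if (is.null(pts)) {
        stop("infeasible placement: Poisson focus counts around ",
             foci_per_nucleus, " cannot be separated by ",
             min_focus_separation, " px inside nucleus ", i)
      }
    }
    n_foci[i] <- as.integer(k)
    for (j in seq_len(k)) {
      fk <- fk + 1L
      foci[[fk]] <- data.frame(
        nucleus_id = i, row = pts[j, 1] - 1, col = pts[j, 2] - 1,
        amplitude = focus_amplitude,
        plane = sample.int(z_planes, 1))
    }
  }
  truth_foci <- if (fk > 0) do.call(rbind, foci) else {
    data.frame(nucleus_id = integer(), row = numeric(), col = numeric(),
               amplitude = numeric(), plane = integer())
  }

  # render focus channel (per plane), then add noise
  spot <- function(plane_img, fy, fx, amp) {
    # additive Gaussian footprint on a local window (+/- 4 sigma)
    w <- ceiling(4 * focus_sigma)
    ys <- max(1, floor(fy) - w):min(nr, ceiling(fy) + w)
    xs <- max(1, floor(fx) - w):min(nc, ceiling(fx) + w)
    g <- outer(ys - fy, xs - fx,
               function(dy, dx) exp(-(dy^2 + dx^2) / (2 * focus_sigma^2)))
    plane_img[ys, xs] <- plane_img[ys, xs] + amp * g
    plane_img
  }
  amp_abs <- focus_amplitude * noise_sd
  planes <- array(background, dim = c(nr, nc, z_planes))
  if (fk > 0) {
    for (j in seq_len(nrow(truth_foci))) {
      p <- truth_foci$plane[j]
      planes[, , p] <- spot(planes[, , p], truth_foci$row[j] + 1,
                            truth_foci$col[j] + 1, amp_abs)
    }
  }
  add_noise <- function(img) {
    if (noise == "gaussian") pmax(img + stats::rnorm(length(img), 0, noise_sd), 0)
    else matrix(stats::rpois(length(img), pmax(img, 0)), nrow(img))
  }
  for (p in seq_len(z_planes)) planes[, , p] <- add_noise(planes[, , p])
  focus_channel <- if (z_planes == 1) planes[, , 1] else planes

  dapi_noisy <- add_noise(dapi + background)

  truth_nuclei <- data.frame(
    nucleus_id = seq_len(n_nuclei),
    center_row = vapply(nuclei, function(n) n$cy - 1, 0),
    center_col = vapply(nuclei, function(n) n$cx - 1, 0),
    semi_a = vapply(nuclei, function(n) n$a, 0),
    semi_b = vapply(nuclei, function(n) n$b, 0),
    theta = vapply(nuclei, function(n) n$theta, 0),
    area = vapply(seq_len(max(n_nuclei, 0)), function(i) sum(masks[[i]]), 0L),
    n_foci = n_foci
  )
  if (n_nuclei == 0) {
    truth_nuclei <- truth_nuclei[0, , drop = FALSE]
  }

  channels <- stats::setNames(list(dapi_noisy, focus_channel),
                              c("dapi", channel_name))
  list(stack = image_stack(channels),
       truth = list(nuclei = truth_nuclei, foci = truth_foci))
}
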