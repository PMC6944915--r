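# Independent reference implementations used to validate the package's
# detection and microhomology code. Deliberately naive: explicit loops,
# stack-based flood fill, exhaustive enumeration.

# Brute-force focus detection: per-pixel threshold test + naive flood fill.
oracle_detect_foci <- function(dog, labels, k_sd, abs_min, min_focus_area,
                               connectivity = 8, robust = TRUE) {
  ids <- sort(unique(labels[labels > 0]))
  ids <- ids[vapply(ids, function(i) sum(labels == i) >= 10, TRUE)]
  if (length(ids) == 0) {
    return(data.frame(nucleus_id = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      peak_intensity = numeric(), total_intensity = numeric()))
  }
  med <- sdv <- numeric(max(ids))
  for (i in ids) {
    v <- dog[labels == i]
    med[i] <- median(v)
    sdv[i] <- if (robust) mad(v) else sd(v)
  }
  ref_sd <- median(sdv[ids])
  nr <- nrow(dog); nc <- ncol(dog)
  pass <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    l <- labels[r, c]
    if (l > 0 && l %in% ids &&
        dog[r, c] > med[l] + k_sd * ref_sd && dog[r, c] > abs_min) {
      pass[r, c] <- TRUE
    }
  }
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  seen <- matrix(FALSE, nr, nc)
  out <- list()
  for (r in 1:nr) for (c in 1:nc) {
    if (!pass[r, c] || seen[r, c]) next
    stack <- list(c(r, c)); seen[r, c] <- TRUE
    px <- matrix(numeric(0), ncol = 2)
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      px <- rbind(px, p)
      for (k in seq_len(nrow(offs))) {
        rn <- p[1] + offs[k, 1]; cn <- p[2] + offs[k, 2]
        if (rn < 1 || rn > nr || cn < 1 || cn > nc) next
        if (pass[rn, cn] && !seen[rn, cn] &&
            labels[rn, cn] == labels[r, c]) {
          seen[rn, cn] <- TRUE
          stack[[length(stack) + 1]] <- c(rn, cn)
        }
      }
    }
    if (nrow(px) >= min_focus_area) {
      vals <- dog[px]
      out[[length(out) + 1]] <- data.frame(
        nucleus_id = labels[r, c], area = nrow(px),
        centroid_row = mean(px[, 1]) - 1, centroid_col = mean(px[, 2]) - 1,
        peak_intensity = max(vals), total_intensity = sum(vals))
    }
  }
  df <- if (length(out)) do.call(rbind, out) else {
    data.frame(nucleus_id = integer(), area = integer(),
               centroid_row = numeric(), centroid_col = numeric(),
               peak_intensity = numeric(), total_intensity = numeric())
  }
  df[order(df$nucleus_id, df$centroid_row, df$centroid_col), , drop = FALSE]
}

# Random labelled instance for oracle-equivalence checks: a few rectangular
# "nuclei" over a 64 x 64 field of Gaussian noise with planted bright blobs.
make_detect_instance <- function(seed) {
  set.seed(seed)
  nr <- nc <- 64
  labels <- matrix(0L, nr, nc)
  n_nuc <- sample(2:3, 1)
  anchors <- list(c(4, 4), c(4, 36), c(36, 4), c(36, 36))[sample.int(4, n_nuc)]
  for (i in seq_len(n_nuc)) {
    a <- anchors[[i]]
    h <- sample(14:22, 1); w <- sample(14:22, 1)
    labels[a[1]:(a[1] + h), a[2]:(a[2] + w)] <- i
  }
  dog <- matrix(rnorm(nr * nc), nr, nc)
  for (b in seq_len(sample(3:8, 1))) {
    inside <- which(labels > 0)
    p <- inside[sample.int(length(inside), 1)]
    r <- (p - 1) %% nr + 1; c <- (p - 1) %/% nr + 1
    rr <- max(1, r - 1):min(nr, r + 1)
    cc <- max(1, c - 1):min(nc, c + 1)
    dog[rr, cc] <- dog[rr, cc] + runif(1, 3, 8)
  }
  list(dog = dog, labels = labels,
       k_sd = sample(c(2, 2.5, 3), 1),
       abs_min = sample(c(0, 0.5, 1), 1),
       min_focus_area = sample(2:4, 1),
       connectivity = sample(c(4L, 8L), 1))
}

# wrap a label matrix as the package's nucleus_label_map
as_label_map <- function(labels) {
  areas <- tabulate(labels[labels > 0], nbins = max(labels, 1L))
  structure(list(labels = labels,
                 nuclei = data.frame(nucleus_id = seq_along(areas),
                                     area = areas)[areas > 0, , drop = FALSE]),
            class = "nucleus_label_map")
}

# Brute-force microhomology: count all equal-size deletion placements that
# produce the identical repaired sequence; cap at the deletion size.
oracle_microhomology <- function(seqc, del_start, del_end) {
  L <- nchar(seqc)
  d <- del_end - del_start
  repaired <- paste0(substr(seqc, 1, del_start), substr(seqc, del_end + 1, L))
  n_same <- 0L
  for (s in 0:(L - d)) {
    alt <- paste0(substr(seqc, 1, s), substr(seqc, s + d + 1, L))
    if (alt == repaired) n_same <- n_same + 1L
  }
  min(n_same - 1L, d)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# small helper: compare detect_foci output with the oracle data frame
expect_foci_equal <- function(calls, oracle) {
  got <- calls$foci[order(calls$foci$nucleus_id, calls$foci$centroid_row,
                          calls$foci$centroid_col),
                    c("nucleus_id", "area", "centroid_row", "centroid_col",
                      "peak_intensity", "total_intensity")]
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(nrow(got), nrow(oracle))
  if (nrow(got) > 0) {
    expect_equal(got$nucleus_id, oracle$nucleus_id)
    expect_equal(got$area, oracle$area)
    expect_equal(got$centroid_row, oracle$centroid_row, tolerance = 1e-12)
    expect_equal(got$centroid_col, oracle$centroid_col, tolerance = 1e-12)
    expect_equal(got$peak_intensity, oracle$peak_intensity, tolerance = 1e-12)
    expect_equal(got$total_intensity, oracle$total_intensity, tolerance = 1e-12)
  }
}
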