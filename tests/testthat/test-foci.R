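# Nucleus segmentation, projection, DoG filtering, and focus detection

test_that("segmentation handles blank images and recovers planted ellipses", {
  expect_warning(seg <- segment_nuclei(matrix(0, 64, 64)), "empty foreground")
  expect_equal(nrow(seg$nuclei), 0L)

  sim <- simulate_images(n_nuclei = 1, foci_per_nucleus = 0, seed = 21,
                         nucleus_axes = c(15, 20))
  dapi <- max_project(sim$stack, "dapi")
  seg <- segment_nuclei(dapi, foci_params())
  expect_equal(nrow(seg$nuclei), 1L)
  planted <- sim$truth$nuclei$area[1]
  expect_lt(abs(seg$nuclei$area[1] - planted) / planted, 0.05)
})

test_that("watershed separates touching nuclei", {
  # two high-SNR ellipses overlapping by ~20% of the minor axis
  img <- matrix(0, 128, 128)
  rowg <- matrix(seq_len(128), 128, 128)
  colg <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  e1 <- ((rowg - 64) / 15)^2 + ((colg - 45) / 20)^2 <= 1
  e2 <- ((rowg - 64) / 15)^2 + ((colg - 81) / 20)^2 <= 1
  img[e1 | e2] <- 200
  set.seed(99)
  img <- pmax(img + rnorm(length(img), 0, 5) + 20, 0)
  seg <- segment_nuclei(img, foci_params(min_nucleus_area = 300))
  expect_equal(nrow(seg$nuclei), 2L)
})

test_that("max projection is the per-pixel maximum and identity at one plane", {
  a2 <- matrix(runif(36), 6, 6)
  st <- image_stack(list(dapi = a2, gH2AX = a2))
  expect_identical(max_project(st, "gH2AX"), a2)
  set.seed(3)
  a3 <- array(runif(6 * 6 * 5), dim = c(6, 6, 5))
  st3 <- image_stack(list(dapi = a2, gH2AX = a3))
  got <- max_project(st3, "gH2AX")
  brute <- matrix(0, 6, 6)
  for (r in 1:6) for (c in 1:6) brute[r, c] <- max(a3[r, c, ])
  expect_equal(got, brute)
  expect_error(max_project(st3, "53BP1"), "unknown channel")
})

test_that("DoG annihilates constants, is linear, and peaks on planted spots", {
  const <- matrix(7.5, 32, 32)
  expect_lt(max(abs(dog_subtract(const, 1, 3))), 1e-6 * 7.5)

  set.seed(4)
  img <- matrix(runif(32 * 32, 0, 10), 32, 32)
  expect_equal(dog_subtract(img * 3.5, 1, 4), 3.5 * dog_subtract(img, 1, 4),
               tolerance = 1e-10)

  spot <- outer(1:63, 1:63, function(r, c) 50 * exp(-((r - 32)^2 + (c - 32)^2) / (2 * 4)))
  d <- dog_subtract(spot + 5, 1, 4)
  expect_equal(which(d == max(d)), which.max(spot))
})

test_that("detect_foci matches the brute-force oracle on random instances", {
  for (s in 1:12) {
    inst <- make_detect_instance(1000 + s)
    params <- foci_params(k_sd = inst$k_sd, abs_min = inst$abs_min,
                          min_focus_area = inst$min_focus_area,
                          connectivity = inst$connectivity)
    calls <- detect_foci(inst$dog, as_label_map(inst$labels), params)
    oracle <- oracle_detect_foci(inst$dog, inst$labels, inst$k_sd,
                                 inst$abs_min, inst$min_focus_area,
                                 inst$connectivity)
    expect_foci_equal(calls, oracle)
  }
})

test_that("a single bright planted focus is found at its planted center", {
  sim <- simulate_images(n_nuclei = 1, foci_per_nucleus = 1,
                         focus_amplitude = 10, seed = 31)
  res <- run_irif_pipeline(sim$stack, "gH2AX")
  expect_equal(nrow(res$foci), 1L)
  expect_lt(abs(res$foci$centroid_row - sim$truth$foci$row), 1)
  expect_lt(abs(res$foci$centroid_col - sim$truth$foci$col), 1)
})

test_that("noise below threshold yields zero foci", {
  sim <- simulate_images(n_nuclei = 3, foci_per_nucleus = 0, seed = 32)
  res <- run_irif_pipeline(sim$stack, "gH2AX", foci_params(k_sd = 4))
  expect_equal(sum(res$nuclei$focus_count), 0L)
})

test_that("foci lie inside single nuclei and counts are consistent", {
  sim <- simulate_images(n_nuclei = 4, foci_per_nucleus = 8, seed = 33)
  res <- run_irif_pipeline(sim$stack, "gH2AX")
  expect_true(all(res$foci$nucleus_id %in% res$nuclei$nucleus_id))
  for (i in res$nuclei$nucleus_id) {
    expect_equal(res$nuclei$focus_count[res$nuclei$nucleus_id == i],
                 sum(res$foci$nucleus_id == i))
  }
  # focus centroids fall on pixels labelled with their nucleus
  for (k in seq_len(nrow(res$foci))) {
    r <- round(res$foci$centroid_row[k]) + 1
    c <- round(res$foci$centroid_col[k]) + 1
    expect_equal(res$labels[r, c], res$foci$nucleus_id[k])
  }
})

test_that("focus counts are non-increasing in k_sd, abs_min and min_focus_area", {
  sim <- simulate_images(n_nuclei = 4, foci_per_nucleus = 8,
                         focus_amplitude = 5, seed = 34)
  dapi <- max_project(sim$stack, "dapi")
  seg <- segment_nuclei(dapi, foci_params())
  dog <- dog_subtract(max_project(sim$stack, "gH2AX"), 1, 3)
  count_with <- function(...) {
    sum(detect_foci(dog, seg, foci_params(...))$nuclei$focus_count)
  }
  for (grid in list(
    lapply(c(1.5, 2, 3, 4), function(k) list(k_sd = k)),
    lapply(c(0, 5, 15, 40), function(a) list(k_sd = 2, abs_min = a)),
    lapply(c(1, 3, 6, 12), function(m) list(k_sd = 2, min_focus_area = m))
  )) {
    counts <- vapply(grid, function(g) do.call(count_with, g), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("per-nucleus constant offsets do not change counts after DoG", {
  sim <- simulate_images(n_nuclei = 4, foci_per_nucleus = 6, seed = 35)
  dapi <- max_project(sim$stack, "dapi")
  seg <- segment_nuclei(dapi, foci_params())
  raw <- max_project(sim$stack, "gH2AX")
  base <- detect_foci(dog_subtract(raw, 1, 3), seg, foci_params())
  shifted <- raw
  offs <- c(5, 15, 8, 12)
  for (i in seg$nuclei$nucleus_id) {
    shifted[seg$labels == i] <- shifted[seg$labels == i] + offs[i]
  }
  moved <- detect_foci(dog_subtract(shifted, 1, 3), seg, foci_params())
  expect_equal(moved$nuclei$focus_count, base$nuclei$focus_count)
})

test_that("relabelling nuclei leaves per-nucleus counts unchanged", {
  sim <- simulate_images(n_nuclei = 4, foci_per_nucleus = 6, seed = 36)
  dapi <- max_project(sim$stack, "dapi")
  seg <- segment_nuclei(dapi, foci_params())
  dog <- dog_subtract(max_project(sim$stack, "gH2AX"), 1, 3)
  base <- detect_foci(dog, seg, foci_params())
  perm <- c(3L, 4L, 1L, 2L)
  seg2 <- seg
  seg2$labels[seg$labels > 0] <- perm[seg$labels[seg$labels > 0]]
  seg2$nuclei$nucleus_id <- perm[seg$nuclei$nucleus_id]
  seg2$nuclei <- seg2$nuclei[order(seg2$nuclei$nucleus_id), ]
  moved <- detect_foci(dog, seg2, foci_params())
  expect_equal(moved$nuclei$focus_count[match(perm, moved$nuclei$nucleus_id)],
               base$nuclei$focus_count)
})

test_that("z-stacks are projected before detection", {
  sim <- simulate_images(n_nuclei = 3, foci_per_nucleus = 6, z_planes = 4,
                         seed = 37)
  res <- run_irif_pipeline(sim$stack, "gH2AX")
  expect_equal(sum(res$nuclei$focus_count), nrow(sim$truth$foci))
})
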