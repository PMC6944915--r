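# Z-score computation, hit calling, deconvolution, normalizations, t-test

make_plate <- function(readouts, genes = sprintf("G%02d", seq_along(readouts)),
                       replicate = 1, plate = "P01",
                       ctrl_readouts = c(0.30, 0.31)) {
  n <- length(readouts)
  rbind(
    data.frame(plate_id = plate, well_id = sprintf("A%02d", seq_len(n)),
               gene = genes, sirna_id = "pool", condition = "treated",
               replicate = replicate, readout = readouts, is_control = "none",
               stringsAsFactors = FALSE),
    data.frame(plate_id = plate,
               well_id = sprintf("H%02d", seq_along(ctrl_readouts)),
               gene = "Luciferase", sirna_id = "pool", condition = "treated",
               replicate = replicate, readout = ctrl_readouts,
               is_control = "negative_control", stringsAsFactors = FALSE)
  )
}

test_that("z-scores standardize against the group mean and sample SD", {
  tab <- screen_table(make_plate(c(0.1, 0.2, 0.3, 0.4, 0.5)))
  z <- compute_zscores(tab)
  # group {0.1..0.5}: mean 0.3, sample SD 0.15811; top well z = 1.2649
  expect_equal(z$z_mean[z$gene == "G05"], 1.264911, tolerance = 1e-5)
  expect_equal(z$z_mean[z$gene == "G03"], 0)  # equals the group mean
  expect_equal(z$n_replicates, rep(1L, 5))
})

test_that("non-control z-scores have mean 0 and sample SD 1 in each group", {
  sim <- simulate_screen(n_genes = 180, wells_per_plate = 96,
                         n_replicates = 2, seed = 11)
  z <- compute_zscores(sim$table)
  tab <- sim$table[sim$table$is_control == "none", ]
  for (rep_i in 1:2) {
    for (pl in unique(tab$plate_id)) {
      genes <- tab$gene[tab$plate_id == pl & tab$replicate == rep_i]
      zg <- vapply(z$z_per_replicate[match(genes, z$gene)], `[`, 0, rep_i)
      expect_lt(abs(mean(zg)), 1e-9)
      expect_lt(abs(sd(zg) - 1), 1e-9)
    }
  }
})

test_that("degenerate and incomplete inputs are reported", {
  tab <- screen_table(make_plate(rep(0.3, 5)))
  expect_error(compute_zscores(tab), "degenerate")
  # a gene missing from one replicate is kept with reduced n and a warning
  two_rep <- rbind(make_plate(c(0.1, 0.2, 0.3, 0.4, 0.5), replicate = 1),
                   make_plate(c(0.15, 0.25, 0.35, 0.45), replicate = 2))
  expect_warning(z <- compute_zscores(screen_table(two_rep)), "missing replicate")
  expect_equal(z$n_replicates[z$gene == "G05"], 1L)
  expect_equal(z$n_replicates[z$gene == "G01"], 2L)
})

test_that("per-screen scope pools plates and controls can enter the reference", {
  tab <- rbind(make_plate(c(0.1, 0.2, 0.3), plate = "P01"),
               make_plate(c(0.4, 0.5, 0.6), genes = c("G04", "G05", "G06"),
                          plate = "P02"))
  z_plate <- compute_zscores(screen_table(tab), scope = "per_plate")
  z_screen <- compute_zscores(screen_table(tab), scope = "per_screen")
  expect_false(isTRUE(all.equal(z_plate$z_mean, z_screen$z_mean)))
  expect_lt(abs(mean(unlist(z_screen$z_per_replicate))), 1e-9)
  z_ctrl <- compute_zscores(screen_table(tab), include_controls = TRUE)
  expect_false(isTRUE(all.equal(z_plate$z_mean, z_ctrl$z_mean)))
})

test_that("hit calling uses inclusive asymmetric cutoffs", {
  z <- data.frame(gene = sprintf("G%d", 1:5), sirna_id = "pool",
                  z_mean = c(2.0, 1.99, -0.99, -1.0, -3.2))
  h <- call_hits(z)
  expect_equal(h$direction, c("increased", "none", "none",
                              "decreased", "decreased"))
  expect_error(call_hits(z, up_cutoff = 0), "positive")
})

test_that("raising cutoffs never adds calls (monotonicity)", {
  set.seed(1)
  z <- data.frame(gene = sprintf("G%03d", 1:300), sirna_id = "pool",
                  z_mean = rnorm(300, 0, 1.5))
  prev_up <- prev_dn <- NULL
  for (cut in c(1, 1.5, 2, 2.5, 3)) {
    h <- call_hits(z, up_cutoff = cut, down_cutoff = cut)
    up <- h$gene[h$direction == "increased"]
    dn <- h$gene[h$direction == "decreased"]
    if (!is.null(prev_up)) {
      expect_true(all(up %in% prev_up))
      expect_true(all(dn %in% prev_dn))
    }
    prev_up <- up; prev_dn <- dn
  }
})

test_that("a strongly planted gene attains the top z-score", {
  sim <- simulate_screen(n_genes = 529, n_replicates = 1, seed = 5,
                         planted_hits = data.frame(gene = "GENE100",
                                                   direction = "increased",
                                                   effect_size = 4))
  z <- compute_zscores(sim$table)
  expect_equal(z$gene[which.max(z$z_mean)], "GENE100")
})

test_that("planted effects are recovered with low false discovery over 20 screens", {
  planted <- data.frame(gene = sprintf("GENE%03d", seq_len(41) * 12),
                        direction = rep(c("decreased", "increased"), c(28, 13)))
  tp_sens <- numeric(0); fp <- calls <- 0
  for (s in 1:20) {
    sim <- simulate_screen(planted_hits = planted, seed = 9000 + s)
    hits <- call_hits(compute_zscores(sim$table))
    sc <- score_screen_calls(hits, sim$truth)
    tp_sens <- c(tp_sens, sc$sensitivity)
    called <- hits[hits$direction != "none", ]
    fp <- fp + sum(!called$gene %in% planted$gene)
    calls <- calls + nrow(called)
  }
  expect_gte(mean(tp_sens), 0.95)
  expect_lte(fp / calls, 0.05)
})

make_deconv_table <- function(oligo_readouts, ctrl = c(0.50, 0.52, 0.48, 0.50),
                              n_experiments = 2) {
  do.call(rbind, lapply(seq_len(n_experiments), function(e) {
    n <- length(oligo_readouts)
    rbind(
      data.frame(plate_id = "P01", well_id = sprintf("A%02d", seq_len(n)),
                 gene = "GENE1", sirna_id = sprintf("oligo%d", seq_len(n)),
                 condition = "treated", replicate = e,
                 readout = oligo_readouts, is_control = "none",
                 stringsAsFactors = FALSE),
      data.frame(plate_id = "P01", well_id = sprintf("H%02d", seq_along(ctrl)),
                 gene = "Luciferase", sirna_id = "pool", condition = "treated",
                 replicate = e, readout = ctrl,
                 is_control = "negative_control", stringsAsFactors = FALSE))
  }))
}

test_that("deconvolution scores oligo deviation against the control SD", {
  # control {0.50, 0.52, 0.48, 0.50}: mean 0.50, sample SD 0.016330;
  # an oligo at 0.51 deviates by 0.61 control SDs > 0.5, so it is altered,
  # but one altered oligo of four is below the 2-oligo validation rule
  d <- deconvolve(screen_table(make_deconv_table(c(0.51, 0.50, 0.50, 0.50))))
  expect_equal(d$n_oligos_altered, 1L)
  expect_false(d$validated)
  # all oligos at the control mean: nothing altered
  d0 <- deconvolve(screen_table(make_deconv_table(rep(0.50, 4))))
  expect_equal(d0$n_oligos_altered, 0L)
  expect_equal(d0$direction, "none")
  # an oligo within 0.5 SD is not altered
  d1 <- deconvolve(screen_table(make_deconv_table(c(0.505, 0.50, 0.50, 0.50))))
  expect_equal(d1$n_oligos_altered, 0L)
})

test_that("a gene validates with >= 2 oligos altered in >= 2 experiments", {
  # 3 of 4 oligos displaced by 5 control SDs in both experiments
  s <- sd(c(0.50, 0.52, 0.48, 0.50))
  d <- deconvolve(screen_table(make_deconv_table(0.50 + c(5, 5, 5, 0) * s)))
  expect_true(d$validated)
  expect_equal(d$n_oligos_altered, 3L)
  expect_equal(d$direction, "increased")
  # altered in only one experiment: does not validate
  one_exp <- make_deconv_table(0.50 + c(5, 5, 5, 0) * s, n_experiments = 2)
  one_exp$readout[one_exp$replicate == 2 & one_exp$is_control == "none"] <- 0.50
  d2 <- deconvolve(screen_table(one_exp))
  expect_false(d2$validated)
  # fewer than 2 control wells: SD undefined
  short <- make_deconv_table(c(0.51, 0.5, 0.5, 0.5), ctrl = 0.50)
  expect_error(deconvolve(screen_table(short)), "control")
})

test_that("normalized ratios set the negative control to exactly 1", {
  r <- normalized_ratio(30, 60, control_ratio = 0.5, kind = "RME")
  expect_identical(r$raw_ratio, 0.5)
  expect_identical(r$normalized, 1)
  expect_equal(normalized_ratio(45, 60, 0.5)$normalized, 1.5)
  expect_equal(normalized_ratio(0, 60, 0.5)$normalized, 0)
  expect_error(normalized_ratio(30, 0, 0.5), "untreated")
})

test_that("repair efficiency is the marker fraction relative to control", {
  expect_equal(repair_efficiency(200, 1000, 0.20)$normalized, 1)
  expect_equal(repair_efficiency(100, 1000, 0.20)$normalized, 0.5)
  expect_identical(repair_efficiency(0, 1000, 0.20)$normalized, 0)
  expect_error(repair_efficiency(10, 0, 0.2), "positive")
  expect_error(repair_efficiency(20, 10, 0.2), "lie in")
})

test_that("two-sample t-test matches the classical pooled statistic", {
  r <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))  # pooled SD 1
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4L)
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_ttest(c(1, 1), c(1, 1)), "variance")
  # p falls monotonically as the mean separation grows at fixed variance
  base <- c(-1, 0, 1)
  ps <- vapply(seq(0, 3, by = 0.5),
               function(d) two_sample_ttest(base, base + d)$p, 0)
  expect_true(all(diff(ps) <= 0))
})
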