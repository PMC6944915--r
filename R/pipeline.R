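#' Default run configuration
#'
#' The full parameter set of a pipeline run, with every default matching
#' the package's documented stage defaults. A user config (YAML or list)
#' overrides fields; the merged effective config is serialized next to the
#' outputs of every run.
#'
#' @return nested list of per-stage parameter defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    stages = c("simulate_screen", "screen"),
    simulate_screen = list(n_genes = 529, oligos_per_gene = 4,
                           n_replicates = 3, wells_per_plate = 96,
                           null_mean = 0.30, null_sd = 0.05, pooled = TRUE),
    screen = list(input = NULL, scope = "per_plate", include_controls = FALSE,
                  up_cutoff = 2, down_cutoff = 1),
    simulate_images = list(width = 256, height = 256, n_nuclei = 5,
                           foci_per_nucleus = 10, focus_amplitude = 8,
                           z_planes = 1),
    foci = list(dapi = NULL, channel = NULL, channel_name = "gH2AX",
                median_radius = 2, min_nucleus_area = 200,
                dog_sigma_small = 1, dog_sigma_large = 3,
                k_sd = 3, abs_min = 0, min_focus_area = 3, connectivity = 8),
    simulate_junctions = list(n_reads = 70, error_rate = 0),
    junctions = list(reads = NULL, reference = NULL, cut_position = NULL,
                     min_anchor = 10,
                     size_bins = c(1, 2, 6, 21, 101), mh_bins = c(0, 1, 3, 6))
  )
}

#' Validate a run configuration
#'
#' Checks structural constraints before anything executes and reports the
#' offending field by name.
#'
#' @param config nested list (after merging onto [default_run_config()]).
#' @return `config`, invisibly; errors on violation.
#' @export
validate_run_config <- function(config) {
  known <- c("simulate_screen", "screen", "simulate_images", "foci",
             "simulate_junctions", "junctions")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  f <- config$foci
  if (!is.null(f$dog_sigma_small) && !is.null(f$dog_sigma_large) &&
      f$dog_sigma_small >= f$dog_sigma_large) {
    stop("invalid config: foci.dog_sigma_small must be smaller than ",
         "foci.dog_sigma_large")
  }
  if (!is.null(f$k_sd) && f$k_sd <= 0) stop("invalid config: foci.k_sd must be > 0")
  s <- config$screen
  if (!is.null(s$up_cutoff) && s$up_cutoff <= 0) {
    stop("invalid config: screen.up_cutoff must be > 0")
  }
  if (!is.null(s$down_cutoff) && s$down_cutoff <= 0) {
    stop("invalid config: screen.down_cutoff must be > 0")
  }
  j <- config$junctions
  if (!is.null(j$size_bins) && any(diff(j$size_bins) <= 0)) {
    stop("invalid config: junctions.size_bins must be strictly increasing")
  }
  invisible(config)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the configured pipeline stages
#'
#' Executes the requested stages in dependency order (simulators before
#' their consumers), writing each stage's tables as CSV into `out_dir`,
#' followed by the merged effective config (`config.yaml`) and a manifest
#' (`manifest.json`) listing every output file with its MD5 checksum.
#' Reruns with an identical config reproduce identical manifests for the
#' deterministic stages. Inputs are never modified.
#'
#' When an analysis stage has no input path configured, it consumes the
#' matching simulator's in-run output (`screen` <- `simulate_screen`,
#' `foci` <- `simulate_images`, `junctions` <- `simulate_junctions`).
#'
#' @param config path to a YAML config, or a nested list; fields override
#'   [default_run_config()].
#' @param out_dir output directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param seed overrides `config$seed`.
#' @param overwrite allow writing into a directory holding a previous run.
#' @return list with `manifest` (data.frame `file`, `md5`) and the per-stage
#'   results, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("recoverkit_run_"),
                         seed = NULL, overwrite = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  validate_run_config(cfg)

  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "manifest.json")) &&
      !overwrite) {
    stop("out_dir already holds a run (manifest.json present); ",
         "outputs are write-once per run directory")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[recoverkit] ", ...)

  results <- list()
  outputs <- character()
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    write_result_csv(obj, p)
    outputs <<- c(outputs, p)
  }

  for (stage in cfg$stages) {
    log_msg("stage: ", stage)
    if (stage == "simulate_screen") {
      sim <- do.call(simulate_screen,
                     c(cfg$simulate_screen, list(seed = cfg$seed)))
      results$simulate_screen <- sim
      emit(sim$table, "screen_table.csv")
      emit(sim$truth, "screen_truth.csv")
    } else if (stage == "screen") {
      tab <- if (!is.null(cfg$screen$input)) {
        read_screen_table(cfg$screen$input)
      } else if (!is.null(results$simulate_screen)) {
        results$simulate_screen$table
      } else stop("screen stage has no input and no simulate_screen output")
      z <- compute_zscores(tab, scope = cfg$screen$scope,
                           include_controls = isTRUE(cfg$screen$include_controls))
      hits <- call_hits(z, cfg$screen$up_cutoff, cfg$screen$down_cutoff)
      results$screen <- list(zscores = z, hits = hits)
      emit(z, "zscores.csv")
      emit(hits, "hits.csv")
    } else if (stage == "simulate_images") {
      sim <- do.call(simulate_images,
                     c(cfg$simulate_images, list(seed = cfg$seed)))
      results$simulate_images <- sim
      emit(sim$truth$nuclei, "image_truth_nuclei.csv")
      emit(sim$truth$foci, "image_truth_foci.csv")
    } else if (stage == "foci") {
      fp <- cfg$foci
      params <- foci_params(
        median_radius = fp$median_radius,
        min_nucleus_area = fp$min_nucleus_area,
        dog_sigma_small = fp$dog_sigma_small,
        dog_sigma_large = fp$dog_sigma_large,
        k_sd = fp$k_sd, abs_min = fp$abs_min,
        min_focus_area = fp$min_focus_area,
        connectivity = fp$connectivity)
      stack <- if (!is.null(fp$dapi) && !is.null(fp$channel)) {
        read_image_channels(stats::setNames(c(fp$dapi, fp$channel),
                                            c("dapi", fp$channel_name)))
      } else if (!is.null(results$simulate_images)) {
        results$simulate_images$stack
      } else stop("foci stage has no input and no simulate_images output")
      res <- run_irif_pipeline(stack, fp$channel_name, params)
      results$foci <- res
      emit(res$nuclei, "foci_per_nucleus.csv")
      emit(res$foci, "foci_per_focus.csv")
    } else if (stage == "simulate_junctions") {
      sim <- do.call(simulate_junction_reads,
                     c(cfg$simulate_junctions, list(seed = cfg$seed)))
      results$simulate_junctions <- sim
      fa <- file.path(out_dir, "junction_reads.fasta")
      write_reads_fasta(sim$reads, fa)
      outputs <- c(outputs, fa)
      emit(sim$truth, "junction_truth.csv")
    } else if (stage == "junctions") {
      jc <- cfg$junctions
      ref <- if (!is.null(jc$reference)) {
        read_reference_amplicon(jc$reference, jc$cut_position)
      } else synthetic_amplicon()
      reads <- if (!is.null(jc$reads)) jc$reads
      else if (!is.null(results$simulate_junctions)) {
        results$simulate_junctions$reads
      } else stop("junctions stage has no input and no simulate_junctions output")
      calls <- classify_junctions(reads, ref, min_anchor = jc$min_anchor)
      spec <- junction_spectrum(calls, size_bins = jc$size_bins,
                                mh_bins = jc$mh_bins)
      results$junctions <- list(calls = calls, spectrum = spec)
      emit(calls, "junction_calls.csv")
      emit(data.frame(category = names(spec$category_counts),
                      count = as.integer(spec$category_counts)),
           "junction_categories.csv")
      emit(spec$deletion_size_hist, "junction_deletion_sizes.csv")
      emit(spec$microhomology_hist, "junction_microhomology.csv")
    }
  }

  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  outputs <- c(outputs, file.path(out_dir, "config.yaml"))
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg("wrote ", nrow(manifest), " outputs to ", out_dir)
  invisible(list(manifest = manifest, results = results, out_dir = out_dir))
}
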