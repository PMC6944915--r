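#' Synthetic reference amplicon for junction simulations
#'
#' A fixed 240-nt synthetic amplicon with the expected break midway
#' (cut position 120), shipped so junction simulations and examples run
#' without external sequence data. It is a stand-in, not the sequence of
#' any real reporter construct.
#'
#' @return a [reference_amplicon()] named `"synthetic_amplicon"`.
#' @export
synthetic_amplicon <- function() {
  seqs <- paste0(
    "TGACCTTGGAACGCTAGTCCATGAAGTCGATACCGGTTCAGCTTGAATCCGATGGTCAAC",
    "GTTAGCATCCGGATACTGCAAGTCGTTGGCATCAGTACCGGAAGTTCATGCCAGTCGGAT",
    "ACCGTTAGGCATCAGATCGGTACCATTGGCAAGCTCGGTAACCATGGTCAGATCCGTTAG",
    "CATGGACCTTAGCGGATCAGTTCACGGTAAGCTTGACCGGATCATGGCAACGTTAGGCTC"
  )
  reference_amplicon(seqs, cut_position = 120, name = "synthetic_amplicon")
}

#' Simulate ground-truthed repair-junction reads
#'
#' Generates one read per planted repair event at the reference cut site,
#' emulating Sanger-sequenced single clones of the amplified break region.
#' Category counts are deterministic: `round(cumsum(proportions) * n_reads)`
#' differences, so planted counts always sum to `n_reads`. Events:
#' \describe{
#'   \item{direct}{read identical to the reference (scar-free re-ligation).}
#'   \item{deletion}{an interval spanning (or abutting) the cut is removed;
#'     the placement is chosen to realize the targeted microhomology when
#'     the reference admits it, otherwise size and target are redrawn (up
#'     to `max_tries`, then an error names the constraint).}
#'   \item{delins}{a deletion plus an inserted sequence; insert ends are
#'     chosen to mismatch the flanks so the planted geometry is the unique
#'     parsimonious parse.}
#'   \item{insertion}{new sequence at the cut, flank-mismatched likewise.}
#' }
#' Per-base substitution errors are applied at `error_rate` (default 0).
#'
#' @param reference a [reference_amplicon()]; default [synthetic_amplicon()].
#' @param n_reads number of reads (clones).
#' @param proportions length-4 numeric summing to 1, in the order direct,
#'   deletion, delins, insertion.
#' @param deletion_size_mean mean of the (geometric) deletion-size
#'   distribution.
#' @param max_deletion_size cap on deletion sizes.
#' @param insertion_length_range inclusive range of insertion lengths.
#' @param microhomology_probs named numeric over target microhomology
#'   lengths for simple deletions (default favours short microhomology).
#' @param error_rate per-base substitution probability.
#' @param min_flank reference bases to keep intact on each side (anchor
#'   room).
#' @param max_tries redraws allowed per event before giving up.
#' @param seed integer seed (private stream).
#' @return list: `reads` (named character vector; use
#'   [Biostrings::DNAStringSet] + `writeXStringSet` to export FASTA),
#'   `truth` (data.frame `read_id`, `category`, `del_start`, `del_end`
#'   (canonical leftmost, 0-based half-open), `deletion_size`,
#'   `inserted_seq`, `microhomology_len`, `n_errors`).
#' @export
simulate_junction_reads <- function(reference = synthetic_amplicon(),
                                    n_reads = 70,
                                    proportions = c(direct = 0.4,
                                                    deletion = 0.3,
                                                    delins = 0.2,
                                                    insertion = 0.1),
                                    deletion_size_mean = 10,
                                    max_deletion_size = 40,
                                    insertion_length_range = c(1, 12),
                                    microhomology_probs = c(`0` = 0.45, `1` = 0.3,
                                                            `2` = 0.15, `3` = 0.1),
                                    error_rate = 0,
                                    min_flank = 15,
                                    max_tries = 200,
                                    seed = NULL) {
  stopifnot(inherits(reference, "reference_amplicon"),
            length(proportions) == 4, all(proportions >= 0),
            abs(sum(proportions) - 1) < 1e-9,
            error_rate >= 0, error_rate < 1)
  local_rng(seed, "junctions")

  L <- nchar(reference$sequence)
  cut <- reference$cut_position
  if (max_deletion_size >= L - 2 * min_flank) {
    stop("reference too short for the largest planted deletion")
  }
  cats <- c("direct", "deletion", "delins", "insertion")
  counts <- diff(c(0, round(cumsum(proportions) * n_reads)))
  names(counts) <- cats
  plan <- rep(cats, counts)

  mh_targets <- as.integer(names(microhomology_probs))
  draw_size <- function() {
    min(max_deletion_size, 1L + stats::rgeom(1, 1 / deletion_size_mean))
  }
  # all deletion placements of size d touching the cut, flanks preserved
  placements <- function(d) {
    s <- max(min_flank, cut - d):min(cut, L - d - min_flank)
    s[s >= min_flank & s + d <= L - min_flank]
  }
  pick_deletion <- function() {
    for (try in seq_len(max_tries)) {
      d <- draw_size()
      m <- sample(mh_targets, 1, prob = microhomology_probs)
      cand <- placements(d)
      if (!length(cand)) next
      mh <- vapply(cand, function(s) microhomology(reference, s, s + d), 0L)
      ok <- cand[mh == m]
      if (length(ok)) {
        s <- if (length(ok) == 1) ok else sample(ok, 1)
        return(list(s = s, d = d, mh = m))
      }
    }
    stop("requested microhomology unrealizable on this reference after ",
         max_tries, " redraws")
  }
  mismatch_base <- function(not) {
    sample(setdiff(c("A", "C", "G", "T"), not), 1)
  }
  draw_insert <- function(left_char, right_char) {
    n <- sample(insertion_length_range[1]:insertion_length_range[2], 1)
    ins <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    # flank-mismatched ends make the planted parse unique
    if (n == 1) {
      ins[1] <- mismatch_base(c(left_char, right_char))
    } else {
      ins[1] <- mismatch_base(right_char)
      ins[n] <- mismatch_base(left_char)
    }
    paste(ins, collapse = "")
  }
  ref_char <- function(i0) substr(reference$sequence, i0 + 1, i0 + 1) # 0-based

  reads <- character(length(plan))
  truth <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    cat_i <- plan[i]
    id <- sprintf("read_%03d", i)
    if (cat_i == "direct") {
      rd <- reference$sequence
      tr <- list(ds = NA_integer_, de = NA_integer_, d = 0L, ins = "",
                 mh = NA_integer_)
    } else if (cat_i == "deletion") {
      ev <- pick_deletion()
      rd <- paste0(substr(reference$sequence, 1, ev$s),
                   substr(reference$sequence, ev$s + ev$d + 1, L))
      ds <- ev$s; de <- ev$s + ev$d
      while (ds > 0 && ref_char(ds - 1) == ref_char(de - 1)) { # leftmost form
        ds <- ds - 1L; de <- de - 1L
      }
      tr <- list(ds = ds, de = de, d = ev$d, ins = "", mh = ev$mh)
    } else if (cat_i == "delins") {
      ev <- pick_deletion()
      # insert ends must mismatch the first retained downstream base and the
      # last deleted base so neither anchor extends into the insert
      ins <- draw_insert(left_char = ref_char(ev$s + ev$d - 1),
                         right_char = ref_char(ev$s))
      rd <- paste0(substr(reference$sequence, 1, ev$s), ins,
                   substr(reference$sequence, ev$s + ev$d + 1, L))
      tr <- list(ds = ev$s, de = ev$s + ev$d, d = ev$d, ins = ins,
                 mh = NA_integer_)
    } else { # insertion at the cut
      ins <- draw_insert(left_char = ref_char(cut - 1),
                         right_char = ref_char(cut))
      rd <- paste0(substr(reference$sequence, 1, cut), ins,
                   substr(reference$sequence, cut + 1, L))
      tr <- list(ds = NA_integer_, de = NA_integer_, d = 0L, ins = ins,
                 mh = NA_integer_)
    }
    n_err <- 0L
    if (error_rate > 0) {
      rv <- strsplit(rd, "")[[1]]
      hit <- which(stats::runif(length(rv)) < error_rate)
      for (h in hit) rv[h] <- mismatch_base(rv[h])
      n_err <- length(hit)
      rd <- paste(rv, collapse = "")
    }
    reads[i] <- rd
    truth[[i]] <- data.frame(
      read_id = id, category = cat_i,
      del_start = as.integer(tr$ds), del_end = as.integer(tr$de),
      deletion_size = as.integer(tr$d), inserted_seq = tr$ins,
      microhomology_len = as.integer(tr$mh), n_errors = n_err,
      stringsAsFactors = FALSE)
  }
  names(reads) <- vapply(truth, function(t) t$read_id, "")
  list(reads = reads, truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Write simulated reads to FASTA
#'
#' @param reads named character vector of DNA sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
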