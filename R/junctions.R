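#' Reference amplicon for junction analysis
#'
#' The amplified region around the expected I-SceI break, with the cut
#' position given as the 0-based offset of the boundary between the two
#' nucleotides flanking the break.
#'
#' @param sequence DNA string (A/C/G/T/N), any case.
#' @param cut_position integer, 0 < cut_position < nchar(sequence).
#' @param name label.
#' @return list of class `"reference_amplicon"`.
#' @export
reference_amplicon <- function(sequence, cut_position, name = "amplicon") {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("reference sequence is empty")
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference may contain only A/C/G/T/N")
  }
  if (!(cut_position > 0 && cut_position < nchar(sequence))) {
    stop("cut_position must satisfy 0 < cut_position < length(sequence)")
  }
  structure(list(sequence = sequence, cut_position = as.integer(cut_position),
                 name = name),
            class = "reference_amplicon")
}

#' Read a reference amplicon from FASTA
#'
#' @param path FASTA file with a single record.
#' @param cut_position 0-based cut offset (see [reference_amplicon()]).
#' @return a `"reference_amplicon"`.
#' @export
read_reference_amplicon <- function(path, cut_position) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1) stop("reference FASTA must contain exactly one record")
  reference_amplicon(as.character(ss[[1]]), cut_position, names(ss)[1])
}

#' Anchor a read to the reference by exact flank matching
#'
#' The left anchor is the longest read prefix exactly matching the
#' reference prefix, the right anchor the longest read suffix matching the
#' reference suffix (an `N` never matches). Both raw anchors must reach
#' `min_anchor` or the read is flagged unanchored. The right anchor is then
#' trimmed so the anchors overlap neither on the read nor on the reference
#' (the longer left anchor is preferred); the trimmed geometry determines
#' the junction.
#'
#' @param read DNA string.
#' @param ref a [reference_amplicon()].
#' @param min_anchor minimum exact-match length required on each side.
#' @return list: `anchored` (logical), `left` / `right` (trimmed anchor
#'   lengths used for the junction geometry), `left_raw` / `right_raw`
#'   (untrimmed match lengths).
#' @export
anchor_read <- function(read, ref, min_anchor = 10) {
  stopifnot(inherits(ref, "reference_amplicon"), min_anchor >= 1)
  read <- toupper(as.character(read))
  if (nchar(read) < 2 * min_anchor) {
    return(list(anchored = FALSE, left = 0L, right = 0L,
                left_raw = 0L, right_raw = 0L))
  }
  rd <- strsplit(read, "", fixed = TRUE)[[1]]
  rf <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  rd[rd == "N"] <- NA
  n <- min(length(rd), length(rf))
  eq_pref <- rd[seq_len(n)] == rf[seq_len(n)]
  eq_pref[is.na(eq_pref)] <- FALSE
  p <- first_false(eq_pref) - 1L
  eq_suff <- rev(rd)[seq_len(n)] == rev(rf)[seq_len(n)]
  eq_suff[is.na(eq_suff)] <- FALSE
  s <- first_false(eq_suff) - 1L
  anchored <- p >= min_anchor && s >= min_anchor
  r <- min(s, length(rd) - p, length(rf) - p)
  list(anchored = anchored, left = as.integer(p), right = as.integer(max(r, 0L)),
       left_raw = as.integer(p), right_raw = as.integer(s))
}

first_false <- function(x) {
  i <- which(!x)
  if (length(i)) i[1] else length(x) + 1L
}

#' Classify a repair junction read
#'
#' Anchors the read to the reference ([anchor_read()]) and classifies the
#' junction into the four repair-event categories: `direct` (re-ligation
#' without scar), `deletion` (sequence lost, nothing gained), `delins`
#' (deletion with an inclusion of new DNA), `insertion` (new DNA without
#' loss). Reads that cannot be anchored on both flanks are reported as
#' `unclassified`. For pure deletions the interval is canonicalized to its
#' leftmost microhomology-equivalent placement and the microhomology length
#' is computed with [microhomology()].
#'
#' @param read DNA string.
#' @param ref a [reference_amplicon()].
#' @param min_anchor minimum exact flank match (default 10 nt; Sanger reads
#'   of single clones are high quality, so anchoring is exact).
#' @param read_id label carried into the output.
#' @return one-row data.frame: `read_id`, `category`, `del_start`,
#'   `del_end` (0-based half-open on the reference; `NA` when no deletion),
#'   `deletion_size`, `inserted_seq`, `microhomology_len` (simple deletions
#'   only, else `NA`), `left_anchor_len`, `right_anchor_len` (raw match
#'   lengths).
#' @export
classify_junction <- function(read, ref, min_anchor = 10, read_id = "read") {
  read <- toupper(as.character(read))
  anc <- anchor_read(read, ref, min_anchor)
  un <- data.frame(read_id = read_id, category = "unclassified",
                   del_start = NA_integer_, del_end = NA_integer_,
                   deletion_size = 0L, inserted_seq = "",
                   microhomology_len = NA_integer_,
                   left_anchor_len = anc$left_raw,
                   right_anchor_len = anc$right_raw,
                   stringsAsFactors = FALSE)
  if (!anc$anchored) return(un)
  L_read <- nchar(read)
  L_ref <- nchar(ref$sequence)
  p <- anc$left
  r <- anc$right
  del_size <- L_ref - p - r
  ins <- if (L_read - r >= p + 1) substr(read, p + 1, L_read - r) else ""
  if (del_size < 0) return(un) # cannot happen after trimming; defensive
  category <- if (del_size == 0 && !nzchar(ins)) "direct"
  else if (del_size > 0 && !nzchar(ins)) "deletion"
  else if (del_size == 0) "insertion"
  else "delins"

  ds <- de <- NA_integer_
  mh <- NA_integer_
  if (del_size > 0) {
    ds <- p
    de <- p + del_size
    if (category == "deletion") {
      # canonical leftmost placement: shift while the repaired string is unchanged
      while (ds > 0 &&
             substr(ref$sequence, ds, ds) == substr(ref$sequence, de, de)) {
        ds <- ds - 1L
        de <- de - 1L
      }
      mh <- microhomology(ref, ds, de)
    }
  }
  data.frame(read_id = read_id, category = category,
             del_start = as.integer(ds), del_end = as.integer(de),
             deletion_size = as.integer(del_size), inserted_seq = ins,
             microhomology_len = mh,
             left_anchor_len = anc$left_raw, right_anchor_len = anc$right_raw,
             stringsAsFactors = FALSE)
}

#' Classify a set of reads
#'
#' @param reads named character vector, `DNAStringSet`, or path to a FASTA
#'   file of junction reads (one record per sequenced clone).
#' @param ref a [reference_amplicon()].
#' @param min_anchor see [classify_junction()].
#' @return data.frame with one row per read (see [classify_junction()]).
#' @export
classify_junctions <- function(reads, ref, min_anchor = 10) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- Biostrings::readDNAStringSet(reads)
  }
  if (inherits(reads, "DNAStringSet")) {
    nms <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nms
  }
  if (length(reads) == 0) {
    return(classify_junction(strrep("N", 2 * min_anchor), ref,
                             min_anchor = min_anchor)[0, , drop = FALSE])
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read_%03d", seq_along(reads))
  out <- do.call(rbind, Map(function(s, id) {
    classify_junction(s, ref, min_anchor = min_anchor, read_id = id)
  }, reads, names(reads)))
  rownames(out) <- NULL
  out
}

#' Microhomology length of a deletion junction
#'
#' The microhomology of a deletion \[`del_start`, `del_end`) is the length
#' of identical sequence shared by the two deletion flanks at the junction:
#' the number of alternative placements of the same-size deletion that yield
#' the identical repaired sequence (shifting the interval left or right
#' while `ref[del_start + i] == ref[del_end + i]` holds), capped at the
#' deletion size. Intervals are 0-based half-open on the reference.
#'
#' @param ref a [reference_amplicon()] (or plain DNA string).
#' @param del_start,del_end 0-based half-open deletion interval,
#'   `0 <= del_start < del_end <= length(ref)`.
#' @return integer microhomology length >= 0.
#' @examples
#' microhomology(reference_amplicon("AAGGGGAA", 4), 2, 4)  # 2, capped at size
#' @export
microhomology <- function(ref, del_start, del_end) {
  seqc <- if (inherits(ref, "reference_amplicon")) ref$sequence else toupper(ref)
  L <- nchar(seqc)
  if (!(del_start >= 0 && del_start < del_end && del_end <= L)) {
    stop("deletion interval out of bounds")
  }
  ch <- strsplit(seqc, "", fixed = TRUE)[[1]]
  d <- del_end - del_start
  right <- 0L
  while (del_end + right + 1L <= L &&
         ch[del_start + right + 1L] == ch[del_end + right + 1L]) {
    right <- right + 1L
  }
  left <- 0L
  while (del_start - left >= 1L &&
         ch[del_start - left] == ch[del_end - left]) {
    left <- left + 1L
  }
  as.integer(min(left + right, d))
}

#' Tabulate a junction spectrum
#'
#' Counts calls per category and bins deletion sizes and microhomology
#' lengths into half-open bins \[e_i, e_{i+1}) defined by strictly
#' increasing integer edges (an implicit upper edge of `Inf` is appended).
#' Deletion-size histograms cover simple deletions and, by default, delins
#' events (both lose sequence); microhomology histograms cover simple
#' deletions only. Unclassified reads are counted but excluded from the
#' histograms.
#'
#' @param calls data.frame from [classify_junctions()].
#' @param size_bins integer edges for deletion size (default 1, 2, 6, 21,
#'   101, i.e. bins 1, 2-5, 6-20, 21-100, >100 nt).
#' @param mh_bins integer edges for microhomology length (default 0, 1, 3,
#'   6, i.e. bins 0, 1-2, 3-5, >=6 nt).
#' @param include_delins include delins deletions in the size histogram.
#' @return list of class `"junction_spectrum"`: `category_counts` (named
#'   integer vector over direct/deletion/delins/insertion/unclassified),
#'   `deletion_size_hist` and `microhomology_hist` (data.frames `bin`,
#'   `count`), `n_total`.
#' @export
junction_spectrum <- function(calls,
                              size_bins = c(1, 2, 6, 21, 101),
                              mh_bins = c(0, 1, 3, 6),
                              include_delins = TRUE) {
  stopifnot(is.data.frame(calls), all(diff(size_bins) > 0), all(diff(mh_bins) > 0))
  cats <- c("direct", "deletion", "delins", "insertion", "unclassified")
  counts <- vapply(cats, function(k) sum(calls$category == k), 0L)
  sizes <- calls$deletion_size[calls$category %in%
                                 c("deletion", if (include_delins) "delins")]
  mh <- calls$microhomology_len[calls$category == "deletion"]
  structure(list(
    category_counts = counts,
    deletion_size_hist = bin_counts(sizes, size_bins),
    microhomology_hist = bin_counts(mh[!is.na(mh)], mh_bins),
    n_total = nrow(calls)
  ), class = "junction_spectrum")
}

bin_counts <- function(x, edges) {
  edges2 <- c(edges, Inf)
  labs <- vapply(seq_along(edges), function(i) {
    lo <- edges[i]
    hi <- edges2[i + 1] - 1
    if (is.infinite(edges2[i + 1])) sprintf(">=%d", lo)
    else if (hi == lo) sprintf("%d", lo)
    else sprintf("%d-%d", lo, hi)
  }, "")
  idx <- findInterval(x, edges2)
  data.frame(bin = labs,
             count = vapply(seq_along(edges), function(i) sum(idx == i), 0L))
}

#' @export
print.junction_spectrum <- function(x, ...) {
  cat("junction_spectrum of", x$n_total, "reads\n")
  print(x$category_counts)
  cat("deletion sizes:\n"); print(x$deletion_size_hist)
  cat("microhomology (simple deletions):\n"); print(x$microhomology_hist)
  invisible(x)
}
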