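#' Enumerate microhomology patterns around a cut site
#'
#' Scans a sequence window for identical substring pairs (length >=
#' `min_len`) with one copy ending at or before the cut and the other
#' starting at or after it. Each such pair templates a deletion that
#' collapses the two copies; its length is the offset between the copies.
#' Patterns wholly contained in a longer pattern with the same deletion
#' length (identical deletion boundaries) are removed as duplicates.
#'
#' Each retained pattern carries the published length- and GC-weighted
#' score: 100 * round(exp(-deletion_length/20), 3) * (len + gc_count),
#' the exponential factor being rounded to 3 decimals for
#' bit-reproducibility.
#'
#' @param window DNA string around the cut.
#' @param cut_index number of bases of `window` left of the cut (the cut
#'   falls between `window[cut_index]` and `window[cut_index + 1]`).
#' @param min_len minimum microhomology arm length (default 2).
#' @return data.frame with one row per pattern: `sequence`,
#'   `left_start`, `right_start` (0-based offsets in `window`),
#'   `length`, `deletion_length`, `gc_count`, `pattern_score`.
#' @export
enumerate_patterns <- function(window, cut_index, min_len = 2L) {
  assert_dna(window, "window", allow_n = TRUE)
  L <- nchar(window)
  if (cut_index < min_len || L - cut_index < min_len)
    stop_validation("window must contain >= ", min_len,
                    " bases on each side of the cut")
  ch <- strsplit(window, "")[[1L]]
  pats <- list()
  # longer patterns first so containment dedup sees the container early
  for (k in seq.int(min(cut_index, L - cut_index), min_len)) {
    for (i in seq.int(0L, cut_index - k)) {          # left copy [i, i+k)
      for (j in seq.int(cut_index, L - k)) {         # right copy [j, j+k)
        if (!identical(ch[(i + 1L):(i + k)], ch[(j + 1L):(j + k)])) next
        sq <- substr(window, i + 1L, i + k)
        if (grepl("N", sq, fixed = TRUE)) next
        del <- j - i
        contained <- any(vapply(pats, function(p)
          p$length > k && p$deletion_length == del &&
            i >= p$left_start && (i + k) <= (p$left_start + p$length) &&
            j >= p$right_start && (j + k) <= (p$right_start + p$length),
          logical(1)))
        if (contained) next
        gc <- nchar(gsub("[AT]", "", sq))
        pats[[length(pats) + 1L]] <- list(
          sequence = sq, left_start = i, right_start = j, length = k,
          deletion_length = del, gc_count = gc,
          pattern_score = 100 * round(exp(-del / 20), 3) * (k + gc))
      }
    }
  }
  if (!length(pats))
    return(data.frame(sequence = character(), left_start = integer(),
                      right_start = integer(), length = integer(),
                      deletion_length = integer(), gc_count = integer(),
                      pattern_score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(pats, as.data.frame, stringsAsFactors = FALSE))
  out <- out[order(out$left_start, out$right_start, -out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Microhomology out-of-frame score
#'
#' Fraction of total microhomology pattern weight carried by deletions
#' whose length is not a multiple of 3, as a 0-100 integer:
#' round(100 * sum(out-of-frame scores) / sum(all scores)). High scores
#' predict frameshift-causing repair outcomes, desirable for knockout.
#' An empty pattern list scores 0 by convention (no microhomology gives
#' no evidence of frameshift), with a warning.
#'
#' @param patterns data.frame from [enumerate_patterns()].
#' @return integer score 0-100.
#' @export
out_of_frame_score <- function(patterns) {
  if (nrow(patterns) == 0L) {
    warning("no microhomology patterns; out-of-frame score set to 0")
    return(0L)
  }
  total <- sum(patterns$pattern_score)
  oof <- sum(patterns$pattern_score[patterns$deletion_length %% 3L != 0L])
  round_half_up(100 * oof / total)
}

#' Microhomology score for a guide at its genomic cut site
#'
#' Extracts a window of `flank` bases on each side of the guide's cut
#' (truncated at contig ends), enumerates microhomology patterns and
#' returns the out-of-frame score. Deletion outcomes are a property of
#' the genomic locus, so the forward-strand sequence is used for guides
#' on either strand. `NA` if either flank is shorter than `min_len`.
#'
#' @param genome a `genome_seq`.
#' @param g one-row guide data.frame with `contig`, `strand`, `cut_pos`.
#' @param flank window half-width in bp (default 40).
#' @param min_len minimum microhomology arm length (default 2).
#' @return integer score 0-100, or `NA_integer_`.
#' @export
microhomology_score <- function(genome, g, flank = 40L, min_len = 2L) {
  seq <- genome$contigs[[g$contig]]
  L <- nchar(seq)
  # cut boundary in 0-based genomic coordinates: the break sits 3 nt 5'
  # of the PAM on the guide strand
  boundary <- if (g$strand == "+") g$cut_pos + 1L else g$cut_pos
  w0 <- max(0L, boundary - flank)
  w1 <- min(L, boundary + flank)
  cut_index <- boundary - w0
  if (cut_index < min_len || (w1 - w0) - cut_index < min_len)
    return(NA_integer_)
  window <- substr(seq, w0 + 1L, w1)
  pats <- enumerate_patterns(window, cut_index, min_len)
  if (nrow(pats) == 0L) return(suppressWarnings(out_of_frame_score(pats)))
  out_of_frame_score(pats)
}
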