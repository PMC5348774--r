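#' Round a non-negative score half away from zero
#'
#' All reported panel scores are rounded to the nearest integer with ties
#' going up (so 0.5 -> 1), matching the convention of guide-design web
#' tools. Base `round()` rounds half to even and is not used for scores.
#'
#' @param x numeric vector, non-negative.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5 + 1e-9))
}

stop_validation <- function(...) {
  stop(structure(class = c("guidekit_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_lookup <- function(...) {
  stop(structure(class = c("guidekit_lookup_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_dna <- function(seq, what = "sequence", allow_n = TRUE) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq))
    stop_validation(what, " must be a single character string")
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, seq))
    stop_validation(what, " contains characters outside ",
                    if (allow_n) "ACGTN" else "ACGT", ": ", seq)
  invisible(seq)
}

assert_protospacer <- function(seq) {
  assert_dna(seq, "protospacer", allow_n = FALSE)
  if (nchar(seq) != 20L)
    stop_validation("protospacer must be exactly 20 nt, got ", nchar(seq))
  invisible(seq)
}
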