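#' Enumerate SpCas9 NGG guide candidates over a gene's MCDS
#'
#' Exhaustively scans both strands of the gene's contig for 23-mers of the
#' form N20+NGG and keeps every candidate whose predicted cut site (the
#' blunt double-strand break 3 nt 5' of the PAM, i.e. between protospacer
#' positions 17 and 18) falls on an MCDS position. Candidates whose
#' protospacer or PAM contains N are discarded. Overlapping PAMs yield
#' distinct candidates.
#'
#' Candidates are ordered by genomic start of the 23-mer site, then strand
#' (+ before -), and carry a deterministic id `<contig>:<site_start>:<strand>`
#' (0-based genomic start).
#'
#' @param genome a `genome_seq` from [load_genome()].
#' @param mcds an `mcds` from [build_mcds()].
#' @return a data.frame with one row per candidate: `guide_id`, `contig`,
#'   `strand`, `start`, `end` (0-based half-open 23-mer interval),
#'   `protospacer`, `pam`, `cut_pos` (0-based genomic coordinate of the
#'   protospacer base immediately 5' of the cut, position 17 from the
#'   PAM-distal end), `context30` (30-mer context or NA near contig edges).
#' @export
enumerate_guides <- function(genome, mcds) {
  stopifnot(inherits(genome, "genome_seq"), inherits(mcds, "mcds"))
  if (!mcds$contig %in% names(genome$contigs))
    stop_validation("contig '", mcds$contig, "' not present in genome")
  seq <- genome$contigs[[mcds$contig]]
  L <- nchar(seq)
  mpos <- mcds$positions

  rows <- list()
  # + strand: PAM = NGG at genomic [s+20, s+23); find GG at offset 21 of the
  # 23-mer. Overlapping matches via lookahead.
  gg <- gregexpr("(?=GG)", seq, perl = TRUE)[[1L]]
  if (gg[1L] != -1L) {
    pam_n0 <- as.integer(gg) - 2L        # 0-based position of the PAM's N
    s0 <- pam_n0 - 20L                   # 0-based 23-mer start
    ok <- s0 >= 0L & (s0 + 23L) <= L
    for (s in s0[ok]) {
      cut <- s + 16L                     # protospacer position 17, 0-based
      if (!(cut %in% mpos)) next
      proto <- substr(seq, s + 1L, s + 20L)
      pam <- substr(seq, s + 21L, s + 23L)
      if (grepl("N", proto, fixed = TRUE) || grepl("N", pam, fixed = TRUE)) next
      rows[[length(rows) + 1L]] <- list(contig = mcds$contig, strand = "+",
                                        start = s, end = s + 23L,
                                        protospacer = proto, pam = pam,
                                        cut_pos = cut)
    }
  }
  # - strand: genomic forward shows CCN at the 23-mer start.
  cc <- gregexpr("(?=CC)", seq, perl = TRUE)[[1L]]
  if (cc[1L] != -1L) {
    s0 <- as.integer(cc) - 1L            # 0-based 23-mer start
    ok <- s0 >= 0L & (s0 + 23L) <= L
    for (s in s0[ok]) {
      cut <- s + 6L                      # position 17 on the minus strand
      if (!(cut %in% mpos)) next
      site <- substr(seq, s + 1L, s + 23L)
      if (grepl("N", site, fixed = TRUE)) next
      rc <- reverse_complement(site)
      rows[[length(rows) + 1L]] <- list(contig = mcds$contig, strand = "-",
                                        start = s, end = s + 23L,
                                        protospacer = substr(rc, 1L, 20L),
                                        pam = substr(rc, 21L, 23L),
                                        cut_pos = cut)
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(guide_id = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), protospacer = character(),
                      pam = character(), cut_pos = integer(),
                      context30 = character(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  out$guide_id <- paste(out$contig, out$start, out$strand, sep = ":")
  out$context30 <- vapply(seq_len(nrow(out)), function(i)
    extract_context(genome, out[i, ]), character(1))
  rownames(out) <- NULL
  out[, c("guide_id", "contig", "strand", "start", "end", "protospacer",
          "pam", "cut_pos", "context30")]
}

#' Extract the 30-mer scoring context for a guide
#'
#' Returns the 4 + 20 + 3 + 3 window (4 nt upstream of the protospacer,
#' protospacer, PAM, 3 nt downstream) on the guide's strand, as required
#' by the Rule Set 1 on-target scorer. `NA` when the window runs off the
#' contig or contains N: score absence is a value, never a zero.
#'
#' @param genome a `genome_seq`.
#' @param g a one-row guide data.frame (or list) with `contig`, `strand`,
#'   `start`, `end`.
#' @return 30-nt character string, or `NA_character_`.
#' @export
extract_context <- function(genome, g) {
  seq <- genome$contigs[[g$contig]]
  L <- nchar(seq)
  if (g$strand == "+") {
    w0 <- g$start - 4L; w1 <- g$end + 3L
    if (w0 < 0L || w1 > L) return(NA_character_)
    ctx <- substr(seq, w0 + 1L, w1)
  } else {
    w0 <- g$start - 3L; w1 <- g$end + 4L
    if (w0 < 0L || w1 > L) return(NA_character_)
    ctx <- reverse_complement(substr(seq, w0 + 1L, w1))
  }
  if (grepl("N", ctx, fixed = TRUE)) return(NA_character_)
  ctx
}

#' Export guide candidates as BED
#'
#' One BED6 row per 23-mer site (0-based half-open, strand column 6).
#'
#' @param guides guide data.frame from [enumerate_guides()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
guides_to_bed <- function(guides, path) {
  lines <- paste(guides$contig, guides$start, guides$end, guides$guide_id,
                 0L, guides$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
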