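#' Build the master coding DNA sequence (MCDS) of a gene
#'
#' The MCDS overlays the CDS of every retained protein-coding transcript
#' into one ordered coding coordinate system: the set union of all CDS
#' genomic positions, ordered 5' to 3' in the gene's reading direction
#' (ascending genomic coordinates for + strand genes, descending for -).
#' Each position records which transcripts' CDS cover it, so positional
#' scores (percent peptide, transcript representation) are defined for
#' every coding guide.
#'
#' @param gene a `gene_model` from [load_gene()].
#' @return an `mcds` object: list with `gene_id`, `contig`, `strand`,
#'   `positions` (0-based genomic coordinates in transcription order),
#'   `membership` (list of character vectors of transcript ids, parallel
#'   to `positions`) and `n_transcripts`.
#' @export
build_mcds <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  tx_ids <- vapply(gene$transcripts, `[[`, character(1), "transcript_id")
  per_tx <- lapply(gene$transcripts, function(tx) {
    unlist(lapply(seq_len(nrow(tx$cds_intervals)), function(r)
      seq.int(tx$cds_intervals[r, 1L], tx$cds_intervals[r, 2L] - 1L)))
  })
  positions <- sort(unique(unlist(per_tx)))
  if (length(positions) == 0L) stop_validation("gene has an empty CDS union")
  if (gene$strand == "-") positions <- rev(positions)
  member_mat <- vapply(per_tx, function(p) positions %in% p,
                       logical(length(positions)))
  member_mat <- matrix(member_mat, nrow = length(positions))
  membership <- apply(member_mat, 1L, function(row) tx_ids[row],
                      simplify = FALSE)
  structure(list(gene_id = gene$gene_id, contig = gene$contig,
                 strand = gene$strand, positions = as.integer(positions),
                 membership = membership,
                 n_transcripts = length(tx_ids)),
            class = "mcds")
}

#' @export
print.mcds <- function(x, ...) {
  cat("mcds of", x$gene_id, "-", length(x$positions), "coding bp over",
      x$n_transcripts, "transcript(s),", x$strand, "strand\n")
  invisible(x)
}

#' Percent peptide score: progression through the MCDS
#'
#' Expresses a cut-site position as its percentage progression through the
#' MCDS, 5' to 3': 100 * rank / length, rounded to the nearest integer
#' (half up). The final coding base scores exactly 100; scores below 50
#' indicate a guide cutting in the 5' half of the coding sequence.
#'
#' @param mcds an `mcds` object.
#' @param cut_pos 0-based genomic coordinate; must be an MCDS position.
#' @return integer score in 0-100.
#' @export
percent_peptide <- function(mcds, cut_pos) {
  rank <- match(cut_pos, mcds$positions)
  if (is.na(rank))
    stop_validation("position ", cut_pos, " is not in the MCDS of ", mcds$gene_id)
  round_half_up(100 * rank / length(mcds$positions))
}

#' Transcript representation score
#'
#' Percentage of the gene's protein-coding transcripts whose CDS contains
#' the cut position: 100 * |covering transcripts| / n_transcripts, rounded
#' to the nearest integer. 100 means the guide targets every transcript
#' (a consensus exon).
#'
#' @inheritParams percent_peptide
#' @return integer score in 0-100.
#' @export
transcript_representation <- function(mcds, cut_pos) {
  rank <- match(cut_pos, mcds$positions)
  if (is.na(rank))
    stop_validation("position ", cut_pos, " is not in the MCDS of ", mcds$gene_id)
  round_half_up(100 * length(mcds$membership[[rank]]) / mcds$n_transcripts)
}

#' Export the MCDS as BED intervals
#'
#' Collapses the MCDS position set into maximal genomic intervals and
#' writes them as BED (0-based half-open, strand in column 6) for
#' genome-browser inspection.
#'
#' @param mcds an `mcds` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
mcds_to_bed <- function(mcds, path) {
  pos <- sort(mcds$positions)
  brk <- which(diff(pos) != 1L)
  starts <- pos[c(1L, brk + 1L)]
  ends <- pos[c(brk, length(pos))] + 1L
  lines <- paste(mcds$contig, starts, ends,
                 paste0(mcds$gene_id, "_mcds_", seq_along(starts)),
                 0L, mcds$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
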