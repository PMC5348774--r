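#' Load a genome from a FASTA file
#'
#' Reads every record of a (possibly multi-record, line-wrapped) FASTA file
#' into an in-memory genome object. Sequences are uppercased; only the
#' alphabet ACGTN is accepted. Contig ids are the first whitespace-delimited
#' token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a `genome_seq` object: list with `contigs` (named character
#'   vector of uppercase DNA strings) and `lengths` (named integer vector).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' g <- load_genome(fa)
#' g$lengths
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop_validation("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop_validation("duplicate contig id(s) in FASTA: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  contigs <- toupper(as.character(seqs))
  names(contigs) <- ids
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop_validation("contig(s) with bases outside ACGTN: ",
                    paste(ids[bad], collapse = ", "))
  structure(list(contigs = contigs,
                 lengths = setNames(nchar(contigs), ids)),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq with", length(x$contigs), "contig(s),",
      sum(x$lengths), "bp total\n")
  invisible(x)
}

#' Reverse-complement a DNA string
#'
#' Standard Watson-Crick complement, reversed; N maps to N. Input alphabet
#' is restricted to ACGTN.
#'
#' @param seq a single DNA string.
#' @return the reverse complement as a character string.
#' @examples
#' reverse_complement("AAGG")  # "CCTT"
#' @export
reverse_complement <- function(seq) {
  assert_dna(seq, "sequence", allow_n = TRUE)
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Load a gene model from a GFF3 annotation
#'
#' Parses gene, mRNA/transcript, and CDS features (linked by `Parent`
#' attributes) and returns the gene whose `ID` or `Name` matches
#' `gene_query`. Only protein-coding transcripts are retained: a transcript
#' is kept iff its `biotype` attribute equals `"protein_coding"`, or it has
#' no biotype attribute but owns at least one CDS feature. GFF3 1-based
#' inclusive coordinates are converted to the package's internal 0-based
#' half-open convention.
#'
#' @param path path to a GFF3 file.
#' @param gene_query gene ID or Name to look up.
#' @return a `gene_model` object: list with `gene_id`, `gene_name`,
#'   `contig`, `strand` and `transcripts` (each a list with
#'   `transcript_id`, `biotype`, and `cds_intervals`, a two-column matrix
#'   of 0-based half-open `[start, end)` intervals sorted by start).
#' @export
load_gene <- function(path, gene_query) {
  if (!file.exists(path)) stop_validation("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)

  genes <- gr[type == "gene"]
  gmd <- S4Vectors::mcols(genes)
  ids <- as.character(gmd$ID)
  nms <- if (!is.null(gmd$Name)) as.character(gmd$Name) else rep(NA_character_, length(genes))
  hit <- which(ids == gene_query | (!is.na(nms) & nms == gene_query))
  if (length(hit) == 0L) {
    known <- unique(c(ids, nms[!is.na(nms)]))
    near <- unique(unlist(lapply(gene_query, agrep, x = known, max.distance = 0.3,
                                 ignore.case = TRUE, value = TRUE)))
    stop_lookup("gene '", gene_query, "' not found",
                if (length(near)) paste0("; near matches: ",
                                         paste(head(near, 5), collapse = ", "))
                else paste0("; known genes: ",
                            paste(head(known, 5), collapse = ", ")))
  }
  gene <- genes[hit[1L]]
  gene_id <- ids[hit[1L]]
  gene_name <- if (is.na(nms[hit[1L]])) gene_id else nms[hit[1L]]
  contig <- as.character(GenomicRanges::seqnames(gene))
  strand <- as.character(GenomicRanges::strand(gene))
  if (!strand %in% c("+", "-"))
    stop_validation("gene '", gene_id, "' has no defined strand")

  parents <- md$Parent  # CharacterList
  has_parent <- function(p) lengths(parents) > 0 & vapply(
    as.list(parents), function(v) p %in% v, logical(1))

  tx_mask <- type %in% c("mRNA", "transcript") & has_parent(gene_id)
  txs <- gr[tx_mask]
  tmd <- S4Vectors::mcols(txs)
  tx_ids <- as.character(tmd$ID)
  biotypes <- if (!is.null(tmd$biotype)) as.character(tmd$biotype)
              else rep(NA_character_, length(txs))

  transcripts <- list()
  for (k in seq_along(tx_ids)) {
    cds_mask <- type == "CDS" & has_parent(tx_ids[k])
    cds <- gr[cds_mask]
    n_cds <- length(cds)
    keep <- if (is.na(biotypes[k])) n_cds >= 1L
            else identical(biotypes[k], "protein_coding")
    if (!keep || n_cds == 0L) next
    # GFF3 1-based inclusive -> 0-based half-open
    iv <- cbind(start = GenomicRanges::start(cds) - 1L,
                end = GenomicRanges::end(cds))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[-1L, 1L] < iv[-nrow(iv), 2L]) && nrow(iv) > 1L)
      stop_validation("overlapping CDS intervals in transcript ", tx_ids[k])
    transcripts[[length(transcripts) + 1L]] <- list(
      transcript_id = tx_ids[k],
      biotype = biotypes[k],
      cds_intervals = iv)
  }
  if (length(transcripts) == 0L)
    stop_validation("gene '", gene_id, "' has no protein-coding transcripts with CDS")

  structure(list(gene_id = gene_id, gene_name = gene_name,
                 contig = contig, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, paste0("(", x$gene_name, ")"),
      "on", x$contig, x$strand, "with", length(x$transcripts),
      "coding transcript(s)\n")
  invisible(x)
}

#' Write a gene model back to GFF3
#'
#' Emits gene, mRNA and CDS rows with `ID`/`Name`/`Parent`/`biotype`
#' attributes, converting internal 0-based half-open intervals back to
#' GFF3 1-based inclusive coordinates. Re-loading the file with
#' [load_gene()] reproduces the model.
#'
#' @param gene a `gene_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_gff3 <- function(gene, path) {
  stopifnot(inherits(gene, "gene_model"))
  all_iv <- do.call(rbind, lapply(gene$transcripts, `[[`, "cds_intervals"))
  gmin <- min(all_iv[, 1L]) + 1L
  gmax <- max(all_iv[, 2L])
  lines <- c("##gff-version 3",
             paste(gene$contig, "guidekit", "gene", gmin, gmax, ".",
                   gene$strand, ".",
                   sprintf("ID=%s;Name=%s", gene$gene_id, gene$gene_name),
                   sep = "\t"))
  for (tx in gene$transcripts) {
    tmin <- min(tx$cds_intervals[, 1L]) + 1L
    tmax <- max(tx$cds_intervals[, 2L])
    attr_bt <- if (is.na(tx$biotype)) "" else sprintf(";biotype=%s", tx$biotype)
    lines <- c(lines,
               paste(gene$contig, "guidekit", "mRNA", tmin, tmax, ".",
                     gene$strand, ".",
                     sprintf("ID=%s;Parent=%s%s", tx$transcript_id,
                             gene$gene_id, attr_bt),
                     sep = "\t"))
    for (r in seq_len(nrow(tx$cds_intervals))) {
      lines <- c(lines,
                 paste(gene$contig, "guidekit", "CDS",
                       tx$cds_intervals[r, 1L] + 1L, tx$cds_intervals[r, 2L],
                       ".", gene$strand, "0",
                       sprintf("ID=cds-%s-%d;Parent=%s", tx$transcript_id,
                               r, tx$transcript_id),
                       sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
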