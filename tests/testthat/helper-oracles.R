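# Independent brute-force oracles. These deliberately avoid the code
# paths of the implementation (plain character loops, no Biostrings
# matching, no lookahead regex) so equivalence tests mean something.

# write a genome to a temp FASTA and load it through the package reader
genome_from_seqs <- function(...) {
  seqs <- c(...)
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             fa)
  load_genome(fa)
}

# construct a gene_model directly (0-based half-open CDS intervals)
make_gene <- function(contig, strand, tx_cds, gene_id = "G1",
                      biotype = "protein_coding") {
  txs <- lapply(seq_along(tx_cds), function(k) {
    iv <- tx_cds[[k]]
    iv <- matrix(as.integer(iv), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
    list(transcript_id = paste0("T", k), biotype = biotype,
         cds_intervals = iv[order(iv[, 1]), , drop = FALSE])
  })
  structure(list(gene_id = gene_id, gene_name = gene_id, contig = contig,
                 strand = strand, transcripts = txs),
            class = "gene_model")
}

rc_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# exhaustive per-position scan for N20+NGG sites with cut in the MCDS
oracle_enumerate <- function(seq, mcds_positions, contig = "chr") {
  L <- nchar(seq)
  out <- list()
  for (s in 0:(L - 23)) {
    site <- substr(seq, s + 1, s + 23)
    if (grepl("N", site, fixed = TRUE)) next
    if (substr(site, 22, 23) == "GG" && (s + 16) %in% mcds_positions)
      out[[length(out) + 1]] <- data.frame(
        contig = contig, strand = "+", start = s, end = s + 23,
        protospacer = substr(site, 1, 20), pam = substr(site, 21, 23),
        cut_pos = s + 16, stringsAsFactors = FALSE)
    if (substr(site, 1, 2) == "CC" && (s + 6) %in% mcds_positions) {
      rc <- rc_chr(site)
      out[[length(out) + 1]] <- data.frame(
        contig = contig, strand = "-", start = s, end = s + 23,
        protospacer = substr(rc, 1, 20), pam = substr(rc, 21, 23),
        cut_pos = s + 6, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), , drop = FALSE]
}

# sliding-window Hamming scan for off-target candidates, both strands
oracle_offtargets <- function(genome, proto, max_mm = 4) {
  pvec <- strsplit(proto, "")[[1]]
  out <- list()
  for (contig in names(genome$contigs)) {
    seq <- genome$contigs[[contig]]
    L <- nchar(seq)
    if (L < 23) next
    ch <- strsplit(seq, "")[[1]]
    for (s in 0:(L - 23)) {
      # + strand: protospacer at [s, s+20), PAM at [s+20, s+23)
      pam23 <- paste0(ch[s + 22], ch[s + 23])
      if (pam23 %in% c("GG", "AG")) {
        mm <- which(ch[(s + 1):(s + 20)] != pvec)
        if (length(mm) <= max_mm)
          out[[length(out) + 1]] <- data.frame(
            contig = contig, strand = "+", site_start = s,
            pam_class = if (pam23 == "GG") "NGG" else "NAG",
            n_mismatches = length(mm),
            mismatch_positions = paste(mm, collapse = ","),
            stringsAsFactors = FALSE)
      }
      # - strand: forward shows revcomp(site): CCN/CTN then revcomp(proto)
      pam12 <- paste0(ch[s + 1], ch[s + 2])
      if (pam12 %in% c("CC", "CT")) {
        obs <- rc_chr(substr(seq, s + 4, s + 23))
        mm <- which(strsplit(obs, "")[[1]] != pvec)
        if (length(mm) <= max_mm)
          out[[length(out) + 1]] <- data.frame(
            contig = contig, strand = "-", site_start = s,
            pam_class = if (pam12 == "CC") "NGG" else "NAG",
            n_mismatches = length(mm),
            mismatch_positions = paste(mm, collapse = ","),
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), strand = character(),
                      site_start = integer(), pam_class = character(),
                      n_mismatches = integer(),
                      mismatch_positions = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$contig, df$site_start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# quadratic pair enumeration + containment filter for microhomology
oracle_mh <- function(window, cut, min_len = 2) {
  L <- nchar(window)
  cand <- list()
  for (k in min_len:min(cut, L - cut)) {
    for (i in 0:(cut - k)) {
      for (j in cut:(L - k)) {
        if (substr(window, i + 1, i + k) == substr(window, j + 1, j + k))
          cand[[length(cand) + 1]] <- list(i = i, j = j, k = k,
                                           seq = substr(window, i + 1, i + k))
      }
    }
  }
  if (!length(cand)) return(data.frame())
  keep <- vapply(seq_along(cand), function(a) {
    ca <- cand[[a]]
    !any(vapply(seq_along(cand), function(b) {
      cb <- cand[[b]]
      b != a && cb$k > ca$k && (cb$j - cb$i) == (ca$j - ca$i) &&
        ca$i >= cb$i && (ca$i + ca$k) <= (cb$i + cb$k) &&
        ca$j >= cb$j && (ca$j + ca$k) <= (cb$j + cb$k)
    }, logical(1)))
  }, logical(1))
  cand <- cand[keep]
  df <- do.call(rbind, lapply(cand, function(p) {
    gc <- nchar(gsub("[AT]", "", p$seq))
    data.frame(sequence = p$seq, left_start = p$i, right_start = p$j,
               length = p$k, deletion_length = p$j - p$i, gc_count = gc,
               pattern_score = 100 * round(exp(-(p$j - p$i) / 20), 3) * (p$k + gc),
               stringsAsFactors = FALSE)
  }))
  df[order(df$left_start, df$right_start, -df$length), , drop = FALSE]
}

# independent row filter over a score table
oracle_filter <- function(df, clauses) {
  keep <- rep(TRUE, nrow(df))
  for (cl in clauses) {
    v <- df[[cl$name]]
    keep <- keep & !is.na(v) & v >= cl$min & v <= cl$max
  }
  df[keep, , drop = FALSE]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
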