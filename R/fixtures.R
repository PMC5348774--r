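# Fixed codebook of planted protospacers. Pairwise Hamming distance >= 12,
# so a 4-mismatch off-target search around one planted guide can never
# stray into another; GC 40-60%, no homopolymer or TTT except the two
# dedicated probes at the end.
.codebook <- c(
  "GATCGCGATCCATACGACAA", "CAATCACAAAGCCGCGAGCC", "GCTTAACTCCTGATCTATAC",
  "CAGTTCGCGAGAGCAGTACG", "CTTACACTGGCTTCCACCCT", "ACTGTCCGGTGATAACCTGG")
.codebook_homopolymer <- "TCCTCTGTTAAAAGGCAATG"   # AAAA run, no TTT
.codebook_uuu <- "CTGGCTTTAACCGTTGTGTC"            # TTT, no 4-run

#' Specify a synthetic mini-genome fixture
#'
#' Describes a deterministic single-contig mini-genome carrying one gene
#' (one or two protein-coding transcripts with a shared/unique exon
#' structure) and a set of planted, truth-tracked features. The same spec
#' always yields byte-identical FASTA/GFF3/truth outputs.
#'
#' Plant directives (character vector or list of lists with a `type`
#' field):
#' \describe{
#'   \item{exact_duplicate}{a second exact copy of the primary guide's
#'     protospacer + NGG at an intergenic locus.}
#'   \item{mismatch_site}{an intergenic near-match of the primary guide;
#'     fields `k` (mismatches, default 2) and `pam_class` ("NGG"/"NAG",
#'     default "NGG"), optional `strand`.}
#'   \item{homopolymer_guide}{a guide containing an AAAA run, planted in
#'     the last shared exon.}
#'   \item{uuu_guide}{a guide containing TTT, planted in the last shared
#'     exon.}
#'   \item{terminal_guide}{a guide whose cut site is the final (most 3')
#'     base of the MCDS.}
#' }
#' A primary guide (codebook entry 1) is always planted in the first
#' shared exon, so every fixture has at least one guide covered by all
#' transcripts.
#'
#' @param seed integer seed for the single pseudo-random stream.
#' @param contig_length contig size in bp (default 2000).
#' @param transcripts 1 or 2 transcripts; with 2, the middle exon belongs
#'   only to the first (shared_exon + unique_exon structure).
#' @param plant plant directives (see above). Default: all five types.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(seed, contig_length = 2000L, transcripts = 2L,
                         plant = list("exact_duplicate",
                                      list(type = "mismatch_site", k = 2L,
                                           pam_class = "NAG"),
                                      "homopolymer_guide", "uuu_guide",
                                      "terminal_guide")) {
  plant <- lapply(plant, function(p) {
    if (is.character(p)) p <- list(type = p)
    stopifnot(!is.null(p$type))
    if (p$type == "mismatch_site") {
      p$k <- as.integer(p$k %||% 2L)
      p$pam_class <- p$pam_class %||% "NGG"
      p$strand <- p$strand %||% "+"
      if (!p$pam_class %in% c("NGG", "NAG"))
        stop_validation("mismatch_site pam_class must be NGG or NAG")
      if (p$k < 1L || p$k > 4L)
        stop_validation("mismatch_site k must be in 1-4")
    }
    if (p$type == "exact_duplicate") p$strand <- p$strand %||% "+"
    p
  })
  types <- vapply(plant, `[[`, character(1), "type")
  known <- c("exact_duplicate", "mismatch_site", "homopolymer_guide",
             "uuu_guide", "terminal_guide")
  if (length(setdiff(types, known)))
    stop_validation("unknown plant type(s): ",
                    paste(setdiff(types, known), collapse = ", "))
  n_inter <- sum(types %in% c("exact_duplicate", "mismatch_site"))
  need <- 1400L + 100L * n_inter
  if (contig_length < need)
    stop_validation("contig_length ", contig_length, " too small for the ",
                    "requested plants; need >= ", need)
  if (!transcripts %in% 1:2)
    stop_validation("transcripts must be 1 or 2")
  structure(list(seed = as.integer(seed),
                 contig_length = as.integer(contig_length),
                 transcripts = as.integer(transcripts), plant = plant),
            class = "fixture_spec")
}

#' Generate a synthetic fixture genome, annotation and truth table
#'
#' Realizes a [fixture_spec()]: writes `genome.fa`, `genes.gff3` and
#' `truth.json` under `outdir`. Every planted feature is recorded in the
#' truth table at its genomic coordinate, and the background sequence is
#' rejection-checked so that no unplanned 20-mer with an NGG/NAG PAM lies
#' within 4 mismatches of any planted protospacer on either strand.
#'
#' @param spec a `fixture_spec`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `paths` (fasta/gff3/truth) and `truth`
#'   (the truth table as an R list).
#' @export
generate_fixture <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  L <- spec$contig_length
  contig <- "chrT"
  # fixed exon layout (0-based half-open)
  exon1 <- c(200L, 290L); exon2 <- c(400L, 460L); exon3 <- c(600L, 690L)
  types <- vapply(spec$plant, `[[`, character(1), "type")

  # guide plants: label, protospacer, pam, 0-based 23-mer start, strand +
  guides <- list(list(label = "primary", protospacer = .codebook[1L],
                      pam = "TGG", site_start = exon1[1L] + 10L))
  if ("homopolymer_guide" %in% types)
    guides <- c(guides, list(list(label = "homopolymer",
                                  protospacer = .codebook_homopolymer,
                                  pam = "TGG", site_start = exon3[1L] + 5L)))
  if ("uuu_guide" %in% types)
    guides <- c(guides, list(list(label = "uuu",
                                  protospacer = .codebook_uuu,
                                  pam = "TGG", site_start = exon3[1L] + 35L)))
  if ("terminal_guide" %in% types)
    # cut site (site_start + 16) on the last MCDS base (exon3 end - 1)
    guides <- c(guides, list(list(label = "terminal",
                                  protospacer = .codebook[2L],
                                  pam = "TGG",
                                  site_start = exon3[2L] - 17L)))

  # intergenic plants referencing the primary protospacer
  mutate_k <- function(seq, k) {
    pos <- sort(sample.int(18L, k) + 1L)   # keep position 1 and 20 intact
    ch <- strsplit(seq, "")[[1L]]
    rot <- c(A = "C", C = "G", G = "T", T = "A")
    ch[pos] <- rot[ch[pos]]
    list(seq = paste(ch, collapse = ""), pos = pos)
  }
  offt <- list()
  next_locus <- 1100L
  for (p in spec$plant[types %in% c("exact_duplicate", "mismatch_site")]) {
    if (p$type == "exact_duplicate") {
      offt <- c(offt, list(list(label = "exact_duplicate",
                                guide_label = "primary",
                                protospacer = .codebook[1L], pam = "TGG",
                                pam_class = "NGG", n_mismatches = 0L,
                                mismatch_positions = integer(),
                                site_start = next_locus, strand = p$strand)))
    } else {
      v <- mutate_k(.codebook[1L], p$k)
      pam <- if (p$pam_class == "NGG") "TGG" else "TAG"
      offt <- c(offt, list(list(label = sprintf("mismatch_%dmm_%s", p$k,
                                                p$pam_class),
                                guide_label = "primary",
                                protospacer = v$seq, pam = pam,
                                pam_class = p$pam_class,
                                n_mismatches = p$k,
                                mismatch_positions = v$pos,
                                site_start = next_locus, strand = p$strand)))
    }
    next_locus <- next_locus + 100L
  }

  plant_all <- function(bg) {
    ch <- strsplit(bg, "")[[1L]]
    put <- function(s, at) {  # at: 0-based
      v <- strsplit(s, "")[[1L]]
      ch[(at + 1L):(at + length(v))] <<- v
    }
    for (g in guides) put(paste0(g$protospacer, g$pam), g$site_start)
    for (o in offt) {
      site <- paste0(o$protospacer, o$pam)
      if (o$strand == "-") site <- reverse_complement(site)
      put(site, o$site_start)
    }
    paste(ch, collapse = "")
  }

  seq <- NULL
  for (attempt in seq_len(50L)) {
    bg <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = "")
    cand <- plant_all(bg)
    if (fixture_scan_clean(cand, .codebook[1L], guides, offt) &&
        all(vapply(guides[-1L], function(g)
          fixture_scan_clean(cand, g$protospacer, guides, offt),
          logical(1))))
      { seq <- cand; break }
  }
  if (is.null(seq))
    stop_validation("could not generate a clean background in 50 attempts")

  # gene model: exon2 belongs only to transcript 1
  t1 <- list(transcript_id = "T1", biotype = "protein_coding",
             cds_intervals = rbind(exon1, exon2, exon3))
  t2 <- list(transcript_id = "T2", biotype = "protein_coding",
             cds_intervals = rbind(exon1, exon3))
  txs <- if (spec$transcripts == 2L) list(t1, t2) else list(t1)
  txs <- lapply(txs, function(tx) {
    colnames(tx$cds_intervals) <- c("start", "end")
    rownames(tx$cds_intervals) <- NULL
    tx
  })
  gene <- structure(list(gene_id = "GENE1", gene_name = "DEMO1",
                         contig = contig, strand = "+",
                         transcripts = txs),
                    class = "gene_model")

  fasta <- file.path(outdir, "genome.fa")
  gff <- file.path(outdir, "genes.gff3")
  truth_path <- file.path(outdir, "truth.json")
  ss <- Biostrings::DNAStringSet(setNames(seq, contig))
  Biostrings::writeXStringSet(ss, fasta, width = 70L)
  write_gene_gff3(gene, gff)

  truth <- list(
    seed = spec$seed, contig = contig, contig_length = L,
    gene = list(gene_id = "GENE1", gene_name = "DEMO1", strand = "+",
                n_transcripts = spec$transcripts,
                shared_exons = list(as.integer(exon1), as.integer(exon3)),
                unique_exon = if (spec$transcripts == 2L) as.integer(exon2)
                              else NULL,
                transcripts = lapply(txs, function(tx) list(
                  transcript_id = tx$transcript_id,
                  cds = lapply(seq_len(nrow(tx$cds_intervals)), function(r)
                    as.integer(tx$cds_intervals[r, ]))))),
    guides = lapply(guides, function(g) list(
      label = g$label, protospacer = g$protospacer, pam = g$pam,
      strand = "+", site_start = g$site_start,
      cut_pos = g$site_start + 16L)),
    offtargets = lapply(offt, function(o) o))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(list(paths = list(fasta = fasta, gff3 = gff, truth = truth_path),
                 truth = truth))
}

# Generation-time brute scanner: TRUE iff every 20-mer within 4 mismatches
# of `proto` that sits next to an NGG/NAG PAM (either strand) is one of
# the recorded planted sites.
fixture_scan_clean <- function(seq, proto, guides, offt, max_mm = 4L) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1L]]
  pvec <- strsplit(proto, "")[[1L]]
  recorded <- c(
    lapply(guides, function(g) c(g$site_start, "+")),
    lapply(offt, function(o) c(o$site_start, o$strand)))
  rec_key <- vapply(recorded, paste, character(1), collapse = ":")
  is_recorded <- function(site, strand)
    paste(site, strand, sep = ":") %in% rec_key

  scan_strand <- function(qvec, minus) {
    n_win <- L - 19L
    mm <- integer(n_win)
    for (t in 1:20) mm <- mm + (ch[t:(n_win + t - 1L)] != qvec[t])
    hits <- which(mm <= max_mm)
    for (h in hits) {
      w <- h - 1L  # 0-based 20-mer start
      if (!minus) {
        if (w + 23L > L) next
        p23 <- paste0(ch[w + 22L], ch[w + 23L])
        if (!p23 %in% c("GG", "AG")) next
        if (!is_recorded(w, "+")) return(FALSE)
      } else {
        site <- w - 3L
        if (site < 0L) next
        # forward shows revcomp(PAM): CCN (NGG) or CTN (NAG)
        p12 <- paste0(ch[site + 1L], ch[site + 2L])
        if (!p12 %in% c("CC", "CT")) next
        if (!is_recorded(site, "-")) return(FALSE)
      }
    }
    TRUE
  }
  rc <- strsplit(reverse_complement(proto), "")[[1L]]
  scan_strand(pvec, minus = FALSE) && scan_strand(rc, minus = TRUE)
}
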