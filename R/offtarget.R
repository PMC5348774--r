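#' Load the packaged position-dependent mismatch weights
#'
#' 20 weights in \[0,1\], one per protospacer position (position 1 =
#' PAM-distal end, position 20 abuts the PAM), read from the shipped
#' tab-separated file and cached for the session.
#'
#' @param path optional alternative weight file (columns position, weight).
#' @return numeric vector of length 20.
#' @export
mismatch_weights <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("hsu_weights", envir = .scorers)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "hsu2013_weights.tsv",
                        package = "guidekit", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  w <- tab$weight[order(tab$position)]
  if (length(w) != 20L || any(w < 0 | w > 1))
    stop_validation("mismatch weight file must give 20 weights in [0,1]")
  if (cache) assign("hsu_weights", w, envir = .scorers)
  w
}

#' Find candidate off-target sites for a protospacer
#'
#' Exhaustively scans both strands of every contig for 20-mers adjacent to
#' an NGG or NAG PAM whose Hamming distance to the query protospacer is at
#' most `max_mismatches`. The on-target site itself (same contig, 23-mer
#' start, and strand) is excluded. The scan is exact at mini-genome scale:
#' no heuristic seeding, no missed sites.
#'
#' Candidate matching is delegated to [Biostrings::matchPattern()] with
#' mismatch tolerance, then PAM class and per-position mismatches are
#' resolved on each hit.
#'
#' @param genome a `genome_seq`.
#' @param protospacer 20-nt query (ACGT).
#' @param target_site optional list/row with `contig`, `start` (0-based
#'   23-mer start) and `strand` identifying the on-target site to exclude.
#' @param max_mismatches maximum Hamming distance searched (default 4).
#' @return data.frame with one row per hit: `contig`, `strand`,
#'   `site_start` (0-based 23-mer start), `pam_class` ("NGG"/"NAG"),
#'   `n_mismatches`, `mismatch_positions` (comma-joined, 1 = PAM-distal),
#'   and `hit_score`.
#' @export
find_offtargets <- function(genome, protospacer, target_site = NULL,
                            max_mismatches = 4L) {
  stopifnot(inherits(genome, "genome_seq"))
  assert_protospacer(protospacer)
  if (max_mismatches < 0L) stop_validation("max_mismatches must be >= 0")
  w <- mismatch_weights()
  hits <- list()
  add <- function(contig, strand, site_start, pam_class, mm) {
    hits[[length(hits) + 1L]] <<- list(
      contig = contig, strand = strand, site_start = site_start,
      pam_class = pam_class, n_mismatches = length(mm),
      mismatch_positions = paste(mm, collapse = ","),
      hit_score = hit_score(mm, w))
  }
  pvec <- strsplit(protospacer, "")[[1L]]
  for (contig in names(genome$contigs)) {
    seq <- genome$contigs[[contig]]
    L <- nchar(seq)
    if (L < 23L) next
    subj <- Biostrings::DNAString(seq)
    # + strand: protospacer matches forward, PAM NGG/NAG immediately 3'
    m <- Biostrings::matchPattern(protospacer, subj,
                                  max.mismatch = max_mismatches)
    for (k in seq_along(m)) {
      st <- Biostrings::start(m)[k] - 1L          # 0-based protospacer start
      if (st + 23L > L) next
      pam <- substr(seq, st + 21L, st + 23L)
      cls <- pam_class_of(pam)
      if (is.na(cls)) next
      mm <- which(strsplit(substr(seq, st + 1L, st + 20L), "")[[1L]] != pvec)
      add(contig, "+", st, cls, mm)
    }
    # - strand: forward genome shows revcomp(protospacer) preceded by
    # revcomp(PAM) = CCN (NGG) or CTN (NAG)
    rcq <- reverse_complement(protospacer)
    m <- Biostrings::matchPattern(rcq, subj, max.mismatch = max_mismatches)
    for (k in seq_along(m)) {
      pst <- Biostrings::start(m)[k] - 1L         # 0-based revcomp-protospacer start
      site <- pst - 3L                            # 0-based 23-mer start
      if (site < 0L) next
      pam_fwd <- substr(seq, site + 1L, site + 3L)
      cls <- pam_class_of(reverse_complement(pam_fwd))
      if (is.na(cls)) next
      obs <- reverse_complement(substr(seq, pst + 1L, pst + 20L))
      mm <- which(strsplit(obs, "")[[1L]] != pvec)
      add(contig, "-", site, cls, mm)
    }
  }
  out <- if (length(hits)) do.call(rbind, lapply(hits, as.data.frame,
                                                 stringsAsFactors = FALSE))
         else data.frame(contig = character(), strand = character(),
                         site_start = integer(), pam_class = character(),
                         n_mismatches = integer(),
                         mismatch_positions = character(),
                         hit_score = numeric(), stringsAsFactors = FALSE)
  if (!is.null(target_site) && nrow(out)) {
    self <- out$contig == target_site$contig &
      out$site_start == target_site$start &
      out$strand == target_site$strand
    out <- out[!self, , drop = FALSE]
  }
  out <- out[order(out$contig, out$site_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

pam_class_of <- function(pam) {
  p23 <- substr(pam, 2L, 3L)
  if (p23 == "GG") "NGG" else if (p23 == "AG") "NAG" else NA_character_
}

#' Score a single off-target hit from its mismatch positions
#'
#' For an exact match (no mismatches) the hit scores 100. For m >= 1
#' mismatches at protospacer positions p (1 = PAM-distal), the score is
#'
#'   100 * prod(1 - w\[p\]) * 1 / (((19 - dbar)/19) * 4 + 1) * 1 / m^2
#'
#' where dbar is the mean distance between consecutive mismatch positions
#' (density penalty; absent for m = 1). Mismatches close to the PAM carry
#' large position weights and crush the hit score; clustered mismatches
#' are penalized less than spread ones.
#'
#' @param mismatch_positions integer vector of positions 1-20, sorted.
#' @param weights 20-entry weight vector from [mismatch_weights()].
#' @return numeric hit score in (0, 100\].
#' @export
hit_score <- function(mismatch_positions, weights = mismatch_weights()) {
  m <- length(mismatch_positions)
  if (m == 0L) return(100)
  if (any(mismatch_positions < 1L | mismatch_positions > 20L))
    stop_validation("mismatch positions must lie in 1-20")
  p <- sort(mismatch_positions)
  s <- prod(1 - weights[p])
  if (m > 1L) {
    dbar <- mean(diff(p))
    s <- s * (1 / (((19 - dbar) / 19) * 4 + 1)) * (1 / m^2)
  }
  100 * s
}

#' Aggregate specificity score over a hit list
#'
#' Collapses all candidate off-target hit scores into one 0-100 guide
#' specificity score: round(100 * 100 / (100 + sum of hit scores)). A
#' guide with no candidate off-targets scores 100 (maximum specificity);
#' a single additional exact genomic duplicate yields 50, so any score
#' above 50 certifies that the protospacer has no exact match elsewhere.
#'
#' @param hits data.frame from [find_offtargets()] (needs `hit_score`),
#'   or a numeric vector of hit scores.
#' @param nag_factor multiplicative attenuation applied to NAG-PAM hit
#'   scores before summing (default 1, i.e. NAG hits count fully).
#' @return integer score 0-100.
#' @export
hsu_specificity <- function(hits, nag_factor = 1) {
  if (is.numeric(hits)) s <- hits
  else {
    s <- hits$hit_score
    if (!is.null(hits$pam_class) && nag_factor != 1)
      s <- ifelse(hits$pam_class == "NAG", s * nag_factor, s)
  }
  round_half_up(100 * 100 / (100 + sum(s)))
}

#' Export off-target hits as BED
#'
#' BED6 rows for each candidate site, hit score in the score column.
#'
#' @param hits data.frame from [find_offtargets()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
offtargets_to_bed <- function(hits, path) {
  lines <- paste(hits$contig, hits$site_start, hits$site_start + 23L,
                 paste0(hits$pam_class, "_", hits$n_mismatches, "mm"),
                 formatC(hits$hit_score, format = "fg", digits = 6),
                 hits$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
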