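#' GC content score of a protospacer
#'
#' Percentage of G+C bases over the 20-nt protospacer (the PAM is not
#' included), rounded to the nearest integer. Extreme GC content in either
#' direction is associated with poor guide activity; 30-70% is the usual
#' working range.
#'
#' @param protospacer 20-nt DNA string (ACGT).
#' @return integer score 0-100.
#' @examples
#' gc_score("GCGCGCGCGCGCGCGCGCGC")  # 100
#' @export
gc_score <- function(protospacer) {
  assert_protospacer(protospacer)
  n_gc <- nchar(gsub("[AT]", "", protospacer))
  round_half_up(100 * n_gc / 20)
}

#' Homopolymer score (binary)
#'
#' 100 if the protospacer contains no run of four or more identical
#' nucleotides (desirable), 0 if it does. Homopolymers, poly-T in
#' particular, impair guide transcription and activity.
#'
#' @inheritParams gc_score
#' @return 0 or 100.
#' @export
homopolymer_score <- function(protospacer) {
  assert_protospacer(protospacer)
  if (grepl("AAAA|CCCC|GGGG|TTTT", protospacer)) 0L else 100L
}

#' Uracil-triplet score (binary)
#'
#' 100 if the protospacer contains no TTT substring (UUU in the RNA
#' product, an RNA Pol III terminator), 0 if it does.
#'
#' @inheritParams gc_score
#' @return 0 or 100.
#' @export
uuu_score <- function(protospacer) {
  assert_protospacer(protospacer)
  if (grepl("TTT", protospacer, fixed = TRUE)) 0L else 100L
}

#' Load the packaged Rule Set 1 coefficient table
#'
#' Reads the versioned tab-separated coefficient file shipped with the
#' package (feature_kind, position, sequence, weight) into the list the
#' scorer consumes. The table is read once per session and cached.
#'
#' @param path optional path to an alternative coefficient file with the
#'   same schema.
#' @return list with `intercept`, `gc_low`, `gc_high`, `single` (named
#'   numeric, names like "5:G" for position:nucleotide over the 30-mer)
#'   and `dinuc` (named numeric, names like "12:GG").
#' @export
rule_set1_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("rs1_coeffs", envir = .scorers)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "rule_set1_weights.tsv",
                        package = "guidekit", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  pick <- function(kind) tab[tab$feature_kind == kind, , drop = FALSE]
  one <- function(kind) {
    w <- pick(kind)$weight
    if (length(w) != 1L) stop_validation("coefficient table needs exactly one ", kind)
    w
  }
  sn <- pick("single"); dn <- pick("dinuc")
  if (any(sn$position < 1 | sn$position > 30))
    stop_validation("single-nucleotide positions must lie in 1-30")
  if (any(dn$position < 1 | dn$position > 29))
    stop_validation("dinucleotide positions must lie in 1-29")
  co <- list(intercept = one("intercept"),
             gc_low = one("gc_low"), gc_high = one("gc_high"),
             single = setNames(sn$weight, paste0(sn$position, ":", sn$sequence)),
             dinuc = setNames(dn$weight, paste0(dn$position, ":", dn$sequence)))
  if (cache) assign("rs1_coeffs", co, envir = .scorers)
  co
}

#' Rule Set 1 on-target activity score
#'
#' Logistic regression over position-specific nucleotide and dinucleotide
#' features of the 30-mer context (protospacer at offset 4, PAM at offset
#' 24), plus a protospacer GC-count deviation term: penalties accrue per
#' base of GC below or above 10/20. The predicted knockout probability
#' p = 1/(1 + exp(-linear score)) is reported as round(100 p). An absent
#' context (edge of contig) yields an absent score (`NA`).
#'
#' @param context30 30-nt DNA string, or `NA`.
#' @param coeffs coefficient list from [rule_set1_coefficients()].
#' @return integer score 0-100, or `NA_integer_`.
#' @export
doench2014_score <- function(context30, coeffs = rule_set1_coefficients()) {
  if (length(context30) != 1L) stop_validation("context30 must be length 1")
  if (is.na(context30)) return(NA_integer_)
  assert_dna(context30, "context30", allow_n = FALSE)
  if (nchar(context30) != 30L)
    stop_validation("context30 must be exactly 30 nt, got ", nchar(context30))
  ch <- strsplit(context30, "")[[1L]]
  total <- coeffs$intercept
  gc <- sum(ch[5:24] %in% c("G", "C"))
  if (gc < 10) total <- total + (10 - gc) * coeffs$gc_low
  if (gc > 10) total <- total + (gc - 10) * coeffs$gc_high
  skey <- paste0(seq_len(30L), ":", ch)
  total <- total + sum(coeffs$single[skey], na.rm = TRUE)
  dkey <- paste0(seq_len(29L), ":", ch[-30L], ch[-1L])
  total <- total + sum(coeffs$dinuc[dkey], na.rm = TRUE)
  p <- 1 / (1 + exp(-total))
  round_half_up(100 * p)
}

#' Register an external on-target scorer plugin
#'
#' Registers a scoring function under a new panel name. When enabled in
#' [score_all()]'s config, the plugin is called with each guide's 30-mer
#' context (`NA` for edge guides) and its integer 0-100 return value (or
#' `NA`) appears as an extra column in the score table and CSV export.
#' This is the attachment point for externally trained activity models
#' that the package does not re-implement.
#'
#' @param name plugin column name; must not collide with a core score or
#'   an already registered plugin.
#' @param fn function taking a 30-mer context string (or `NA`) and
#'   returning a numeric score in 0-100 (or `NA`).
#' @return `name`, invisibly.
#' @export
register_scorer <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (name %in% core_score_names())
    stop_validation("'", name, "' is a core score name")
  if (!is.null(get0(name, envir = scorer_registry())))
    stop_validation("scorer '", name, "' is already registered")
  assign(name, fn, envir = scorer_registry())
  invisible(name)
}

#' Remove a registered plugin scorer
#' @param name registered plugin name.
#' @return `TRUE` invisibly; error if not registered.
#' @export
unregister_scorer <- function(name) {
  reg <- scorer_registry()
  if (is.null(get0(name, envir = reg)))
    stop_validation("scorer '", name, "' is not registered")
  rm(list = name, envir = reg)
  invisible(TRUE)
}

#' List registered plugin scorer names
#' @return character vector, alphabetical.
#' @export
registered_scorers <- function() sort(ls(scorer_registry()))

scorer_registry <- function() {
  reg <- get0("plugins", envir = .scorers)
  if (is.null(reg)) {
    reg <- new.env(parent = emptyenv())
    assign("plugins", reg, envir = .scorers)
  }
  reg
}

#' Names and kinds of the core score panel
#'
#' The eight core panel entries, in canonical column order, with their
#' kind: continuous (0-100), stepped (percent of transcripts), or binary
#' (0 or 100).
#'
#' @return data.frame with `name` and `kind`.
#' @export
score_panel_info <- function() {
  data.frame(
    name = core_score_names(),
    kind = c("continuous", "stepped", "continuous", "binary", "binary",
             "continuous", "continuous", "continuous"),
    stringsAsFactors = FALSE)
}

core_score_names <- function() {
  c("percent_peptide", "transcript_representation", "gc", "no_homopolymer",
    "no_uuu", "doench2014", "hsu2013", "microhomology")
}
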