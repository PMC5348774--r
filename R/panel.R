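#' Enumerate and score every guide targeting a gene
#'
#' End-to-end engine: builds the MCDS, enumerates all NGG candidates whose
#' cut site lies in it, and attaches the enabled score panel to each guide.
#' All scores are integers 0-100 (binary scores take only 0/100); an
#' edge-of-contig guide without a 30-mer context carries `NA` for the
#' on-target score, and `NA` propagates to the CSV as an empty cell,
#' never as 0.
#'
#' @param genome a `genome_seq`.
#' @param gene a `gene_model`.
#' @param config list of options: `scores` (character vector of enabled
#'   core score names, default all eight), `plugins` (names of registered
#'   plugin scorers to enable, default none), `max_mismatches` (off-target
#'   search radius, default 4), `nag_factor` (NAG hit attenuation, default
#'   1), `mh_flank` (microhomology window half-width, default 40).
#' @return data.frame of scored guides, ordered by `guide_id`: the
#'   candidate columns of [enumerate_guides()] plus `gene_id` and one
#'   integer column per enabled score.
#' @export
score_all <- function(genome, gene, config = list()) {
  stopifnot(inherits(genome, "genome_seq"), inherits(gene, "gene_model"))
  enabled <- config$scores %||% core_score_names()
  unknown <- setdiff(enabled, core_score_names())
  if (length(unknown))
    stop_validation("unknown score(s): ", paste(unknown, collapse = ", "),
                    "; known: ", paste(core_score_names(), collapse = ", "))
  plugins <- config$plugins %||% character()
  missing_plugins <- setdiff(plugins, registered_scorers())
  if (length(missing_plugins))
    stop_validation("plugin(s) not registered: ",
                    paste(missing_plugins, collapse = ", "))
  max_mm <- config$max_mismatches %||% 4L
  nag_factor <- config$nag_factor %||% 1
  mh_flank <- config$mh_flank %||% 40L

  mcds <- build_mcds(gene)
  guides <- enumerate_guides(genome, mcds)
  guides <- guides[order(guides$guide_id), , drop = FALSE]
  rownames(guides) <- NULL
  guides <- cbind(gene_id = rep(gene$gene_id, nrow(guides)), guides,
                  stringsAsFactors = FALSE)
  n <- nrow(guides)
  per_guide <- function(fn) {
    if (n == 0L) return(integer())
    vapply(seq_len(n), function(i) {
      g <- guides[i, ]
      tryCatch(fn(g),
               error = function(e) stop_validation(
                 "scoring failed for guide ", g$guide_id, ": ",
                 conditionMessage(e)))
    }, integer(1))
  }
  na_int <- function(x) if (is.na(x)) NA_integer_ else as.integer(x)
  for (sc in intersect(core_score_names(), enabled)) {
    guides[[sc]] <- switch(sc,
      percent_peptide = per_guide(function(g) percent_peptide(mcds, g$cut_pos)),
      transcript_representation = per_guide(function(g)
        transcript_representation(mcds, g$cut_pos)),
      gc = per_guide(function(g) gc_score(g$protospacer)),
      no_homopolymer = per_guide(function(g) homopolymer_score(g$protospacer)),
      no_uuu = per_guide(function(g) uuu_score(g$protospacer)),
      doench2014 = per_guide(function(g) na_int(doench2014_score(g$context30))),
      hsu2013 = per_guide(function(g) {
        hits <- find_offtargets(genome, g$protospacer,
                                target_site = list(contig = g$contig,
                                                   start = g$start,
                                                   strand = g$strand),
                                max_mismatches = max_mm)
        hsu_specificity(hits, nag_factor = nag_factor)
      }),
      microhomology = per_guide(function(g)
        na_int(microhomology_score(genome, g, flank = mh_flank))))
  }
  for (pl in sort(plugins)) {
    fn <- get(pl, envir = scorer_registry())
    guides[[pl]] <- per_guide(function(g) na_int(fn(g$context30)))
  }
  attr(guides, "enabled_scores") <- c(intersect(core_score_names(), enabled),
                                      sort(plugins))
  guides
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a filter specification
#'
#' A filter is a conjunction of inclusive interval clauses over score
#' columns, plus an optional result limit. Clauses can be given as
#' three-element lists `list(name, min, max)` or compact strings
#' `"name:min:max"`. More than four clauses is allowed but draws a
#' warning, since four axes (two plots, two axes each) is the natural
#' working set.
#'
#' @param ... clauses.
#' @param limit optional maximum number of guides kept after filtering.
#' @return a `filter_spec` object.
#' @export
filter_spec <- function(..., limit = NULL) {
  raw <- list(...)
  clauses <- lapply(raw, function(cl) {
    if (is.character(cl) && length(cl) == 1L) {
      parts <- strsplit(cl, ":", fixed = TRUE)[[1L]]
      if (length(parts) != 3L)
        stop_validation("clause string must be 'name:min:max', got '", cl, "'")
      cl <- list(parts[1L], as.numeric(parts[2L]), as.numeric(parts[3L]))
    }
    if (length(cl) != 3L) stop_validation("a clause needs name, min, max")
    out <- list(name = as.character(cl[[1L]]), min = as.numeric(cl[[2L]]),
                max = as.numeric(cl[[3L]]))
    if (is.na(out$min) || is.na(out$max) || out$min > out$max)
      stop_validation("clause on '", out$name, "' needs min <= max")
    if (out$min < 0 || out$max > 100)
      stop_validation("clause bounds must lie in 0-100")
    out
  })
  if (length(clauses) > 4L)
    warning("more than 4 filter clauses; the visual workflow uses at most 4 axes")
  structure(list(clauses = clauses, limit = limit), class = "filter_spec")
}

#' Filter scored guides on score thresholds
#'
#' A guide passes iff every clause interval (inclusive on both ends)
#' contains its value for that score. A guide with an absent (`NA`) value
#' for a clause's score fails that clause. Input order is preserved;
#' `limit` truncates after filtering. Applying the same spec twice is a
#' no-op.
#'
#' @param guides scored guide data.frame from [score_all()].
#' @param spec a `filter_spec` (or arguments coercible via [filter_spec()]).
#' @return the passing subset of `guides`.
#' @export
apply_filters <- function(guides, spec) {
  if (!inherits(spec, "filter_spec")) stop_validation("spec must be a filter_spec")
  for (cl in spec$clauses) {
    if (!cl$name %in% names(guides))
      stop_validation("unknown score '", cl$name, "' in filter; known: ",
                      paste(intersect(c(core_score_names(), registered_scorers()),
                                      names(guides)), collapse = ", "))
    v <- guides[[cl$name]]
    keep <- !is.na(v) & v >= cl$min & v <= cl$max
    guides <- guides[keep, , drop = FALSE]
  }
  if (!is.null(spec$limit)) guides <- head(guides, spec$limit)
  rownames(guides) <- NULL
  guides
}

#' Preset filters for common workflows
#'
#' `"knockout"` maximizes guide efficiency: high on-target and specificity
#' scores, no homopolymer or uracil triplet, full transcript
#' representation, and a high out-of-frame score (cut position along the
#' coding sequence is left free). `"tiling"` keeps guides along the whole
#' coding length: on-target, GC 30-70, and specificity clauses with no
#' positional restriction.
#'
#' @param preset `"knockout"` or `"tiling"`.
#' @param limit optional result limit.
#' @return a `filter_spec`.
#' @export
preset_filter <- function(preset = c("knockout", "tiling"), limit = NULL) {
  preset <- match.arg(preset)
  if (preset == "knockout")
    suppressWarnings(filter_spec("doench2014:50:100", "hsu2013:68:100",
                                 "no_homopolymer:100:100", "no_uuu:100:100",
                                 "transcript_representation:100:100",
                                 "microhomology:50:100", limit = limit))
  else
    filter_spec("doench2014:50:100", "gc:30:70", "hsu2013:68:100",
                limit = limit)
}

#' Export scored guides to CSV
#'
#' Writes a deterministic CSV report: a `#` schema-version comment line, a
#' header, then one row per guide in input order. Genomic coordinates are
#' converted to 1-based inclusive (`start`, `end`, `cut_pos`); absent
#' scores become empty cells. Identical input yields byte-identical files
#' (no timestamps, fixed column order: core columns then plugin columns
#' alphabetically).
#'
#' @param guides scored guide data.frame from [score_all()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_csv <- function(guides, path) {
  core_cols <- c("gene_id", "guide_id", "contig", "start", "end", "strand",
                 "protospacer", "pam", "context30", "cut_pos",
                 core_score_names())
  present <- intersect(core_cols, names(guides))
  plugin_cols <- sort(setdiff(names(guides), core_cols))
  cols <- c(present, plugin_cols)
  df <- guides[, cols, drop = FALSE]
  if ("start" %in% cols) df$start <- df$start + 1L        # 1-based inclusive
  if ("cut_pos" %in% cols) df$cut_pos <- df$cut_pos + 1L
  # `end` is already the 1-based inclusive last base of the half-open interval
  con <- file(path, open = "wb")                          # fixed \n line endings
  on.exit(close(con))
  writeLines(paste0("#guidekit_csv_v1 columns=", paste(cols, collapse = ";")),
             con)
  lines <- vapply(c(list(as.list(cols)),
                    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))),
                  function(row) paste(vapply(row, function(v) {
                    if (length(v) != 1L || is.na(v)) "" else as.character(v)
                  }, character(1)), collapse = ","), character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Re-read a guidekit CSV report
#'
#' Parses a file written by [export_csv()] back into a scored guide
#' data.frame (internal 0-based coordinates restored, empty cells as
#' `NA`). Round-trips losslessly.
#'
#' @param path CSV path.
#' @return data.frame of scored guides.
#' @export
read_guides_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = "")
  if ("start" %in% names(df)) df$start <- df$start - 1L
  if ("cut_pos" %in% names(df)) df$cut_pos <- df$cut_pos - 1L
  for (sc in intersect(c(core_score_names()), names(df)))
    df[[sc]] <- as.integer(df[[sc]])
  df
}
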