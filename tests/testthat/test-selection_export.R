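fixture_scored <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- generate_fixture(fixture_spec(7), tempfile("fx"))
      genome <- load_genome(fx$paths$fasta)
      gene <- load_gene(fx$paths$gff3, "DEMO1")
      cache <<- list(fx = fx, genome = genome, gene = gene,
                     scored = score_all(genome, gene))
    }
    cache
  }
})

test_that("score_all attaches the full panel to every enumerated guide", {
  env <- fixture_scored()
  scored <- env$scored
  m <- build_mcds(env$gene)
  want <- oracle_enumerate(env$genome$contigs[[1]], m$positions, "chrT")
  expect_equal(nrow(scored), nrow(want))
  core <- score_panel_info()$name
  expect_true(all(core %in% names(scored)))
  for (sc in core) {
    v <- scored[[sc]]
    expect_true(all(is.na(v) | (v >= 0 & v <= 100)), label = sc)
  }
  expect_true(all(scored$no_homopolymer %in% c(0L, 100L)))
  expect_true(all(scored$no_uuu %in% c(0L, 100L)))
  expect_equal(scored$guide_id, sort(scored$guide_id))
  # planted probes carry their designed flags
  tr <- env$fx$truth
  by_label <- function(lab) {
    g <- Filter(function(x) x$label == lab, tr$guides)[[1]]
    scored[scored$start == g$site_start & scored$strand == "+", ]
  }
  expect_equal(by_label("homopolymer")$no_homopolymer, 0L)
  expect_equal(by_label("uuu")$no_uuu, 0L)
  expect_equal(by_label("terminal")$percent_peptide, 100L)
  expect_equal(by_label("primary")$transcript_representation, 100L)
})

test_that("a guide hanging off the contig edge gets an absent on-target score", {
  proto <- "GATCGCGATCCATACGACAA"
  seq <- paste0("AT", proto, "TGG", paste(rep("AT", 10), collapse = ""))
  genome <- genome_from_seqs(chr = seq)
  gene <- make_gene("chr", "+", list(rbind(c(10L, nchar(seq)))))
  scored <- score_all(genome, gene)
  edge <- scored[scored$start == 2L & scored$strand == "+", ]
  expect_equal(nrow(edge), 1L)
  expect_true(is.na(edge$doench2014))
  for (sc in setdiff(score_panel_info()$name, "doench2014"))
    expect_false(is.na(edge[[sc]]))
})

test_that("disabling a score removes its column; unknown scores error", {
  env <- fixture_scored()
  sub <- score_all(env$genome, env$gene,
                   config = list(scores = c("gc", "no_uuu")))
  expect_false("hsu2013" %in% names(sub))
  expect_true(all(c("gc", "no_uuu") %in% names(sub)))
  expect_error(score_all(env$genome, env$gene,
                         config = list(scores = "bogus")), "unknown score")
})

test_that("interval filters are inclusive, conjunctive, and fail absent values", {
  df <- data.frame(guide_id = letters[1:5], gc = c(20L, 30L, 50L, 70L, 80L),
                   no_uuu = c(100L, 100L, 0L, 100L, 100L),
                   doench2014 = c(10L, NA, 60L, 80L, 90L))
  got <- apply_filters(df, filter_spec("gc:30:70"))
  expect_equal(got$guide_id, c("b", "c", "d"))
  # absent doench2014 fails a clause naming it
  got <- apply_filters(df, filter_spec("doench2014:0:100"))
  expect_false("b" %in% got$guide_id)
  # empty clause list is vacuous
  expect_equal(apply_filters(df, filter_spec()), df)
  expect_error(apply_filters(df, filter_spec("nope:0:100")), "unknown score")
  expect_error(filter_spec("gc:70:30"), "min <= max")
  # limit truncates after filtering
  expect_equal(nrow(apply_filters(df, filter_spec("gc:30:80", limit = 2))), 2L)
})

test_that("filtering is idempotent, order-independent, and monotone in clause width", {
  env <- fixture_scored()
  scored <- env$scored
  clauses <- list("gc:30:70", "no_uuu:100:100", "no_homopolymer:100:100",
                  "hsu2013:40:100")
  spec <- do.call(filter_spec, clauses)
  once <- apply_filters(scored, spec)
  expect_equal(apply_filters(once, spec), once)
  set.seed(9)
  perm <- do.call(filter_spec, sample(clauses))
  expect_equal(apply_filters(scored, perm), once)
  # shrinking an interval never admits more guides
  for (lo in c(0, 20, 40, 60)) {
    wide <- apply_filters(scored, filter_spec(sprintf("gc:%d:100", lo)))
    narrow <- apply_filters(scored, filter_spec(sprintf("gc:%d:90", lo + 10)))
    expect_lte(nrow(narrow), nrow(wide))
  }
})

test_that("a four-axis knockout-style filter matches the row-filter oracle", {
  env <- fixture_scored()
  scored <- env$scored
  clauses <- list(list(name = "gc", min = 30, max = 70),
                  list(name = "no_uuu", min = 100, max = 100),
                  list(name = "no_homopolymer", min = 100, max = 100),
                  list(name = "hsu2013", min = 68, max = 100))
  spec <- do.call(filter_spec, lapply(clauses, function(cl)
    list(cl$name, cl$min, cl$max)))
  got <- apply_filters(scored, spec)
  want <- oracle_filter(scored, clauses)
  expect_equal(got$guide_id, want$guide_id)
  # beyond four clauses the engine warns but still filters
  expect_warning(filter_spec("gc:0:100", "no_uuu:0:100", "no_homopolymer:0:100",
                             "hsu2013:0:100", "doench2014:0:100"),
                 "more than 4")
})

test_that("CSV export is deterministic, ordered, and round-trips losslessly", {
  env <- fixture_scored()
  scored <- env$scored
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  export_csv(scored, f1)
  export_csv(scored, f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  header <- readLines(f1, n = 2)
  expect_match(header[1], "^#guidekit_csv_v1")
  expect_equal(strsplit(header[2], ",")[[1]][1:10],
               c("gene_id", "guide_id", "contig", "start", "end", "strand",
                 "protospacer", "pam", "context30", "cut_pos"))
  back <- read_guides_csv(f1)
  expect_equal(back$start, scored$start)
  expect_equal(back$cut_pos, scored$cut_pos)
  expect_equal(back$protospacer, scored$protospacer)
  for (sc in score_panel_info()$name)
    expect_equal(back[[sc]], scored[[sc]], label = sc)
  # 1-based inclusive coordinates on disk
  raw <- utils::read.csv(f1, comment.char = "#")
  expect_equal(raw$start, scored$start + 1L)
  expect_equal(raw$end, scored$end)
  # empty table still writes a header
  empty <- scored[0, ]
  f0 <- tempfile(fileext = ".csv")
  export_csv(empty, f0)
  expect_equal(length(readLines(f0)), 2L)
})

test_that("plugin scorers add columns only when enabled", {
  env <- fixture_scored()
  on.exit(try(unregister_scorer("const42"), silent = TRUE), add = TRUE)
  register_scorer("const42", function(ctx) 42L)
  plain <- score_all(env$genome, env$gene, config = list(scores = "gc"))
  expect_false("const42" %in% names(plain))
  with_pl <- score_all(env$genome, env$gene,
                       config = list(scores = "gc", plugins = "const42"))
  expect_true(all(with_pl$const42 == 42L))
  f <- tempfile(fileext = ".csv")
  export_csv(with_pl, f)
  cols <- strsplit(readLines(f, n = 2)[2], ",")[[1]]
  expect_equal(cols[length(cols)], "const42")  # plugin columns trail
  expect_error(score_all(env$genome, env$gene,
                         config = list(plugins = "ghost")), "not registered")
})

test_that("the command-line wrapper designs, filters and reports errors by exit code", {
  cli <- system.file("cli", "guidekit.R", package = "guidekit")
  expect_true(nzchar(cli))
  fx <- generate_fixture(fixture_spec(7), tempfile("fx"))
  out <- tempfile(fileext = ".csv")
  rscript <- file.path(R.home("bin"), "Rscript")
  st <- system2(rscript, c(cli, "design", "--genome", fx$paths$fasta,
                           "--gff", fx$paths$gff3, "--gene", "DEMO1",
                           "--filter", "gc:30:70", "--out", out),
                stdout = TRUE, stderr = TRUE)
  st_code <- attr(st, "status")
  expect_true(is.null(st_code) || st_code == 0L)
  expect_true(file.exists(out))
  got <- read_guides_csv(out)
  expect_true(all(got$gc >= 30 & got$gc <= 70))
  bad <- suppressWarnings(
    system2(rscript, c(cli, "design", "--genome", fx$paths$fasta,
                       "--gff", fx$paths$gff3, "--gene", "NOSUCH"),
            stdout = TRUE, stderr = TRUE))
  expect_equal(attr(bad, "status"), 2L)
})

test_that("preset filters encode the knockout and tiling workflows", {
  ko <- preset_filter("knockout")
  names_of <- function(sp) vapply(sp$clauses, `[[`, character(1), "name")
  expect_true(all(c("doench2014", "hsu2013", "no_homopolymer", "no_uuu",
                    "transcript_representation", "microhomology") %in%
                    names_of(ko)))
  ti <- preset_filter("tiling")
  expect_false("percent_peptide" %in% names_of(ti))
  expect_true(all(c("doench2014", "gc", "hsu2013") %in% names_of(ti)))
  env <- fixture_scored()
  res <- apply_filters(env$scored, ti)
  want <- oracle_filter(env$scored, ti$clauses)
  expect_equal(res$guide_id, want$guide_id)
})
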