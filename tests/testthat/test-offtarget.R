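test_that("per-hit mismatch scoring follows the position/density/count formula", {
  w <- mismatch_weights()
  expect_length(w, 20L)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(hit_score(integer(), w), 100)
  # single penalty-free mismatch: positions 1, 2 carry weight 0
  expect_equal(hit_score(1L, w), 100)
  expect_equal(hit_score(2L, w), 100)
  # frozen hand evaluation for mismatches at 5 and 6:
  # 100 * (1-0)(1-0.395) * 1/(((19-1)/19)*4+1) * 1/4 = 287.375/91
  expect_equal(hit_score(c(5L, 6L), w), 287.375 / 91, tolerance = 1e-12)
  expect_error(hit_score(c(0L, 5L), w), "1-20")
  expect_error(hit_score(21L, w), "1-20")
})

test_that("hit scores weaken as mismatches accumulate at fixed spread", {
  w <- mismatch_weights()
  set.seed(12)
  for (i in 1:50) {
    m <- sample(1:4, 1)
    pos <- sort(sample(1:20, m))
    s <- hit_score(pos, w)
    expect_true(s > 0 && s <= 100)
    if (m < 4) {
      extra <- setdiff(1:20, pos)
      s2 <- hit_score(sort(c(pos, sample(extra, 1))), w)
      expect_lte(s2, s)
    }
  }
})

test_that("aggregate specificity collapses hit mass with the stated closed form", {
  expect_equal(hsu_specificity(numeric()), 100L)
  expect_equal(hsu_specificity(100), 50L)    # one exact duplicate
  expect_equal(hsu_specificity(c(100, 100, 100)), 25L)
  # adding any hit strictly decreases the unrounded aggregate
  set.seed(7)
  for (i in 1:50) {
    hits <- runif(sample(0:5, 1), min = 0.5, max = 100)
    more <- c(hits, runif(1, min = 0.5, max = 100))
    agg <- function(s) 100 * 100 / (100 + sum(s))
    expect_lt(agg(more), agg(hits))
    expect_lte(hsu_specificity(more), hsu_specificity(hits))
  }
})

test_that("specificity above 50 certifies no exact duplicate", {
  # with every hit score <= 100 and exact hits scoring exactly 100,
  # sum < 100 <=> no exact hit when mismatch scores stay below 50
  w <- mismatch_weights()
  set.seed(42)
  for (i in 1:100) {
    n_exact <- sample(0:2, 1)
    n_mm <- sample(0:3, 1)
    mm_scores <- if (n_mm) vapply(seq_len(n_mm), function(.)
      hit_score(sort(sample(1:20, sample(2:4, 1))), w), numeric(1)) else numeric()
    scores <- c(rep(100, n_exact), mm_scores)
    spec <- 100 * 100 / (100 + sum(scores))
    if (n_exact > 0) expect_lte(spec, 50)
  }
  # and a guide with zero candidate sites is maximally specific
  expect_equal(hsu_specificity(data.frame(hit_score = numeric())), 100L)
})

test_that("off-target search finds planted duplicates and near-matches", {
  fx <- generate_fixture(fixture_spec(101), tempfile("fx"))
  genome <- load_genome(fx$paths$fasta)
  tr <- fx$truth
  primary <- tr$guides[[1]]
  hits <- find_offtargets(genome, primary$protospacer,
                          target_site = list(contig = tr$contig,
                                             start = primary$site_start,
                                             strand = "+"))
  expect_equal(nrow(hits), length(tr$offtargets))
  for (o in tr$offtargets) {
    row <- hits[hits$site_start == o$site_start & hits$strand == o$strand, ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$pam_class, o$pam_class)
    expect_equal(row$n_mismatches, o$n_mismatches)
    expect_equal(row$mismatch_positions,
                 paste(o$mismatch_positions, collapse = ","))
    if (o$n_mismatches == 0L) expect_equal(row$hit_score, 100)
  }
})

test_that("an exact 20-mer without a valid PAM is not a hit", {
  proto <- "GATCGCGATCCATACGACAA"
  bg <- paste(rep("AT", 15), collapse = "")
  genome <- genome_from_seqs(chr = paste0(bg, proto, "ATT", bg))
  hits <- find_offtargets(genome, proto)
  expect_equal(nrow(hits), 0L)
})

test_that("off-target search equals the sliding-window Hamming oracle", {
  fx <- generate_fixture(fixture_spec(77), tempfile("fx"))
  genome <- load_genome(fx$paths$fasta)
  for (g in fx$truth$guides) {
    got <- find_offtargets(genome, g$protospacer)  # no self-exclusion
    want <- oracle_offtargets(genome, g$protospacer)
    expect_equal(nrow(got), nrow(want))
    for (col in c("contig", "strand", "site_start", "pam_class",
                  "n_mismatches", "mismatch_positions"))
      expect_equal(got[[col]], want[[col]], label = col)
  }
  # a small random genome exercises incidental near-matches too
  set.seed(3)
  rg <- genome_from_seqs(c1 = random_dna(400), c2 = random_dna(150))
  q <- fx$truth$guides[[1]]$protospacer
  got <- find_offtargets(rg, q)
  want <- oracle_offtargets(rg, q)
  expect_equal(got$site_start, want$site_start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$pam_class, want$pam_class)
})

test_that("the on-target site is excluded and NAG attenuation applies", {
  fx <- generate_fixture(fixture_spec(55), tempfile("fx"))
  genome <- load_genome(fx$paths$fasta)
  tr <- fx$truth
  primary <- tr$guides[[1]]
  all_hits <- find_offtargets(genome, primary$protospacer)
  excl <- find_offtargets(genome, primary$protospacer,
                          target_site = list(contig = tr$contig,
                                             start = primary$site_start,
                                             strand = "+"))
  expect_equal(nrow(all_hits) - nrow(excl), 1L)
  expect_false(any(excl$site_start == primary$site_start & excl$strand == "+"))
  # NAG attenuation of 0 removes NAG hit mass from the aggregate
  nag <- excl[excl$pam_class == "NAG", ]
  expect_gt(nrow(nag), 0L)
  expect_gte(hsu_specificity(excl, nag_factor = 0),
             hsu_specificity(excl, nag_factor = 1))
})
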