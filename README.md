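# guidekit

guidekit is an R package for designing SpCas9 CRISPR knockout and tiling
experiments. It exhaustively enumerates every guide RNA (20-nt
protospacer + NGG PAM) whose predicted cut site falls in the
protein-coding portion of a gene, scores each guide on a ten-parameter
panel, filters on user-chosen thresholds, and exports a deterministic
CSV report. It is aimed at researchers who want all the standard guide
design criteria — position, on-target activity, specificity, sequence
composition, repair outcome — computed in one place, offline, over any
FASTA genome with a GFF3 annotation.

## The model

**Coding coordinate system.** All protein-coding transcripts of a gene
are overlaid into one *master coding DNA sequence* (MCDS): the set union
of their CDS genomic positions, ordered 5′→3′. Every guide is located by
its cut site (the blunt double-strand break 3 nt 5′ of the PAM).

**The score panel** (all integer 0–100):

| score | meaning |
|---|---|
| `percent_peptide` | 100 × rank(cut)/\|MCDS\| — progression through the coding sequence |
| `transcript_representation` | % of the gene's coding transcripts whose CDS contains the cut |
| `gc` | % G+C of the protospacer |
| `no_homopolymer` | binary: 100 iff no run of ≥ 4 identical bases |
| `no_uuu` | binary: 100 iff no TTT (RNA Pol III terminator) |
| `doench2014` | Rule Set 1 logistic on-target activity over the 30-mer context, round(100·p) |
| `hsu2013` | aggregate off-target specificity, 100·100/(100 + Σ hit scores) over all NGG/NAG sites within 4 mismatches; per-hit score 100·Π(1−w_p)·density·1/m² |
| `microhomology` | % of microhomology-weighted deletion outcomes that shift the reading frame |

A score of 100 on `hsu2013` means no candidate off-target at all; > 50
certifies no exact genomic duplicate. Externally trained on-target
models can be attached through `register_scorer()` and appear as extra
CSV columns.

## Worked example

Everything runs on a bundled synthetic mini-genome generator — no
downloads:

```r
library(guidekit)
fx     <- generate_fixture(fixture_spec(7), file.path(tempdir(), "fx"))
genome <- load_genome(fx$paths$fasta)
gene   <- load_gene(fx$paths$gff3, "DEMO1")
scored <- score_all(genome, gene)
nrow(scored)
#> [1] 27
head(scored[, c("guide_id", "strand", "percent_peptide",
                "transcript_representation", "gc", "doench2014",
                "hsu2013", "microhomology")], 5)
#>     guide_id strand percent_peptide transcript_representation gc doench2014 hsu2013 microhomology
#> 1 chrT:188:+      +               2                       100 60         49     100            60
#> 2 chrT:194:-      -               0                       100 60          6     100            53
#> 3 chrT:203:-      -               4                       100 55         31     100            60
#> 4 chrT:210:+      +              11                       100 50         53      49            60
#> 5 chrT:219:-      -              11                       100 40         28     100            50
```

27 guides target the 240-bp MCDS of the fixture gene. Guide
`chrT:210:+` is the planted primary guide: it cuts at 11% of the coding
sequence, in an exon shared by both transcripts (representation 100),
but its specificity is 49 — below the 50 boundary — because the fixture
also plants an exact intergenic duplicate of its protospacer plus a
2-mismatch NAG site. Filtering with the tiling preset (on-target ≥ 50,
GC 30–70, specificity ≥ 68):

```r
picked <- apply_filters(scored, preset_filter("tiling"))
picked[, c("guide_id", "percent_peptide", "gc", "doench2014", "hsu2013")]
#>     guide_id percent_peptide gc doench2014 hsu2013
#> 1 chrT:261:+              33 30         62     100
export_csv(picked, "guides.csv")
```

A command-line wrapper over the same functions ships at
`inst/cli/guidekit.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","guidekit.R",package="guidekit"))')" \
  design --genome genome.fa --gff genes.gff3 --gene DEMO1 \
  --filter gc:30:70 --preset tiling --out guides.csv
```

See `vignettes/guide-scoring-methods.Rmd` for the full account of each
scoring function, its parameters and defaults, and the design choices.

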