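---
title: "Guide RNA scoring methods in guidekit"
author: "guidekit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide RNA scoring methods in guidekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidekit)
```

## The problem

Designing an SpCas9 knockout or tiling experiment means choosing, from
every 20-nt protospacer adjacent to an NGG PAM in a gene's coding
sequence, the handful of guides that cut where you want, cut efficiently,
cut nowhere else, and leave a frameshift behind. guidekit implements the
computational engine for that workflow: exhaustive enumeration of
candidates over a gene's coding positions, a panel of ten interpretable
0–100 scores per guide, conjunctive threshold filtering, and a
deterministic CSV report.

All scores are rounded half-away-from-zero to the nearest integer.
Decimal precision is statistically meaningless for ranking guides, and
integer scores are what practitioners compare across tools; the rounding
is applied uniformly by `round_half_up()` at the reporting boundary, so
internal arithmetic stays exact.

## The master coding DNA sequence (MCDS)

A gene usually has several protein-coding transcripts whose CDS only
partially overlap. guidekit overlays them into one coordinate system, the
MCDS: the **set union** of all retained transcripts' CDS genomic
positions, ordered 5′→3′ in the gene's reading direction, with each
position recording which transcripts cover it. Union (rather than a
longest-transcript scaffold) is the only definition under which *every*
guide that cuts coding sequence in *any* transcript has a defined
position score; this was a genuinely open design choice and is worth
remembering when comparing numbers against other tools.

Transcript retention: a transcript is kept iff its `biotype` attribute is
`protein_coding`, or it has no biotype but owns at least one CDS feature.
Transcripts with incomplete CDS annotation (no start or stop codon
flagged) are treated as ordinary coding transcripts — the annotation
flags are not consulted.

Two scores derive from the MCDS, both evaluated at the guide's **cut
site** (the blunt DSB 3 nt 5′ of the PAM, i.e. between protospacer
positions 17 and 18), not at the protospacer start — the cut is where the
indel lands, so it is the biologically meaningful anchor:

* **percent peptide** = 100 × rank(cut position)/|MCDS|. The final coding
  base scores exactly 100; < 50 means the guide targets the 5′ half.
* **transcript representation** = 100 × (covering transcripts)/(all
  transcripts). Reported as the exact rounded percentage; a stepped
  0,10,…,100 axis cannot represent a 3-transcript gene exactly, so
  stepping is treated as presentation, not data.

Guide inclusion uses the criterion *cut position ∈ MCDS*; whether the
whole protospacer must lie in coding sequence is left open by the source
conventions, and the cut-site criterion is the one that ties inclusion to
the repair event.

## Enumeration

`enumerate_guides()` scans both strands of the contig for N20+NGG
23-mers (overlapping PAMs give distinct candidates; NAG sites are never
candidates — NAG matters only for off-target search). Guides containing N
in protospacer or PAM are discarded: every scoring function is undefined
on ambiguity codes. Duplicate protospacers at different loci stay
separate records because position-derived scores differ per locus. The
guide id `<contig>:<site start>:<strand>` is a stable join key across
runs. Internally all coordinates are 0-based half-open; conversion to
1-based inclusive happens only at the GFF3 and CSV boundaries.

## Sequence-intrinsic scores

* **GC** — percent G+C of the protospacer (PAM excluded), continuous.
* **no_homopolymer** — binary; 0 iff a run of ≥ 4 identical bases exists.
* **no_uuu** — binary; 0 iff TTT occurs (UUU is an RNA Pol III
  terminator in the transcribed guide).
* **doench2014** — the Rule Set 1 logistic regression over the 30-mer
  context (4 nt upstream + protospacer + PAM + 3 nt downstream):
  intercept, a protospacer GC-deviation term (separate per-base weights
  below and above 10/20 GC), 38 position-specific nucleotide weights and
  30 position-specific dinucleotide weights. The coefficient table ships
  as `inst/extdata/rule_set1_weights.tsv`, pinned so scores are
  reproducible; the shipped variant has no NGGX interaction feature (the
  file documents exactly which features it includes). The reported score
  is round(100 × p). Externally trained successors (gradient-boosted
  models distributed as Python packages) are deliberately not
  re-implemented; `register_scorer()` exposes a plugin slot so such a
  scorer can be attached and exported as an extra CSV column.

A guide whose 30-mer window runs off the contig has an **absent** score,
exported as an empty CSV cell — never 0, because 0 is a meaningful score.

## Off-target specificity

`find_offtargets()` scans every contig, both strands, for 20-mers
adjacent to NGG **or** NAG PAMs within `max_mismatches` (default 4, the
convention of the original web tool; the search radius is configurable)
of the query protospacer. The search is an exhaustive windowed scan —
correctness first; at the mini-genome scales this package targets it is
also fast. Each hit is scored from its mismatch positions alone
(position and density matter, nucleotide identity does not):

$$\mathrm{hit} = 100 \times \prod_{p \in M}(1-w_p) \times
\frac{1}{\frac{19-\bar d}{19}\times 4+1} \times \frac{1}{m^2}$$

with $w$ the 20-entry position weight vector
(`inst/extdata/hsu2013_weights.tsv`, position 1 = PAM-distal), $\bar d$
the mean distance between consecutive mismatch positions (no density
penalty when $m = 1$), and an exact match scoring 100. The aggregate
guide score is $100 \times 100/(100+\sum \mathrm{hits})$: 100 with no
candidate sites, exactly 50 with a single exact duplicate, so > 50
certifies no exact match elsewhere. NAG hits enter the sum with the same
formula; an optional multiplicative `nag_factor` (default 1.0) makes the
equal-weighting assumption explicit and testable, since no published
weighting for NAG exists in this scheme.

## Microhomology out-of-frame score

Around each cut, `enumerate_patterns()` finds all identical substring
pairs (arm length ≥ 2) with one copy ending at or before the cut and one
starting at or after it; collapsing a pair deletes `deletion_length`
bases. Patterns contained in a longer pattern with identical deletion
boundaries are deduplicated. Each pattern scores
100 × round(exp(−deletion_length/20), 3) × (arm length + GC count) — the
exponential factor is rounded to 3 decimals before multiplication, for
bit-reproducible pattern scores. The guide's score is the percentage of
total pattern weight from deletions whose length is not a multiple of 3.
The window is 40 bp per side (configurable); published work used fixed
flanks of that order and the production choice is not documented
anywhere, so 40 bp is adopted as the default and stated here. A window
with no pattern scores 0 with a warning — absence of microhomology is not
evidence of frameshift. Deletion outcomes are a property of the locus,
so the forward-strand window is used for guides on either strand.

## Filtering and export

`apply_filters()` takes inclusive interval clauses (the phrasing "a
range of 30–70%" implies closed intervals) combined conjunctively;
guides with an absent score fail any clause naming it, mirroring a plot
where unplottable points simply disappear. More than four clauses is
permitted with a warning — four is the natural working set of a
two-plot, four-axis view, not an engine limit. Two presets encode the
standard workflows: `knockout` (on-target ≥ 50, specificity ≥ 68,
homopolymer/UUU clean, full transcript representation, out-of-frame ≥
50 — cut position left free) and `tiling` (on-target ≥ 50, GC 30–70,
specificity ≥ 68, **no** positional clause, so the panel still tiles the
whole coding length). The preset thresholds follow the published tiling
walkthrough, with the in-scope Rule Set 1 axis standing where that
walkthrough used a successor on-target score.

`export_csv()` writes a fixed, versioned column order with 1-based
inclusive coordinates and is byte-deterministic; `read_guides_csv()`
round-trips it losslessly.

## The synthetic fixture generator

`generate_fixture()` exists so the entire engine is testable offline: it
emulates the situation the production tool faces — a reference genome
plus an Ensembl-style GFF3 gene annotation — at desk scale. A fixture is
one 2 kb contig carrying a two-transcript gene (two shared exons and one
transcript-specific exon, 240 bp of MCDS) and planted, truth-tracked
features: guides in shared exons, a guide cutting the final MCDS base,
homopolymer- and TTT-containing guides, an intergenic exact duplicate,
and bounded-mismatch NGG/NAG near-match sites. Planted protospacers come
from a fixed codebook with pairwise Hamming distance ≥ 12, so a
4-mismatch search around one plant can never reach another; the random
background is rejection-checked at generation time so no unplanned
20-mer with an NGG/NAG PAM lies within 4 mismatches of any plant. One
seeded RNG stream drives everything, and the generator restores the
caller's RNG state, so identical specs give byte-identical
FASTA/GFF3/truth.json outputs.

What the fixtures do **not** emulate: realistic base composition
(isochores, repeats), multi-contig genomes at scale, alternative splice
complexity beyond two transcripts, and incomplete/overlapping gene
annotations. Passing tests therefore demonstrate algorithmic
correctness, not that score distributions on real genomes are
reproduced; on a real genome the off-target search cost grows linearly
with genome size and a seeded index (which must return scan-identical
results) would be the natural accelerator.

## Worked example

```{r example}
fx <- generate_fixture(fixture_spec(7), file.path(tempdir(), "fx"))
genome <- load_genome(fx$paths$fasta)
gene <- load_gene(fx$paths$gff3, "DEMO1")
scored <- score_all(genome, gene)
nrow(scored)
head(scored[, c("guide_id", "strand", "percent_peptide",
                "transcript_representation", "gc", "doench2014",
                "hsu2013", "microhomology")])
picked <- apply_filters(scored, preset_filter("tiling"))
nrow(picked)
```

## Numerical choices, degenerate inputs, limitations

* Rounding: half-away-from-zero, applied once per reported score.
* Ties in ordering: guides sort by genomic start, then + before −; the
  scored table sorts by guide id, so output order is total and stable.
* Degenerate inputs: genes with zero coding transcripts, unknown score
  names, out-of-MCDS cut positions, and malformed clause bounds all fail
  fast with typed validation errors rather than producing silent zeros.
* Problem sizes: fixtures are 2 kb with ~25–30 candidate guides per
  gene; property suites run hundreds of randomized cases per invariant.
  These sizes make every oracle comparison exact and exhaustive.
* Known limitations: no bulge/indel off-targets and no
  nucleotide-identity-aware mismatch penalties (position-only weighting
  is intrinsic to this specificity score); no chromatin or accessibility
  features; the successor on-target models are plugin-only; GTF dialect
  and Ensembl REST lookup are out of scope.
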