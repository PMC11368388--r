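---
title: "Gene conservation and synteny diagrams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene conservation and synteny diagrams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what the pipeline computes, the choices behind its
defaults, what the synthetic-genome generator does and does not emulate, and
the limitations a user should keep in mind. It states no result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The model of conservation

The unit of comparison is the annotated gene, not the whole genome. For a
gene $q$ of genome $g_i$ and any other genome $g_j$, the pipeline keeps at
most one *best hit*: the highest-bitscore homology match of $q$ among
$g_j$'s genes. Conservation is then a per-plot quantity: for a plotted
selection of $n$ genomes, a gene's match count $m \in \{0, \dots, n-1\}$ is
the number of *other* selected genomes holding a best hit, and its
conservation fraction is $c = m/(n-1)$.

The denominator $n-1$ excludes the gene's own genome, so the scale's ends
have exact meaning: $c = 0$ is a gene unique within the displayed set and
$c = 1$ a strictly conserved one. Matching is *directional* (query →
subject): a gene counts genome $g_j$ if its own search found a best hit
there, whether or not $g_j$'s reciprocal search picks the same partner.
Reciprocal-best filtering would give a stricter orthology notion but makes
"conserved" depend on the rest of $g_j$'s gene complement; the directional
count matches the best-hit tables the user can inspect. A "match" is any
best hit that passed the e-value screen — no second identity floor is
applied for counting; identity thresholds affect only which cross-links are
drawn.

## Homology engines

Two engines satisfy the same contract (same hit tables, same thresholds):

* **external** — BLAST+ (`makeblastdb`, `blastn -task blastn`,
  `blastp`, tabular output), the engine of choice when the binaries are
  installed. `-dust no` keeps low-complexity gene ends from truncating
  alignments on short genes.
* **builtin** — global Needleman–Wunsch via Biostrings, so the package has
  no hard external dependency. Scoring is blastn-like for nucleotides
  (match +2, mismatch −3, gap open 5, extend 2) and BLOSUM62 (gap open 11,
  extend 1) for proteins. The raw alignment score is reported in the
  `bitscore` column and the e-value is the Karlin–Altschul approximation
  $E = m N 2^{-S'}$ with $S' = (\lambda S - \ln K)/\ln 2$, using the
  published gapped constants ($\lambda = 0.625, K = 0.41$ for the
  nucleotide scheme; $\lambda = 0.267, K = 0.041$ for BLOSUM62). These
  constants are conventional defaults, not fitted values.

Hits with $E > 10^{-3}$ are discarded; the threshold is a standard homology
screen and is configurable (`evalue_threshold`). Percent identity follows
the BLAST convention, matches / alignment length × 100, where the alignment
length includes gaps.

Ties on bitscore break by greater alignment length, then smaller e-value,
then lexicographically smaller subject key. The order is total, so repeated
runs produce byte-identical summary tables — a deliberate property that the
tests assert on the written Parquet files.

"Best" is defined by bitscore rather than percent identity: a long
80%-identity alignment is a better homology statement than a 20-bp perfect
match, and bitscore is the BLAST-native ranking. Since the builtin engine's
raw score is a monotone proxy under the same scheme, the two engines rank
hits compatibly.

The builtin engine's global alignment is a simplification: genes of very
different lengths pay end-gap penalties that BLAST's local model does not,
so weak partial-domain matches may be missed. For production comparisons of
real genomes the external engine is recommended; the builtin engine's role
is deterministic desk-scale operation, and the suite checks that the two
agree on well-separated fixtures (identities ≥ 70 %).

## Identifier resolution

GenBank submissions are inconsistent about identifiers, so keying follows
the file's feature composition: files with gene features key by
`locus_tag`; CDS-only files key by `protein_id`. Files that mix the clean
cases fall back per feature (other identifier, then gene name) before
rejecting, which keeps nearly-complete files usable. For gene-annotated
files the matching CDS (same locus_tag, else nested interval) contributes
its protein id, product and translation, so one processed row per gene unit
carries everything downstream stages need. `|` is forbidden in keys because
intermediate FASTA headers use `genome|key`. Pseudo-genes are retained when
they carry an identifier — the pipeline annotates conservation, it does not
judge functionality. Features other than gene/CDS (tRNA, regulatory) stay
in the raw table but are excluded from homology and plotting.

Coordinates are converted once, at the parse boundary, from GenBank's
1-based inclusive convention to 0-based half-open, and converted back only
when writing GenBank. Compound (`join`) locations keep their exact segments
for sequence extraction and translation but are collapsed to outer bounds,
flagged, for plotting — phage genes are essentially never spliced, and a
plot needs one interval per gene.

## The diagram

Tracks are stacked in selection order, left-aligned, on a shared
base-pair-true x-scale (no per-genome normalisation), so genome lengths are
visually comparable. A reverse-oriented genome is mirrored coordinate-wise:
a gene at $[s, e)$ is drawn at $[L-e, L-s)$ with its arrowhead flipped —
mirroring twice reproduces the forward rendering exactly. Gene fills come
from the conservation palette (yellow → green → blue → purple by default;
fractions 0 and 1 map to the first and last anchor hex exactly). Links are
drawn only between adjacent tracks, from either query direction,
deduplicated by unordered gene pair, and shaded light-grey → dark-red by
percent identity; `min_link_identity` (default 0) hides weak links without
touching the counting. Centring tracks instead of left-aligning them was
considered and rejected: left alignment keeps genome starts comparable, and
orientation flips are the supported way to line features up.

The SVG is generated by direct text serialisation with fixed number
formatting — identical inputs give byte-identical files, which makes
regression testing trivial and diffs meaningful. The PNG re-draws the same
scene tree on R's cairo device at 300 dpi; it is a raster of the same
geometry, not an independent layout.

## The synthetic-genome generator

Tests and the acceptance script run on generated genome sets whose ground
truth is known exactly. A fixture spec plants three kinds of genes:

* **core families** present in every genome;
* **shared blocks**: families present in a stated genome subset at a target
  percent identity $t$ — the family's first member carries the reference
  sequence, the others a variant with $\mathrm{round}((1-t/100) \cdot L)$
  point substitutions placed preferentially at codon position 3 (never
  creating an in-frame stop), so every within-family pairwise identity is
  at least $t$;
* **unique genes**: random coding sequences rejection-sampled until they
  share no 11-bp exact match, on either strand, with any other genome's
  genes — an operational guarantee of undetectability, not a biological
  claim.

Genes are laid out with random intergenic spacers and random strands, with
both a gene and a CDS feature (locus tag `G<i>_<j>`, protein id,
translation), and everything is deterministic given the seed. The default
study conditions are 3 core families, a 2-gene block over half the genomes
at 85 % identity, 1 unique gene per genome, gene lengths 120–300 bp and
spacers 20–80 bp — a deliberately compact caricature of small phage
genomes that keeps a full 30-run acceptance sweep (n ∈ {3, 5, 8} × 10
seeds) in the order of a minute on one core. What the generator does *not*
emulate: real mosaicism (no recombination model), indels, paralogy within a
genome, annotation errors, or partial/pseudo features. Passing tests
therefore demonstrate the pipeline's *accounting* — parsing, best-hit
reduction, counting, colouring, rendering — under controlled homology, not
the sensitivity of any aligner on diverged natural sequences.

`expected_conservation()` is the independent oracle: it counts family
co-membership directly from the manifest, never touching the alignment
path, and the acceptance suite requires the full pipeline to reproduce it
exactly, with planted unique genes recovered at zero false positives and
zero false negatives.

## Orchestration

The four steps (download, validate, blastn/blastp, plot) are plain
commands over one YAML-configurable run directory, with an append-only
JSON-lines metadata log and a `status` subcommand in place of any daemon or
web interface. Step ordering is enforced by artifact presence: `blastn`
without prior `validate` fails naming the missing table, and `plot` reads
but never rewrites upstream tables, so replotting different selections,
orientations and palettes is free. The NCBI downloader (Entrez
esearch/efetch) requires a contact email, honours `NCBI_API_KEY`, retries
transient failures with exponential backoff, rate-limits per NCBI policy
and skips files already present; all its tests run against injected mock
transports.

## Known limitations

* Conservation is pairwise-best-hit based; there is no orthology
  clustering, so a gene family duplicated within one genome contributes
  only its single best partner per subject genome.
* The builtin aligner's global model under-scores genes of very unequal
  length; use BLAST+ for real data.
* E-values from the builtin engine are approximations for screening, not
  calibrated significance statements.
* The linear diagram draws links only between adjacent tracks; relations
  between distant tracks are expressed through colour, not ribbons, so
  track order matters to what is visible.
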