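# phagesynteny

Comparative genomics of annotated bacteriophage genomes in R: parse GenBank
files, measure per-gene conservation across a set of related phages, and draw
stacked linear synteny diagrams in which every gene is colour-coded by how
widely it is conserved and cross-links between adjacent genomes are shaded by
percent identity.

Phage genomes are mosaic: a genome is a patchwork of genes with different
evolutionary histories. Within a group of related phages (say, one genus),
knowing which genes are strictly conserved, which are shared by only some
members, and which are unique to a single genome points directly at core
structural machinery, accessory genes, and recombination hotspots. This
package is for phage biologists (and anyone comparing plasmids, operons or
small bacterial loci) who want that picture from a directory of `.gb` files
without manual BLAST bookkeeping.

## The method

For genomes \(g_1, \dots, g_N\) with annotated gene features:

1. **Ingest and validate.** Each GenBank file is parsed into a feature table;
   completeness checks decide per genome whether genes are keyed by
   `locus_tag` (files with gene features) or by `protein_id` (CDS-only
   files). Failing genomes are dropped with a warning, never abort a run.
2. **All-vs-all homology.** Every gene is searched against the genes of every
   *other* genome, as nucleotide (`blastn`) and/or translated protein
   (`blastp`), with either external BLAST+ or a built-in Needleman–Wunsch
   engine. For each query gene and each subject genome only the best-scoring
   hit is kept:

   \[ \mathrm{best}(q, g) = \arg\max_{h \in \mathrm{hits}(q,g)} \mathrm{bitscore}(h) \]

   with percent identity defined as matches / alignment length × 100.
3. **Conservation.** For a plotted selection of \(n\) genomes, each gene's
   conservation is

   \[ c = \frac{\text{number of other selected genomes with a best hit}}{n - 1} \in [0, 1], \]

   so \(c = 0\) is unique within the set and \(c = 1\) strictly conserved.
   \(c\) is mapped through a yellow→green→blue→purple gradient to colour the
   gene glyphs; links between adjacent tracks are shaded by percent identity.

All intermediate tables (`genbank_df`, `processed_genbank_df`,
`blastn_summary`/`blastp_summary`, `gene_uniqueness`/`protein_uniqueness`,
and the per-plot `colour_table`) are written as Parquet and can be queried
with arrow, DuckDB, pandas, etc. Re-plotting with a new selection,
orientation or palette reuses them untouched, so any number of figures can
be produced from one homology run.

## Worked example

A synthetic four-genome set with three core genes, a two-gene block shared by
three genomes at 80 % identity, and one unique gene per genome:

```r
library(phagesynteny)

data_dir <- "demo"
spec <- fixture_spec(
  n_genomes = 4, n_core = 3,
  shared_blocks = list(list(n_genes = 2, genomes = 1:3, identity = 80)),
  n_unique_per_genome = 1, seed = 7)
man <- generate_genome_set(spec, file.path(data_dir, "genbank"))

cfg <- run_config(data_dir = data_dir)
cmd_validate(cfg)          # parse + check, writes the parquet feature tables
cmd_blast(cfg, "blastn")   # all-vs-all search + best-hit + uniqueness tables

sel <- sequence_selection(man$genomes)
res <- plot_job(data_dir, sel, "blastn",
                plot_config(title = "Four synthetic phages"))

head(res$colour_table[, c("genome_id", "key", "match_count_in_set",
                          "conservation_fraction", "colour")], 6)
#>   genome_id  key match_count_in_set conservation_fraction  colour
#> 1     SYN01 G1_1                  3             1.0000000 #6A1B9A
#> 2     SYN01 G1_2                  3             1.0000000 #6A1B9A
#> 3     SYN01 G1_3                  3             1.0000000 #6A1B9A
#> 4     SYN01 G1_4                  2             0.6666667 #1E88E5
#> 5     SYN01 G1_5                  2             0.6666667 #1E88E5
#> 6     SYN01 G1_6                  0             0.0000000 #FDD835
```

The three core genes are strictly conserved (fraction 1, purple); the block
genes match 2 of the 3 other plotted genomes (blue); `G1_6` matches nothing
(yellow). The colour table can be queried directly:

```r
query_unique_genes(res$colour_table, "SYN01")
#>    key gene_name              product
#> 1 G1_6      <NA> hypothetical protein

uniq <- arrow::read_parquet(file.path(data_dir, "tables", "gene_uniqueness.parquet"))
query_gene_matches(uniq, "G1_4", "SYN01")
#>   subject_genome subject_key percent_identity
#> 1          SYN02        G2_4         80.13468
#> 2          SYN03        G3_4         80.13468
```

`plot_job()` wrote `demo/plots/synteny.svg` and `.png` (four tracks, genes
coloured as above, adjacent-track links shaded by identity) plus
`colour_table.parquet` next to them.

The same pipeline runs from a shell via the bundled entry point:

```sh
inst/cli/synteny-conserve validate --data-dir demo
inst/cli/synteny-conserve blastn   --data-dir demo
inst/cli/synteny-conserve plot     --data-dir demo --selection sel.csv --format svg,png
```

where `sel.csv` has a `sequence,orientation` header (orientation `1` =
forward, `0` = reverse, one row per genome in top-to-bottom plot order).
Genomes can also be pulled straight from NCBI with
`synteny-conserve download` given an Entrez `search_key` and contact email
in the YAML config.

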