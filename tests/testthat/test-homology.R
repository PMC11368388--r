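make_gene_table <- function(...) {
  # named genome -> character vector of gene seqs (names = keys)
  args <- list(...)
  do.call(rbind, lapply(names(args), function(g) {
    data.frame(genome_id = g, key = names(args[[g]]), seq = unname(args[[g]]),
               kind = "nucleotide", stringsAsFactors = FALSE)
  }))
}

test_that("gene extraction slices forward strands and reverse-complements minus strands", {
  rec <- list(genome_id = "G", sequence = "ATGAAACCCGGG")
  feats <- data.frame(genome_id = "G", key = c("f", "r"),
                      start = c(0L, 0L), end = c(6L, 6L),
                      strand = c("+", "-"), segments = NA_character_,
                      stringsAsFactors = FALSE)
  out <- extract_gene_sequences(feats, list(rec))
  expect_equal(out$seq, c("ATGAAA", "TTTCAT"))

  bad <- feats; bad$end <- 99L
  expect_error(extract_gene_sequences(bad, list(rec)), "outside sequence")
})

test_that("extracted fixture genes equal the generator's stored sequences", {
  run <- shared_run()
  proc <- read_table(run, "processed_genbank_df")
  genomes <- read_table(run, "genomes")
  records <- lapply(seq_len(nrow(genomes)), function(i) {
    list(genome_id = genomes$genome_id[i], sequence = genomes$sequence[i])
  })
  genes <- extract_gene_sequences(proc, records)
  truth <- run$man$genes
  idx <- match(paste(genes$genome_id, genes$key), paste(truth$genome_id, truth$key))
  expect_false(anyNA(idx))
  expect_equal(genes$seq, truth$seq[idx])
})

test_that("translation uses code 11, strips stops, honours qualifiers and flags defects", {
  g <- data.frame(genome_id = "G", key = c("a", "b", "c"),
                  seq = c("ATGAAATAA",        # MK + stop
                          "ATGTGATTTTAA",     # internal stop after M
                          "ATGGGA"),          # no stop at all
                  kind = "nucleotide", stringsAsFactors = FALSE)
  out <- translate_genes(g)
  expect_equal(out$seq, c("MK", "M", "MG"))
  expect_equal(out$internal_stop, c(FALSE, TRUE, FALSE))
  expect_true(all(out$kind == "protein"))

  # GenBank translation qualifier wins over recomputation
  feats <- data.frame(genome_id = "G", key = "a", translation = "MKLV",
                      stringsAsFactors = FALSE)
  out2 <- translate_genes(g[1, ], feats)
  expect_equal(out2$seq, "MKLV")

  offframe <- data.frame(genome_id = "G", key = "x", seq = "ATGAAAT",
                         kind = "nucleotide", stringsAsFactors = FALSE)
  expect_warning(out3 <- translate_genes(offframe), "codon boundary")
  expect_equal(out3$seq, "MK")

  expect_error(translate_genes(out), "nucleotide")
})

test_that("fixture translations match the generator manifest", {
  run <- shared_run()
  proc <- read_table(run, "processed_genbank_df")
  genomes <- read_table(run, "genomes")
  records <- lapply(seq_len(nrow(genomes)), function(i) {
    list(genome_id = genomes$genome_id[i], sequence = genomes$sequence[i])
  })
  prots <- translate_genes(extract_gene_sequences(proc, records), proc)
  truth <- run$man$genes
  idx <- match(paste(prots$genome_id, prots$key), paste(truth$genome_id, truth$key))
  expect_equal(prots$seq, truth$protein[idx])
})

test_that("identical genes hit at 100% identity in both directions; loners hit nothing", {
  set.seed(101)
  gene <- phagesynteny:::.random_gene(300L)
  loner <- phagesynteny:::.random_gene(150L)
  tab <- make_gene_table(A = c(g1 = gene, solo = loner), B = c(h1 = gene))
  hits <- all_vs_all(tab, "blastn", "builtin")
  ab <- hits[hits$query_genome == "A" & hits$query_key == "g1", ]
  ba <- hits[hits$query_genome == "B", ]
  expect_equal(ab$percent_identity, 100)
  expect_equal(ba$percent_identity, 100)
  expect_equal(nrow(hits[hits$query_key == "solo", ]), 0L)
})

test_that("mixed sequence kinds are refused", {
  tab <- make_gene_table(A = c(g = "ATGAAATAA"), B = c(h = "ATGAAATAA"))
  tab$kind[2] <- "protein"
  expect_error(all_vs_all(tab, "blastn", "builtin"), "kind")
})

test_that("best-hit summarisation keeps the maximal bitscore with deterministic tie-breaks", {
  base <- data.frame(query_genome = "A", query_key = "q", subject_genome = "B",
                     alignment_length = 100L, evalue = 1e-10,
                     stringsAsFactors = FALSE)
  hits <- rbind(cbind(base, subject_key = "s1", bitscore = 50),
                cbind(base, subject_key = "s2", bitscore = 75),
                cbind(base, subject_key = "s3", bitscore = 60))
  best <- summarize_best_hits(hits)
  expect_equal(nrow(best), 1L)
  expect_equal(best$subject_key, "s2")
  expect_equal(best$bitscore, 75)

  # exact tie on bitscore/length/evalue: lexicographically smaller key wins
  tie <- rbind(cbind(base, subject_key = "zeta", bitscore = 75),
               cbind(base, subject_key = "alpha", bitscore = 75))
  expect_equal(summarize_best_hits(tie)$subject_key, "alpha")

  # multiple HSPs for one gene pair collapse before per-genome selection
  hsp <- rbind(cbind(base, subject_key = "s1", bitscore = 80),
               cbind(base, subject_key = "s1", bitscore = 30))
  expect_equal(nrow(summarize_best_hits(hsp)), 1L)
  expect_equal(summarize_best_hits(hsp)$bitscore, 80)

  expect_equal(nrow(summarize_best_hits(hits[0, ])), 0L)
})

test_that("best-hit cardinality is bounded by genes x (genomes - 1)", {
  run <- shared_run()
  best <- read_table(run, "blastn_summary")
  n_genes <- nrow(run$man$genes)
  n_genomes <- length(run$man$genomes)
  expect_lte(nrow(best), n_genes * (n_genomes - 1L))
  expect_false(anyDuplicated(best[, c("query_genome", "query_key",
                                      "subject_genome")]) > 0)
})

test_that("byte-identical duplicated genomes give every gene a reciprocal 100% best hit", {
  spec <- fixture_spec(n_genomes = 2, n_core = 4, n_unique_per_genome = 0, seed = 11)
  dir <- tempfile()
  man <- generate_genome_set(spec, dir)
  rec <- parse_genbank(file.path(dir, paste0(man$genomes[1], ".gb")))
  dup <- rec
  dup$genome_id <- "SYNDUP"
  write_genbank(dup, file.path(dir, "SYNDUP.gb"))
  records <- read_genbank_dir(dir)[c(man$genomes[1], "SYNDUP")]
  proc <- resolve_keys(build_feature_table(records), lapply(records, validate_record))
  genes <- extract_gene_sequences(proc, records)
  best <- summarize_best_hits(all_vs_all(genes, "blastn", "builtin"))
  expect_equal(nrow(best), 2L * nrow(rec$features[rec$features$feature_type == "gene", ]))
  expect_true(all(best$percent_identity == 100))
})

test_that("builtin and external BLAST engines agree on hits and identities", {
  skip_if(Sys.which("blastn") == "", "BLAST+ not on PATH")
  run <- shared_run()
  proc <- read_table(run, "processed_genbank_df")
  genomes <- read_table(run, "genomes")
  records <- lapply(seq_len(nrow(genomes)), function(i) {
    list(genome_id = genomes$genome_id[i], sequence = genomes$sequence[i])
  })
  genes <- extract_gene_sequences(proc, records)
  best_b <- summarize_best_hits(all_vs_all(genes, "blastn", "builtin"))
  best_e <- summarize_best_hits(all_vs_all(genes, "blastn", "external"))
  pair <- function(b) sort(paste(b$query_genome, b$query_key, b$subject_genome))
  expect_equal(pair(best_e), pair(best_b))
  m <- merge(best_b, best_e,
             by = c("query_genome", "query_key", "subject_genome"),
             suffixes = c("_b", "_e"))
  expect_true(all(abs(m$percent_identity_b - m$percent_identity_e) <= 5))
})

test_that("repeated searches are deterministic", {
  set.seed(202)
  tab <- make_gene_table(
    A = c(g1 = phagesynteny:::.random_gene(150L), g2 = phagesynteny:::.random_gene(210L)),
    B = c(h1 = phagesynteny:::.random_gene(150L)))
  tab$seq[3] <- tab$seq[1]  # plant one homolog
  r1 <- summarize_best_hits(all_vs_all(tab, "blastn", "builtin"))
  r2 <- summarize_best_hits(all_vs_all(tab, "blastn", "builtin"))
  expect_identical(r1, r2)
})

test_that("protein search finds planted families under BLOSUM62", {
  run <- shared_run()
  proc <- read_table(run, "processed_genbank_df")
  genomes <- read_table(run, "genomes")
  records <- lapply(seq_len(nrow(genomes)), function(i) {
    list(genome_id = genomes$genome_id[i], sequence = genomes$sequence[i])
  })
  prots <- translate_genes(extract_gene_sequences(proc, records), proc)
  best <- summarize_best_hits(all_vs_all(prots, "blastp", "builtin"))
  core <- run$man$genes[!is.na(run$man$genes$family) &
                        grepl("^core", run$man$genes$family), ]
  for (i in seq_len(nrow(core))) {
    got <- best[best$query_genome == core$genome_id[i] &
                best$query_key == core$key[i], ]
    expect_equal(nrow(got), length(run$man$genomes) - 1L)
  }
})
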