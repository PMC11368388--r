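test_that("GenBank 1-based inclusive coordinates become 0-based half-open at parse", {
  p <- write_toy_gb(tempfile(fileext = ".gb"))
  rec <- parse_genbank(p)
  expect_s3_class(rec, "genome_record")
  expect_equal(rec$genome_id, "TST01")
  expect_equal(rec$length, 1200L)
  expect_equal(rec$features$start, c(0L, 400L, 800L))
  expect_equal(rec$features$end, c(300L, 700L, 1100L))
  expect_true(all(rec$features$strand == "+"))
  expect_equal(rec$features$locus_tag, c("cdsA", "cdsB", "cdsC"))
  expect_equal(rec$features$product[1], "first protein")
})

test_that("compound and complement locations collapse to flagged outer bounds", {
  lines <- toy_gb_lines("TST02")
  lines <- append(lines,
                  c("     CDS             complement(join(101..160,201..260))",
                    "                     /locus_tag=\"split\""),
                  after = grep("ORIGIN", lines) - 1L)
  p <- tempfile(fileext = ".gb")
  writeLines(lines, p)
  rec <- parse_genbank(p)
  row <- rec$features[rec$features$locus_tag == "split", ]
  expect_equal(row$start, 100L)
  expect_equal(row$end, 260L)
  expect_true(row$compound)
  expect_equal(row$strand, "-")
  expect_equal(row$segments, "100-160;200-260")
})

test_that("garbled and sequence-less files raise parse errors naming the path", {
  bad <- tempfile(fileext = ".gb")
  writeLines(c("this is", "not genbank"), bad)
  expect_error(parse_genbank(bad), "LOCUS")
  expect_error(parse_genbank(bad), basename(bad), fixed = TRUE)

  noseq <- tempfile(fileext = ".gb")
  lines <- toy_gb_lines("TST03")
  writeLines(lines[seq_len(grep("^ORIGIN", lines))], noseq)
  expect_error(parse_genbank(noseq), "no sequence")
})

test_that("a file lacking identifiers still parses; validation rejects it", {
  lines <- toy_gb_lines("TST04")
  lines <- lines[!grepl("locus_tag|product", lines)]
  p <- tempfile(fileext = ".gb")
  writeLines(lines, p)
  rec <- parse_genbank(p)
  expect_equal(nrow(rec$features), 3L)
  rep <- validate_record(rec)
  expect_equal(rep$routing, "rejected")
  expect_equal(rep$checks$status[rep$checks$check == "identifiers_present"], "fail")
})

test_that("fixture genomes reparse to the generator's ground truth", {
  run <- shared_run()
  man <- run$man
  for (gid in man$genomes) {
    rec <- parse_genbank(file.path(run$data_dir, "genbank", paste0(gid, ".gb")))
    genes <- rec$features[rec$features$feature_type == "gene", ]
    truth <- man$genes[man$genes$genome_id == gid, ]
    expect_equal(nrow(genes), nrow(truth))
    expect_equal(genes$start, truth$start)
    expect_equal(genes$end, truth$end)
    expect_equal(genes$strand, truth$strand)
    expect_equal(genes$locus_tag, truth$key)
  }
})

test_that("coordinate conversion round-trips through the writer for all fixture genomes", {
  run <- shared_run()
  for (gid in run$man$genomes) {
    src <- file.path(run$data_dir, "genbank", paste0(gid, ".gb"))
    rec <- parse_genbank(src)
    out <- tempfile(fileext = ".gb")
    write_genbank(rec, out)
    rec2 <- parse_genbank(out)
    expect_equal(rec2$features$start, rec$features$start)
    expect_equal(rec2$features$end, rec$features$end)
    expect_equal(rec2$features$strand, rec$features$strand)
    expect_equal(rec2$sequence, rec$sequence)
    # simple locations re-serialise to the source file's location strings
    src_locs <- grep("^     (gene|CDS) ", readLines(src), value = TRUE)
    out_locs <- grep("^     (gene|CDS) ", readLines(out), value = TRUE)
    expect_equal(trimws(out_locs), trimws(src_locs))
  }
})

test_that("validation is total and routes gene+CDS, CDS-only and broken files", {
  run <- shared_run()
  rec <- parse_genbank(file.path(run$data_dir, "genbank",
                                 paste0(run$man$genomes[1], ".gb")))
  rep <- validate_record(rec)
  expect_true(all(rep$checks$status == "pass"))
  expect_equal(rep$routing, "gene_and_cds")

  # CDS-only variant of the same genome: protein_id becomes the identifier
  cds_only <- rec
  cds_only$features <- rec$features[rec$features$feature_type == "CDS", ]
  rep2 <- validate_record(cds_only)
  expect_equal(rep2$routing, "cds_only")

  # duplicate locus_tags are named in the failure detail
  dup <- rec
  dup$features$locus_tag[dup$features$feature_type == "gene"] <- "same"
  rep3 <- validate_record(dup)
  expect_equal(rep3$routing, "rejected")
  expect_match(rep3$checks$detail[rep3$checks$check == "identifiers_unique"], "same")

  # degenerate records still produce a report rather than an error
  empty <- structure(list(genome_id = "E1", sequence = "",
                          features = rec$features[0, ]),
                     class = "genome_record")
  expect_no_error(rep4 <- validate_record(empty))
  expect_equal(rep4$routing, "rejected")
})

test_that("build_feature_table concatenates all genomes and rejects empty input", {
  run <- shared_run()
  records <- read_genbank_dir(file.path(run$data_dir, "genbank"))
  tab <- build_feature_table(records)
  expect_equal(nrow(tab), sum(vapply(records, function(r) nrow(r$features), 0L)))
  per_genome <- table(tab$genome_id[tab$feature_type == "gene"])
  truth <- table(run$man$genes$genome_id)
  expect_equal(as.vector(per_genome[names(truth)]), as.vector(truth))
  expect_error(build_feature_table(list()), "no genomes loaded")
})

test_that("key resolution follows routing: locus_tag for gene+CDS, protein_id for CDS-only", {
  run <- shared_run()
  records <- read_genbank_dir(file.path(run$data_dir, "genbank"))
  reports <- lapply(records, validate_record)
  tab <- build_feature_table(records)
  proc <- resolve_keys(tab, reports)
  expect_true(all(proc$key_source == "locus_tag"))
  expect_equal(sort(proc$key[proc$genome_id == run$man$genomes[1]]),
               sort(run$man$genes$key[run$man$genes$genome_id == run$man$genomes[1]]))
  expect_false(anyDuplicated(proc[, c("genome_id", "key")]) > 0)
  # gene rows inherit protein_id/product/translation from their CDS partner
  expect_true(all(!is.na(proc$translation)))
  expect_true(all(!is.na(proc$protein_id)))

  # CDS-only genome: protein_id becomes the key
  cds_recs <- lapply(records, function(r) {
    r$features <- r$features[r$features$feature_type == "CDS", ]
    r
  })
  cds_reports <- lapply(cds_recs, validate_record)
  proc2 <- resolve_keys(build_feature_table(cds_recs), cds_reports)
  expect_true(all(proc2$key_source == "protein_id"))
  expect_true(all(grepl("^P\\d+_\\d+\\.1$", proc2$key)))

  # a rejected genome in the input violates the contract
  broken <- records[[1]]
  broken$features$locus_tag <- NA_character_
  broken$features$protein_id <- NA_character_
  broken$features$gene_name <- NA_character_
  rep_bad <- validate_record(broken)
  expect_error(resolve_keys(build_feature_table(list(broken)), list(rep_bad)),
               "rejected")
})
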