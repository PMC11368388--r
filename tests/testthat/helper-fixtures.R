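# Shared fixture machinery: every test input is generated in code at run
# time; nothing binary is stored in the repository.

# a small handcrafted GenBank text, written independently of write_genbank(),
# so the parser is exercised against a file our own writer did not produce
toy_gb_lines <- function(id = "TST01") {
  seqlen <- 1200L
  seq <- paste(rep("acgtacgtac", seqlen / 10), collapse = "")
  origin <- vapply(seq(1L, seqlen, 60L), function(p) {
    chunk <- substr(seq, p, p + 59L)
    blocks <- substring(chunk, seq(1, 60, 10), seq(10, 60, 10))
    sprintf("%9d %s", p, paste(blocks, collapse = " "))
  }, "")
  c(sprintf("LOCUS       %s               1200 bp    DNA     linear   PHG 01-JAN-2024", id),
    "DEFINITION  handcrafted test phage",
    sprintf("ACCESSION   %s", id),
    "FEATURES             Location/Qualifiers",
    "     source          1..1200",
    "     CDS             1..300",
    "                     /locus_tag=\"cdsA\"",
    "                     /product=\"first protein\"",
    "     CDS             401..700",
    "                     /locus_tag=\"cdsB\"",
    "     CDS             801..1100",
    "                     /locus_tag=\"cdsC\"",
    "ORIGIN",
    origin,
    "//")
}

write_toy_gb <- function(path, id = "TST01") {
  writeLines(toy_gb_lines(id), path)
  path
}

# standard study fixture: 3 core families in all genomes, a 2-gene block
# over the first half of the genomes at the given identity, 1 unique gene
# per genome
study_spec <- function(n, seed, identity = 85) {
  fixture_spec(
    n_genomes = n, n_core = 3L,
    shared_blocks = list(list(n_genes = 2L, genomes = seq_len(ceiling(n / 2)),
                              identity = identity)),
    n_unique_per_genome = 1L, seed = seed)
}

# generate + validate + blastn(builtin) in a temp data dir
run_study_pipeline <- function(spec, data_dir = tempfile("study")) {
  man <- generate_genome_set(spec, file.path(data_dir, "genbank"))
  cfg <- run_config(data_dir = data_dir)
  stopifnot(cmd_validate(cfg) == 0L, cmd_blast(cfg, "blastn") == 0L)
  list(man = man, cfg = cfg,
       tables = file.path(data_dir, "tables"), data_dir = data_dir)
}

read_table <- function(run, name) {
  as.data.frame(arrow::read_parquet(file.path(run$tables, paste0(name, ".parquet"))))
}

# one shared n=4 pipeline run reused across test files (built once per session)
.shared_cache <- new.env(parent = emptyenv())
shared_run <- function() {
  if (is.null(.shared_cache$run)) {
    .shared_cache$run <- run_study_pipeline(study_spec(4L, seed = 42L))
  }
  .shared_cache$run
}

# mock Entrez transports ----------------------------------------------------

mock_search_transport <- function(ids) {
  function(url) {
    stopifnot(grepl("esearch", url))
    paste0("<eSearchResult><Count>", length(ids), "</Count>",
           paste0("<Id>", ids, "</Id>", collapse = ""), "</eSearchResult>")
  }
}

mock_fetch_transport <- function(records, log = NULL) {
  # records: named list accession -> genbank text
  function(url) {
    if (!is.null(log)) log$urls <- c(log$urls, url)
    id <- sub(".*[&?]id=([^&]+).*", "\\1", url)
    id <- utils::URLdecode(id)
    if (!id %in% names(records)) stop("unknown accession: ", id)
    records[[id]]
  }
}
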