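svg_count <- function(path, xpath) {
  doc <- xml2::read_xml(path)
  length(xml2::xml_find_all(doc, xpath))
}

test_that("cross-links exist only between adjacent tracks and honour the threshold", {
  best <- data.frame(
    query_genome = c("A", "A", "B", "A"),
    query_key = c("a1", "a2", "b1", "a3"),
    subject_genome = c("B", "C", "C", "B"),
    subject_key = c("b1", "c2", "c1", "b3"),
    percent_identity = c(95, 88, 70, 40),
    alignment_length = 100L, bitscore = 200, evalue = 1e-20,
    stringsAsFactors = FALSE)
  sel <- sequence_selection(c("A", "B", "C"))
  links <- compute_cross_links(best, sel)
  # a2 -> C is non-adjacent to A and must not link; b1 -> c1 links B|C
  expect_setequal(paste(links$upper_genome, links$upper_key, links$lower_key),
                  c("A a1 b1", "A a3 b3", "B b1 c1"))
  # reciprocal hits collapse to one link per unordered gene pair
  recip <- rbind(best[1, ],
                 data.frame(query_genome = "B", query_key = "b1",
                            subject_genome = "A", subject_key = "a1",
                            percent_identity = 94, alignment_length = 100L,
                            bitscore = 200, evalue = 1e-20))
  l2 <- compute_cross_links(recip, sequence_selection(c("A", "B")))
  expect_equal(nrow(l2), 1L)
  expect_equal(l2$percent_identity, 95)

  l3 <- compute_cross_links(best, sel, min_link_identity = 80)
  expect_true(all(l3$percent_identity >= 80))
  expect_equal(paste(l3$upper_key, l3$lower_key), "a1 b1")
})

test_that("fixture genes shared only between non-adjacent tracks yield zero links", {
  run <- shared_run()
  best <- read_table(run, "blastn_summary")
  # order the two block genomes first and last so their block genes are
  # never adjacent to each other
  blk <- run$man$genes[!is.na(run$man$genes$family) &
                       grepl("^blk", run$man$genes$family), ]
  gA <- run$man$genomes[1]; gB <- run$man$genomes[2]
  others <- setdiff(run$man$genomes, c(gA, gB))
  sel <- sequence_selection(c(gA, others, gB))
  links <- compute_cross_links(best, sel)
  blk_of_A <- blk$key[blk$genome_id == gA]
  blk_of_B <- blk$key[blk$genome_id == gB]
  # no link may join a block gene of A to a block gene of B (non-adjacent),
  # and A's block genes link nowhere since only B shares them
  expect_false(any(links$upper_genome == gA & links$upper_key %in% blk_of_A))
  expect_false(any(links$lower_genome == gB & links$lower_key %in% blk_of_B &
                   links$upper_genome == gA))
})

test_that("the rendered SVG has the stated structure and re-renders byte-identically", {
  skip_if_not_installed("xml2")
  run <- shared_run()
  uniq <- read_table(run, "gene_uniqueness")
  best <- read_table(run, "blastn_summary")
  proc <- read_table(run, "processed_genbank_df")
  sel <- sequence_selection(run$man$genomes)
  ct <- compute_colour_table(uniq, sel)
  links <- compute_cross_links(best, sel)
  cfg <- plot_config(output_formats = "svg")
  out1 <- tempfile(); out2 <- tempfile()
  render_synteny(proc, ct, links, sel, cfg, out1)
  render_synteny(proc, ct, links, sel, cfg, out2)
  svg1 <- paste0(out1, ".svg")
  expect_equal(svg_count(svg1, "//*[@class='track']"), length(sel$genome_id))
  expect_equal(svg_count(svg1, "//*[@class='gene']"), nrow(proc))
  expect_equal(svg_count(svg1, "//*[@class='cross-link']"), nrow(links))
  doc <- xml2::read_xml(svg1)
  for (i in seq_along(sel$genome_id)) {
    trk <- xml2::xml_find_first(doc, sprintf("//*[@id='track-%d']", i))
    n_glyphs <- length(xml2::xml_find_all(trk, ".//*[@class='gene']"))
    expect_equal(n_glyphs, sum(proc$genome_id == sel$genome_id[i]))
  }
  expect_identical(tools::md5sum(svg1)[[1]], tools::md5sum(paste0(out2, ".svg"))[[1]])
})

test_that("reverse-oriented genomes are mirrored coordinate-wise", {
  run <- shared_run()
  uniq <- read_table(run, "gene_uniqueness")
  proc <- read_table(run, "processed_genbank_df")
  sel_f <- sequence_selection(run$man$genomes[1:2], c("forward", "forward"))
  sel_r <- sequence_selection(run$man$genomes[1:2], c("forward", "reverse"))
  ct <- compute_colour_table(uniq, sel_f)
  cfg <- plot_config(output_formats = "svg")
  links0 <- compute_cross_links(read_table(run, "blastn_summary")[0, ], sel_f)
  out_f <- tempfile(); out_r <- tempfile()
  render_synteny(proc, ct, links0, sel_f, cfg, out_f)
  render_synteny(proc, ct, links0, sel_r, cfg, out_r)
  gx <- function(path, track) {
    doc <- xml2::read_xml(path)
    trk <- xml2::xml_find_first(doc, sprintf("//*[@id='track-%d']", track))
    glyphs <- xml2::xml_find_all(trk, ".//*[@class='gene']")
    lapply(xml2::xml_attr(glyphs, "points"), function(p) {
      pts <- do.call(rbind, lapply(strsplit(strsplit(p, " ")[[1]], ","), as.numeric))
      range(pts[, 1])
    })
  }
  fwd <- gx(paste0(out_f, ".svg"), 2L)
  mir <- gx(paste0(out_r, ".svg"), 2L)
  g2 <- proc[proc$genome_id == run$man$genomes[2], ]
  g2 <- g2[order(g2$start), ]
  L <- g2$genome_length[1]
  margin <- 150; plot_w <- 1180 - 150 - 30
  lens <- tapply(proc$genome_length[proc$genome_id %in% run$man$genomes[1:2]],
                 proc$genome_id[proc$genome_id %in% run$man$genomes[1:2]], max)
  ppb <- plot_w / max(lens)
  for (j in seq_len(nrow(g2))) {
    exp_x <- sort(margin + c(L - g2$end[j], L - g2$start[j]) * ppb)
    expect_equal(mir[[j]], exp_x, tolerance = 0.02)
    # and the mirror of the mirror is the forward position
    mirrored_back <- sort(2 * margin + (L * ppb) - mir[[j]])
    expect_equal(mirrored_back, fwd[[j]], tolerance = 0.02)
  }
})

test_that("palette changes restyle fills without moving geometry", {
  run <- shared_run()
  uniq <- read_table(run, "gene_uniqueness")
  proc <- read_table(run, "processed_genbank_df")
  best <- read_table(run, "blastn_summary")
  sel <- sequence_selection(run$man$genomes)
  links <- compute_cross_links(best, sel)
  pal2 <- c("#FFFFFF", "#FF0000", "#000000")
  ct1 <- compute_colour_table(uniq, sel)
  ct2 <- compute_colour_table(uniq, sel, pal2)
  o1 <- tempfile(); o2 <- tempfile()
  cfg1 <- plot_config(output_formats = "svg")
  cfg2 <- plot_config(output_formats = "svg", palette = pal2)
  render_synteny(proc, ct1, links, sel, cfg1, o1)
  render_synteny(proc, ct2, links, sel, cfg2, o2)
  strip_fill <- function(p) gsub("fill=\"[^\"]*\"", "", readLines(paste0(p, ".svg")))
  expect_identical(strip_fill(o1), strip_fill(o2))
  expect_false(identical(readLines(paste0(o1, ".svg")), readLines(paste0(o2, ".svg"))))
})

test_that("plot_job renders from existing tables and renders even without links", {
  run <- shared_run()
  sel <- sequence_selection(run$man$genomes[1:2])
  res <- plot_job(run$data_dir, sel, "blastn",
                  plot_config(output_formats = c("svg", "png"), title = "fixture set"),
                  out_base = tempfile())
  expect_true(file.exists(res$plot_paths[["svg"]]))
  expect_true(file.exists(res$plot_paths[["png"]]))
  expect_gt(file.size(res$plot_paths[["png"]]), 0)
  expect_true(file.exists(res$colour_table_path))

  # a selection whose genomes share nothing draws no links but still renders
  uniq <- read_table(run, "gene_uniqueness")
  proc <- read_table(run, "processed_genbank_df")
  ct <- compute_colour_table(uniq, sel)
  empty_links <- compute_cross_links(read_table(run, "blastn_summary")[0, ], sel)
  expect_no_error(render_synteny(proc, ct, empty_links, sel,
                                 plot_config(output_formats = "svg"), tempfile()))

  expect_error(plot_job(tempfile(), sel, "blastn"), "validate")
  expect_error(plot_job(run$data_dir, sequence_selection(run$man$genomes[1:2]),
                        "blastp"),
               "blastp")
})

test_that("selection CSVs round-trip order and orientation", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("sequence,orientation", "G2,1", "G1,0"), p)
  sel <- read_selection(p)
  expect_equal(sel$genome_id, c("G2", "G1"))
  expect_equal(sel$orientation, c("forward", "reverse"))
  expect_error(sequence_selection(c("A", "A")), "duplicate")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("genome,flip", "G1,1"), bad)
  expect_error(read_selection(bad), "sequence")
})
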