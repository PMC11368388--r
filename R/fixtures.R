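#' Specification for a synthetic genome set
#'
#' Describes a set of genomes with planted homology: a core of gene
#' families present in every genome, optional shared blocks present in a
#' stated genome subset at a controlled percent identity, and
#' genome-unique genes guaranteed to share no detectable similarity with
#' any other genome. Generation is fully deterministic given `seed`.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param n_core Core gene families present in every genome.
#' @param shared_blocks List of blocks, each
#'   `list(n_genes =, genomes =, identity =)` where `genomes` are genome
#'   indices and `identity` is the planted percent identity in (50, 100].
#' @param n_unique_per_genome Unique genes planted per genome.
#' @param gene_length_range `(min, max)` gene length in bp; lengths are
#'   rounded to codon multiples.
#' @param intergenic_range `(min, max)` spacer length in bp.
#' @param seed Integer RNG seed.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_genomes, n_core = 3L, shared_blocks = list(),
                         n_unique_per_genome = 1L,
                         gene_length_range = c(120L, 300L),
                         intergenic_range = c(20L, 80L), seed = 1L) {
  stopifnot(n_genomes >= 2L, n_core >= 0L, n_unique_per_genome >= 0L,
            length(gene_length_range) == 2L, gene_length_range[1L] >= 30L,
            gene_length_range[1L] <= gene_length_range[2L],
            intergenic_range[1L] >= 0L,
            intergenic_range[1L] <= intergenic_range[2L])
  for (b in shared_blocks) {
    stopifnot(is.list(b), b$n_genes >= 1L, length(b$genomes) >= 2L,
              all(b$genomes >= 1L & b$genomes <= n_genomes),
              b$identity > 50, b$identity <= 100)
  }
  structure(list(n_genomes = as.integer(n_genomes), n_core = as.integer(n_core),
                 shared_blocks = shared_blocks,
                 n_unique_per_genome = as.integer(n_unique_per_genome),
                 gene_length_range = as.integer(gene_length_range),
                 intergenic_range = as.integer(intergenic_range),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.STOPS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

# sample() without the length-1 "1:n" surprise
.pick <- function(x, n = 1L) x[sample.int(length(x), n)]
.shuffle <- function(x) x[sample.int(length(x))]

.random_codons <- function(n) {
  if (n <= 0L) return(character(0))
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cdn <- paste(sample(.BASES, 3L, replace = TRUE), collapse = "")
      if (!(cdn %in% .STOPS)) break
    }
    out[i] <- cdn
  }
  out
}

.random_gene <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  paste0("ATG", paste(.random_codons(len / 3L - 2L), collapse = ""), "TAA")
}

# Mutate a gene to a target percent identity by point substitutions at
# codon position 3 preferentially (then 1, then 2), never creating an
# in-frame stop or touching the start/stop codons.
.mutate_to_identity <- function(seq, identity) {
  L <- nchar(seq)
  n_mut <- round((1 - identity / 100) * L)
  if (n_mut == 0L) return(seq)
  n_codons <- L / 3L
  interior <- seq(2L, n_codons - 1L)
  cand <- c(.shuffle((interior - 1L) * 3L + 3L),
            .shuffle((interior - 1L) * 3L + 1L),
            .shuffle((interior - 1L) * 3L + 2L))
  if (n_mut > length(cand)) {
    stop("cannot plant ", n_mut, " mutations in a ", L, " bp gene", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1L]]
  done <- 0L
  for (pos in cand) {
    if (done >= n_mut) break
    codon_i <- (pos - 1L) %/% 3L
    old <- chars[pos]
    alts <- .shuffle(setdiff(.BASES, old))
    for (alt in alts) {
      trial <- chars
      trial[pos] <- alt
      cdn <- paste(trial[codon_i * 3L + 1:3], collapse = "")
      if (!(cdn %in% .STOPS)) {
        chars <- trial
        done <- done + 1L
        break
      }
    }
  }
  if (done < n_mut) stop("could not place all planted mutations", call. = FALSE)
  paste(chars, collapse = "")
}

.kmers <- function(seq, k = 11L) {
  if (nchar(seq) < k) return(character(0))
  s <- c(seq, as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq))))
  unique(unlist(lapply(s, function(x) {
    substring(x, seq_len(nchar(x) - k + 1L), k:nchar(x))
  })))
}

#' Generate a GenBank genome set with a known homology manifest
#'
#' Emits one GenBank file per genome (gene + CDS features, locus tags
#' `G<i>_<j>`, protein ids and translations) plus a JSON manifest that is
#' the exact ground truth for every downstream stage. Each gene family has
#' a reference copy in its first member genome; the other members carry a
#' variant mutated to the block's target identity (mutation count
#' `round((1 - identity) x length)`, codon position 3 preferred, no
#' in-frame stops), so every within-family pairwise identity is at least
#' the planted value. Unique genes are random sequences rejected until
#' they share no 11-bp exact match, on either strand, with any other
#' genome's genes.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Directory for the GenBank files and `manifest.json`.
#' @return A `fixture_manifest`: list with `genes` (data.frame of per-gene
#'   ground truth incl. planted identity and family), `genomes`, and the
#'   echoed `spec`.
#' @export
generate_genome_set <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  n <- spec$n_genomes
  genome_ids <- sprintf("SYN%02d", seq_len(n))

  rand_len <- function() {
    L <- .pick(seq(spec$gene_length_range[1L], spec$gene_length_range[2L]))
    max(9L, (L %/% 3L) * 3L)
  }

  # family table: one reference sequence per family, then per-member variants
  fams <- list()
  for (i in seq_len(max(0L, spec$n_core))) {
    fams[[length(fams) + 1L]] <- list(id = sprintf("core%02d", i),
                                      members = seq_len(n), identity = 100)
  }
  for (bi in seq_along(spec$shared_blocks)) {
    b <- spec$shared_blocks[[bi]]
    for (gi in seq_len(b$n_genes)) {
      fams[[length(fams) + 1L]] <- list(id = sprintf("blk%02d_%02d", bi, gi),
                                        members = sort(unique(as.integer(b$genomes))),
                                        identity = b$identity)
    }
  }

  # member sequences: reference in the first member, one mutated variant in
  # the rest (keeps all pairwise within-family identities >= the target)
  fam_seqs <- list()
  for (f in fams) {
    ref <- .random_gene(rand_len())
    variant <- if (f$identity < 100) .mutate_to_identity(ref, f$identity) else ref
    seqs <- stats::setNames(
      c(list(ref), rep(list(variant), length(f$members) - 1L)),
      as.character(f$members))
    fam_seqs[[f$id]] <- seqs
  }

  # per-genome gene lists (family genes first, unique genes appended)
  genes_of <- rep(list(list()), n)
  for (f in fams) {
    for (m in f$members) {
      genes_of[[m]][[length(genes_of[[m]]) + 1L]] <- list(
        family = f$id, seq = fam_seqs[[f$id]][[as.character(m)]],
        identity = if (m == f$members[1L]) 100 else f$identity,
        is_unique = FALSE)
    }
  }

  # unique genes: screened against every other genome's 11-mers
  if (spec$n_unique_per_genome > 0L) {
    kmer_pool <- lapply(seq_len(n), function(m) {
      unique(unlist(lapply(genes_of[[m]], function(g) .kmers(g$seq))))
    })
    for (m in seq_len(n)) {
      for (u in seq_len(spec$n_unique_per_genome)) {
        other <- unique(unlist(kmer_pool[-m]))
        ok <- FALSE
        for (try in seq_len(200L)) {
          cand <- .random_gene(rand_len())
          if (!any(.kmers(cand) %in% other)) { ok <- TRUE; break }
        }
        if (!ok) stop("could not generate a screened unique gene", call. = FALSE)
        genes_of[[m]][[length(genes_of[[m]]) + 1L]] <- list(
          family = NA_character_, seq = cand, identity = NA_real_, is_unique = TRUE)
        kmer_pool[[m]] <- unique(c(kmer_pool[[m]], .kmers(cand)))
      }
    }
  }

  # assemble genomes and write GenBank files
  rows <- list()
  for (m in seq_len(n)) {
    gid <- genome_ids[m]
    glist <- genes_of[[m]]
    spacer <- function() {
      k <- .pick(seq(spec$intergenic_range[1L], spec$intergenic_range[2L]))
      paste(sample(.BASES, k, replace = TRUE), collapse = "")
    }
    seq_parts <- list(spacer())
    cursor <- nchar(seq_parts[[1L]])
    feats <- list()
    for (j in seq_along(glist)) {
      g <- glist[[j]]
      strand <- .pick(c("+", "-"))
      placed <- if (strand == "+") g$seq else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$seq)))
      start0 <- cursor
      end0 <- cursor + nchar(g$seq)
      key <- sprintf("G%d_%d", m, j)
      prot <- sub("\\*$", "", as.character(Biostrings::translate(
        Biostrings::DNAString(g$seq), genetic.code = Biostrings::getGeneticCode("11"))))
      product <- if (g$is_unique) "hypothetical protein" else
        sprintf("%s family protein", g$family)
      base <- data.frame(
        genome_id = gid, locus_tag = key, gene_name = NA_character_,
        protein_id = NA_character_, product = NA_character_,
        start = start0, end = end0, strand = strand,
        translation = NA_character_, stringsAsFactors = FALSE)
      gene_row <- base; gene_row$feature_type <- "gene"
      cds_row <- base; cds_row$feature_type <- "CDS"
      cds_row$protein_id <- sprintf("P%d_%d.1", m, j)
      cds_row$product <- product
      cds_row$translation <- prot
      feats[[length(feats) + 1L]] <- gene_row
      feats[[length(feats) + 1L]] <- cds_row
      seq_parts[[length(seq_parts) + 1L]] <- placed
      sp <- spacer()
      seq_parts[[length(seq_parts) + 1L]] <- sp
      cursor <- end0 + nchar(sp)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid, key = key, family = g$family,
        start = start0, end = end0, strand = strand, length = nchar(g$seq),
        planted_identity = g$identity, is_unique = g$is_unique,
        seq = g$seq, protein = prot, stringsAsFactors = FALSE)
    }
    ft <- do.call(rbind, feats)
    record <- list(genome_id = gid,
                   description = sprintf("synthetic phage genome %s", gid),
                   sequence = paste(unlist(seq_parts), collapse = ""),
                   features = ft)
    write_genbank(record, file.path(out_dir, paste0(gid, ".gb")))
  }

  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  manifest <- structure(list(genes = genes, genomes = genome_ids,
                             spec = unclass(spec)),
                        class = "fixture_manifest")
  jsonlite::write_json(list(genomes = genome_ids, spec = unclass(spec),
                            genes = genes),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Brute-force expected conservation from a fixture manifest
#'
#' The independent oracle for the conservation metrics: for every gene of
#' every selected genome, counts the other selected genomes containing a
#' member of the same planted family (unique genes count 0), directly from
#' the manifest, without touching the alignment pipeline.
#'
#' @param manifest A `fixture_manifest` from [generate_genome_set()].
#' @param selection A [sequence_selection()] (or character vector of
#'   genome ids).
#' @return data.frame: `genome_id`, `key`, `expected_match_count`.
#' @export
expected_conservation <- function(manifest, selection) {
  sel <- if (inherits(selection, "sequence_selection")) selection$genome_id else selection
  stopifnot(all(sel %in% manifest$genomes))
  g <- manifest$genes[manifest$genes$genome_id %in% sel, , drop = FALSE]
  counts <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    if (is.na(g$family[i])) { counts[i] <- 0L; next }
    counts[i] <- length(unique(g$genome_id[g$family == g$family[i] &
                                           g$genome_id != g$genome_id[i] &
                                           !is.na(g$family)]))
  }
  out <- data.frame(genome_id = g$genome_id, key = g$key,
                    expected_match_count = counts, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
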