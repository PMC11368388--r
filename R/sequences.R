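#' Extract the nucleotide sequence of every gene
#'
#' Slices each processed feature out of its genome. Compound locations use
#' their exact exon segments (concatenated in genomic order); minus-strand
#' features are reverse-complemented, so every returned sequence reads
#' 5'→3' in gene orientation.
#'
#' @param features Processed feature table from [resolve_keys()].
#' @param records List of `genome_record`s covering every genome in
#'   `features`.
#' @return data.frame of gene sequences: `genome_id`, `key`, `seq`,
#'   `kind = "nucleotide"`.
#' @export
extract_gene_sequences <- function(features, records) {
  seqs <- vapply(records, `[[`, "", "sequence")
  names(seqs) <- vapply(records, `[[`, "", "genome_id")
  missing <- setdiff(unique(features$genome_id), names(seqs))
  if (length(missing)) {
    stop("no genome record for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out_seq <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    g <- features$genome_id[i]
    genome <- seqs[[g]]
    segs <- .parse_segments(features$segments[i], features$start[i], features$end[i])
    if (any(segs[, 1L] < 0L) || any(segs[, 2L] > nchar(genome))) {
      stop("feature interval outside sequence in ", g, " for key ",
           features$key[i], call. = FALSE)
    }
    s <- paste(substring(genome, segs[, 1L] + 1L, segs[, 2L]), collapse = "")
    if (identical(features$strand[i], "-")) {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    out_seq[i] <- s
  }
  data.frame(genome_id = features$genome_id, key = features$key,
             seq = out_seq, kind = "nucleotide", stringsAsFactors = FALSE)
}

.parse_segments <- function(segments, start, end) {
  if (is.na(segments) || !nzchar(segments)) return(cbind(start, end))
  parts <- strsplit(segments, ";", fixed = TRUE)[[1L]]
  do.call(rbind, lapply(parts, function(p) as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])))
}

#' Translate gene sequences to proteins
#'
#' Translates nucleotide gene sequences with the bacterial/plastid genetic
#' code (translation table 11). When the processed feature carries a
#' `translation` qualifier from the GenBank file, that translation takes
#' precedence over recomputation. A trailing stop is removed; an internal
#' stop truncates the protein at the stop with a flag; a length not
#' divisible by 3 is truncated to the codon boundary with a warning.
#'
#' @param genes Gene-sequence table from [extract_gene_sequences()].
#' @param features Optional processed feature table supplying `translation`
#'   qualifiers (matched on genome_id and key).
#' @return data.frame: `genome_id`, `key`, `seq` (amino acids),
#'   `kind = "protein"`, `internal_stop` flag.
#' @export
translate_genes <- function(genes, features = NULL) {
  if (!all(genes$kind == "nucleotide")) {
    stop("translate_genes expects nucleotide input", call. = FALSE)
  }
  qual <- rep(NA_character_, nrow(genes))
  if (!is.null(features) && "translation" %in% names(features)) {
    idx <- match(paste(genes$genome_id, genes$key, sep = "\r"),
                 paste(features$genome_id, features$key, sep = "\r"))
    qual <- features$translation[idx]
  }
  aa <- character(nrow(genes))
  internal_stop <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (!is.na(qual[i]) && nzchar(qual[i])) {
      aa[i] <- sub("\\*$", "", qual[i])
      next
    }
    nt <- genes$seq[i]
    if (nchar(nt) %% 3L != 0L) {
      warning("gene ", genes$genome_id[i], "/", genes$key[i],
              " length not divisible by 3; truncating to codon boundary")
      nt <- substr(nt, 1L, nchar(nt) - nchar(nt) %% 3L)
    }
    p <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt),
      genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "solve"))
    p <- sub("\\*$", "", p)
    stop_at <- regexpr("*", p, fixed = TRUE)
    if (stop_at > 0L) {
      internal_stop[i] <- TRUE
      p <- substr(p, 1L, stop_at - 1L)
    }
    aa[i] <- p
  }
  data.frame(genome_id = genes$genome_id, key = genes$key, seq = aa,
             kind = "protein", internal_stop = internal_stop,
             stringsAsFactors = FALSE)
}
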