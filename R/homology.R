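#' All-vs-all gene homology search
#'
#' Searches every gene (or protein) against the gene set of every *other*
#' genome; self-genome comparisons are excluded at search time, so a gene
#' with no hits is unique relative to all other genomes. Two engines are
#' available behind the same contract:
#'
#' \describe{
#'   \item{builtin}{global Needleman-Wunsch alignment via
#'     \pkg{Biostrings}: match +2 / mismatch -3, gap open 5 / extend 2 for
#'     nucleotides; BLOSUM62 with gap open 11 / extend 1 for proteins. The
#'     reported `bitscore` is the raw alignment score and the e-value is a
#'     Karlin-Altschul approximation from that score (blastn-gapped
#'     lambda = 0.625, K = 0.41; BLOSUM62-gapped lambda = 0.267,
#'     K = 0.041).}
#'   \item{external}{BLAST+ (`makeblastdb` + `blastn`/`blastp`,
#'     tabular `-outfmt 6`), the production engine when the binaries are
#'     installed.}
#' }
#'
#' Hits with e-value above `evalue_max` are discarded. Percent identity
#' follows the BLAST convention: matches / alignment length x 100.
#'
#' @param queries Gene-sequence table ([extract_gene_sequences()] or
#'   [translate_genes()]); all rows must share the kind matching `mode`.
#' @param mode `"blastn"` (nucleotide) or `"blastp"` (protein).
#' @param engine `"builtin"` or `"external"`.
#' @param evalue_max Retention threshold on the e-value (default `1e-3`).
#' @param work_dir Scratch directory for the external engine's FASTA/DB
#'   files (default a session temp dir).
#' @return data.frame of raw hits: `query_genome`, `query_key`,
#'   `subject_genome`, `subject_key`, `percent_identity`,
#'   `alignment_length`, `bitscore`, `evalue`.
#' @export
all_vs_all <- function(queries, mode = c("blastn", "blastp"),
                       engine = c("builtin", "external"),
                       evalue_max = 1e-3, work_dir = tempfile("homology")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  want_kind <- if (mode == "blastn") "nucleotide" else "protein"
  if (nrow(queries) && !all(queries$kind == want_kind)) {
    stop("mode ", mode, " requires ", want_kind, " sequences; got mixed or wrong kind",
         call. = FALSE)
  }
  if (nrow(queries) < 2L || length(unique(queries$genome_id)) < 2L) {
    return(.empty_rawhits())
  }
  if (engine == "builtin") {
    .all_vs_all_builtin(queries, mode, evalue_max)
  } else {
    .all_vs_all_external(queries, mode, evalue_max, work_dir)
  }
}

.empty_rawhits <- function() {
  data.frame(query_genome = character(0), query_key = character(0),
             subject_genome = character(0), subject_key = character(0),
             percent_identity = numeric(0), alignment_length = integer(0),
             bitscore = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

.ka_params <- function(mode) {
  if (mode == "blastn") list(lambda = 0.625, K = 0.41) else list(lambda = 0.267, K = 0.041)
}

.all_vs_all_builtin <- function(queries, mode, evalue_max) {
  ka <- .ka_params(mode)
  if (mode == "blastn") {
    set <- Biostrings::DNAStringSet(queries$seq)
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
    go <- 5; ge <- 2
  } else {
    set <- Biostrings::AAStringSet(queries$seq)
    submat <- "BLOSUM62"
    go <- 11; ge <- 1
  }
  names(set) <- paste(queries$genome_id, queries$key, sep = "|")
  db_len <- sum(nchar(queries$seq))

  # every cross-genome (query, subject) gene pair, aligned elementwise in
  # chunks (one C call per chunk keeps the R overhead negligible)
  pairs <- expand.grid(q = seq_len(nrow(queries)), s = seq_len(nrow(queries)))
  pairs <- pairs[queries$genome_id[pairs$q] != queries$genome_id[pairs$s], ,
                 drop = FALSE]
  if (!nrow(pairs)) return(.empty_rawhits())
  # pass 1: scores only (no alignment objects) for every pair; pass 2:
  # full alignments, for identity bookkeeping, only for retained hits
  raw_score <- Biostrings::pairwiseAlignment(
    pattern = set[pairs$q], subject = set[pairs$s], type = "global",
    substitutionMatrix = submat, gapOpening = go, gapExtension = ge,
    scoreOnly = TRUE)
  bit <- (ka$lambda * raw_score - log(ka$K)) / log(2)
  evalue <- nchar(queries$seq[pairs$q]) * db_len * 2^(-bit)
  keep <- which(evalue <= evalue_max & raw_score > 0)
  if (!length(keep)) return(.empty_rawhits())
  q <- pairs$q[keep]; s <- pairs$s[keep]
  aln <- Biostrings::pairwiseAlignment(
    pattern = set[q], subject = set[s], type = "global",
    substitutionMatrix = submat, gapOpening = go, gapExtension = ge)
  nmat <- Biostrings::nmatch(aln)
  alen <- Biostrings::width(Biostrings::alignedPattern(aln))
  res <- data.frame(
    query_genome = queries$genome_id[q], query_key = queries$key[q],
    subject_genome = queries$genome_id[s], subject_key = queries$key[s],
    percent_identity = 100 * nmat / alen,
    alignment_length = alen,
    bitscore = raw_score[keep], evalue = evalue[keep],
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

.all_vs_all_external <- function(queries, mode, evalue_max, work_dir) {
  bin <- if (mode == "blastn") "blastn" else "blastp"
  if (Sys.which(bin) == "" || Sys.which("makeblastdb") == "") {
    stop("external engine requires BLAST+ (", bin, ", makeblastdb) on PATH; ",
         "install BLAST+ or use engine = \"builtin\"", call. = FALSE)
  }
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(work_dir, paste0(mode, "_genes.fasta"))
  ids <- paste(queries$genome_id, queries$key, sep = "|")
  writeLines(paste0(">", ids, "\n", queries$seq), fasta)
  dbtype <- if (mode == "blastn") "nucl" else "prot"
  db <- file.path(work_dir, paste0(mode, "_db"))
  st <- system2("makeblastdb", c("-in", shQuote(fasta), "-dbtype", dbtype,
                                 "-out", shQuote(db)),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("makeblastdb failed (exit ", st, ")", call. = FALSE)
  outfile <- file.path(work_dir, paste0(mode, "_hits.tsv"))
  args <- c("-query", shQuote(fasta), "-db", shQuote(db),
            "-outfmt", "6", "-evalue", format(evalue_max, scientific = TRUE),
            "-out", shQuote(outfile))
  if (mode == "blastn") args <- c(args, "-task", "blastn", "-dust", "no")
  st <- system2(bin, args, stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop(bin, " failed (exit ", st, ")", call. = FALSE)
  if (!file.size(outfile)) return(.empty_rawhits())
  tab <- utils::read.table(outfile, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("qseqid", "sseqid", "pident", "length",
                                         "mismatch", "gapopen", "qstart", "qend",
                                         "sstart", "send", "evalue", "bitscore"))
  qg <- sub("\\|.*$", "", tab$qseqid); qk <- sub("^[^|]*\\|", "", tab$qseqid)
  sg <- sub("\\|.*$", "", tab$sseqid); sk <- sub("^[^|]*\\|", "", tab$sseqid)
  keep <- qg != sg
  data.frame(query_genome = qg[keep], query_key = qk[keep],
             subject_genome = sg[keep], subject_key = sk[keep],
             percent_identity = tab$pident[keep],
             alignment_length = tab$length[keep],
             bitscore = tab$bitscore[keep], evalue = tab$evalue[keep],
             stringsAsFactors = FALSE)
}

#' Reduce raw hits to one best match per query gene and subject genome
#'
#' For each blasted gene, the best score is kept: multiple HSPs between the
#' same query/subject gene pair are first collapsed to the best-scoring
#' HSP, then one hit per (query genome, query key, subject genome) is
#' selected by maximal bitscore. Ties break deterministically: greater
#' alignment length, then smaller e-value, then lexicographically smaller
#' subject key, so repeated runs yield byte-identical tables.
#'
#' @param hits Raw-hit table from [all_vs_all()].
#' @return data.frame of best hits, at most one row per
#'   (query_genome, query_key, subject_genome); the table written as
#'   `blastn_summary.parquet` / `blastp_summary.parquet`.
#' @export
summarize_best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(.empty_rawhits())
  ord <- order(hits$query_genome, hits$query_key, hits$subject_genome,
               -hits$bitscore, -hits$alignment_length, hits$evalue,
               hits$subject_key, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  grp <- paste(hits$query_genome, hits$query_key, hits$subject_genome, sep = "\r")
  out <- hits[!duplicated(grp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
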