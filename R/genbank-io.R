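#' Parse a GenBank flat file into a genome record
#'
#' Reads a GenBank flat file (`.gb`/`.gbk`) and returns a `genome_record`:
#' the genome identifier, its nucleotide sequence, and a flat table of
#' annotated features. GenBank's 1-based inclusive coordinates are converted
#' to 0-based half-open intervals at this boundary and nowhere else, so all
#' downstream arithmetic uses ordinary slice conventions. Compound
#' (`join`/`complement(join)`) locations are collapsed to their outermost
#' bounds and flagged; the exact exon segments are retained in the
#' `segments` column so gene extraction and translation can use them.
#'
#' @param path Path to a GenBank flat file.
#' @return An object of class `genome_record`: a list with elements
#'   `genome_id`, `description`, `sequence`, `length`, `features`
#'   (a data.frame of one row per feature, in ascending start order) and
#'   `source_path`.
#' @examples
#' gb <- system.file("extdata", "toy_phage.gb", package = "phagesynteny")
#' rec <- parse_genbank(gb)
#' rec$genome_id
#' head(rec$features[, c("feature_type", "locus_tag", "start", "end", "strand")])
#' @export
parse_genbank <- function(path) {
  if (!file.exists(path)) {
    stop("GenBank file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS ", lines)
  if (length(locus_idx) == 0L) {
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  }
  if (length(locus_idx) > 1L) {
    warning("multiple records in ", path, "; only the first is parsed")
    lines <- lines[seq(locus_idx[1L], locus_idx[2L] - 1L)]
  }

  locus_fields <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  locus_name <- if (length(locus_fields) >= 2L) locus_fields[2L] else ""
  stated_len <- suppressWarnings(as.integer(locus_fields[3L]))

  definition <- .gb_header_field(lines, "DEFINITION")
  accession <- .gb_header_field(lines, "ACCESSION")
  accession <- if (nzchar(accession)) strsplit(accession, "[[:space:]]+")[[1L]][1L] else ""
  genome_id <- if (nzchar(accession)) accession else locus_name
  if (!nzchar(genome_id)) {
    stop("GenBank record has no ACCESSION or LOCUS name: ", path, call. = FALSE)
  }

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  end_marker <- grep("^//", lines)
  seq_end <- if (length(end_marker)) end_marker[1L] - 1L else length(lines)

  sequence <- ""
  if (length(origin_start) && origin_start[1L] < seq_end) {
    seq_lines <- lines[seq(origin_start[1L] + 1L, seq_end)]
    sequence <- toupper(paste(gsub("[^A-Za-z]", "", seq_lines), collapse = ""))
  }
  if (!nzchar(sequence)) {
    stop("GenBank record ", genome_id, " has no sequence (ORIGIN section empty): ",
         path, call. = FALSE)
  }

  feat_lines <- character(0)
  if (length(feat_start)) {
    feat_end <- if (length(origin_start)) origin_start[1L] - 1L else seq_end
    if (feat_end > feat_start[1L]) {
      feat_lines <- lines[seq(feat_start[1L] + 1L, feat_end)]
    }
  }
  features <- .gb_parse_features(feat_lines, genome_id, path)
  features$genome_length <- nchar(sequence)

  if (!is.na(stated_len) && stated_len != nchar(sequence)) {
    warning("LOCUS length (", stated_len, ") differs from sequence length (",
            nchar(sequence), ") in ", path)
  }
  bad <- features$end > nchar(sequence)
  if (any(bad)) {
    stop("feature interval beyond sequence end in ", genome_id, ": ",
         paste0("[", features$start[bad], ",", features$end[bad], ")",
                collapse = ", "), call. = FALSE)
  }

  structure(
    list(genome_id = genome_id,
         description = definition,
         sequence = sequence,
         length = nchar(sequence),
         features = features,
         source_path = path),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id, " (", x$length, " bp)\n", sep = "")
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  tab <- table(x$features$feature_type)
  cat("  features:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# header fields may continue over indented lines
.gb_header_field <- function(lines, key) {
  i <- grep(paste0("^", key, " "), lines)
  if (!length(i)) return("")
  i <- i[1L]
  out <- sub(paste0("^", key, "[[:space:]]*"), "", lines[i])
  j <- i + 1L
  while (j <= length(lines) && grepl("^[[:space:]]{4,}", lines[j]) &&
         !grepl("^[[:space:]]{5}\\S", substr(lines[j], 1, 21))) {
    out <- paste(out, trimws(lines[j]))
    j <- j + 1L
  }
  trimws(out)
}

.gb_empty_features <- function() {
  data.frame(
    genome_id = character(0), feature_type = character(0),
    locus_tag = character(0), gene_name = character(0),
    protein_id = character(0), product = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    compound = logical(0), partial = logical(0), pseudo = logical(0),
    segments = character(0), translation = character(0),
    genome_length = integer(0),
    stringsAsFactors = FALSE
  )
}

.gb_parse_features <- function(feat_lines, genome_id, path) {
  if (!length(feat_lines)) return(.gb_empty_features())

  # a feature header has a non-space key in columns 6-20; qualifiers start "/"
  is_key <- grepl("^ {5}\\S", feat_lines) & !grepl("^ {6,}", feat_lines)
  key_idx <- which(is_key)
  if (!length(key_idx)) return(.gb_empty_features())

  rows <- vector("list", length(key_idx))
  bounds <- c(key_idx, length(feat_lines) + 1L)
  for (k in seq_along(key_idx)) {
    block <- feat_lines[seq(bounds[k], bounds[k + 1L] - 1L)]
    header <- trimws(block[1L])
    ftype <- sub("[[:space:]].*$", "", header)
    loc <- sub("^[^[:space:]]+[[:space:]]*", "", header)
    body <- if (length(block) > 1L) trimws(block[-1L]) else character(0)
    # location may continue until the first qualifier line
    qual_at <- which(startsWith(body, "/"))
    first_q <- if (length(qual_at)) qual_at[1L] else length(body) + 1L
    if (first_q > 1L) {
      loc <- paste0(loc, paste(body[seq_len(first_q - 1L)], collapse = ""))
      body <- body[seq_along(body) >= first_q]
    }
    pl <- tryCatch(.gb_parse_location(loc), error = function(e) {
      stop("unparseable location '", loc, "' in ", path, call. = FALSE)
    })
    quals <- .gb_parse_qualifiers(body)
    rows[[k]] <- data.frame(
      genome_id = genome_id,
      feature_type = ftype,
      locus_tag = quals[["locus_tag"]],
      gene_name = quals[["gene"]],
      protein_id = quals[["protein_id"]],
      product = quals[["product"]],
      start = pl$start, end = pl$end, strand = pl$strand,
      compound = pl$compound, partial = pl$partial,
      pseudo = quals[["pseudo"]],
      segments = pl$segments,
      translation = quals[["translation"]],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[out$feature_type != "source", , drop = FALSE]
  # at equal coordinates keep GenBank's conventional order: gene, then CDS
  out <- out[order(out$start, out$end,
                   match(out$feature_type, c("gene", "CDS"), nomatch = 99L)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Location grammar subset: N, N..M, complement(X), join(X,...), order(X,...),
# with optional < > partial markers. Returns 0-based half-open outer bounds
# plus exact segments.
.gb_parse_location <- function(loc) {
  loc <- gsub("[[:space:]]", "", loc)
  strand <- "+"
  partial <- grepl("[<>]", loc)
  loc2 <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc2)) {
    strand <- "-"
    loc2 <- sub("^complement\\((.*)\\)$", "\\1", loc2)
  }
  compound <- FALSE
  if (grepl("^(join|order)\\(", loc2)) {
    compound <- TRUE
    loc2 <- sub("^(join|order)\\((.*)\\)$", "\\2", loc2)
  }
  parts <- strsplit(loc2, ",", fixed = TRUE)[[1L]]
  segs <- lapply(parts, function(p) {
    if (grepl("^complement\\(", p)) {
      strand <<- "-"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("\\.\\.", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    } else {
      ab <- rep(as.integer(p), 2L)
    }
    if (anyNA(ab) || ab[1L] > ab[2L] || ab[1L] < 1L) stop("bad segment")
    ab
  })
  segs <- do.call(rbind, segs)
  # 1-based inclusive -> 0-based half-open
  seg0 <- cbind(segs[, 1L] - 1L, segs[, 2L])
  list(start = min(seg0[, 1L]), end = max(seg0[, 2L]), strand = strand,
       compound = compound || nrow(seg0) > 1L, partial = partial,
       segments = paste(seg0[, 1L], seg0[, 2L], sep = "-", collapse = ";"))
}

.gb_parse_qualifiers <- function(body) {
  out <- list(locus_tag = NA_character_, gene = NA_character_,
              protein_id = NA_character_, product = NA_character_,
              translation = NA_character_, pseudo = FALSE)
  if (!length(body)) return(out)
  starts <- which(startsWith(body, "/"))
  if (!length(starts)) return(out)
  ends <- c(starts[-1L] - 1L, length(body))
  for (q in seq_along(starts)) {
    chunk <- body[seq(starts[q], ends[q])]
    first <- chunk[1L]
    if (!grepl("=", first, fixed = TRUE)) {
      name <- sub("^/", "", first)
      if (name == "pseudo" || name == "pseudogene") out$pseudo <- TRUE
      next
    }
    name <- sub("^/([^=]+)=.*$", "\\1", first)
    value <- sub("^/[^=]+=", "", first)
    if (length(chunk) > 1L) {
      sep <- if (name == "translation") "" else " "
      value <- paste(c(value, chunk[-1L]), collapse = sep)
    }
    value <- gsub("\"", "", value)
    if (name %in% c("locus_tag", "gene", "protein_id", "product", "translation")) {
      out[[name]] <- value
    }
  }
  out
}

#' Read every GenBank file in a directory
#'
#' Parses all `.gb` and `.gbk` files under `dir`. Files that fail to parse
#' are reported with a warning and skipped, so one garbled download does not
#' abort a multi-genome run.
#'
#' @param dir Directory containing GenBank flat files.
#' @return A named list of `genome_record` objects (names are genome ids).
#' @export
read_genbank_dir <- function(dir) {
  paths <- list.files(dir, pattern = "\\.(gb|gbk)$", full.names = TRUE)
  paths <- sort(paths)
  records <- list()
  for (p in paths) {
    rec <- tryCatch(parse_genbank(p), error = function(e) {
      warning("skipping ", basename(p), ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(rec)) records[[rec$genome_id]] <- rec
  }
  records
}

#' Write a genome record as a GenBank flat file
#'
#' Serialises a `genome_record` (or a list with the same elements) back to
#' GenBank flat-file format, converting the internal 0-based half-open
#' coordinates back to GenBank's 1-based inclusive convention. Used by the
#' synthetic-fixture generator; round-tripping through [parse_genbank()]
#' reproduces coordinates exactly.
#'
#' @param record A `genome_record` or compatible list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  seq <- record$sequence
  len <- nchar(seq)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     linear   PHG 01-JAN-2024",
            record$genome_id, len),
    sprintf("DEFINITION  %s", if (nzchar(record$description %||% "")) record$description else record$genome_id),
    sprintf("ACCESSION   %s", record$genome_id),
    sprintf("VERSION     %s", record$genome_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len)
  )
  ft <- record$features
  if (!is.null(ft) && nrow(ft)) {
    for (i in seq_len(nrow(ft))) {
      loc <- sprintf("%d..%d", ft$start[i] + 1L, ft$end[i])
      if (identical(ft$strand[i], "-")) loc <- sprintf("complement(%s)", loc)
      lines <- c(lines, sprintf("     %-15s %s", ft$feature_type[i], loc))
      for (q in c("locus_tag", "gene_name", "protein_id", "product", "translation")) {
        v <- ft[[q]][i]
        if (is.null(v) || is.na(v) || !nzchar(v)) next
        qname <- if (q == "gene_name") "gene" else q
        lines <- c(lines, .gb_wrap_qualifier(qname, v))
      }
    }
  }
  lines <- c(lines, "ORIGIN")
  pos <- seq(1L, len, by = 60L)
  for (p in pos) {
    chunk <- substr(seq, p, min(p + 59L, len))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, tolower(paste(blocks, collapse = " "))))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

.gb_wrap_qualifier <- function(name, value) {
  full <- sprintf("/%s=\"%s\"", name, value)
  width <- 58L  # payload width after the 21-column margin
  if (nchar(full) <= width) return(paste0(strrep(" ", 21L), full))
  pieces <- substring(full, seq(1L, nchar(full), width),
                      pmin(seq(width, nchar(full) + width - 1L, width), nchar(full)))
  paste0(strrep(" ", 21L), pieces)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
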