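#' Validate the completeness of a parsed genome record
#'
#' Runs the named completeness checks on one genome and decides how its
#' features will be keyed downstream. Validation is total: any parseable
#' record yields a report, never an error, so a bad file cannot abort a
#' multi-genome run.
#'
#' Checks:
#' \describe{
#'   \item{sequence_present}{nucleotide sequence has nonzero length}
#'   \item{has_features}{at least one `gene` or `CDS` feature}
#'   \item{identifiers_present}{every keyable feature resolves an identifier:
#'     `locus_tag` for files with gene features, `protein_id` for CDS-only
#'     files, falling back per feature to the other identifier and then to
#'     the gene name}
#'   \item{identifiers_unique}{resolved identifiers are unique within the
#'     genome}
#'   \item{keys_clean}{no identifier contains `|` (reserved as the
#'     genome/key separator in intermediate FASTA headers)}
#' }
#'
#' Routing: `gene_and_cds` when gene features are present and keyable,
#' `cds_only` when only CDS features are present and keyable, otherwise
#' `rejected`.
#'
#' @param record A `genome_record` from [parse_genbank()].
#' @return A `validation_report`: list with `genome_id`, `checks`
#'   (data.frame of check, status, detail) and `routing`.
#' @export
validate_record <- function(record) {
  checks <- list()
  add <- function(name, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, status = if (ok) "pass" else "fail", detail = detail,
      stringsAsFactors = FALSE)
    ok
  }

  seq_ok <- add("sequence_present", nzchar(record$sequence %||% ""),
                if (nzchar(record$sequence %||% "")) "" else "empty sequence")

  ft <- record$features
  keyable <- ft[ft$feature_type %in% c("gene", "CDS"), , drop = FALSE]
  n_gene <- sum(keyable$feature_type == "gene")
  n_cds <- sum(keyable$feature_type == "CDS")
  feat_ok <- add("has_features", nrow(keyable) > 0L,
                 sprintf("gene=%d CDS=%d", n_gene, n_cds))

  routing <- if (n_gene > 0L) "gene_and_cds" else if (n_cds > 0L) "cds_only" else "rejected"

  units <- .keyable_units(ft, routing)
  keys <- if (nrow(units)) .resolve_feature_keys(units, routing) else character(0)

  miss <- is.na(keys)
  id_ok <- add("identifiers_present", nrow(units) > 0L && !any(miss),
               if (any(miss)) {
                 paste0("no identifier for feature(s) at ",
                        paste0("[", units$start[miss], ",", units$end[miss], ")",
                               collapse = ", "))
               } else "")

  dup <- duplicated(keys[!miss])
  uniq_ok <- add("identifiers_unique", !any(dup),
                 if (any(dup)) paste("duplicates:",
                                     paste(unique(keys[!miss][dup]), collapse = ", "))
                 else "")

  pipe_bad <- grepl("|", keys[!miss], fixed = TRUE)
  pipe_ok <- add("keys_clean", !any(pipe_bad),
                 if (any(pipe_bad)) paste("'|' in key(s):",
                                          paste(keys[!miss][pipe_bad], collapse = ", "))
                 else "")

  if (!(seq_ok && feat_ok && id_ok && uniq_ok && pipe_ok)) routing <- "rejected"

  structure(
    list(genome_id = record$genome_id,
         checks = do.call(rbind, checks),
         routing = routing),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$genome_id, " -> ", x$routing, "\n", sep = "")
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%s] %s %s\n", x$checks$status[i], x$checks$check[i],
                x$checks$detail[i]))
  }
  invisible(x)
}

# the features that become one keyed unit each under a given routing
.keyable_units <- function(ft, routing) {
  if (routing == "gene_and_cds") {
    ft[ft$feature_type == "gene", , drop = FALSE]
  } else {
    ft[ft$feature_type == "CDS", , drop = FALSE]
  }
}

# per-feature identifier with graceful fallback; NA when nothing usable
.resolve_feature_keys <- function(units, routing) {
  pick <- function(...) {
    cols <- list(...)
    out <- rep(NA_character_, nrow(units))
    for (col in cols) {
      v <- units[[col]]
      take <- is.na(out) & !is.na(v) & nzchar(v)
      out[take] <- v[take]
    }
    out
  }
  if (routing == "gene_and_cds") {
    pick("locus_tag", "protein_id", "gene_name")
  } else {
    pick("protein_id", "locus_tag", "gene_name")
  }
}

#' Combine genome records into one flat feature table
#'
#' Stacks every annotated feature of every genome into a single data.frame
#' (one row per gene/CDS/other feature), the columnar table written as
#' `genbank_df.parquet` by the validate job.
#'
#' @param records List of `genome_record` objects.
#' @return data.frame with one row per feature across all genomes.
#' @export
build_feature_table <- function(records) {
  if (length(records) == 0L) stop("no genomes loaded", call. = FALSE)
  out <- do.call(rbind, lapply(records, `[[`, "features"))
  rownames(out) <- NULL
  out
}

#' Resolve the join key for every gene unit
#'
#' Reduces the raw feature table to one row per gene unit per genome and
#' attaches the identifier used in all downstream joins and plots: the
#' `locus_tag` for genomes annotated with gene features, or the
#' `protein_id` for CDS-only genomes (per-feature fallback to the other
#' identifier, then the gene name). For gene-annotated genomes the matching
#' CDS (same locus_tag, or failing that the same interval) contributes its
#' `protein_id`, `product` and `translation`.
#'
#' @param table Feature table from [build_feature_table()].
#' @param reports List of `validation_report`s covering every genome in
#'   `table`; all must be non-rejected.
#' @return data.frame of processed features, one row per (genome, key),
#'   with a `key` column; the table written as
#'   `processed_genbank_df.parquet`.
#' @export
resolve_keys <- function(table, reports) {
  routing <- vapply(reports, `[[`, "", "routing")
  names(routing) <- vapply(reports, `[[`, "", "genome_id")
  gids <- unique(table$genome_id)
  unknown <- setdiff(gids, names(routing))
  if (length(unknown)) {
    stop("no validation report for genome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rej <- gids[routing[gids] == "rejected"]
  if (length(rej)) {
    stop("rejected genome(s) present in feature table: ",
         paste(rej, collapse = ", "), call. = FALSE)
  }

  per_genome <- lapply(gids, function(g) {
    ft <- table[table$genome_id == g, , drop = FALSE]
    r <- routing[[g]]
    units <- .keyable_units(ft, r)
    keys <- .resolve_feature_keys(units, r)
    bad <- is.na(keys)
    if (any(bad)) {
      stop("genome ", g, ": no usable identifier for feature(s) at ",
           paste0("[", units$start[bad], ",", units$end[bad], ")", collapse = ", "),
           call. = FALSE)
    }
    units$key <- keys
    units$key_source <- if (r == "gene_and_cds") "locus_tag" else "protein_id"
    if (r == "gene_and_cds") {
      cds <- ft[ft$feature_type == "CDS", , drop = FALSE]
      for (i in seq_len(nrow(units))) {
        j <- if (nrow(cds)) which(!is.na(cds$locus_tag) & cds$locus_tag == units$locus_tag[i]) else integer(0)
        if (!length(j) && nrow(cds)) {
          j <- which(cds$start >= units$start[i] & cds$end <= units$end[i])
        }
        if (length(j)) {
          j <- j[1L]
          for (col in c("protein_id", "product", "translation", "gene_name")) {
            if (is.na(units[[col]][i])) units[[col]][i] <- cds[[col]][j]
          }
        }
      }
    }
    units
  })
  out <- do.call(rbind, per_genome)
  rownames(out) <- NULL
  dup <- duplicated(out[, c("genome_id", "key")])
  if (any(dup)) {
    stop("duplicate (genome_id, key) after resolution: ",
         paste(unique(paste(out$genome_id[dup], out$key[dup], sep = "/")),
               collapse = ", "), call. = FALSE)
  }
  out
}
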