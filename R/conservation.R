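#' Sequence selections for plotting
#'
#' A sequence selection names the genomes to plot, their top-to-bottom
#' order and per-genome orientation. On disk it is a CSV with header
#' `sequence,orientation`, one row per genome, orientation `1` = forward,
#' `0` = reverse.
#'
#' @param genome_id Character vector of genome ids in plot order.
#' @param orientation Character (`"forward"`/`"reverse"`) or numeric
#'   (`1`/`0`) vector recycled along `genome_id`.
#' @return A `sequence_selection` object.
#' @export
sequence_selection <- function(genome_id, orientation = "forward") {
  if (anyDuplicated(genome_id)) {
    stop("duplicate genome ids in selection: ",
         paste(unique(genome_id[duplicated(genome_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.numeric(orientation)) {
    orientation <- ifelse(orientation == 1, "forward", "reverse")
  }
  orientation <- rep_len(orientation, length(genome_id))
  if (!all(orientation %in% c("forward", "reverse"))) {
    stop("orientation must be forward/reverse (or 1/0)", call. = FALSE)
  }
  structure(list(genome_id = as.character(genome_id), orientation = orientation),
            class = "sequence_selection")
}

#' @rdname sequence_selection
#' @param path Path to a selection CSV (`sequence,orientation` header).
#' @export
read_selection <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence", "orientation")
  if (!all(need %in% names(tab))) {
    stop("selection CSV must have columns 'sequence' and 'orientation': ", path,
         call. = FALSE)
  }
  sequence_selection(tab$sequence, tab$orientation)
}

#' @export
print.sequence_selection <- function(x, ...) {
  cat("<sequence_selection> ", length(x$genome_id), " genomes\n", sep = "")
  cat(paste0("  ", x$genome_id, " (", x$orientation, ")", collapse = "\n"), "\n")
  invisible(x)
}

#' Colour palettes for conservation and identity gradients
#'
#' The default conservation palette runs yellow (unique) through green and
#' blue to purple (strictly conserved); the default cross-link identity
#' gradient runs light grey (low identity) to dark red (100\%). Endpoint
#' hexes map exactly to conservation fractions 0 and 1.
#'
#' @param name Palette name (currently `"conservation"` or `"identity"`).
#' @return Character vector of hex colours (gradient anchor points).
#' @export
default_palette <- function(name = c("conservation", "identity")) {
  name <- match.arg(name)
  switch(name,
         conservation = c("#FDD835", "#43A047", "#1E88E5", "#6A1B9A"),
         identity = c("#D3D3D3", "#8B0000"))
}

#' Map a fraction in [0,1] through a colour gradient
#'
#' Deterministic: equal fractions always yield identical hex strings, and
#' fractions 0 and 1 return the palette's first and last anchors exactly.
#'
#' @param fraction Numeric vector in `[0, 1]`.
#' @param palette Character vector of hex anchor colours.
#' @return Character vector of `#RRGGBB` hex colours.
#' @export
colour_for_fraction <- function(fraction, palette = default_palette("conservation")) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  ramp <- grDevices::colorRamp(palette, space = "rgb")
  m <- round(ramp(fraction))
  sprintf("#%02X%02X%02X", m[, 1L], m[, 2L], m[, 3L])
}

#' Build the gene-uniqueness table
#'
#' Joins the best-hit summary onto the processed feature table: one row per
#' (gene, other genome) pair over all processed genomes, whether or not a
#' match exists there. `total_match_count` is the number of distinct other
#' genomes in which the gene has a best hit, so filtering
#' `total_match_count == 0` lists the genes unique across the whole run.
#'
#' @param best_hits Best-hit table from [summarize_best_hits()].
#' @param features Processed feature table from [resolve_keys()].
#' @return data.frame (`gene_uniqueness` / `protein_uniqueness` table):
#'   `genome_id`, `key`, `gene_name`, `product`, `start`, `end`, `strand`,
#'   `subject_genome`, `subject_key`, `has_match`, `percent_identity`,
#'   `total_match_count`.
#' @export
build_uniqueness <- function(best_hits, features) {
  feat_id <- paste(features$genome_id, features$key, sep = "\r")
  if (nrow(best_hits)) {
    hit_q <- paste(best_hits$query_genome, best_hits$query_key, sep = "\r")
    unknown <- !(hit_q %in% feat_id)
    if (any(unknown)) {
      stop("best hits reference unknown features (tables out of sync): ",
           paste(unique(paste(best_hits$query_genome[unknown],
                              best_hits$query_key[unknown], sep = "/"))[1:5],
                 collapse = ", "), call. = FALSE)
    }
  }
  genomes <- sort(unique(features$genome_id))
  per <- lapply(seq_len(nrow(features)), function(i) {
    others <- setdiff(genomes, features$genome_id[i])
    if (!length(others)) return(NULL)
    data.frame(genome_id = features$genome_id[i], key = features$key[i],
               gene_name = features$gene_name[i], product = features$product[i],
               start = features$start[i], end = features$end[i],
               strand = features$strand[i],
               subject_genome = others, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  if (is.null(out)) {
    out <- data.frame(genome_id = character(0), key = character(0),
                      gene_name = character(0), product = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      subject_genome = character(0), stringsAsFactors = FALSE)
  }
  if (nrow(best_hits)) {
    idx <- match(paste(out$genome_id, out$key, out$subject_genome, sep = "\r"),
                 paste(best_hits$query_genome, best_hits$query_key,
                       best_hits$subject_genome, sep = "\r"))
  } else {
    idx <- rep(NA_integer_, nrow(out))
  }
  out$subject_key <- ifelse(is.na(idx), NA_character_, best_hits$subject_key[idx])
  out$has_match <- !is.na(idx)
  out$percent_identity <- ifelse(is.na(idx), NA_real_, best_hits$percent_identity[idx])
  gene_grp <- paste(out$genome_id, out$key, sep = "\r")
  counts <- tapply(out$has_match, gene_grp, sum)
  out$total_match_count <- as.integer(counts[gene_grp])
  rownames(out) <- NULL
  out
}

#' Compute the per-plot colour table
#'
#' Restricts match counting to the genomes of a plot selection: for every
#' gene of every selected genome, `match_count_in_set` counts the *other*
#' selected genomes holding a best hit, `conservation_fraction` is that
#' count over `n - 1`, and `colour` maps the fraction through the palette
#' gradient. Fraction 0 means unique within the plotted set, 1 strictly
#' conserved. Regenerated for every plot (the `colour_table` output).
#'
#' @param uniq Uniqueness table from [build_uniqueness()].
#' @param selection A [sequence_selection()].
#' @param palette Hex anchor colours for the conservation gradient.
#' @return data.frame: `genome_id`, `key`, `gene_name`, `product`, `start`,
#'   `end`, `strand`, `match_count_in_set`, `conservation_fraction`,
#'   `colour`.
#' @export
compute_colour_table <- function(uniq, selection,
                                 palette = default_palette("conservation")) {
  stopifnot(inherits(selection, "sequence_selection"))
  sel <- selection$genome_id
  if (length(sel) < 2L) stop("a plot selection needs at least 2 genomes", call. = FALSE)
  known <- unique(uniq$genome_id)
  missing <- setdiff(sel, known)
  if (length(missing)) {
    stop("selection genome(s) absent from uniqueness table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- length(sel)
  rows <- uniq[uniq$genome_id %in% sel, , drop = FALSE]
  in_set_match <- rows$has_match & rows$subject_genome %in% sel
  grp <- paste(rows$genome_id, rows$key, sep = "\r")
  counts <- tapply(in_set_match, grp, sum)
  first <- !duplicated(grp)
  out <- rows[first, c("genome_id", "key", "gene_name", "product",
                       "start", "end", "strand"), drop = FALSE]
  out$match_count_in_set <- as.integer(counts[grp[first]])
  out$conservation_fraction <- out$match_count_in_set / (n - 1L)
  out$colour <- colour_for_fraction(out$conservation_fraction, palette)
  out <- out[order(match(out$genome_id, sel), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' List the genes unique within a plotted set
#'
#' Filters the colour table for one genome's genes with zero matches in the
#' plotted set, in genome order.
#'
#' @param colour Colour table from [compute_colour_table()].
#' @param genome_id Genome to query.
#' @return data.frame: `key`, `gene_name`, `product`, sorted by start
#'   coordinate.
#' @export
query_unique_genes <- function(colour, genome_id) {
  if (!genome_id %in% colour$genome_id) {
    stop("unknown genome: ", genome_id, " (have: ",
         paste(unique(colour$genome_id), collapse = ", "), ")", call. = FALSE)
  }
  rows <- colour[colour$genome_id == genome_id & colour$match_count_in_set == 0L, ,
                 drop = FALSE]
  rows <- rows[order(rows$start), c("key", "gene_name", "product"), drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' List every genome in which a gene of interest has a match
#'
#' Resolves `gene` first as an exact (case-sensitive) key in `genome_id`,
#' then as a case-insensitive gene name, and returns the matching subject
#' gene and percent identity in every genome holding a best hit — e.g.
#' querying a core gene over a genus set shows it strictly conserved, with
#' the corresponding locus tag in each other genome.
#'
#' @param uniq Uniqueness table from [build_uniqueness()].
#' @param gene Gene key or gene name.
#' @param genome_id Genome carrying the query gene.
#' @return data.frame: `subject_genome`, `subject_key`,
#'   `percent_identity`, one row per genome with a match.
#' @export
query_gene_matches <- function(uniq, gene, genome_id) {
  mine <- uniq[uniq$genome_id == genome_id, , drop = FALSE]
  if (!nrow(mine)) stop("unknown genome: ", genome_id, call. = FALSE)
  hit <- mine$key == gene
  if (!any(hit)) {
    gn <- !is.na(mine$gene_name) & tolower(mine$gene_name) == tolower(gene)
    if (any(gn)) hit <- gn
  }
  if (!any(hit)) {
    cand <- unique(c(mine$key, mine$gene_name[!is.na(mine$gene_name)]))
    near <- cand[agrepl(gene, cand, max.distance = 0.3, ignore.case = TRUE)]
    stop("gene '", gene, "' not found in ", genome_id,
         if (length(near)) paste0("; did you mean: ", paste(utils::head(near, 5), collapse = ", "))
         else "", call. = FALSE)
  }
  rows <- mine[hit & mine$has_match, c("subject_genome", "subject_key",
                                       "percent_identity"), drop = FALSE]
  rows <- rows[order(rows$subject_genome), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
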