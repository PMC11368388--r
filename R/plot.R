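#' Plot configuration
#'
#' Collects the configurable appearance of a synteny diagram: title,
#' conservation palette, gene glyph shape, output formats, the minimum
#' percent identity below which cross-links are not drawn, and the
#' horizontal scale.
#'
#' @param title Plot title.
#' @param palette Conservation gradient anchors (hex), yellow-to-purple by
#'   default.
#' @param link_palette Cross-link identity gradient anchors (hex),
#'   light-grey-to-dark-red by default.
#' @param gene_shape `"arrow"` or `"box"`.
#' @param output_formats Subset of `c("svg", "png")`.
#' @param min_link_identity Links below this percent identity are dropped
#'   (default 0 = draw every adjacent match).
#' @param scale Base pairs per pixel; `NULL` (default) fits the longest
#'   selected genome into a 1000 px track.
#' @param dpi PNG raster resolution (default 300).
#' @return A `plot_config` object.
#' @export
plot_config <- function(title = "Synteny plot",
                        palette = default_palette("conservation"),
                        link_palette = default_palette("identity"),
                        gene_shape = c("arrow", "box"),
                        output_formats = c("svg", "png"),
                        min_link_identity = 0,
                        scale = NULL, dpi = 300) {
  gene_shape <- match.arg(gene_shape)
  output_formats <- match.arg(output_formats, several.ok = TRUE)
  stopifnot(length(palette) >= 2L, length(link_palette) >= 2L,
            palette[1L] != palette[length(palette)],
            min_link_identity >= 0, min_link_identity <= 100)
  structure(list(title = title, palette = palette, link_palette = link_palette,
                 gene_shape = gene_shape, output_formats = output_formats,
                 min_link_identity = min_link_identity, scale = scale, dpi = dpi),
            class = "plot_config")
}

#' Cross-links between adjacent plotted genomes
#'
#' For each adjacent pair of tracks in the selection, emits one link per
#' gene whose best hit lies in the neighbouring track at or above the
#' identity threshold. Matches found in either query direction are used;
#' reciprocal duplicates are collapsed by unordered gene pair (keeping the
#' higher identity). Non-adjacent tracks never link.
#'
#' @param best_hits Best-hit table from [summarize_best_hits()].
#' @param selection A [sequence_selection()].
#' @param min_link_identity Minimum percent identity for a drawn link.
#' @return data.frame: `upper_genome`, `upper_key`, `lower_genome`,
#'   `lower_key`, `percent_identity`.
#' @export
compute_cross_links <- function(best_hits, selection, min_link_identity = 0) {
  stopifnot(inherits(selection, "sequence_selection"))
  sel <- selection$genome_id
  out <- list()
  for (i in seq_len(length(sel) - 1L)) {
    up <- sel[i]; lo <- sel[i + 1L]
    a <- best_hits[best_hits$query_genome == up & best_hits$subject_genome == lo, ,
                   drop = FALSE]
    b <- best_hits[best_hits$query_genome == lo & best_hits$subject_genome == up, ,
                   drop = FALSE]
    links <- rbind(
      data.frame(upper_genome = rep(up, nrow(a)), upper_key = a$query_key,
                 lower_genome = rep(lo, nrow(a)), lower_key = a$subject_key,
                 percent_identity = a$percent_identity, stringsAsFactors = FALSE),
      data.frame(upper_genome = rep(up, nrow(b)), upper_key = b$subject_key,
                 lower_genome = rep(lo, nrow(b)), lower_key = b$query_key,
                 percent_identity = b$percent_identity, stringsAsFactors = FALSE))
    links <- links[links$percent_identity >= min_link_identity, , drop = FALSE]
    if (!nrow(links)) next
    ord <- order(links$upper_key, links$lower_key, -links$percent_identity,
                 method = "radix")
    links <- links[ord, , drop = FALSE]
    links <- links[!duplicated(paste(links$upper_key, links$lower_key, sep = "\r")), ,
                   drop = FALSE]
    out[[length(out) + 1L]] <- links
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(upper_genome = character(0), upper_key = character(0),
                      lower_genome = character(0), lower_key = character(0),
                      percent_identity = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

# ---- geometry / scene tree ------------------------------------------------
# The diagram is built once as a tree of primitive nodes (rect, polygon,
# line, text, group); the SVG writer serialises it with fixed number
# formatting so re-renders are byte-identical, and the PNG renderer draws
# the same tree on a cairo device.

.node <- function(tag, attrs = list(), children = list()) {
  list(tag = tag, attrs = attrs, children = children)
}

.fmt <- function(x) {
  s <- sprintf("%.2f", x)
  s <- sub("\\.?0+$", "", s)
  ifelse(s == "-0", "0", s)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.svg_serialize <- function(node, indent = 0) {
  pad <- strrep(" ", indent)
  attrs <- node$attrs
  astr <- if (length(attrs)) {
    paste0(" ", paste0(names(attrs), "=\"", vapply(attrs, as.character, ""), "\"",
                       collapse = " "))
  } else ""
  if (node$tag == "text") {
    label <- .xml_escape(node$children[[1L]])
    return(paste0(pad, "<text", astr, ">", label, "</text>"))
  }
  if (!length(node$children)) {
    return(paste0(pad, "<", node$tag, astr, "/>"))
  }
  inner <- unlist(lapply(node$children, .svg_serialize, indent = indent + 2L))
  c(paste0(pad, "<", node$tag, astr, ">"), inner, paste0(pad, "</", node$tag, ">"))
}

.scene_layout <- function(n_tracks) {
  list(width = 1180, margin_left = 150, margin_right = 30, title_y = 30,
       first_track_y = 80, track_gap = 70, glyph_h = 14,
       legend_h = 80)
}

.gene_node <- function(x1, x2, y, h, fill, direction, shape) {
  if (shape == "box" || abs(x2 - x1) < 3) {
    return(.node("rect", list(class = "gene", x = .fmt(min(x1, x2)),
                              y = .fmt(y - h / 2), width = .fmt(abs(x2 - x1)),
                              height = .fmt(h), fill = fill, stroke = "#333333",
                              `stroke-width` = "0.4")))
  }
  head <- min(8, abs(x2 - x1) * 0.5)
  if (direction > 0) {
    xh <- x2 - head
    px <- c(x1, xh, x2, xh, x1); py <- c(y - h / 2, y - h / 2, y, y + h / 2, y + h / 2)
  } else {
    xh <- x1 + head
    px <- c(x2, xh, x1, xh, x2); py <- c(y - h / 2, y - h / 2, y, y + h / 2, y + h / 2)
  }
  .node("polygon", list(class = "gene",
                        points = paste(.fmt(px), .fmt(py), sep = ",", collapse = " "),
                        fill = fill, stroke = "#333333", `stroke-width` = "0.4"))
}

.legend_bar <- function(x, y, w, h, palette, label, left_lab, right_lab) {
  nseg <- 40L
  xs <- x + (seq_len(nseg) - 1L) * w / nseg
  cols <- colour_for_fraction((seq_len(nseg) - 1L) / (nseg - 1L), palette)
  segs <- lapply(seq_len(nseg), function(i) {
    .node("rect", list(class = "legend-seg", x = .fmt(xs[i]), y = .fmt(y),
                       width = .fmt(w / nseg + 0.5), height = .fmt(h),
                       fill = cols[i]))
  })
  labels <- list(
    .node("text", list(class = "legend-label", x = .fmt(x + w / 2), y = .fmt(y - 6),
                       `text-anchor` = "middle", `font-size` = "11",
                       `font-family` = "Helvetica"), list(label)),
    .node("text", list(class = "legend-tick", x = .fmt(x), y = .fmt(y + h + 12),
                       `text-anchor` = "middle", `font-size` = "10",
                       `font-family` = "Helvetica"), list(left_lab)),
    .node("text", list(class = "legend-tick", x = .fmt(x + w), y = .fmt(y + h + 12),
                       `text-anchor` = "middle", `font-size` = "10",
                       `font-family` = "Helvetica"), list(right_lab)))
  .node("g", list(class = "legend"), c(segs, labels))
}

.build_scene <- function(features, colours, links, selection, config) {
  sel <- selection$genome_id
  n <- length(sel)
  lay <- .scene_layout(n)
  feats <- features[features$genome_id %in% sel, , drop = FALSE]
  lens <- tapply(feats$genome_length, feats$genome_id, max)
  max_len <- max(lens)
  plot_w <- lay$width - lay$margin_left - lay$margin_right
  ppb <- if (is.null(config$scale)) plot_w / max_len else 1 / config$scale
  height <- lay$first_track_y + (n - 1L) * lay$track_gap + lay$legend_h + 40

  col_idx <- paste(colours$genome_id, colours$key, sep = "\r")
  track_y <- stats::setNames(lay$first_track_y + (seq_len(n) - 1L) * lay$track_gap, sel)
  reversed <- stats::setNames(selection$orientation == "reverse", sel)

  gene_geom <- new.env(parent = emptyenv())  # key -> c(x1, x2, y)

  tracks <- lapply(seq_len(n), function(i) {
    g <- sel[i]
    y <- track_y[[g]]
    L <- lens[[g]]
    rows <- feats[feats$genome_id == g, , drop = FALSE]
    rows <- rows[order(rows$start, rows$end), , drop = FALSE]
    glyphs <- lapply(seq_len(nrow(rows)), function(j) {
      s <- rows$start[j]; e <- rows$end[j]
      if (reversed[[g]]) { s2 <- L - e; e2 <- L - s } else { s2 <- s; e2 <- e }
      x1 <- lay$margin_left + s2 * ppb
      x2 <- lay$margin_left + e2 * ppb
      dirn <- if (identical(rows$strand[j], "-")) -1 else 1
      if (reversed[[g]]) dirn <- -dirn
      ci <- match(paste(g, rows$key[j], sep = "\r"), col_idx)
      if (is.na(ci)) {
        stop("no colour row for gene ", rows$key[j], " of ", g, call. = FALSE)
      }
      assign(paste(g, rows$key[j], sep = "\r"), c(x1, x2, y), envir = gene_geom)
      .gene_node(x1, x2, y, lay$glyph_h, colours$colour[ci], dirn, config$gene_shape)
    })
    baseline <- .node("line", list(class = "baseline",
                                   x1 = .fmt(lay$margin_left),
                                   y1 = .fmt(y),
                                   x2 = .fmt(lay$margin_left + L * ppb),
                                   y2 = .fmt(y), stroke = "#999999",
                                   `stroke-width` = "1"))
    lab_txt <- if (reversed[[g]]) paste0(g, " (rev)") else g
    label <- .node("text", list(class = "track-label", x = .fmt(lay$margin_left - 8),
                                y = .fmt(y + 4), `text-anchor` = "end",
                                `font-size` = "11", `font-family` = "Helvetica"),
                   list(lab_txt))
    .node("g", list(class = "track", id = paste0("track-", i),
                    `data-genome` = g),
          c(list(baseline, label), glyphs))
  })

  link_nodes <- lapply(seq_len(nrow(links)), function(k) {
    up <- get(paste(links$upper_genome[k], links$upper_key[k], sep = "\r"),
              envir = gene_geom)
    lo <- get(paste(links$lower_genome[k], links$lower_key[k], sep = "\r"),
              envir = gene_geom)
    h2 <- lay$glyph_h / 2
    px <- c(up[1L], up[2L], lo[2L], lo[1L])
    py <- c(up[3L] + h2, up[3L] + h2, lo[3L] - h2, lo[3L] - h2)
    fill <- colour_for_fraction(links$percent_identity[k] / 100, config$link_palette)
    .node("polygon", list(class = "cross-link",
                          points = paste(.fmt(px), .fmt(py), sep = ",", collapse = " "),
                          fill = fill, `fill-opacity` = "0.55", stroke = "none"))
  })

  legend_y <- lay$first_track_y + (n - 1L) * lay$track_gap + 45
  legends <- list(
    .legend_bar(lay$margin_left, legend_y, 220, 12, config$link_palette,
                "Cross-link identity (%)", "0", "100"),
    .legend_bar(lay$margin_left + 320, legend_y, 220, 12, config$palette,
                "Gene conservation (%)", "0", "100"))

  title <- .node("text", list(class = "title", x = .fmt(lay$width / 2),
                              y = .fmt(lay$title_y), `text-anchor` = "middle",
                              `font-size` = "16", `font-family` = "Helvetica"),
                 list(config$title))
  background <- .node("rect", list(class = "background", x = "0", y = "0",
                                   width = .fmt(lay$width), height = .fmt(height),
                                   fill = "#FFFFFF"))
  root <- .node("svg", list(xmlns = "http://www.w3.org/2000/svg",
                            width = .fmt(lay$width), height = .fmt(height),
                            viewBox = paste("0 0", .fmt(lay$width), .fmt(height))),
                c(list(background, title),
                  list(.node("g", list(class = "links"), link_nodes)),
                  tracks, legends))
  list(root = root, width = lay$width, height = height)
}

# draw the scene tree on the active graphics device
.draw_node <- function(node) {
  a <- node$attrs
  num <- function(name) as.numeric(a[[name]])
  switch(node$tag,
    rect = graphics::rect(num("x"), num("y") + num("height"), num("x") + num("width"),
                          num("y"),
                          col = a$fill %||% NA,
                          border = if (is.null(a$stroke) || a$stroke == "none") NA else a$stroke),
    polygon = {
      pts <- do.call(rbind, lapply(strsplit(strsplit(a$points, " ")[[1L]], ","),
                                   as.numeric))
      fill <- a$fill
      if (!is.null(a$`fill-opacity`)) {
        fill <- grDevices::adjustcolor(fill, alpha.f = as.numeric(a$`fill-opacity`))
      }
      graphics::polygon(pts[, 1L], pts[, 2L], col = fill,
                        border = if (is.null(a$stroke) || a$stroke == "none") NA else a$stroke)
    },
    line = graphics::segments(num("x1"), num("y1"), num("x2"), num("y2"),
                              col = a$stroke %||% "black"),
    text = {
      adj <- switch(a$`text-anchor` %||% "start",
                    middle = c(0.5, 0.35), end = c(1, 0.35), c(0, 0.35))
      size <- as.numeric(a$`font-size` %||% "12")
      graphics::text(num("x"), num("y"), node$children[[1L]], adj = adj,
                     cex = size / 12)
    },
    { for (ch in node$children) .draw_node(ch) }
  )
  if (node$tag %in% c("svg", "g")) invisible() else invisible()
}

#' Render a stacked linear synteny diagram
#'
#' Draws one horizontal track per selected genome, in selection order, with
#' gene glyphs filled by the colour table's conservation colours and
#' cross-link ribbons between adjacent tracks shaded by percent identity.
#' Reverse-oriented genomes are mirrored coordinate-wise (a gene at
#' `[s, e)` is drawn at `[L - e, L - s)` with its arrowhead flipped). Two
#' legend bars show the identity and conservation gradients. The SVG is
#' written deterministically (identical inputs give byte-identical files);
#' the PNG re-draws the same scene on a raster device.
#'
#' @param features Processed feature table covering every selected genome.
#' @param colours Colour table from [compute_colour_table()].
#' @param links Cross-link table from [compute_cross_links()]; may be
#'   empty (a diagram with no links still renders).
#' @param selection A [sequence_selection()].
#' @param config A [plot_config()].
#' @param out_base Output path without extension.
#' @return Named character vector of written file paths, invisibly.
#' @export
render_synteny <- function(features, colours, links, selection, config,
                           out_base = "synteny") {
  stopifnot(inherits(selection, "sequence_selection"), inherits(config, "plot_config"))
  missing <- setdiff(selection$genome_id, unique(features$genome_id))
  if (length(missing)) {
    stop("selected genome(s) have no features: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  scene <- .build_scene(features, colours, links, selection, config)
  paths <- character(0)
  if ("svg" %in% config$output_formats) {
    svg_path <- paste0(out_base, ".svg")
    lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               .svg_serialize(scene$root))
    con <- file(svg_path, open = "wb")
    writeLines(lines, con, sep = "\n")
    close(con)
    paths["svg"] <- svg_path
  }
  if ("png" %in% config$output_formats) {
    png_path <- paste0(out_base, ".png")
    f <- config$dpi / 96
    grDevices::png(png_path, width = scene$width * f, height = scene$height * f,
                   res = config$dpi)
    graphics::par(mar = rep(0, 4), xaxs = "i", yaxs = "i")
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, scene$width), ylim = c(scene$height, 0))
    .draw_node(scene$root)
    grDevices::dev.off()
    paths["png"] <- png_path
  }
  invisible(paths)
}

#' Run the plot job over a processed data directory
#'
#' Regenerates the colour table for a selection and renders the synteny
#' diagram from the tables a previous validate/blast run left in
#' `data_dir`, touching none of them — so any number of plots with
#' different selections, orientations and styles can be produced without
#' re-processing the data.
#'
#' @param data_dir Pipeline data directory (holds `tables/`).
#' @param selection A [sequence_selection()] or path to a selection CSV.
#' @param mode `"blastn"` (uses `gene_uniqueness`) or `"blastp"`
#'   (`protein_uniqueness`).
#' @param config A [plot_config()].
#' @param out_base Output path base; default `<data_dir>/plots/synteny`.
#' @return List with `plot_paths`, `colour_table_path`, and the computed
#'   `colour_table` and `links`, invisibly.
#' @export
plot_job <- function(data_dir, selection, mode = c("blastn", "blastp"),
                     config = plot_config(), out_base = NULL) {
  mode <- match.arg(mode)
  if (is.character(selection)) selection <- read_selection(selection)
  tables <- file.path(data_dir, "tables")
  proc_path <- file.path(tables, "processed_genbank_df.parquet")
  if (!file.exists(proc_path)) {
    stop("missing ", proc_path, "; run the validate job first", call. = FALSE)
  }
  summary_path <- file.path(tables, paste0(mode, "_summary.parquet"))
  uniq_name <- if (mode == "blastn") "gene_uniqueness.parquet" else "protein_uniqueness.parquet"
  uniq_path <- file.path(tables, uniq_name)
  if (!file.exists(summary_path) || !file.exists(uniq_path)) {
    stop("missing ", paste0(mode, " tables"), "; run the ", mode, " job first",
         call. = FALSE)
  }
  features <- as.data.frame(arrow::read_parquet(proc_path))
  best <- as.data.frame(arrow::read_parquet(summary_path))
  uniq <- as.data.frame(arrow::read_parquet(uniq_path))

  colour <- compute_colour_table(uniq, selection, config$palette)
  links <- compute_cross_links(best, selection, config$min_link_identity)

  if (is.null(out_base)) out_base <- file.path(data_dir, "plots", "synteny")
  dir.create(dirname(out_base), recursive = TRUE, showWarnings = FALSE)
  ct_path <- file.path(dirname(out_base), "colour_table.parquet")
  arrow::write_parquet(colour, ct_path)
  paths <- render_synteny(features, colour, links, selection, config, out_base)
  invisible(list(plot_paths = paths, colour_table_path = ct_path,
                 colour_table = colour, links = links))
}
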