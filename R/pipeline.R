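#' Pipeline run configuration
#'
#' Loads (optionally) a YAML config file, interpolates `${VAR}`
#' environment references in string values, and merges it over the
#' defaults. The pipeline's four steps — download, validate,
#' blastn/blastp, plot — all read from this one object.
#'
#' @param path Optional YAML file.
#' @param ... Named overrides applied last (e.g. `data_dir = "run1"`).
#' @return A `run_config` list: `data_dir`, `genbank_dir`, `run_blastn`,
#'   `run_blastp`, `evalue_threshold`, `engine`, `download` (list),
#'   `plot` (list).
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    data_dir = "data",
    genbank_dir = NULL,  # default <data_dir>/genbank
    run_blastn = TRUE,
    run_blastp = FALSE,
    evalue_threshold = 1e-3,
    engine = "builtin",
    download = list(search_key = NULL, email = NULL, api_key = NULL,
                    max_records = 100L),
    plot = list(title = "Synteny plot", gene_shape = "arrow",
                output_formats = c("svg", "png"), min_link_identity = 0)
  )
  cfg <- defaults
  if (!is.null(path)) {
    loaded <- .interp_env(yaml::read_yaml(path))
    cfg <- utils::modifyList(cfg, loaded)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  if (is.null(cfg$genbank_dir)) cfg$genbank_dir <- file.path(cfg$data_dir, "genbank")
  stopifnot(cfg$engine %in% c("builtin", "external"))
  structure(cfg, class = "run_config")
}

# recursive ${VAR} interpolation for secrets in YAML configs
.interp_env <- function(x) {
  if (is.list(x)) return(lapply(x, .interp_env))
  if (is.character(x)) {
    for (m in regmatches(x, gregexpr("\\$\\{[A-Za-z_][A-Za-z0-9_]*\\}", x))[[1L]]) {
      var <- sub("^\\$\\{(.*)\\}$", "\\1", m)
      x <- sub(m, Sys.getenv(var, ""), x, fixed = TRUE)
    }
  }
  x
}

.meta_path <- function(config) file.path(config$data_dir, "run_metadata.jsonl")

# append-only JSON-lines run metadata: one record per executed step
.log_step <- function(config, step, status, started, artifacts = character(0),
                      details = list()) {
  dir.create(config$data_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- list(step = step, status = status,
              started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
              finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              artifacts = as.list(artifacts), details = details)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), "\n",
      sep = "", file = .meta_path(config), append = TRUE)
}

#' Read the run metadata log
#'
#' @param config A [run_config()].
#' @return List of step records (empty when no job has run yet).
#' @export
read_run_metadata <- function(config) {
  p <- .meta_path(config)
  if (!file.exists(p)) return(list())
  lapply(readLines(p, warn = FALSE), jsonlite::fromJSON)
}

.tables_dir <- function(config) file.path(config$data_dir, "tables")

#' Pipeline jobs
#'
#' The four pipeline steps as callable commands, each returning a shell
#' exit status (0 = success) and appending a record to the run metadata
#' log. `cmd_download` fetches GenBank records from NCBI into the genbank
#' directory; `cmd_validate` parses and validates every GenBank file and
#' writes `genbank_df.parquet` / `processed_genbank_df.parquet` (rejected
#' genomes are logged and dropped, never fatal); `cmd_blast` extracts (and
#' for blastp translates) gene sequences, runs the all-vs-all search,
#' and writes the best-hit summary and uniqueness tables; `cmd_plot`
#' renders a synteny diagram from the existing tables without touching
#' them. `cmd_status` prints the latest state of each step.
#'
#' @param config A [run_config()].
#' @param transport Entrez transport (injectable for testing).
#' @param mode `"blastn"` or `"blastp"`.
#' @param selection A selection CSV path or [sequence_selection()].
#' @param out_base Plot output base path (default under
#'   `<data_dir>/plots`).
#' @return Integer exit status, invisibly.
#' @name pipeline-jobs
NULL

#' @rdname pipeline-jobs
#' @export
cmd_download <- function(config, transport = entrez_transport()) {
  started <- Sys.time()
  res <- tryCatch({
    dl <- config$download
    req <- download_request(dl$search_key, dl$email, dl$api_key,
                            dl$max_records %||% 100L,
                            output_dir = config$genbank_dir)
    ids <- search_accessions(req, transport)
    paths <- if (length(ids)) fetch_genbank(ids, req, transport) else character(0)
    .log_step(config, "download", "success", started, paths,
              list(n_ids = length(ids), n_files = length(paths)))
    0L
  }, error = function(e) {
    message("download failed: ", conditionMessage(e))
    .log_step(config, "download", "error", started,
              details = list(error = conditionMessage(e)))
    1L
  })
  invisible(res)
}

#' @rdname pipeline-jobs
#' @export
cmd_validate <- function(config) {
  started <- Sys.time()
  res <- tryCatch({
    records <- read_genbank_dir(config$genbank_dir)
    if (!length(records)) stop("no genomes loaded from ", config$genbank_dir,
                               call. = FALSE)
    reports <- lapply(records, validate_record)
    routing <- vapply(reports, `[[`, "", "routing")
    rejected <- names(records)[routing == "rejected"]
    for (r in rejected) {
      warning("genome ", r, " rejected by validation", call. = FALSE)
    }
    accepted <- records[routing != "rejected"]
    if (!length(accepted)) stop("no genomes passed validation", call. = FALSE)

    td <- .tables_dir(config)
    dir.create(td, recursive = TRUE, showWarnings = FALSE)
    raw <- build_feature_table(records)
    arrow::write_parquet(raw, file.path(td, "genbank_df.parquet"))
    proc <- resolve_keys(build_feature_table(accepted),
                         reports[routing != "rejected"])
    arrow::write_parquet(proc, file.path(td, "processed_genbank_df.parquet"))
    genomes <- data.frame(
      genome_id = vapply(accepted, `[[`, "", "genome_id"),
      description = vapply(accepted, `[[`, "", "description"),
      length = vapply(accepted, `[[`, 1L, "length"),
      sequence = vapply(accepted, `[[`, "", "sequence"),
      stringsAsFactors = FALSE)
    arrow::write_parquet(genomes, file.path(td, "genomes.parquet"))

    check_summary <- lapply(reports, function(r) {
      list(genome_id = r$genome_id, routing = r$routing,
           failed = r$checks$check[r$checks$status == "fail"])
    })
    .log_step(config, "validate", "success", started,
              file.path(td, c("genbank_df.parquet", "processed_genbank_df.parquet",
                              "genomes.parquet")),
              list(n_accepted = length(accepted), rejected = rejected,
                   checks = check_summary))
    0L
  }, error = function(e) {
    message("validate failed: ", conditionMessage(e))
    .log_step(config, "validate", "error", started,
              details = list(error = conditionMessage(e)))
    1L
  })
  invisible(res)
}

#' @rdname pipeline-jobs
#' @export
cmd_blast <- function(config, mode = c("blastn", "blastp")) {
  mode <- match.arg(mode)
  started <- Sys.time()
  res <- tryCatch({
    td <- .tables_dir(config)
    proc_path <- file.path(td, "processed_genbank_df.parquet")
    if (!file.exists(proc_path)) {
      stop("missing ", proc_path, "; run the validate job first", call. = FALSE)
    }
    proc <- as.data.frame(arrow::read_parquet(proc_path))
    genomes <- as.data.frame(arrow::read_parquet(file.path(td, "genomes.parquet")))
    records <- lapply(seq_len(nrow(genomes)), function(i) {
      list(genome_id = genomes$genome_id[i], sequence = genomes$sequence[i])
    })
    genes <- extract_gene_sequences(proc, records)
    if (mode == "blastp") {
      genes <- translate_genes(genes, proc)
      genes <- genes[nzchar(genes$seq), , drop = FALSE]
      if (!nrow(genes)) stop("no translatable genes available for blastp",
                             call. = FALSE)
    }
    hits <- all_vs_all(genes, mode = mode, engine = config$engine,
                       evalue_max = config$evalue_threshold)
    best <- summarize_best_hits(hits)
    summary_path <- file.path(td, paste0(mode, "_summary.parquet"))
    arrow::write_parquet(best, summary_path)
    uniq <- build_uniqueness(best, proc)
    uniq_name <- if (mode == "blastn") "gene_uniqueness.parquet" else "protein_uniqueness.parquet"
    uniq_path <- file.path(td, uniq_name)
    arrow::write_parquet(uniq, uniq_path)
    .log_step(config, mode, "success", started, c(summary_path, uniq_path),
              list(n_genes = nrow(genes), n_raw_hits = nrow(hits),
                   n_best_hits = nrow(best), engine = config$engine))
    0L
  }, error = function(e) {
    message(mode, " failed: ", conditionMessage(e))
    .log_step(config, mode, "error", started,
              details = list(error = conditionMessage(e)))
    1L
  })
  invisible(res)
}

#' @rdname pipeline-jobs
#' @export
cmd_plot <- function(config, selection, out_base = NULL) {
  started <- Sys.time()
  res <- tryCatch({
    mode <- if (isTRUE(config$run_blastp) && !isTRUE(config$run_blastn)) "blastp" else "blastn"
    pc <- plot_config(
      title = config$plot$title %||% "Synteny plot",
      palette = config$plot$palette %||% default_palette("conservation"),
      gene_shape = config$plot$gene_shape %||% "arrow",
      output_formats = config$plot$output_formats %||% c("svg", "png"),
      min_link_identity = config$plot$min_link_identity %||% 0)
    job <- plot_job(config$data_dir, selection, mode = mode, config = pc,
                    out_base = out_base)
    .log_step(config, "plot", "success", started,
              c(job$plot_paths, job$colour_table_path),
              list(n_links = nrow(job$links), n_genes = nrow(job$colour_table)))
    0L
  }, error = function(e) {
    message("plot failed: ", conditionMessage(e))
    .log_step(config, "plot", "error", started,
              details = list(error = conditionMessage(e)))
    1L
  })
  invisible(res)
}

#' @rdname pipeline-jobs
#' @export
cmd_status <- function(config) {
  meta <- read_run_metadata(config)
  if (!length(meta)) {
    cat("no jobs have run in", config$data_dir, "\n")
    return(invisible(0L))
  }
  latest <- list()
  for (rec in meta) latest[[rec$step]] <- rec
  for (step in names(latest)) {
    rec <- latest[[step]]
    cat(sprintf("%-10s %-8s %s\n", step, rec$status, rec$finished))
  }
  invisible(0L)
}

#' Command-line entry point
#'
#' Dispatches `synteny-conserve <subcommand>` invocations:
#' `download | validate | blastn | blastp | plot | status | fixtures`.
#' Options: `--config PATH`, `--data-dir DIR`, `--genbank-dir DIR`,
#' `--engine builtin|external`, and for `plot`: `--selection CSV`,
#' `--title T`, `--format svg,png`, `--min-link-identity X`,
#' `--out BASE`; for `fixtures`: `--spec YAML`, `--out DIR`,
#' `--seed N`.
#'
#' @param args Character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    cat("usage: synteny-conserve <download|validate|blastn|blastp|plot|status|fixtures> [options]\n")
    return(invisible(if (length(args)) 0L else 2L))
  }
  cmd <- args[1L]
  opts <- .parse_cli_opts(args[-1L])
  cfg_args <- list(path = opts[["config"]])
  if (!is.null(opts[["data-dir"]])) cfg_args$data_dir <- opts[["data-dir"]]
  if (!is.null(opts[["genbank-dir"]])) cfg_args$genbank_dir <- opts[["genbank-dir"]]
  if (!is.null(opts[["engine"]])) cfg_args$engine <- opts[["engine"]]
  config <- do.call(run_config, cfg_args)

  status <- switch(cmd,
    download = cmd_download(config),
    validate = cmd_validate(config),
    blastn = cmd_blast(config, "blastn"),
    blastp = cmd_blast(config, "blastp"),
    status = cmd_status(config),
    plot = {
      if (is.null(opts[["selection"]])) {
        message("plot requires --selection CSV")
        2L
      } else {
        if (!is.null(opts[["title"]])) config$plot$title <- opts[["title"]]
        if (!is.null(opts[["format"]])) {
          config$plot$output_formats <- strsplit(opts[["format"]], ",")[[1L]]
        }
        if (!is.null(opts[["min-link-identity"]])) {
          config$plot$min_link_identity <- as.numeric(opts[["min-link-identity"]])
        }
        cmd_plot(config, opts[["selection"]], out_base = opts[["out"]])
      }
    },
    fixtures = {
      sp <- if (!is.null(opts[["spec"]])) {
        do.call(fixture_spec, yaml::read_yaml(opts[["spec"]]))
      } else {
        fixture_spec(n_genomes = 4L, seed = as.integer(opts[["seed"]] %||% "1"))
      }
      out <- opts[["out"]] %||% config$genbank_dir
      generate_genome_set(sp, out)
      cat("wrote fixture set to", out, "\n")
      0L
    },
    { message("unknown subcommand: ", cmd); 2L }
  )
  invisible(status)
}

.parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  opts
}
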