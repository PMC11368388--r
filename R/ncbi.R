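#' Describe an NCBI nucleotide download
#'
#' NCBI's Entrez API requires a valid email address; an API key (optional)
#' raises the permitted request rate from 3 to 10 per second. When
#' `api_key` is not given it is read from the `NCBI_API_KEY` environment
#' variable.
#'
#' @param search_key Entrez query, e.g.
#'   `'"Spbetavirus"[Organism] AND complete genome[Title] AND phage[Title]'`.
#' @param email Contact email (required by NCBI).
#' @param api_key Optional Entrez API key.
#' @param max_records Cap on returned accessions (default 100).
#' @param output_dir Directory receiving the `.gb` files.
#' @return A `download_request` object.
#' @export
download_request <- function(search_key, email, api_key = NULL,
                             max_records = 100L, output_dir = "genbank") {
  if (is.null(search_key) || !nzchar(search_key)) {
    stop("search_key must be non-empty", call. = FALSE)
  }
  if (is.null(email) || !grepl("^[^@[:space:]]+@[^@[:space:]]+\\.[^@[:space:]]+$", email)) {
    stop("a valid email address is required to use the NCBI Entrez API",
         call. = FALSE)
  }
  if (is.null(api_key) || !nzchar(api_key)) {
    env <- Sys.getenv("NCBI_API_KEY", "")
    api_key <- if (nzchar(env)) env else NULL
  }
  stopifnot(max_records > 0L)
  structure(list(search_key = search_key, email = email, api_key = api_key,
                 max_records = as.integer(max_records), output_dir = output_dir),
            class = "download_request")
}

#' Default Entrez HTTPS transport
#'
#' Returns a function of one URL that fetches the response body as a
#' single string. Tests inject mock transports instead; live calls go
#' through base R's libcurl connections.
#'
#' @param timeout Per-request timeout in seconds.
#' @return `function(url) -> character(1)`.
#' @export
entrez_transport <- function(timeout = 30) {
  force(timeout)
  function(url) {
    old <- options(timeout = timeout)
    on.exit(options(old), add = TRUE)
    con <- url(url, open = "rb")
    on.exit(close(con), add = TRUE)
    paste(readLines(con, warn = FALSE), collapse = "\n")
  }
}

.eutils <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"

.entrez_params <- function(req, extra) {
  p <- c(list(db = "nucleotide", email = req$email, tool = "phagesynteny"), extra)
  if (!is.null(req$api_key)) p$api_key <- req$api_key
  paste(names(p), vapply(p, function(v) utils::URLencode(as.character(v), reserved = TRUE), ""),
        sep = "=", collapse = "&")
}

.with_retries <- function(f, attempts = 3L, base_wait = 1) {
  for (a in seq_len(attempts)) {
    res <- tryCatch(f(), error = function(e) e)
    if (!inherits(res, "error")) return(res)
    if (a == attempts) stop(res)
    Sys.sleep(base_wait * 2^(a - 1L))
  }
}

#' Search NCBI nucleotide for accessions matching a query
#'
#' Runs an Entrez `esearch` (accession id type), capped at the request's
#' `max_records`, with 3 retry attempts under exponential backoff. An
#' empty result is a warning, not an error.
#'
#' @param req A [download_request()].
#' @param transport Transport function (see [entrez_transport()]);
#'   injectable for testing.
#' @return Character vector of accession ids in NCBI return order.
#' @export
search_accessions <- function(req, transport = entrez_transport()) {
  stopifnot(inherits(req, "download_request"))
  url <- paste0(.eutils, "/esearch.fcgi?",
                .entrez_params(req, list(term = req$search_key,
                                         retmax = req$max_records,
                                         idtype = "acc")))
  body <- .with_retries(function() transport(url))
  ids <- regmatches(body, gregexpr("<Id>[^<]+</Id>", body))[[1L]]
  ids <- gsub("</?Id>", "", ids)
  if (!length(ids)) {
    warning("Entrez search returned no records for: ", req$search_key)
    return(character(0))
  }
  utils::head(ids, req$max_records)
}

#' Fetch GenBank flat files for a set of accessions
#'
#' Runs Entrez `efetch` (`rettype=gb`, `retmode=text`) per accession and
#' writes `<accession>.gb` into the request's output directory. Existing
#' files are skipped unless `force`, making the download idempotent.
#' Requests are rate-limited to 3/s without an API key, 10/s with one.
#' Per-accession failures are warned and skipped; only total failure is an
#' error.
#'
#' @param ids Character vector of accession ids (non-empty).
#' @param req A [download_request()].
#' @param transport Transport function; injectable for testing.
#' @param force Re-download files that already exist.
#' @return Character vector of file paths (written or already present).
#' @export
fetch_genbank <- function(ids, req, transport = entrez_transport(), force = FALSE) {
  stopifnot(inherits(req, "download_request"))
  if (!length(ids)) stop("no accession ids to fetch", call. = FALSE)
  dir.create(req$output_dir, recursive = TRUE, showWarnings = FALSE)
  wait <- if (is.null(req$api_key)) 1 / 3 else 1 / 10
  paths <- character(0)
  failed <- character(0)
  for (id in ids) {
    dest <- file.path(req$output_dir, paste0(sub("\\.\\d+$", "", id), ".gb"))
    if (file.exists(dest) && !force) {
      paths <- c(paths, dest)
      next
    }
    url <- paste0(.eutils, "/efetch.fcgi?",
                  .entrez_params(req, list(id = id, rettype = "gb",
                                           retmode = "text")))
    body <- tryCatch(.with_retries(function() transport(url)),
                     error = function(e) e)
    if (inherits(body, "error") || !grepl("^LOCUS", body)) {
      warning("failed to fetch ", id, ": ",
              if (inherits(body, "error")) conditionMessage(body) else "not a GenBank record")
      failed <- c(failed, id)
    } else {
      writeLines(body, dest)
      paths <- c(paths, dest)
    }
    Sys.sleep(wait)
  }
  if (!length(paths)) {
    stop("all ", length(ids), " fetches failed", call. = FALSE)
  }
  paths
}
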