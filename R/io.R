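#' Read and write document corpora as JSON Lines
#'
#' One JSON object per line with fields `doc_id`, `chars` (the text as one
#' string), `mentions` (array of objects with `start`, `end`, `category`,
#' `time_attr`, `surface`; `null` when unannotated) and `cvd_label`
#' (`"positive"`, `"negative"` or `null`).  Files are UTF-8; the round
#' trip is lossless.
#'
#' @param docs List of [emr_document()] objects.
#' @param path File path.
#' @return `read_documents()` returns a list of documents;
#'   `write_documents()` returns `path` invisibly.
#' @export
write_documents <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    obj <- list(
      doc_id = d$doc_id,
      chars = paste(d$chars, collapse = ""),
      mentions = if (is.null(d$mentions)) NULL else lapply(d$mentions, function(m)
        list(start = m$start, end = m$end, category = m$category,
             time_attr = m$time_attr, surface = m$surface)),
      cvd_label = d$cvd_label
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE, sep = "\n")
  invisible(path)
}

#' @rdname write_documents
#' @export
read_documents <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(obj) || is.null(obj$doc_id) || is.null(obj$chars)) {
      stop("malformed document on line ", i, " of '", path, "'",
           call. = FALSE)
    }
    mentions <- if (is.null(obj$mentions)) NULL else
      lapply(obj$mentions, function(m)
        entity_mention(m$start, m$end, m$category, m$time_attr, m$surface))
    docs[[i]] <- emr_document(obj$doc_id, obj$chars, mentions,
                              obj$cvd_label)
  }
  docs
}

#' Read and write CoNLL-style tagged files
#'
#' Dialect: one character and one tag per line, tab-separated; a blank
#' line terminates each document.  UTF-8 throughout.
#'
#' @param tagged List of `list(chars =, tags =)` pairs (equal-length
#'   character vectors).
#' @param path File path.
#' @param vocab Tag vocabulary used to validate tags on read.
#' @return `read_conll()` returns a list of `list(chars, tags)`;
#'   `write_conll()` returns `path` invisibly.
#' @export
write_conll <- function(tagged, path) {
  out <- character(0)
  for (d in tagged) {
    stopifnot(length(d$chars) == length(d$tags))
    out <- c(out, paste(d$chars, d$tags, sep = "\t"), "")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' @rdname write_conll
#' @export
read_conll <- function(path, vocab = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  chars <- character(0); tags <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) {
      if (length(chars) > 0L) {
        docs[[length(docs) + 1L]] <- list(chars = chars, tags = tags)
        chars <- character(0); tags <- character(0)
      }
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !nzchar(parts[1L]) || !nzchar(parts[2L])) {
      stop("malformed CoNLL line ", i, " of '", path, "': '", ln, "'",
           call. = FALSE)
    }
    if (!is.null(vocab) && !parts[2L] %in% vocab$tags) {
      stop("unknown tag '", parts[2L], "' on line ", i, " of '", path, "'",
           call. = FALSE)
    }
    chars <- c(chars, parts[1L]); tags <- c(tags, parts[2L])
  }
  if (length(chars) > 0L) {
    docs[[length(docs) + 1L]] <- list(chars = chars, tags = tags)
  }
  docs
}
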