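#' Create a risk-factor entity mention
#'
#' A mention is a half-open, 0-based character span `[start, end)` of a
#' document, carrying a risk-factor category and a time attribute.
#'
#' @param start,end Integer character offsets, 0-based, half-open:
#'   `0 <= start < end`.
#' @param category Category code (see [risk_factor_categories()]).
#' @param time_attr Time-attribute code; must be admissible for the
#'   category (see [admissible_attributes()]).
#' @param surface The mention text, a string whose number of characters
#'   equals `end - start`.
#' @return An `entity_mention` object.
#' @export
entity_mention <- function(start, end, category, time_attr, surface) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid span: need 0 <= start < end, got [", start, ", ", end, ")",
         call. = FALSE)
  }
  if (!time_attr %in% admissible_attributes(category)) {
    stop("inadmissible pair: category '", category,
         "' does not take time attribute '", time_attr, "'", call. = FALSE)
  }
  if (nchar(surface) != end - start) {
    stop("surface '", surface, "' has ", nchar(surface),
         " characters but the span [", start, ", ", end, ") covers ",
         end - start, call. = FALSE)
  }
  structure(list(start = start, end = end, category = category,
                 time_attr = time_attr, surface = surface),
            class = "entity_mention")
}

#' Create an EMR document
#'
#' The unit of both pipeline stages: a character sequence, gold risk-factor
#' mentions (possibly empty; `NULL` when unannotated), and an optional
#' binary CVD label.
#'
#' @param doc_id Document identifier.
#' @param chars The text, either a single string (split into characters) or
#'   a character vector of single-character tokens.
#' @param mentions List of [entity_mention()] objects; `NULL` means the
#'   document carries no entity annotation at all.
#' @param cvd_label `"positive"`, `"negative"`, or `NULL` when unlabeled.
#' @return An `emr_document` object.
#' @export
emr_document <- function(doc_id, chars, mentions = list(), cvd_label = NULL) {
  if (length(chars) == 1L && nchar(chars[1L]) != 1L) {
    chars <- strsplit(chars, "", fixed = TRUE)[[1L]]
  }
  n <- length(chars)
  if (!is.null(cvd_label) && !cvd_label %in% c("positive", "negative")) {
    stop("cvd_label must be 'positive', 'negative' or NULL", call. = FALSE)
  }
  if (!is.null(mentions)) {
    mentions <- mentions[order(vapply(mentions, `[[`, 0L, "start"))]
    prev_end <- 0L
    for (m in mentions) {
      stopifnot(inherits(m, "entity_mention"))
      if (m$end > n) {
        stop("mention [", m$start, ", ", m$end, ") exceeds document length ",
             n, call. = FALSE)
      }
      if (m$start < prev_end) {
        stop("overlapping mentions at position ", m$start, call. = FALSE)
      }
      span_text <- paste(chars[(m$start + 1L):m$end], collapse = "")
      if (!identical(span_text, m$surface)) {
        stop("mention surface '", m$surface, "' does not match text '",
             span_text, "' at [", m$start, ", ", m$end, ")", call. = FALSE)
      }
      prev_end <- m$end
    }
  }
  structure(list(doc_id = as.character(doc_id), chars = chars,
                 mentions = mentions, cvd_label = cvd_label),
            class = "emr_document")
}

#' @export
print.emr_document <- function(x, ...) {
  cat("<emr_document> ", x$doc_id, ": ", length(x$chars), " chars, ",
      if (is.null(x$mentions)) "unannotated" else
        paste0(length(x$mentions), " mention(s)"),
      if (!is.null(x$cvd_label)) paste0(", CVD ", x$cvd_label) else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
print.entity_mention <- function(x, ...) {
  cat("<entity_mention> [", x$start, ", ", x$end, ") '", x$surface, "' ",
      x$category, "/", x$time_attr, "\n", sep = "")
  invisible(x)
}
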