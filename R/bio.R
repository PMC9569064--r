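#' Convert a document's mentions to a BIO tag sequence
#'
#' Each mention's first character receives the `B-` tag of its
#' (category, time attribute) pair, interior characters the matching `I-`
#' tag, and every other character `O`.
#'
#' @param doc An [emr_document()] with non-`NULL` mentions.
#' @param vocab A [build_tag_vocabulary()] vocabulary covering the
#'   mention pairs.
#' @return Character vector of tags, one per character.
#' @export
to_bio <- function(doc, vocab) {
  stopifnot(inherits(doc, "emr_document"), inherits(vocab, "tag_vocabulary"))
  if (is.null(doc$mentions)) {
    stop("document '", doc$doc_id, "' carries no mention annotation",
         call. = FALSE)
  }
  tags <- rep("O", length(doc$chars))
  for (m in doc$mentions) {
    b <- bio_tag(m$category, m$time_attr, "B")
    i <- bio_tag(m$category, m$time_attr, "I")
    if (!b %in% vocab$tags) {
      stop("pair ", m$category, "/", m$time_attr,
           " is not covered by the tag vocabulary", call. = FALSE)
    }
    tags[m$start + 1L] <- b
    if (m$end - m$start > 1L) tags[(m$start + 2L):m$end] <- i
  }
  tags
}

#' Recover entity mentions from a BIO tag sequence
#'
#' Maximal `B`-then-`I` runs of one (category, attribute) pair become
#' mentions.  Ill-formed sequences are repaired, never rejected: an `I-`
#' tag that does not continue a compatible run (no preceding tag, a
#' preceding `O`, or a run of a different pair) is promoted to `B-`
#' (IOB2 repair), so arbitrary model output always decodes.
#'
#' @param chars Character vector of the document's characters.
#' @param tags Character vector of tags, one per character, drawn from
#'   `vocab`.
#' @param vocab The tag vocabulary.
#' @return List of [entity_mention()] objects in document order.
#' @export
from_bio <- function(chars, tags, vocab) {
  stopifnot(length(chars) == length(tags))
  n <- length(tags)
  mentions <- list()
  cur <- NULL  # list(start, pair)
  flush <- function(end_pos) {
    if (is.null(cur)) return()
    surf <- paste(chars[(cur$start + 1L):end_pos], collapse = "")
    mentions[[length(mentions) + 1L]] <<- entity_mention(
      cur$start, end_pos, cur$category, cur$time_attr, surf)
    cur <<- NULL
  }
  for (t in seq_len(n)) {
    p <- parse_tag(tags[t], vocab)
    if (is.null(p)) {            # O
      flush(t - 1L)
      next
    }
    continues <- !is.null(cur) && p$prefix == "I" &&
      identical(cur$category, p$category) &&
      identical(cur$time_attr, p$time_attr)
    if (!continues) {            # B, or an I promoted to B by repair
      flush(t - 1L)
      cur <- list(start = t - 1L, category = p$category,
                  time_attr = p$time_attr)
    }
  }
  flush(n)
  mentions
}
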