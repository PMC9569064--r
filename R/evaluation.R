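#' F-score from precision and recall
#'
#' `F = 2 * P * R / (P + R)`, defined as 0 when `P + R = 0`.  Works on
#' the percent scale used throughout.
#'
#' @param P,R Precision and recall (non-negative, typically percent).
#' @return The F-score on the same scale.
#' @export
#' @examples
#' f_score(93.46, 92.73)  # 93.09...
f_score <- function(P, R) {
  stopifnot(P >= 0, R >= 0)
  if (P + R == 0) return(0)
  2 * P * R / (P + R)
}

#' Document-level classification metrics
#'
#' Accuracy, precision, recall and F on the percent scale.  Precision and
#' recall are support-weighted across the classes; F is computed from the
#' aggregated precision and recall via [f_score()].
#'
#' @param gold,pred Equal-length vectors of class labels.
#' @return A `metrics_report`: list with `A`, `P`, `R`, `F`, `averaging`,
#'   `per_class` (data frame with per-class precision/recall/F/support).
#' @export
classification_report <- function(gold, pred) {
  gold <- as.character(gold); pred <- as.character(pred)
  if (length(gold) != length(pred)) {
    stop("gold and predicted label vectors differ in length (",
         length(gold), " vs ", length(pred), ")", call. = FALSE)
  }
  classes <- sort(union(gold, pred))
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(gold == cl & pred == cl)
    fp <- sum(gold != cl & pred == cl)
    fn <- sum(gold == cl & pred != cl)
    p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    data.frame(class = cl, precision = p, recall = r, F = f_score(p, r),
               support = sum(gold == cl), stringsAsFactors = FALSE)
  }))
  w <- per$support / sum(per$support)
  P <- sum(w * per$precision)
  R <- sum(w * per$recall)
  structure(list(A = 100 * mean(gold == pred), P = P, R = R,
                 F = f_score(P, R), averaging = "weighted",
                 per_class = per),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> A %.2f  P %.2f  R %.2f  F %.2f (%s)\n",
              x$A, x$P, x$R, x$F, x$averaging))
  invisible(x)
}

mention_key <- function(m) {
  paste(m$start, m$end, m$category, m$time_attr, sep = "|")
}

#' Entity-level tagger metrics
#'
#' Micro-averaged precision/recall/F under the exact-match criterion: a
#' predicted mention counts as correct only when its span, category and
#' time attribute all equal a gold mention of the same document.
#'
#' @param gold,pred Per-document lists of mention lists (a single
#'   document's flat mention list is also accepted).
#' @return A `metrics_report` (accuracy is `NA`: it is undefined at the
#'   entity level).
#' @export
entity_report <- function(gold, pred) {
  wrap <- function(x) {
    if (length(x) > 0L && inherits(x[[1L]], "entity_mention")) list(x)
    else if (length(x) == 0L) list(x) else x
  }
  gold <- wrap(gold); pred <- wrap(pred)
  stopifnot(length(gold) == length(pred))
  tp <- 0L; n_gold <- 0L; n_pred <- 0L
  for (i in seq_along(gold)) {
    gk <- vapply(gold[[i]], mention_key, character(1))
    pk <- vapply(pred[[i]], mention_key, character(1))
    tp <- tp + length(intersect(gk, pk))
    n_gold <- n_gold + length(gk)
    n_pred <- n_pred + length(pk)
  }
  P <- if (n_pred > 0L) 100 * tp / n_pred else 0
  R <- if (n_gold > 0L) 100 * tp / n_gold else 0
  structure(list(A = NA_real_, P = P, R = R, F = f_score(P, R),
                 averaging = "micro",
                 per_class = NULL, tp = tp, n_gold = n_gold,
                 n_pred = n_pred),
            class = "metrics_report")
}

#' Export attention weights as a heatmap-ready table
#'
#' Writes one row per risk factor: `doc_id`, `factor_index`,
#' `factor_surface`, then the per-character-position attention weights
#' `a1..aM` (rows from shorter documents are right-padded with `NA`).
#' Each row's weights sum to 1.
#'
#' @param records List of `attention_record` objects (fields `doc_id`,
#'   `factor_index`, `surface`, `weights`).
#' @param path Output TSV path.
#' @return `read_attention()` returns the records (weights restored,
#'   padding removed); `export_attention()` returns `path` invisibly.
#' @export
export_attention <- function(records, path) {
  stopifnot(length(records) > 0L)
  M <- max(vapply(records, function(r) length(r$weights), 0L))
  header <- c("doc_id", "factor_index", "factor_surface",
              paste0("a", seq_len(M)))
  rows <- vapply(records, function(r) {
    w <- c(r$weights, rep(NA_real_, M - length(r$weights)))
    ws <- ifelse(is.na(w), "NA", sprintf("%.17g", w))
    paste(c(r$doc_id, r$factor_index, r$surface, ws), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"), rows), con)
  invisible(path)
}

#' @rdname export_attention
#' @export
read_attention <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(doc_id = "character",
                                          factor_surface = "character"))
  lapply(seq_len(nrow(tab)), function(i) {
    w <- as.numeric(unlist(tab[i, -(1:3)], use.names = FALSE))
    structure(list(doc_id = tab$doc_id[i],
                   factor_index = tab$factor_index[i],
                   surface = tab$factor_surface[i],
                   weights = w[!is.na(w)]),
              class = "attention_record")
  })
}
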