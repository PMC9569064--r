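#' Build the BIO tag vocabulary over (category, time attribute) pairs
#'
#' Constructs the ordered tag set used by the sequence tagger: the outside
#' tag `O` first, then for each category (in the given order) and each of
#' its admissible time attributes, a `B-` (begin) and `I-` (inside) tag.
#' Tag strings follow the `B-<CatShort><AttrLetter>` convention, e.g.
#' `B-HyC` for the first character of a hypertension mention with the
#' Continue attribute.  For the full 12-category inventory this yields
#' 2 * (10 * 4 + 2 * 1) + 1 = 85 tags.
#'
#' @param categories Character vector of category codes (default: the full
#'   inventory from [risk_factor_categories()]).
#' @param attribute_rule Function mapping a category code to its admissible
#'   attribute codes (default: [admissible_attributes()]).
#' @return A `tag_vocabulary`: list with `tags` (ordered character vector)
#'   and `index` (named integer map tag -> position).
#' @export
#' @examples
#' v <- build_tag_vocabulary()
#' length(v$tags)  # 85
build_tag_vocabulary <- function(categories = risk_factor_categories()$code,
                                 attribute_rule = admissible_attributes) {
  stopifnot(length(categories) >= 1L)
  dup <- unique(categories[duplicated(categories)])
  if (length(dup) > 0L) {
    stop("duplicate category codes: '", paste(dup, collapse = "', '"), "'",
         call. = FALSE)
  }
  tags <- "O"
  pairs <- list()
  for (cat in categories) {
    for (att in attribute_rule(cat)) {
      lab <- paste0(category_short(cat), attr_letter(att))
      tags <- c(tags, paste0("B-", lab), paste0("I-", lab))
      pairs[[lab]] <- c(category = cat, time_attr = att)
    }
  }
  structure(
    list(tags = tags,
         index = stats::setNames(seq_along(tags), tags),
         pairs = pairs),
    class = "tag_vocabulary"
  )
}

#' @export
print.tag_vocabulary <- function(x, ...) {
  cat("<tag_vocabulary> ", length(x$tags), " tags (",
      length(x$pairs), " category/attribute pairs)\n", sep = "")
  invisible(x)
}

#' Tag string for a (category, time attribute) pair
#'
#' @param category,time_attr Codes of the pair.
#' @param prefix `"B"` or `"I"`.
#' @return The tag string, e.g. `"B-HyC"`.
#' @export
bio_tag <- function(category, time_attr, prefix = c("B", "I")) {
  prefix <- match.arg(prefix)
  if (!time_attr %in% admissible_attributes(category)) {
    stop("inadmissible pair: category '", category,
         "' does not take time attribute '", time_attr, "'", call. = FALSE)
  }
  paste0(prefix, "-", category_short(category), attr_letter(time_attr))
}

# decompose a non-O tag into list(prefix, category, time_attr); NULL for "O"
parse_tag <- function(tag, vocab) {
  if (tag == "O") return(NULL)
  lab <- sub("^[BI]-", "", tag)
  pair <- vocab$pairs[[lab]]
  if (is.null(pair)) {
    stop("tag '", tag, "' is not in the vocabulary", call. = FALSE)
  }
  list(prefix = substr(tag, 1L, 1L),
       category = unname(pair["category"]),
       time_attr = unname(pair["time_attr"]))
}
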