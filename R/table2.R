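#' Reference counts of risk-factor mentions by time attribute
#'
#' The tabulated distribution of risk-factor mentions over time attributes
#' in the annotated reference corpus, shipped as a plain-text fixture.
#' Counts are per category for Before/During/After/Continue (relative to
#' the duration of the hospital stay); Age and Gender carry a single
#' `None` count.  Each concatenated printed row admits exactly one split
#' into four counts summing to the printed total (no leading zeros on
#' multi-digit counts), which is what the fixture stores.
#'
#' @return An `attribute_count_table`: data frame with columns `category`,
#'   `Before`, `During`, `After`, `Continue`, `None`, `Total`.
#' @export
#' @examples
#' tab <- table2_fixture()
#' table2_total(tab, "Hypertension")  # 3729
table2_fixture <- function() {
  path <- system.file("extdata", "table2_attribute_counts.tsv",
                      package = "rfab", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(tab) <- c("attribute_count_table", "data.frame")
  tab
}

#' @rdname table2_fixture
#' @param table An `attribute_count_table`.
#' @param category A category code.
#' @return `table2_total()` returns the category's total mention count,
#'   recomputed as the sum of its attribute counts.
#' @export
table2_total <- function(table, category) {
  i <- match(category, table$category)
  if (is.na(i)) {
    stop("unknown risk-factor category: '", category, "'", call. = FALSE)
  }
  counts <- unlist(table[i, c("Before", "During", "After", "Continue",
                              "None")])
  total <- sum(counts, na.rm = TRUE)
  if (!is.na(table$Total[i]) && total != table$Total[i]) {
    stop("attribute counts for '", category, "' sum to ", total,
         " but the stored total is ", table$Total[i], call. = FALSE)
  }
  unname(total)
}
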