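#' The twelve cardiovascular risk-factor categories
#'
#' The inventory of clinical attributes whose textual mentions drive CVD
#' prediction: overweight/obesity (O2), hypertension, diabetes,
#' dyslipidemia, chronic kidney disease (CKD), atherosis, obstructive sleep
#' apnea syndrome (OSAS), smoking, alcohol abuse (A2), family history of
#' CVD (FHCVD), age and gender.
#'
#' @return A data frame with columns `code`, `short` (the two-character
#'   abbreviation used in tag strings) and `description`.
#' @export
#' @examples
#' risk_factor_categories()
risk_factor_categories <- function() {
  data.frame(
    code = c("O2", "Hypertension", "Diabetes", "Dyslipidemia", "CKD",
             "Atherosis", "OSAS", "Smoking", "A2", "FHCVD", "Age", "Gender"),
    short = c("O2", "Hy", "Di", "Dy", "CK", "At", "OS", "Sm", "A2", "FH",
              "Ag", "Ge"),
    description = c(
      "Overweight or obesity",
      "Diagnosis or history of hypertension",
      "Diagnosis or history of diabetes",
      "Dyslipidemia or hyperlipidemia",
      "Chronic kidney disease",
      "Atherosclerosis or atherosclerotic plaque",
      "Obstructive sleep apnea syndrome",
      "Smoking or history of smoking",
      "Alcohol abuse",
      "Family history of CVD",
      "Age of the patient",
      "Gender of the patient"),
    stringsAsFactors = FALSE
  )
}

#' Time attributes of a risk-factor mention
#'
#' Temporal relation of a mention to the duration of the hospital stay:
#' `Before`, `During`, `After`, `Continue` (always accompanying the
#' patient), or `None` for the two categories (Age, Gender) that carry no
#' temporal information.
#'
#' @return Character vector of the five attribute codes, with the
#'   single-letter abbreviations used in tag strings as names.
#' @export
time_attributes <- function() {
  c(B = "Before", D = "During", A = "After", C = "Continue", N = "None")
}

#' Admissible time attributes for a category
#'
#' Age and Gender admit only `None`; every other category admits the four
#' temporal attributes.
#'
#' @param category A category code from [risk_factor_categories()].
#' @return Character vector of admissible attribute codes.
#' @export
admissible_attributes <- function(category) {
  stopifnot(length(category) == 1L)
  inv <- risk_factor_categories()
  if (!category %in% inv$code) {
    stop("unknown risk-factor category: '", category, "'", call. = FALSE)
  }
  if (category %in% c("Age", "Gender")) "None"
  else c("Before", "During", "After", "Continue")
}

# two-letter category code for tag strings, e.g. Hypertension -> "Hy"
category_short <- function(category) {
  inv <- risk_factor_categories()
  i <- match(category, inv$code)
  if (anyNA(i)) {
    stop("unknown risk-factor category: '",
         paste(category[is.na(i)], collapse = "', '"), "'", call. = FALSE)
  }
  inv$short[i]
}

# single-letter attribute code, e.g. Continue -> "C"
attr_letter <- function(attr) {
  ab <- time_attributes()
  i <- match(attr, ab)
  if (anyNA(i)) {
    stop("unknown time attribute: '",
         paste(attr[is.na(i)], collapse = "', '"), "'", call. = FALSE)
  }
  names(ab)[i]
}
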