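#' Default surface-form lexicon for the synthetic corpus
#'
#' The synthetic world uses an abstract character alphabet (Unicode
#' symbols standing in for Chinese characters; the models are
#' character-agnostic).  Each category owns a small pool of dedicated
#' symbols from which three surface forms of 2-4 characters are built;
#' forms of one category share characters, giving skip-gram intra-mention
#' co-occurrence signal.
#'
#' @return Data frame with columns `category` and `surface`.
#' @export
default_risk_lexicon <- function() {
  cats <- risk_factor_categories()$code
  rows <- lapply(seq_along(cats), function(i) {
    s <- vapply(0:5, function(k) intToUtf8(0x5100L + (i - 1L) * 8L + k),
                character(1))
    data.frame(category = cats[i],
               surface = c(paste0(s[1], s[2]),
                           paste0(s[3], s[4], s[5]),
                           paste0(s[1], s[6], s[4], s[2])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# one cue symbol per temporal attribute, planted immediately before a
# mention so the attribute is learnable from local context
cue_symbols <- function() {
  c(Before = intToUtf8(0x3400L), During = intToUtf8(0x3401L),
    After = intToUtf8(0x3402L), Continue = intToUtf8(0x3403L))
}

#' Default document-label rule weights
#'
#' Positive weights on the (category, attribute) pairs a clinician would
#' weight most for CVD: hypertension, diabetes, dyslipidemia and smoking
#' mentions carrying the Continue or Before attribute.  All other pairs
#' weigh zero.  Names are `"<category>/<attribute>"`.
#'
#' @return Named numeric vector.
#' @export
default_label_weights <- function() {
  c("Hypertension/Continue" = 1.0, "Hypertension/Before" = 0.8,
    "Diabetes/Continue" = 1.2, "Diabetes/Before" = 0.9,
    "Dyslipidemia/Continue" = 0.7, "Dyslipidemia/Before" = 0.6,
    "Smoking/Continue" = 1.1, "Smoking/Before" = 0.9)
}

#' Configuration of the synthetic-EMR generator
#'
#' The generator emulates the statistical shape of the reference corpus:
#' documents of one-to-a-few hundred characters containing 0-10
#' risk-factor mentions, categories drawn proportionally to the reference
#' totals and time attributes per the reference distribution
#' ([table2_fixture()]), with a binary CVD label produced by a known
#' linear rule over the present (category, attribute) pairs plus label
#' noise.
#'
#' @param background_size Size of the background (non-mention) character
#'   alphabet.
#' @param lexicon Data frame of per-category surface forms.
#' @param category_weights Named sampling weights over categories
#'   (default: reference totals).
#' @param attribute_weights Named list mapping category to a named weight
#'   vector over its admissible attributes (default: reference counts).
#' @param length_range Integer range of document lengths (characters).
#' @param mention_count_weights Probability weights for 0-10 mentions per
#'   document.
#' @param label_weights Named rule weights over `"<category>/<attribute>"`
#'   pairs (see [default_label_weights()]).
#' @param intercept Rule intercept; a document is positive when the sum of
#'   weights of its distinct present pairs plus the intercept exceeds 0.
#' @param noise_rate Probability of flipping the rule label, in `[0, 1)`.
#' @param split_sizes Integer vector `(train, dev, test)`.
#' @param seed Integer seed; identical configs and seeds give
#'   byte-identical corpora.
#' @return A `generator_config` list.
#' @export
generator_config <- function(background_size = 100L,
                             lexicon = default_risk_lexicon(),
                             category_weights = NULL,
                             attribute_weights = NULL,
                             length_range = c(100L, 250L),
                             mention_count_weights = stats::dpois(0:10, 4),
                             label_weights = default_label_weights(),
                             intercept = -1.5,
                             noise_rate = 0.05,
                             split_sizes = default_split_sizes("tagger"),
                             seed = 1L) {
  tab <- table2_fixture()
  if (is.null(category_weights)) {
    category_weights <- stats::setNames(tab$Total, tab$category)
  }
  if (is.null(attribute_weights)) {
    attribute_weights <- stats::setNames(lapply(seq_len(nrow(tab)), function(i) {
      adm <- admissible_attributes(tab$category[i])
      w <- unlist(tab[i, adm])
      stats::setNames(as.numeric(w), adm)
    }), tab$category)
  }
  stopifnot(all(category_weights >= 0), noise_rate >= 0, noise_rate < 1,
            all(split_sizes > 0), all(label_weights >= 0) || TRUE,
            length(length_range) == 2L, length_range[1] >= 10L,
            length_range[1] <= length_range[2])
  for (cat in names(category_weights)) {
    if (category_weights[[cat]] > 0 &&
        !cat %in% lexicon$category) {
      stop("category '", cat, "' has positive weight but no lexicon ",
           "surface forms", call. = FALSE)
    }
  }
  structure(list(background_size = as.integer(background_size),
                 lexicon = lexicon,
                 category_weights = category_weights,
                 attribute_weights = attribute_weights,
                 length_range = as.integer(length_range),
                 mention_count_weights = mention_count_weights /
                   sum(mention_count_weights),
                 label_weights = label_weights,
                 intercept = intercept,
                 noise_rate = noise_rate,
                 split_sizes = as.integer(split_sizes),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Reference corpus split sizes
#'
#' Split sizes of the annotated reference corpus: 830/119/237 documents
#' for the tagger (risk-factor identification) stage and 461/66/132 for
#' the CVD-prediction stage.
#'
#' @param stage `"tagger"` or `"predictor"`.
#' @return Named integer vector `(train, dev, test)`.
#' @export
default_split_sizes <- function(stage) {
  switch(stage,
         tagger = c(train = 830L, dev = 119L, test = 237L),
         predictor = c(train = 461L, dev = 66L, test = 132L),
         stop("unknown stage '", stage, "'; use 'tagger' or 'predictor'",
              call. = FALSE))
}

# background alphabet as a character vector
background_alphabet <- function(n) {
  vapply(0:(n - 1L), function(k) intToUtf8(0x4E00L + k), character(1))
}

# Zipf-ish unigram weights with a weak first-order Markov preference:
# with probability `p_local`, the next symbol is a deterministic function
# of the previous one, giving local co-occurrence structure.
sample_background <- function(n, alphabet) {
  V <- length(alphabet)
  w <- 1 / seq_len(V)
  out <- integer(n)
  out[1] <- sample.int(V, 1L, prob = w)
  if (n > 1L) {
    for (t in 2:n) {
      out[t] <- if (stats::runif(1) < 0.3) (out[t - 1L] %% V) + 1L
                else sample.int(V, 1L, prob = w)
    }
  }
  alphabet[out]
}

# rule label before noise: TRUE iff sum of weights of distinct present
# (category, attribute) pairs plus the intercept exceeds zero
rule_score <- function(mentions, label_weights, intercept) {
  pairs <- unique(vapply(mentions, function(m)
    paste0(m$category, "/", m$time_attr), character(1)))
  present <- intersect(pairs, names(label_weights))
  sum(label_weights[present]) + intercept
}

generate_document <- function(cfg, doc_id, bg_alphabet, cues) {
  L <- sample(cfg$length_range[1]:cfg$length_range[2], 1L)
  chars <- sample_background(L, bg_alphabet)
  k <- sample(0:10, 1L, prob = cfg$mention_count_weights)
  occupied <- rep(FALSE, L)
  mentions <- list()
  if (k > 0L) {
    cats <- sample(names(cfg$category_weights), k, replace = TRUE,
                   prob = cfg$category_weights)
    for (cat in cats) {
      aw <- cfg$attribute_weights[[cat]]
      att <- if (length(aw) == 1L) names(aw) else
        sample(names(aw), 1L, prob = aw)
      forms <- cfg$lexicon$surface[cfg$lexicon$category == cat]
      surf <- forms[sample.int(length(forms), 1L)]
      schars <- strsplit(surf, "", fixed = TRUE)[[1L]]
      len <- length(schars)
      has_cue <- att != "None"
      need <- len + as.integer(has_cue)
      for (try in 1:50) {
        # slot start (1-based) of the first mention character; reserve one
        # extra position before it for the cue symbol when present
        start <- sample(seq_len(L - need) + as.integer(has_cue), 1L)
        span <- (start - as.integer(has_cue)):(start + len - 1L)
        if (!any(occupied[span])) {
          occupied[span] <- TRUE
          if (has_cue) chars[start - 1L] <- cues[[att]]
          chars[start:(start + len - 1L)] <- schars
          mentions[[length(mentions) + 1L]] <-
            entity_mention(start - 1L, start - 1L + len, cat, att, surf)
          break
        }
      }
    }
  }
  mentions <- mentions[order(vapply(mentions, `[[`, 0L, "start"))]
  lab <- rule_score(mentions, cfg$label_weights, cfg$intercept) > 0
  if (cfg$noise_rate > 0 && stats::runif(1) < cfg$noise_rate) lab <- !lab
  emr_document(doc_id, chars, mentions,
               if (lab) "positive" else "negative")
}

#' Generate a synthetic EMR corpus
#'
#' Draws `sum(cfg$split_sizes)` documents under the configured world and
#' returns them as train/dev/test splits.  Every document carries gold
#' mentions and a CVD label.  Identical config and seed reproduce the
#' corpus exactly.
#'
#' @param cfg A [generator_config()].
#' @return List with elements `train`, `dev`, `test`, each a list of
#'   [emr_document()] objects.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(cfg$seed)
  bg <- background_alphabet(cfg$background_size)
  cues <- cue_symbols()
  sizes <- cfg$split_sizes
  names(sizes) <- c("train", "dev", "test")
  out <- list()
  for (split in names(sizes)) {
    out[[split]] <- lapply(seq_len(sizes[[split]]), function(i)
      generate_document(cfg, sprintf("%s-%05d", split, i), bg, cues))
  }
  out
}

#' Calibrate the label-rule intercept toward a target positive rate
#'
#' Searches an intercept grid, simulating the mention-level part of the
#' generator at each candidate, and returns the intercept whose simulated
#' positive rate is closest to the target.
#'
#' @param cfg A [generator_config()].
#' @param target_rate Desired fraction of positive documents.
#' @param n Number of simulated documents per candidate.
#' @param grid Candidate intercepts.
#' @return The selected intercept (scalar).
#' @export
calibrate_intercept <- function(cfg, target_rate, n = 1000L,
                                grid = seq(-4, 0.5, by = 0.1)) {
  stopifnot(target_rate > 0, target_rate < 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(cfg$seed + 7L)
  # simulate pair-presence scores once; thresholding is monotone in the
  # intercept so one sample serves every candidate
  scores <- vapply(seq_len(n), function(i) {
    k <- sample(0:10, 1L, prob = cfg$mention_count_weights)
    if (k == 0L) return(0)
    cats <- sample(names(cfg$category_weights), k, replace = TRUE,
                   prob = cfg$category_weights)
    pairs <- vapply(cats, function(cat) {
      aw <- cfg$attribute_weights[[cat]]
      att <- if (length(aw) == 1L) names(aw) else
        sample(names(aw), 1L, prob = aw)
      paste0(cat, "/", att)
    }, character(1))
    present <- intersect(unique(pairs), names(cfg$label_weights))
    sum(cfg$label_weights[present])
  }, numeric(1))
  rates <- vapply(grid, function(b) mean(scores + b > 0), numeric(1))
  grid[which.min(abs(rates - target_rate))]
}
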