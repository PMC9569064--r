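test_that("reference split sizes", {
  expect_identical(unname(default_split_sizes("tagger")),
                   c(830L, 119L, 237L))
  expect_identical(unname(default_split_sizes("predictor")),
                   c(461L, 66L, 132L))
  expect_equal(sum(default_split_sizes("tagger")), 1186L)
  expect_error(default_split_sizes("embedding"), "unknown stage")
})

test_that("attribute count fixture reproduces printed totals", {
  tab <- table2_fixture()
  expect_equal(table2_total(tab, "Hypertension"), 3729)
  expect_equal(405 + 1909 + 10 + 1405, 3729)
  expect_equal(table2_total(tab, "O2"), 18)
  expect_equal(table2_total(tab, "Age"), 1859)
  # every row's counts sum to its stored total
  for (cat in tab$category) {
    expect_equal(table2_total(tab, cat), tab$Total[tab$category == cat])
  }
  expect_error(table2_total(tab, "Gout"), "unknown")
})

test_that("same config and seed give identical corpora", {
  cfg <- small_world(seed = 9L)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  # and byte-identical on disk
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_documents(c1$train, p1); write_documents(c2$train, p2)
  expect_identical(readLines(p1, warn = FALSE), readLines(p2, warn = FALSE))
})

test_that("generated documents satisfy all invariants", {
  co <- generate_corpus(small_world(seed = 21L))
  for (d in c(co$train, co$dev, co$test)) {
    expect_s3_class(d, "emr_document")   # constructor enforces invariants
    expect_true(d$cvd_label %in% c("positive", "negative"))
    n <- length(d$chars)
    ends <- 0L
    for (m in d$mentions) {
      expect_true(m$start >= ends)       # sorted, non-overlapping
      expect_true(m$end <= n)
      expect_identical(paste(d$chars[(m$start + 1):m$end], collapse = ""),
                       m$surface)
      ends <- m$end
    }
  }
})

test_that("degenerate label rules behave as stated", {
  base <- small_world(seed = 3L)
  # zero weights, intercept below threshold, no noise -> all negative
  cfg <- generator_config(label_weights = c("Hypertension/Continue" = 0),
                          intercept = -1, noise_rate = 0,
                          split_sizes = c(25L, 5L, 5L),
                          length_range = base$length_range, seed = 3L)
  co <- generate_corpus(cfg)
  expect_true(all(vapply(co$train, `[[`, "", "cvd_label") == "negative"))

  # intercept above threshold -> all positive
  cfg2 <- generator_config(label_weights = c("Hypertension/Continue" = 0),
                           intercept = 1, noise_rate = 0,
                           split_sizes = c(25L, 5L, 5L),
                           length_range = base$length_range, seed = 3L)
  co2 <- generate_corpus(cfg2)
  expect_true(all(vapply(co2$train, `[[`, "", "cvd_label") == "positive"))
})

test_that("empty lexicon for a positively weighted category is rejected", {
  lex <- default_risk_lexicon()
  expect_error(
    generator_config(lexicon = lex[lex$category != "Hypertension", ]),
    "Hypertension.*no lexicon")
})

test_that("attribute frequencies track the configured weights", {
  # sample many mentions; empirical per-attribute frequencies for the
  # temporal categories must sit within 3 standard errors of expectation
  cfg <- generator_config(split_sizes = c(400L, 5L, 5L),
                          length_range = c(60L, 100L), seed = 17L)
  co <- generate_corpus(cfg)
  mention_attrs <- list()
  for (d in co$train) for (m in d$mentions) {
    mention_attrs[[length(mention_attrs) + 1L]] <- c(m$category, m$time_attr)
  }
  tab <- do.call(rbind, mention_attrs)
  expect_gt(nrow(tab), 1000L)
  for (cat in c("Hypertension", "Diabetes", "Smoking")) {
    sub <- tab[tab[, 1L] == cat, 2L]
    n <- length(sub)
    w <- cfg$attribute_weights[[cat]]
    p <- w / sum(w)
    for (att in names(p)) {
      if (p[[att]] == 0) {
        expect_equal(sum(sub == att), 0L)
      } else {
        se <- sqrt(p[[att]] * (1 - p[[att]]) / n)
        expect_lt(abs(mean(sub == att) - p[[att]]), 3 * se + 1e-9)
      }
    }
  }
})

test_that("class balance is steerable via intercept search", {
  cfg <- generator_config(split_sizes = c(250L, 5L, 5L),
                          length_range = c(60L, 100L), seed = 23L)
  b <- calibrate_intercept(cfg, target_rate = 0.5, n = 1000L)
  cfg2 <- generator_config(split_sizes = c(1000L, 5L, 5L),
                           length_range = c(60L, 100L),
                           intercept = b, noise_rate = 0, seed = 29L)
  co <- generate_corpus(cfg2)
  rate <- mean(vapply(co$train, `[[`, "", "cvd_label") == "positive")
  expect_lt(abs(rate - 0.5), 0.05)
})

test_that("label rule is recoverable from gold pair indicators", {
  # noise-free world: logistic regression on (category, attribute)
  # presence indicators must reach F >= 0.95 -- the pipeline's ceiling
  cfg <- generator_config(split_sizes = c(300L, 5L, 100L),
                          length_range = c(60L, 100L),
                          noise_rate = 0, seed = 31L)
  co <- generate_corpus(cfg)
  feats <- function(docs) {
    keys <- names(cfg$label_weights)
    X <- t(vapply(docs, function(d) {
      present <- unique(vapply(d$mentions, function(m)
        paste0(m$category, "/", m$time_attr), character(1)))
      as.numeric(keys %in% present)
    }, numeric(length(keys))))
    colnames(X) <- paste0("x", seq_along(keys))
    X
  }
  y_tr <- as.integer(vapply(co$train, `[[`, "", "cvd_label") == "positive")
  fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(),
               data = data.frame(y = y_tr, feats(co$train))))
  p <- stats::predict(fit, newdata = data.frame(feats(co$test)),
                      type = "response")
  pred <- ifelse(p > 0.5, "positive", "negative")
  gold <- vapply(co$test, `[[`, "", "cvd_label")
  expect_gte(classification_report(gold, pred)$F, 95)
})
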