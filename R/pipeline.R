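#' Pipeline configuration
#'
#' Reads a YAML file (or takes a list) and fills defaults for every
#' stage.  Top-level keys: `outdir`, `seed`, and optional `generator`,
#' `embedding`, `tagger`, `rfab` blocks overriding the corresponding
#' constructor defaults.
#'
#' @param config Path to a YAML file, or a list.
#' @param seed Optional seed overriding the config's.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(outdir = "rfab-run", seed = 1L,
         generator = list(), embedding = list(), tagger = list(),
         rfab = list()),
    config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$outdir <- NULL   # hash the scientific config, not where it is written
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

stage_path <- function(cfg, ...) file.path(cfg$outdir, ...)

require_artifact <- function(cfg, path, producer) {
  if (!file.exists(path)) {
    stop("missing artifact '", path, "'; run stage '", producer,
         "' first", call. = FALSE)
  }
  path
}

write_stage_log <- function(cfg, stage, extra = list()) {
  log <- c(list(stage = stage, seed = cfg$seed, config_hash = config_hash(cfg)),
           extra)
  jsonlite::write_json(log, stage_path(cfg, paste0(stage, "_log.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Stages (in dependency order): `generate` (synthetic corpora for both
#' pipeline stages), `embed` (skip-gram pretraining), `train-tagger`,
#' `extract` (apply the tagger to the predictor corpora), `train-rfab`,
#' `predict` (end-to-end on the predictor test split), `evaluate`
#' (metrics JSON), `visualize` (attention TSV).  Every stage writes its
#' artifacts plus a run log (seed, config hash, headline numbers) under
#' `cfg$outdir`, and is a pure function of (config, seed, upstream
#' artifacts).
#'
#' @param stage Stage name, or `"all"`.
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the path(s) of the stage's main artifact.
#' @export
run_stage <- function(stage, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- c("generate", "embed", "train-tagger", "extract", "train-rfab",
              "predict", "evaluate", "visualize")
  if (identical(stage, "all")) {
    for (s in stages) run_stage(s, cfg)
    return(invisible(stage_path(cfg, "metrics.json")))
  }
  if (!stage %in% stages) {
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(stages, collapse = ", "), call. = FALSE)
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
         "generate" = stage_generate(cfg),
         "embed" = stage_embed(cfg),
         "train-tagger" = stage_train_tagger(cfg),
         "extract" = stage_extract(cfg),
         "train-rfab" = stage_train_rfab(cfg),
         "predict" = stage_predict(cfg),
         "evaluate" = stage_evaluate(cfg),
         "visualize" = stage_visualize(cfg))
}

stage_generate <- function(cfg) {
  g <- cfg$generator
  tagger_sizes <- g$tagger_split_sizes %||% default_split_sizes("tagger")
  pred_sizes <- g$predictor_split_sizes %||% default_split_sizes("predictor")
  base <- g[setdiff(names(g), c("tagger_split_sizes",
                                "predictor_split_sizes"))]
  gc1 <- do.call(generator_config,
                 c(base, list(split_sizes = tagger_sizes, seed = cfg$seed)))
  gc2 <- do.call(generator_config,
                 c(base, list(split_sizes = pred_sizes,
                              seed = cfg$seed + 1L)))
  tag <- generate_corpus(gc1)
  prd <- generate_corpus(gc2)
  for (s in names(tag)) {
    write_documents(tag[[s]], stage_path(cfg, paste0("tagger_", s, ".jsonl")))
  }
  for (s in names(prd)) {
    write_documents(prd[[s]],
                    stage_path(cfg, paste0("predictor_", s, ".jsonl")))
  }
  write_stage_log(cfg, "generate",
                  list(tagger_sizes = unname(tagger_sizes),
                       predictor_sizes = unname(pred_sizes)))
  invisible(stage_path(cfg, "tagger_train.jsonl"))
}

stage_embed <- function(cfg) {
  p1 <- require_artifact(cfg, stage_path(cfg, "tagger_train.jsonl"),
                         "generate")
  p2 <- require_artifact(cfg, stage_path(cfg, "predictor_train.jsonl"),
                         "generate")
  corpus <- c(read_documents(p1), read_documents(p2))
  e <- cfg$embedding
  tab <- train_char_embeddings(
    corpus, risk_lexicon = default_risk_lexicon(),
    dim = e$dim %||% 100L, window = e$window %||% 5L,
    negatives = e$negatives %||% 5L, epochs = e$epochs %||% 5L,
    seed = cfg$seed)
  save_embeddings(tab, stage_path(cfg, "embeddings.txt"))
  write_stage_log(cfg, "embed", list(n_chars = ncol(tab$vectors),
                                     dim = tab$dim))
  invisible(stage_path(cfg, "embeddings.txt"))
}

stage_train_tagger <- function(cfg) {
  emb <- load_embeddings(require_artifact(
    cfg, stage_path(cfg, "embeddings.txt"), "embed"))
  train <- read_documents(require_artifact(
    cfg, stage_path(cfg, "tagger_train.jsonl"), "generate"))
  dev <- read_documents(stage_path(cfg, "tagger_dev.jsonl"))
  t <- cfg$tagger
  tc <- tagger_config(embedding_dim = emb$dim,
                      hidden = t$hidden %||% 256L,
                      lr = t$lr %||% 1e-3,
                      batch_size = t$batch_size %||% 10L,
                      epochs = t$epochs %||% 60L,
                      dropout = t$dropout %||% 0.5,
                      seed = cfg$seed)
  model <- train_tagger(train, dev, tc, emb)
  save_tagger(model, stage_path(cfg, "tagger.rds"))
  test <- read_documents(stage_path(cfg, "tagger_test.jsonl"))
  rep <- entity_report(lapply(test, `[[`, "mentions"),
                       lapply(test, extract_risk_factors, model = model))
  write_stage_log(cfg, "train-tagger",
                  list(dev_f = max(model$history$dev_f),
                       test_entity_f = rep$F))
  invisible(stage_path(cfg, "tagger.rds"))
}

stage_extract <- function(cfg) {
  model <- load_tagger(require_artifact(cfg, stage_path(cfg, "tagger.rds"),
                                        "train-tagger"))
  outs <- character(0)
  for (s in c("train", "dev", "test")) {
    docs <- read_documents(require_artifact(
      cfg, stage_path(cfg, paste0("predictor_", s, ".jsonl")), "generate"))
    extracted <- lapply(docs, function(d) {
      emr_document(d$doc_id, d$chars, extract_risk_factors(d, model),
                   d$cvd_label)
    })
    out <- stage_path(cfg, paste0("extracted_", s, ".jsonl"))
    write_documents(extracted, out)
    outs <- c(outs, out)
  }
  write_stage_log(cfg, "extract")
  invisible(outs)
}

stage_train_rfab <- function(cfg) {
  emb <- load_embeddings(require_artifact(
    cfg, stage_path(cfg, "embeddings.txt"), "embed"))
  train <- read_documents(require_artifact(
    cfg, stage_path(cfg, "extracted_train.jsonl"), "extract"))
  dev <- read_documents(require_artifact(
    cfg, stage_path(cfg, "extracted_dev.jsonl"), "extract"))
  r <- cfg$rfab
  rc <- rfab_config(embedding_dim = emb$dim,
                    hidden = r$hidden %||% 256L,
                    lr = r$lr %||% 1e-3,
                    batch_size = r$batch_size %||% 10L,
                    epochs = r$epochs %||% 60L,
                    dropout = r$dropout %||% 0.5,
                    use_attention = r$use_attention %||% TRUE,
                    use_labels = r$use_labels %||% TRUE,
                    seed = cfg$seed)
  model <- train_rfab(train, dev, rc, emb)
  save_rfab(model, stage_path(cfg, "rfab.rds"))
  write_stage_log(cfg, "train-rfab", list(dev_f = max(model$history$dev_f)))
  invisible(stage_path(cfg, "rfab.rds"))
}

stage_predict <- function(cfg) {
  tagger <- load_tagger(require_artifact(
    cfg, stage_path(cfg, "tagger.rds"), "train-tagger"))
  model <- load_rfab(require_artifact(cfg, stage_path(cfg, "rfab.rds"),
                                      "train-rfab"))
  docs <- read_documents(require_artifact(
    cfg, stage_path(cfg, "predictor_test.jsonl"), "generate"))
  lines <- vapply(docs, function(d) {
    out <- predict_document(d, tagger, model)
    jsonlite::toJSON(list(doc_id = d$doc_id,
                          label = out$prediction$label,
                          probabilities =
                            as.list(out$prediction$probabilities)),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, stage_path(cfg, "predictions.jsonl"))
  write_stage_log(cfg, "predict", list(n = length(docs)))
  invisible(stage_path(cfg, "predictions.jsonl"))
}

stage_evaluate <- function(cfg) {
  docs <- read_documents(require_artifact(
    cfg, stage_path(cfg, "predictor_test.jsonl"), "generate"))
  pred_lines <- readLines(require_artifact(
    cfg, stage_path(cfg, "predictions.jsonl"), "predict"), warn = FALSE)
  preds <- lapply(pred_lines, jsonlite::fromJSON)
  pred_map <- stats::setNames(vapply(preds, `[[`, "", "label"),
                              vapply(preds, `[[`, "", "doc_id"))
  gold <- vapply(docs, `[[`, "", "cvd_label")
  pred <- unname(pred_map[vapply(docs, `[[`, "", "doc_id")])
  rep <- classification_report(gold, pred)
  jsonlite::write_json(list(A = rep$A, P = rep$P, R = rep$R, F = rep$F,
                            seed = cfg$seed,
                            config_hash = config_hash(cfg)),
                       stage_path(cfg, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_stage_log(cfg, "evaluate", list(F = rep$F))
  invisible(stage_path(cfg, "metrics.json"))
}

stage_visualize <- function(cfg) {
  tagger <- load_tagger(require_artifact(
    cfg, stage_path(cfg, "tagger.rds"), "train-tagger"))
  model <- load_rfab(require_artifact(cfg, stage_path(cfg, "rfab.rds"),
                                      "train-rfab"))
  docs <- read_documents(require_artifact(
    cfg, stage_path(cfg, "predictor_test.jsonl"), "generate"))
  recs <- list()
  for (d in docs) {
    out <- predict_document(d, tagger, model)
    recs <- c(recs, out$attention)
    if (length(recs) >= 20L) break
  }
  if (length(recs) == 0L) {
    # no-attention variant: nothing to visualise
    writeLines("doc_id\tfactor_index\tfactor_surface",
               stage_path(cfg, "attention.tsv"))
  } else {
    export_attention(recs, stage_path(cfg, "attention.tsv"))
  }
  write_stage_log(cfg, "visualize", list(n_records = length(recs)))
  invisible(stage_path(cfg, "attention.tsv"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
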