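# rfab — risk-factor attention for CVD prediction from clinical text

`rfab` implements a two-stage pipeline that predicts cardiovascular
disease (CVD) from character-level electronic medical record (EMR)
text, for researchers in clinical NLP who want a fully inspectable,
dependency-light reference implementation:

1. **Risk-factor identification** — a BiLSTM-CRF sequence tagger labels
   every character with a BIO tag over (category × time-attribute)
   pairs.  Twelve risk-factor categories are covered (overweight/
   obesity, hypertension, diabetes, dyslipidemia, CKD, atherosis, OSAS,
   smoking, alcohol abuse, family history of CVD, age, gender); ten of
   them carry a temporal attribute relative to the hospital stay
   (*Before*, *During*, *After*, *Continue*), age and gender carry
   *None*, giving an 85-tag vocabulary.  The linear-chain CRF scores a
   tag path `y` as

   `s(X, y) = Σᵢ T[yᵢ, yᵢ₊₁] + Σᵢ P[i, yᵢ]`

   with emissions `P` from the BiLSTM (`eₜ = tanh(Wₑ hₜ)`) and learned
   transitions `T`; training maximises `log p(y_gold | X)` exactly and
   decoding is Viterbi.
2. **CVD prediction (RFAB)** — a character BiLSTM encodes the whole
   record; each extracted risk factor (its surface embedding plus
   learned category/time-attribute label embeddings) attends over the
   character encodings with softmax-normalised dot products; a second
   BiLSTM, initialised from the first one's final states, encodes the
   attended vectors, and the final representation is mapped through
   `sigmoid` + `softmax` to a binary CVD label, trained with
   cross-entropy and Adagrad.

The original corpora are private, so the package ships a first-class
synthetic-EMR generator whose documents carry gold mentions (with the
reference attribute distribution) and a CVD label produced by a known
linear rule — everything needed to train, evaluate and ablate the
pipeline offline.  Character embeddings are pretrained with skip-gram,
augmented with the risk-factor dictionary.

## Worked example

```r
library(rfab)

# a small synthetic world: 150 training, 30 dev, 40 test documents
cfg <- generator_config(split_sizes = c(150, 30, 40),
                        length_range = c(50, 100), seed = 7)
corpus <- generate_corpus(cfg)
corpus$train[[1]]
#> <emr_document> train-00001: 91 chars, 5 mention(s), CVD positive

emb <- train_char_embeddings(corpus$train, default_risk_lexicon(),
                             dim = 50, epochs = 8, lexicon_repeats = 20,
                             seed = 7)
tc <- tagger_config(embedding_dim = 50, hidden = 32, epochs = 24,
                    lr = 0.08, dropout = 0.2, batch_size = 5,
                    warmup_steps = 150, seed = 7)
tagger <- train_tagger(corpus$train, corpus$dev, tc, emb)

rep <- entity_report(lapply(corpus$test, `[[`, "mentions"),
                     lapply(corpus$test, extract_risk_factors,
                            model = tagger))
rep
#> <metrics_report> A NA  P 96.79  R 89.88  F 93.21 (micro)

extract_risk_factors(corpus$test[[1]], tagger)[[1]]
#> <entity_mention> [10, 14) '儈儍儋儉' Hypertension/During
```

`P`, `R`, `F` are percent-scale precision/recall/F under the
exact-match criterion: a predicted mention counts only if its span,
category and time attribute all agree with gold (the `[10, 14)` span
above is a four-character hypertension mention carrying the During
attribute).  At the larger scale used in
`tests/testthat/test-acceptance.R` the tagger's held-out entity-F
reaches 91–97 (median 94) over three seeds; the document classifier's
end-to-end F lands in the mid 80s there, short of the 90 bar that test
asserts — see the methods vignette on why the synthetic world favours
the no-attention route.

The full pipeline (generate → embed → train-tagger → extract →
train-rfab → predict → evaluate → visualize) runs from the command
line:

```sh
Rscript inst/cli/rfab.R all --config my_run.yaml --seed 1
Rscript inst/cli/rfab.R train-rfab --config my_run.yaml --variant no-att
```

Every stage writes versioned artifacts plus a JSON run log (seed,
config hash, headline metrics) under the configured output directory;
identical config + seed reproduces every artifact byte-for-byte.

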