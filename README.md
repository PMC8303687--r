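# flavorlex

Flavor-descriptor extraction from free-text product reviews with a
dual-branch LSTM.

## What it does

Sensory scientists build *lexicons* — vocabularies of flavor, aroma and
mouthfeel descriptors for a product category — traditionally through
expensive Descriptive Analysis panels. Thousands of whisky reviews
already contain that vocabulary, interleaved with ordinary prose.
**flavorlex** implements the complete pipeline for mining it:

1. **Corpus preparation** — read review CSVs, tokenise into POS-tagged
   sentences via a pluggable (deterministic) tagging provider, and rank
   candidate lemmas (nouns, adjectives, whitelisted verbs) by frequency.
2. **Annotation logic** — frequency-prioritised annotation queues
   (pages of ≤ 50 lemmas), two-of-three annotator consensus, and
   projection of lemma labels onto every surface token type ("fruit"
   labels "fruity" and "fruits").
3. **Sequence building** — locate every corpus occurrence of each
   labelled type, extract the `n = 3` words before and after within the
   sentence (zero-vector PAD at sentence edges), look the tokens up in a
   GloVe-format embedding table, and split 80/20 at the instance level.
4. **The classifier** — two unidirectional LSTMs (256 units), one over
   the 2n-step context sequence and one over the target word, each
   followed by a 128-unit dense layer; concatenated and funnelled
   through decreasing dense layers (64, 32) into a binary softmax.
   Trained with Adam (lr 1e-4), cross entropy, batch size 32, 3 epochs,
   20% validation — implemented natively in R over BLAS, with exact
   backpropagation through time (no deep-learning framework required).
5. **Evaluation** — accuracy / precision / recall / F1 with the
   descriptor as positive class, the field's noun/adjective POS
   baseline on the identical test partition, learning curves in 5%
   increments, divergence-based stopping-epoch detection, and 2-D
   embedding projections.
6. **Synthetic data** — a generator producing embedding clusters of
   controllable separation, labelled corpora of controllable descriptor
   density, context-dependent "ambiguous" words, and style-contrasted
   sub-corpora, so the whole pipeline is testable end to end with exact
   gold labels.
7. **Lexicon extraction** — per-review descriptor lists with
   probabilities, threshold-filtered and deduplicated.

## Worked example

```r
library(flavorlex)

cfg <- synth_config(n_reviews = 150, embedding_dim = 16,
                    n_descriptor_types = 30, n_nondescriptor_types = 40,
                    n_function_words = 15, seed = 7)
sim <- simulate_study(cfg)
sim$examples
#> <descriptor_examples> 4270 instances, context 2n = 6, embedding dim 16, 42.7% descriptor

sp  <- split_examples(sim$examples, 0.2, seed = 1)
fit <- descriptor_lstm(sp$train, lstm_units = 32, branch_dense_units = 16,
                       head_layout = c(12, 6), learning_rate = 1e-3,
                       epochs = 3, seed = 1)

compute_metrics(sp$test$label, predict(fit, sp$test, type = "class"))
#> accuracy 1.0000 | precision 1.0000 | recall 1.0000 | F1 1.0000  (n = 854)
#> confusion: TP 358  FP 0  FN 0  TN 496

compute_metrics(sp$test$label, pos_baseline_predict(sp$test$instances))
#> accuracy 0.8560 | precision 0.7443 | recall 1.0000 | F1 0.8534  (n = 854)
#> confusion: TP 358  FP 123  FN 0  TN 373

head(extract_lexicon(fit, sim$space$store, sim$reviews[1, ],
                     rule_tagger(sim$space$dictionary), threshold = 0.5), 3)
#>     token probability
#> 1 desc021   1.0000000
#> 2 desc016   1.0000000
#> 3 desc006   0.9999976
```

The fitted model beats the POS baseline because non-descriptor nouns
and adjectives exist in every corpus: tagging all of them as
descriptors costs the baseline precision, while the LSTM uses the
embedding geometry and the context window. On well-separated synthetic
embeddings the classifier reaches the same ~99% held-out accuracy
reported for real annotated whisky reviews.

A command-line wrapper over the same functions lives in
`inst/cli/flavorlex.R` (subcommands `simulate`, `prepare`, `queue`,
`merge`, `train`, `eval`, `lexicon`).

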