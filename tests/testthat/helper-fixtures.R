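# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A small but non-trivial synthetic study: ~2k instances, well-separated
# clusters.
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_reviews = 80, embedding_dim = 12, n_descriptor_types = 25,
         n_nondescriptor_types = 30, n_function_words = 12, seed = 101),
    list(...))
  do.call(synth_config, args)
}

tiny_study <- function() memo("tiny_study", function() {
  simulate_study(tiny_cfg())
})

tiny_split <- function() memo("tiny_split", function() {
  split_examples(tiny_study()$examples, 0.2, seed = 7)
})

# A small model trained hard enough to separate the tiny study's
# clusters.
tiny_model <- function() memo("tiny_model", function() {
  descriptor_lstm(tiny_split()$train, lstm_units = 16,
                  branch_dense_units = 8, head_layout = c(6, 4),
                  learning_rate = 1e-3, epochs = 3, seed = 42)
})

# A toy embedding store with known vectors.
toy_store <- function(d = 4L) {
  v <- rbind(sweet = seq_len(d) / 10,
             oak = -seq_len(d) / 10,
             vanilla = rep(1, d))
  embedding_store(v)
}

# Brute-force slice-and-pad oracle for context extraction.
naive_context <- function(sentence, pos0, n) {
  p <- pos0 + 1L
  before <- vapply(seq(p - n, p - 1L), function(i) {
    if (i >= 1L) sentence[i] else PAD_TOKEN
  }, "")
  after <- vapply(seq(p + 1L, p + n), function(i) {
    if (i <= length(sentence)) sentence[i] else PAD_TOKEN
  }, "")
  list(before = before, after = after)
}

# Brute-force metrics tally.
naive_metrics <- function(truth, pred) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = (tp + tn) / length(truth), precision = prec,
       recall = rec, f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn)
}
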