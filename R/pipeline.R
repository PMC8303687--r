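#' Run a full descriptor-classification experiment
#'
#' End-to-end protocol: tag the corpus, index labelled instances, build
#' context-window examples, split 80/20 at instance level, train the
#' dual-branch LSTM, and evaluate both the LSTM and the noun/adjective
#' POS baseline on the identical held-out test partition.
#'
#' @param reviews Review data frame ([read_reviews()] or
#'   [generate_corpus()]).
#' @param labels Either a token-type label table (columns `token_type`,
#'   `label`, e.g. from [project_labels_to_tokens()]) or a per-token
#'   gold table (columns `review_id`, `sentence_index`, `position`,
#'   `token`, `label`, e.g. from [generate_corpus()]).
#' @param store An `"embedding_store"`.
#' @param tagger Tagging provider; default [rule_tagger()].
#' @param n Context window size per side; default 3.
#' @param test_fraction Held-out fraction; default 0.2.
#' @param split_seed Seed for the train/test split; default 1.
#' @param split_level `"instance"` (default) or `"type"`; see
#'   [split_examples()].
#' @param ... Model hyperparameters forwarded to [model_config()]
#'   (`embedding_dim`/`context_length` are derived).
#' @return Object of class `"experiment_report"`: config snapshot,
#'   dataset summary (instance counts, class ratio, embedding-lookup
#'   stats, train/test type overlap), training history, LSTM metrics,
#'   POS-baseline metrics (same test partition), recommended stopping
#'   epoch, and the fitted model.
#' @export
run_experiment <- function(reviews, labels, store,
                           tagger = rule_tagger(), n = 3L,
                           test_fraction = 0.2, split_seed = 1L,
                           split_level = c("instance", "type"), ...) {
  split_level <- match.arg(split_level)
  tokens <- tag_corpus(reviews, tagger)
  gold_like <- all(c("review_id", "sentence_index", "position",
                     "token", "label") %in% names(labels))
  instances <- if (gold_like) {
    index_instances_gold(tokens, labels)
  } else if (all(c("token_type", "label") %in% names(labels))) {
    index_instances(tokens, labels)
  } else {
    stop_fl("labels must be a token-type table or a per-token gold table",
            class = "flavorlex_validation_error")
  }
  if (length(unique(instances$label)) < 2L) {
    stop_fl("experiment stage 'index': labels cover fewer than 2 classes",
            class = "flavorlex_validation_error")
  }
  reset_lookup_stats(store)
  examples <- assemble_examples(tokens, instances, store, n = n)
  lookups <- lookup_stats(store)
  sp <- split_examples(examples, test_fraction, seed = split_seed,
                       level = split_level)
  cfg <- model_config(embedding_dim = store$dimension,
                      context_length = 2L * n, ...)
  model <- train_model(build_model(cfg), sp$train)
  prob <- predict(model, sp$test, type = "prob")
  pred <- classify(prob, 0.5)
  metrics_lstm <- compute_metrics(sp$test$label, pred)
  metrics_pos <- compute_metrics(
    sp$test$label, pos_baseline_predict(sp$test$instances))
  rec <- if (cfg$epochs >= 2L) detect_divergence_epoch(model) else
    cfg$epochs
  structure(
    list(
      config = cfg,
      dataset = list(
        n_instances = length(examples$label),
        n_train = length(sp$train$label),
        n_test = length(sp$test$label),
        n_validation = model$n_val,
        class_ratio = class_ratio(examples),
        lookups = lookups,
        oov_rate = unname(lookups["oov"] / sum(lookups)),
        type_overlap = type_overlap_fraction(sp$train, sp$test)
      ),
      history = model$history,
      metrics_lstm = metrics_lstm,
      metrics_pos = metrics_pos,
      recommended_epoch = rec,
      model = model,
      split = list(test_fraction = test_fraction, seed = split_seed,
                   level = split_level)
    ),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  d <- x$dataset
  cat("Descriptor-classification experiment\n")
  cat(sprintf(
    "  instances: %d (train %d / test %d; validation %d); %.1f%% descriptor\n",
    d$n_instances, d$n_train, d$n_test, d$n_validation,
    100 * d$class_ratio["descriptor"]))
  cat(sprintf("  OOV lookup rate: %.3f%%; train/test type overlap: %.3f\n",
              100 * d$oov_rate, d$type_overlap))
  cat("  LSTM: ")
  print(x$metrics_lstm)
  cat("  POS baseline: ")
  print(x$metrics_pos)
  cat("  recommended stopping epoch:", x$recommended_epoch, "\n")
  invisible(x)
}

#' Serialise an experiment report (without the model weights) to JSON
#'
#' @param report An `"experiment_report"`.
#' @param path Optional output path.
#' @return JSON string (invisibly if written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  x <- list(
    config = unclass(report$config),
    dataset = report$dataset,
    history = report$history,
    metrics_lstm = unclass(report$metrics_lstm)[
      c("accuracy", "precision", "recall", "f1", "confusion", "n")],
    metrics_pos = unclass(report$metrics_pos)[
      c("accuracy", "precision", "recall", "f1", "confusion", "n")],
    recommended_epoch = report$recommended_epoch,
    split = report$split
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Extract a per-review descriptor lexicon
#'
#' Scores every non-punctuation token of one review through its context
#' window, keeps token types whose descriptor probability reaches the
#' threshold, case-folds and deduplicates (keeping each type's maximum
#' probability), and returns them sorted by probability descending.
#' Threshold 0 is a no-op filter: every token type is returned; raising
#' the threshold only ever removes types.
#'
#' @param model A trained `"descriptor_model"`.
#' @param store The `"embedding_store"` used in training.
#' @param review A list or one-row data frame with `review_id` and
#'   `text`.
#' @param tagger Tagging provider (the same preprocessing as training:
#'   punctuation removed, stop words kept).
#' @param threshold Minimum descriptor probability, in \[0, 1\];
#'   default 0.5.
#' @param n Context window size per side; must match training.
#'   Default 3.
#' @return data.frame with columns `token` and `probability`, sorted by
#'   probability descending (ties alphabetically).
#' @export
extract_lexicon <- function(model, store, review,
                            tagger = rule_tagger(), threshold = 0.5,
                            n = 3L) {
  stopifnot(inherits(model, "descriptor_model"))
  if (!isTRUE(model$trained)) {
    stop_fl("refusing to extract a lexicon with an untrained model",
            class = "flavorlex_untrained_error")
  }
  assert_scalar_number(threshold, "threshold", 0, 1)
  tokens <- segment_and_tag(review, tagger)
  nonp <- tokens[tokens$pos != "PUNCT", , drop = FALSE]
  if (!nrow(nonp)) {
    return(data.frame(token = character(), probability = numeric()))
  }
  instances <- data.frame(
    token_type = tolower(nonp$surface),
    review_id = nonp$review_id,
    sentence_index = nonp$sentence_index,
    filtered_position = nonp$filtered_position,
    pos = nonp$pos,
    label = 0L,  # unknown; scoring only
    stringsAsFactors = FALSE
  )
  examples <- assemble_examples(tokens, instances, store, n = n)
  prob <- predict(model, examples, type = "prob")
  best <- tapply(prob, instances$token_type, max)
  out <- data.frame(token = names(best), probability = as.numeric(best),
                    stringsAsFactors = FALSE)
  out <- out[out$probability >= threshold, , drop = FALSE]
  out <- out[order(-out$probability, out$token), , drop = FALSE]
  rownames(out) <- NULL
  out
}
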