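#' Index every corpus occurrence of the labelled token types
#'
#' Scans the tagged corpus for occurrences of each labelled surface type
#' (case-folded comparison, punctuation excluded) and records an
#' instance per occurrence, addressed by (review, sentence, filtered
#' position). Labels are inherited from the token type. Output order is
#' deterministic: corpus order by (review order, sentence, position).
#'
#' @param tokens Tagged corpus ([tag_corpus()] output).
#' @param labeled_types data.frame with columns `token_type` and `label`
#'   ([project_labels_to_tokens()] output).
#' @return data.frame with columns `token_type`, `review_id`,
#'   `sentence_index`, `filtered_position`, `pos`, `label`.
#' @export
index_instances <- function(tokens, labeled_types) {
  nonp <- tokens[tokens$pos != "PUNCT", , drop = FALSE]
  tt <- tolower(nonp$surface)
  idx <- match(tt, labeled_types$token_type)
  hit <- !is.na(idx)
  out <- data.frame(
    token_type = tt[hit],
    review_id = nonp$review_id[hit],
    sentence_index = nonp$sentence_index[hit],
    filtered_position = nonp$filtered_position[hit],
    pos = nonp$pos[hit],
    label = as.integer(labeled_types$label[idx[hit]]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Build instances directly from per-token gold labels
#'
#' Synthetic corpora carry a gold label for every non-punctuation token
#' (including context-dependent words whose label varies between
#' occurrences), so instances are joined by address rather than
#' inherited from a type-level table.
#'
#' @param tokens Tagged corpus ([tag_corpus()] output).
#' @param gold data.frame with columns `review_id`, `sentence_index`,
#'   `position` (filtered), `token`, `label` (as emitted by
#'   [generate_corpus()]).
#' @return Instance data frame in the same shape as [index_instances()].
#' @export
index_instances_gold <- function(tokens, gold) {
  nonp <- tokens[tokens$pos != "PUNCT", , drop = FALSE]
  key_tok <- paste(nonp$review_id, nonp$sentence_index,
                   nonp$filtered_position, sep = "\r")
  key_gold <- paste(gold$review_id, gold$sentence_index, gold$position,
                    sep = "\r")
  idx <- match(key_tok, key_gold)
  hit <- !is.na(idx)
  if (any(tolower(nonp$surface[hit]) != tolower(gold$token[idx[hit]]))) {
    stop_fl("gold labels disagree with the tagged corpus at some address",
            class = "flavorlex_internal_error")
  }
  out <- data.frame(
    token_type = tolower(nonp$surface[hit]),
    review_id = nonp$review_id[hit],
    sentence_index = nonp$sentence_index[hit],
    filtered_position = nonp$filtered_position[hit],
    pos = nonp$pos[hit],
    label = as.integer(gold$label[idx[hit]]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Extract the n-before / n-after context of a word within its sentence
#'
#' Context never crosses sentence boundaries: positions falling outside
#' the sentence are filled with the PAD sentinel. Both sides are
#' returned in natural left-to-right reading order, with `before`
#' left-padded and `after` right-padded to exactly `n` entries.
#'
#' @param sentence Character vector: the sentence's non-punctuation
#'   tokens in order.
#' @param position 0-based position of the target word within
#'   `sentence` (i.e. its filtered position).
#' @param n Context size per side; default 3.
#' @return list with character vectors `before` and `after`, each of
#'   length `n`.
#' @examples
#' extract_context(c("rich", "sweet", "vanilla", "cream"), position = 0, n = 3)
#' @export
extract_context <- function(sentence, position, n = 3L) {
  n <- assert_count(n, "n")
  k <- length(sentence)
  if (!is.numeric(position) || length(position) != 1L ||
      position < 0L || position >= k) {
    stop_fl("position ", position, " out of range for sentence of length ", k,
            class = "flavorlex_index_error")
  }
  p <- as.integer(position) + 1L  # to 1-based
  before <- if (p > 1L) sentence[max(1L, p - n):(p - 1L)] else character()
  after <- if (p < k) sentence[(p + 1L):min(k, p + n)] else character()
  list(
    before = c(rep(PAD_TOKEN, n - length(before)), before),
    after = c(after, rep(PAD_TOKEN, n - length(after)))
  )
}

#' Assemble model-ready sequence examples from token instances
#'
#' For every instance, looks up the word vector and the `2n` context
#' vectors (before-context then after-context, each in reading order,
#' PAD mapped to zeros) in the embedding store. The result is the
#' dataset consumed by [descriptor_lstm()]: a `(N, 2n, d)` context
#' array, an `(N, d)` word matrix, the binary labels, and the instance
#' provenance table.
#'
#' @param tokens Tagged corpus ([tag_corpus()] output); punctuation is
#'   dropped and stop words retained when computing context positions.
#' @param instances Instance table ([index_instances()] or
#'   [index_instances_gold()]).
#' @param store An `"embedding_store"`.
#' @param n Context size per side; default 3.
#' @return Object of class `"descriptor_examples"`.
#' @export
assemble_examples <- function(tokens, instances, store, n = 3L) {
  n <- assert_count(n, "n")
  stopifnot(inherits(store, "embedding_store"))
  nonp <- tokens[tokens$pos != "PUNCT", , drop = FALSE]
  sent_key <- paste(nonp$review_id, nonp$sentence_index, sep = "\r")
  sentences <- split(nonp$surface, sent_key)
  N <- nrow(instances)
  tok_mat <- matrix(PAD_TOKEN, nrow = N, ncol = 2L * n + 1L)
  inst_key <- paste(instances$review_id, instances$sentence_index, sep = "\r")
  sent_of <- sentences[inst_key]
  for (i in seq_len(N)) {
    s <- sent_of[[i]]
    ctx <- extract_context(s, instances$filtered_position[i], n)
    tok_mat[i, ] <- c(ctx$before, ctx$after,
                      s[instances$filtered_position[i] + 1L])
  }
  flat <- vector_for(store, as.vector(tok_mat))
  d <- store$dimension
  # as.vector(tok_mat) runs down columns: element (i, j) is row i + (j-1)N
  all_vec <- array(flat, dim = c(N, 2L * n + 1L, d))
  structure(
    list(context = all_vec[, seq_len(2L * n), , drop = FALSE],
         word = matrix(all_vec[, 2L * n + 1L, ], nrow = N, ncol = d),
         label = as.integer(instances$label),
         instances = instances,
         n = n, d = d),
    class = "descriptor_examples"
  )
}

#' @export
print.descriptor_examples <- function(x, ...) {
  cat("<descriptor_examples> ", length(x$label), " instances, context 2n = ",
      dim(x$context)[2], ", embedding dim ", x$d, ", ",
      round(100 * mean(x$label), 1), "% descriptor\n", sep = "")
  invisible(x)
}

#' Subset sequence examples by instance index
#'
#' @param x A `"descriptor_examples"` object.
#' @param i Integer or logical index over instances.
#' @param ... Ignored.
#' @export
`[.descriptor_examples` <- function(x, i, ...) {
  structure(
    list(context = x$context[i, , , drop = FALSE],
         word = x$word[i, , drop = FALSE],
         label = x$label[i],
         instances = x$instances[i, , drop = FALSE],
         n = x$n, d = x$d),
    class = "descriptor_examples"
  )
}

#' @export
length.descriptor_examples <- function(x) length(x$label)

#' Instance-level train/test split
#'
#' Partitions individual occurrences (not word types) into train and
#' test sets: the protocol records each occurrence's exact location, so
#' two occurrences of the same word may land on opposite sides of the
#' split. The split is seeded and reproducible; `|test| =
#' round(test_fraction * N)`. A `"type"` level is also offered for
#' sensitivity analysis: it partitions word types, so no type is shared
#' between train and test.
#'
#' @param examples A `"descriptor_examples"` object.
#' @param test_fraction Fraction held out for testing, in (0, 1);
#'   default 0.2 (the 80/20 convention).
#' @param seed Integer RNG seed.
#' @param level `"instance"` (default) or `"type"`.
#' @return list with elements `train` and `test`
#'   (`"descriptor_examples"` each).
#' @export
split_examples <- function(examples, test_fraction = 0.2, seed = 1L,
                           level = c("instance", "type")) {
  level <- match.arg(level)
  assert_scalar_number(test_fraction, "test_fraction", 0, 1,
                       open_lower = TRUE, open_upper = TRUE)
  N <- length(examples$label)
  if (N < 2L) {
    stop_fl("need at least 2 examples to split",
            class = "flavorlex_validation_error")
  }
  if (level == "instance") {
    n_test <- round(test_fraction * N)
    test_idx <- with_seed(seed, sample.int(N, n_test))
  } else {
    types <- unique(examples$instances$token_type)
    n_test_types <- round(test_fraction * length(types))
    test_types <- with_seed(seed, sample(types, n_test_types))
    test_idx <- which(examples$instances$token_type %in% test_types)
  }
  train_idx <- setdiff(seq_len(N), test_idx)
  list(train = examples[train_idx], test = examples[sort(test_idx)])
}

#' Fraction of word types shared between two example sets
#'
#' Diagnostic for the instance-level split: occurrences of a word type
#' may appear in both partitions, which makes the test easier than a
#' type-level split would be. Reports the fraction of test-set types
#' also present in the training set.
#'
#' @param train,test `"descriptor_examples"` objects.
#' @return Scalar in \[0, 1\].
#' @export
type_overlap_fraction <- function(train, test) {
  tt <- unique(test$instances$token_type)
  if (!length(tt)) return(0)
  mean(tt %in% unique(train$instances$token_type))
}

#' Class balance of an example set
#'
#' @param examples A `"descriptor_examples"` object (or an integer 0/1
#'   label vector).
#' @return Named numeric vector `c(descriptor = ..., non_descriptor =
#'   ...)`, summing to 1.
#' @export
class_ratio <- function(examples) {
  labels <- if (inherits(examples, "descriptor_examples")) {
    examples$label
  } else {
    examples
  }
  if (!length(labels)) {
    stop_fl("cannot compute a class ratio for an empty example set",
            class = "flavorlex_validation_error")
  }
  p <- mean(labels == 1L)
  c(descriptor = p, non_descriptor = 1 - p)
}

#' Write the instance bookkeeping table to CSV
#'
#' Columns `token_type`, `review_id`, `sentence_index`, `position`,
#' `label` — the per-occurrence record that makes the instance-level
#' protocol auditable.
#'
#' @param instances Instance data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instance_table <- function(instances, path) {
  out <- data.frame(token_type = instances$token_type,
                    review_id = instances$review_id,
                    sentence_index = instances$sentence_index,
                    position = instances$filtered_position,
                    label = instances$label)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
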