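#' Read a review corpus from CSV
#'
#' Reads a UTF-8, RFC-4180 CSV with one review per row. Mandatory
#' columns are `review_id` and `text`; `source` and `reviewer` are
#' conventional, and any further columns (ABV, country, ...) are kept
#' verbatim as metadata. Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @return data.frame of reviews, one row per data row of the file.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_reviews(data.frame(review_id = "r1", source = "demo",
#'                          reviewer = NA, text = "Sweet vanilla."), f)
#' read_reviews(f)
#' @export
read_reviews <- function(path) {
  if (!file.exists(path)) {
    stop_fl("no such file: ", path, class = "flavorlex_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  for (col in c("review_id", "text")) {
    if (!col %in% names(df)) {
      stop_fl("reviews CSV is missing mandatory column '", col, "'",
              class = "flavorlex_schema_error")
    }
  }
  dup <- df$review_id[duplicated(df$review_id)]
  if (length(dup)) {
    stop_fl("duplicate review_id values: ",
            paste(unique(dup), collapse = ", "),
            class = "flavorlex_validation_error")
  }
  df
}

#' Write a review corpus to CSV
#'
#' Inverse of [read_reviews()]: well-formed corpora round-trip with all
#' mandatory fields byte-identical.
#'
#' @param reviews Review data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reviews <- function(reviews, path) {
  utils::write.csv(reviews, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' Candidate-descriptor lemma frequencies
#'
#' Counts occurrences of each lemma over the token stream, keeping only
#' nouns, adjectives, and verbs on an explicit whitelist — the word
#' classes that can plausibly carry sensory meaning. All other parts of
#' speech (function words, punctuation, adverbs, ...) are discarded.
#' The resulting table prioritises annotation: frequent lemmas are
#' labelled first.
#'
#' @param tokens Tagged token data frame from [segment_and_tag()] /
#'   [tag_corpus()].
#' @param verb_whitelist Character vector of verb lemmas to retain
#'   (e.g. `"dry"` so that "drying" counts). Default empty.
#' @return data.frame of class `"frequency_table"` with columns `lemma`
#'   and `count`, sorted by count descending then lemma ascending.
#' @examples
#' toks <- tag_corpus(data.frame(review_id = "r1",
#'                               text = "Sweet vanilla and vanilla cream."))
#' lemma_candidates(toks)
#' @export
lemma_candidates <- function(tokens, verb_whitelist = character()) {
  keep <- tokens$pos %in% c("NOUN", "ADJ") |
    (tokens$pos == "VERB" & tokens$lemma %in% tolower(verb_whitelist))
  lemmas <- tolower(tokens$lemma[keep])
  if (!length(lemmas)) {
    out <- data.frame(lemma = character(), count = integer(),
                      stringsAsFactors = FALSE)
  } else {
    tab <- table(lemmas)
    out <- data.frame(lemma = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$lemma), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Read/write a lemma frequency table
#'
#' CSV with columns `lemma`, `count`, sorted by count descending then
#' lemma ascending (a total, reproducible order).
#'
#' @param x A `"frequency_table"` data frame.
#' @param path File path.
#' @return `write_frequency_table` returns `path` invisibly;
#'   `read_frequency_table` returns the table.
#' @export
write_frequency_table <- function(x, path) {
  utils::write.csv(x[, c("lemma", "count")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(lemma = "character",
                                             count = "integer"))
  df <- df[order(-df$count, df$lemma), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("frequency_table", "data.frame")
  df
}
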