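#' Frequency-prioritised annotation queue
#'
#' Orders candidate lemmas by corpus frequency (ties broken
#' lexicographically, giving a total, reproducible order) and cuts the
#' ordering into pages for human annotation, most common words first.
#' Mirrors the paged word-cloud workflow in which annotators see up to
#' 50 words at a time.
#'
#' @param table A `"frequency_table"` from [lemma_candidates()].
#' @param page_size Maximum lemmas per page; default 50.
#' @return List of character vectors (pages); concatenated, they give
#'   the full frequency-ranked lemma ordering.
#' @examples
#' ft <- structure(data.frame(lemma = c("a", "b", "c"), count = c(3, 5, 3)),
#'                 class = c("frequency_table", "data.frame"))
#' build_annotation_queue(ft, page_size = 2)
#' @export
build_annotation_queue <- function(table, page_size = 50L) {
  page_size <- assert_count(page_size, "page_size")
  if (!all(c("lemma", "count") %in% names(table))) {
    stop_fl("table must have columns lemma and count",
            class = "flavorlex_validation_error")
  }
  ord <- order(-table$count, table$lemma)
  lemmas <- table$lemma[ord]
  if (!length(lemmas)) return(list())
  unname(split(lemmas, (seq_along(lemmas) - 1L) %/% page_size))
}

#' Read one annotator's labels
#'
#' Each annotator exports a CSV with columns `lemma` and `label`
#' (1 = descriptor, 0 = non-descriptor).
#'
#' @param path CSV path.
#' @param annotator_id Identifier recorded against these votes; defaults
#'   to the file name without extension.
#' @return data.frame with columns `lemma`, `annotator_id`, `label`.
#' @export
read_annotator_labels <- function(path,
                                  annotator_id = sub("\\.[^.]*$", "",
                                                     basename(path))) {
  df <- utils::read.csv(path, colClasses = c(lemma = "character"))
  if (!all(c("lemma", "label") %in% names(df))) {
    stop_fl("annotator CSV must have columns lemma and label",
            class = "flavorlex_schema_error")
  }
  data.frame(lemma = tolower(df$lemma),
             annotator_id = annotator_id,
             label = df$label, stringsAsFactors = FALSE)
}

#' Two-of-three consensus over annotator votes
#'
#' A lemma is a descriptor exactly when at least two annotators voted 1;
#' otherwise it is a non-descriptor. The same >= 2 rule applies when a
#' lemma received fewer than three votes, so a lone positive vote never
#' promotes a lemma (the default is negative). The rule is symmetric in
#' annotator order.
#'
#' @param votes data.frame with columns `lemma`, `annotator_id`, `label`
#'   (rows from one or more [read_annotator_labels()] calls).
#' @return data.frame of class `"consensus_records"` with columns
#'   `lemma`, `n_votes`, `n_positive`, `final_label`, sorted by lemma.
#' @examples
#' v <- data.frame(lemma = "oak", annotator_id = c("A", "B", "C"),
#'                 label = c(1, 1, 0))
#' merge_consensus(v)
#' @export
merge_consensus <- function(votes) {
  if (!all(c("lemma", "annotator_id", "label") %in% names(votes))) {
    stop_fl("votes must have columns lemma, annotator_id, label",
            class = "flavorlex_validation_error")
  }
  if (!nrow(votes)) {
    out <- data.frame(lemma = character(), n_votes = integer(),
                      n_positive = integer(), final_label = integer())
    class(out) <- c("consensus_records", "data.frame")
    return(out)
  }
  if (!all(votes$label %in% c(0, 1))) {
    bad <- unique(votes$label[!votes$label %in% c(0, 1)])
    stop_fl("non-binary vote value(s): ", paste(bad, collapse = ", "),
            class = "flavorlex_validation_error")
  }
  key <- paste(votes$lemma, votes$annotator_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_fl("duplicate (lemma, annotator) vote(s): ",
            paste(unique(votes$lemma[duplicated(key)]), collapse = ", "),
            class = "flavorlex_validation_error")
  }
  lem <- sort(unique(votes$lemma))
  n_votes <- as.integer(table(factor(votes$lemma, levels = lem)))
  n_pos <- as.integer(tapply(votes$label,
                             factor(votes$lemma, levels = lem), sum))
  out <- data.frame(lemma = lem, n_votes = n_votes, n_positive = n_pos,
                    final_label = as.integer(n_pos >= 2L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("consensus_records", "data.frame")
  out
}

#' Write a consensus table to CSV
#'
#' Columns `lemma`, `final_label`, `n_votes`, `n_positive`.
#'
#' @param records `"consensus_records"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(records, path) {
  utils::write.csv(records[, c("lemma", "final_label", "n_votes",
                               "n_positive")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Project consensus lemma labels onto surface token types
#'
#' Annotation happens once per lemma; classification happens per token.
#' Every distinct case-folded surface form in the corpus whose lemma has
#' a consensus record inherits that record's final label — so the lemma
#' "fruit" labels both "fruity" and "fruits". A surface type whose
#' occurrences map to two differently-labelled lemmas is a labelling
#' conflict and raises an error naming the pair.
#'
#' @param records `"consensus_records"` data frame.
#' @param tokens Tagged corpus tokens ([tag_corpus()] output).
#' @return data.frame with columns `token_type` (case-folded surface),
#'   `source_lemma`, `label`.
#' @export
project_labels_to_tokens <- function(records, tokens) {
  nonp <- tokens[tokens$pos != "PUNCT", , drop = FALSE]
  idx <- match(tolower(nonp$lemma), records$lemma)
  hit <- !is.na(idx)
  if (!any(hit)) {
    return(data.frame(token_type = character(), source_lemma = character(),
                      label = integer(), stringsAsFactors = FALSE))
  }
  map <- unique(data.frame(token_type = tolower(nonp$surface[hit]),
                           source_lemma = tolower(nonp$lemma[hit]),
                           label = records$final_label[idx[hit]],
                           stringsAsFactors = FALSE))
  agg <- tapply(map$label, map$token_type, function(x) length(unique(x)))
  if (any(agg > 1L)) {
    bad <- names(agg)[agg > 1L][1]
    pair <- unique(map$source_lemma[map$token_type == bad])
    stop_fl("token type '", bad, "' maps to differently-labeled lemmas: ",
            paste(pair, collapse = " vs "),
            class = "flavorlex_label_conflict")
  }
  map <- map[order(map$token_type, map$source_lemma), , drop = FALSE]
  map <- map[!duplicated(map$token_type), , drop = FALSE]
  rownames(map) <- NULL
  map
}
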