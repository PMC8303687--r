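#' Deterministic dictionary + suffix-rule part-of-speech tagger
#'
#' Builds a tagging provider: a function mapping raw review text to a
#' table of sentence-segmented, POS-tagged, lemmatised tokens. The
#' provider contract is deterministic — a fixed dictionary and rule set
#' always produce the same tagging — which makes token positions and
#' lemma frequencies exactly reproducible. Production users of large
#' real corpora can substitute any function with the same signature
#' (for example one that shells out to a statistical tagger); all
#' downstream code depends only on the returned columns.
#'
#' Lemmatisation rules, applied in order until a dictionary hit:
#' exact lowercased match; `-ies` to `-y`; plural/3rd-person `-s`
#' stripped; `-ing`/`-ed` stripped (optionally restoring a final `e` or
#' undoing consonant doubling), in which case the token is tagged VERB.
#' Tokens with no dictionary hit keep their lowercased surface as lemma
#' and receive `unknown_pos`.
#'
#' @param dictionary Named character vector mapping lowercase lemmas to
#'   universal POS tags (NOUN, ADJ, VERB, ADV, DET, ADP, PRON, CCONJ,
#'   ...). Defaults to a small built-in whisky-review demo dictionary.
#' @param unknown_pos Tag for words absent from the dictionary. Default
#'   `"NOUN"`: out-of-dictionary words in product reviews are
#'   overwhelmingly content nouns (brand names, rare flavour terms).
#' @return A function `(text) -> data.frame(sentence_index,
#'   raw_position, surface, pos, lemma)` with 0-based indices, of class
#'   `"flavorlex_tagger"`.
#' @seealso [segment_and_tag()], [demo_dictionary()]
#' @examples
#' tagger <- rule_tagger()
#' tagger("Sweet vanilla.")
#' @export
rule_tagger <- function(dictionary = demo_dictionary(),
                        unknown_pos = "NOUN") {
  if (is.null(names(dictionary)) || any(names(dictionary) == "")) {
    stop_fl("dictionary must be a named character vector (lemma -> POS)",
            class = "flavorlex_validation_error")
  }
  names(dictionary) <- tolower(names(dictionary))

  lemmatize <- function(lower) {
    hit <- function(x) !is.na(dictionary[x])
    if (hit(lower)) {
      return(list(lemma = lower, pos = unname(dictionary[lower])))
    }
    # -ies -> -y (berries -> berry)
    if (grepl("ies$", lower)) {
      cand <- sub("ies$", "y", lower)
      if (hit(cand)) return(list(lemma = cand, pos = unname(dictionary[cand])))
    }
    # plural / 3rd person -s (notes -> note), never bare -ss
    if (grepl("[^s]s$", lower)) {
      cand <- sub("s$", "", lower)
      if (hit(cand)) return(list(lemma = cand, pos = unname(dictionary[cand])))
    }
    # participle forms are verbs: drying -> dry, smoked -> smoke
    for (suf in c("ing", "ed")) {
      if (grepl(paste0(suf, "$"), lower) && nchar(lower) > nchar(suf) + 1L) {
        stem <- sub(paste0(suf, "$"), "", lower)
        for (cand in unique(c(stem, paste0(stem, "e"),
                              sub("(.)\\1$", "\\1", stem)))) {
          if (hit(cand)) return(list(lemma = cand, pos = "VERB"))
        }
      }
    }
    list(lemma = lower, pos = unknown_pos)
  }

  tagger <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    out <- list()
    if (!is.na(text) && nzchar(trimws(text))) {
      sentences <- strsplit(trimws(text), "(?<=[.!?])\\s+", perl = TRUE)[[1]]
      sentences <- sentences[nzchar(sentences)]
      for (si in seq_along(sentences)) {
        m <- gregexpr("[[:alnum:]]+(?:['-][[:alnum:]]+)*|[^[:alnum:][:space:]]+",
                      sentences[si], perl = TRUE)
        toks <- regmatches(sentences[si], m)[[1]]
        if (!length(toks)) next
        is_punct <- !grepl("[[:alnum:]]", toks)
        pos <- character(length(toks))
        lemma <- character(length(toks))
        for (j in seq_along(toks)) {
          if (is_punct[j]) {
            pos[j] <- "PUNCT"
            lemma[j] <- toks[j]
          } else {
            lm <- lemmatize(tolower(toks[j]))
            pos[j] <- lm$pos
            lemma[j] <- lm$lemma
          }
        }
        out[[si]] <- data.frame(
          sentence_index = si - 1L,
          raw_position = seq_along(toks) - 1L,
          surface = toks, pos = pos, lemma = lemma,
          stringsAsFactors = FALSE
        )
      }
    }
    if (!length(out)) {
      return(data.frame(sentence_index = integer(), raw_position = integer(),
                        surface = character(), pos = character(),
                        lemma = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, out)
  }
  class(tagger) <- c("flavorlex_tagger", class(tagger))
  tagger
}

#' Built-in demonstration dictionary for the rule tagger
#'
#' A small lemma-to-POS dictionary of common whisky-review vocabulary,
#' sufficient for examples and small fixtures. Real corpora need either
#' a fuller dictionary or an external tagging provider.
#'
#' @return Named character vector (lemma -> universal POS tag).
#' @export
demo_dictionary <- function() {
  c(
    # flavour vocabulary
    sweet = "ADJ", vanilla = "NOUN", dry = "ADJ", smoky = "ADJ",
    rich = "ADJ", cream = "NOUN", creamy = "ADJ", finish = "NOUN",
    oak = "NOUN", peat = "NOUN", smoke = "NOUN", fruit = "NOUN",
    fruity = "ADJ", honey = "NOUN", spice = "NOUN", spicy = "ADJ",
    caramel = "NOUN", maple = "NOUN", aftertaste = "NOUN",
    note = "NOUN", hint = "NOUN", palate = "NOUN", nose = "NOUN",
    long = "ADJ", short = "ADJ", berry = "NOUN", citrus = "NOUN",
    # verbs / adverbs / function words
    linger = "VERB", taste = "VERB", smell = "VERB", nicely = "ADV",
    very = "ADV", the = "DET", a = "DET", an = "DET", this = "DET",
    of = "ADP", with = "ADP", on = "ADP", and = "CCONJ", but = "CCONJ",
    it = "PRON", is = "VERB", be = "VERB"
  )
}

#' Segment a review into POS-tagged, position-indexed tokens
#'
#' Runs the tagging provider over one review and adds the bookkeeping
#' the rest of the pipeline relies on: the review id, and a
#' `filtered_position` — the 0-based position of each non-punctuation
#' token within its sentence after punctuation removal. Classification
#' instances are addressed by (review, sentence, filtered position), so
#' these indices must be stable; they are, because the provider is
#' deterministic.
#'
#' @param review A list or one-row data frame with at least `review_id`
#'   and `text`.
#' @param tagger A tagging provider, e.g. from [rule_tagger()].
#' @return data.frame with columns `review_id`, `sentence_index`,
#'   `raw_position`, `filtered_position` (NA for punctuation),
#'   `surface`, `pos`, `lemma`. Ordered by (sentence, raw position).
#' @examples
#' segment_and_tag(list(review_id = "r1", text = "Dry. Smoky."), rule_tagger())
#' @export
segment_and_tag <- function(review, tagger = rule_tagger()) {
  review <- as.list(review)
  if (is.null(review$review_id) || is.null(review$text)) {
    stop_fl("review must carry review_id and text",
            class = "flavorlex_validation_error")
  }
  toks <- tryCatch(
    tagger(as.character(review$text)),
    error = function(e) {
      stop_fl("tagger failed for review '", review$review_id, "': ",
              conditionMessage(e), class = "flavorlex_tagger_error")
    }
  )
  need <- c("sentence_index", "raw_position", "surface", "pos", "lemma")
  if (!all(need %in% names(toks))) {
    stop_fl("tagger output for review '", review$review_id,
            "' lacks columns: ",
            paste(setdiff(need, names(toks)), collapse = ", "),
            class = "flavorlex_tagger_error")
  }
  toks <- toks[order(toks$sentence_index, toks$raw_position), , drop = FALSE]
  fp <- rep(NA_integer_, nrow(toks))
  if (nrow(toks)) {
    nonp <- toks$pos != "PUNCT"
    fp[nonp] <- stats::ave(
      rep(1L, sum(nonp)), toks$sentence_index[nonp], FUN = cumsum
    ) - 1L
  }
  out <- data.frame(
    review_id = rep(as.character(review$review_id), nrow(toks)),
    toks[, c("sentence_index", "raw_position")],
    filtered_position = fp,
    toks[, c("surface", "pos", "lemma")],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Tag every review in a corpus
#'
#' @param reviews Review data frame from [read_reviews()] or
#'   [generate_corpus()].
#' @inheritParams segment_and_tag
#' @return Row-bound [segment_and_tag()] output for all reviews, in
#'   corpus order.
#' @export
tag_corpus <- function(reviews, tagger = rule_tagger()) {
  parts <- lapply(seq_len(nrow(reviews)), function(i) {
    segment_and_tag(reviews[i, , drop = FALSE], tagger)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- segment_and_tag(list(review_id = "empty", text = ""), tagger)
    out <- out[0, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
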