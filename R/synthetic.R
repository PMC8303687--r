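#' Configuration for the synthetic corpus and embedding generator
#'
#' The generator emulates the statistical structure the pipeline
#' assumes about real review data: a vocabulary split into descriptor
#' and non-descriptor word types whose embedding vectors form two
#' Gaussian clusters of controllable separation; reviews assembled from
#' function words, cue phrases and descriptor insertions at a
#' controllable density; optional context-dependent ("ambiguous") words
#' whose label depends on an immediately preceding cue phrase; and
#' optional writing-style contrasts between sub-corpora. Every
#' non-punctuation token carries a gold 0/1 label, so end-to-end runs
#' can be scored exactly without human annotation.
#'
#' @param n_descriptor_types Number of descriptor word types;
#'   default 120.
#' @param n_nondescriptor_types Number of non-descriptor content word
#'   types; default 150.
#' @param n_function_words Number of function-word types (drawn from
#'   the non-descriptor embedding cluster); default 30.
#' @param embedding_dim Embedding dimension `d`; default 50.
#' @param separation Distance between the two class cluster means in
#'   units of the within-cluster standard deviation; default 4 (the
#'   well-separated regime).
#' @param n_reviews Number of reviews; default 2000.
#' @param sentences_per_review Integer range `c(min, max)`; default
#'   `c(3, 6)`.
#' @param sentence_length Integer range of content slots per sentence
#'   (cue phrases expand a slot into several tokens); default `c(4, 8)`.
#' @param descriptor_density Probability that a slot carries a
#'   descriptor type; default 0.44, matching the roughly 44%-positive /
#'   56%-negative instance mix the classifier is calibrated against.
#' @param ambiguous_fraction Fraction of descriptor types that are
#'   context-dependent: such a token is a descriptor only when
#'   immediately preceded by a cue phrase. Default 0.
#' @param cue_phrases Cue-phrase inventory; default
#'   `c("notes of", "hints of")`.
#' @param cue_rate Probability that a non-descriptor slot emits a
#'   standalone cue phrase; default 0.05.
#' @param style Corpus style label, recorded as the reviews' `source`;
#'   default `"professional"`.
#' @param seed Integer seed; sub-generators derive their own streams
#'   from it unless given one explicitly.
#' @return Validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_descriptor_types = 120L,
                         n_nondescriptor_types = 150L,
                         n_function_words = 30L,
                         embedding_dim = 50L,
                         separation = 4,
                         n_reviews = 2000L,
                         sentences_per_review = c(3L, 6L),
                         sentence_length = c(4L, 8L),
                         descriptor_density = 0.44,
                         ambiguous_fraction = 0,
                         cue_phrases = c("notes of", "hints of"),
                         cue_rate = 0.05,
                         style = "professional",
                         seed = 1L) {
  cfg <- list(
    n_descriptor_types = assert_count(n_descriptor_types,
                                      "n_descriptor_types"),
    n_nondescriptor_types = assert_count(n_nondescriptor_types,
                                         "n_nondescriptor_types"),
    n_function_words = assert_count(n_function_words, "n_function_words"),
    embedding_dim = assert_count(embedding_dim, "embedding_dim"),
    separation = assert_scalar_number(separation, "separation", 0, Inf),
    n_reviews = assert_count(n_reviews, "n_reviews"),
    sentences_per_review = sentences_per_review,
    sentence_length = sentence_length,
    descriptor_density = assert_scalar_number(descriptor_density,
                                              "descriptor_density", 0, 1),
    ambiguous_fraction = assert_scalar_number(ambiguous_fraction,
                                              "ambiguous_fraction", 0, 1),
    cue_phrases = as.character(cue_phrases),
    cue_rate = assert_scalar_number(cue_rate, "cue_rate", 0, 1),
    style = as.character(style),
    seed = assert_count(seed, "seed", lower = 0L)
  )
  for (fld in c("sentences_per_review", "sentence_length")) {
    r <- cfg[[fld]]
    if (length(r) != 2L || any(r < 1L) || r[1] > r[2]) {
      stop_fl(fld, " must be an integer range c(min, max) with min >= 1",
              class = "flavorlex_validation_error")
    }
    cfg[[fld]] <- as.integer(r)
  }
  structure(cfg, class = "synth_config")
}

builtin_function_words <- c(
  "the", "a", "an", "this", "that", "it", "its", "with", "on", "in",
  "and", "but", "or", "very", "quite", "some", "there", "then", "so",
  "to", "for", "as", "at", "by", "from", "not", "is", "was", "has",
  "more"
)

cue_word_pos <- function(w) {
  if (w %in% c("of", "like", "with", "to", "from", "over")) "ADP" else "NOUN"
}

#' Generate a synthetic embedding space with two class clusters
#'
#' Descriptor-type vectors are drawn from an isotropic Gaussian around
#' `+mu`, non-descriptor types (content words, function words and cue
#' words) around `-mu`, with `|2 mu| / sigma` equal to the configured
#' separation along a random unit direction. Separation 0 makes the
#' classes statistically indistinguishable from the embeddings alone.
#' Every type also gets a deterministic POS tag (descriptors NOUN/ADJ;
#' content words NOUN/ADJ/VERB/ADV; function words DET/ADP/PRON/CCONJ),
#' so the rule-based tagger is exact on synthetic text.
#'
#' @param config A [synth_config()].
#' @param seed Seed for this generator; default `config$seed`.
#' @param extra_cue_phrases Additional cue phrases whose tokens must
#'   exist in the vocabulary (used when two styles share one embedding
#'   space).
#' @return list with `store` (an `"embedding_store"`), `types` (data
#'   frame: token, class, pos, label, ambiguous), `dictionary` (named
#'   token -> POS vector for [rule_tagger()]) and `config`.
#' @export
generate_embedding_space <- function(config, seed = config$seed,
                                     extra_cue_phrases = character()) {
  stopifnot(inherits(config, "synth_config"))
  nd <- config$n_descriptor_types
  nc <- config$n_nondescriptor_types
  nf <- config$n_function_words
  d <- config$embedding_dim

  desc <- sprintf("desc%03d", seq_len(nd))
  cont <- sprintf("word%03d", seq_len(nc))
  fun <- rep_len(builtin_function_words, nf)
  if (nf > length(builtin_function_words)) {
    extra <- nf - length(builtin_function_words)
    fun[(length(builtin_function_words) + 1L):nf] <-
      sprintf("fun%02d", seq_len(extra))
  }
  cue_tokens <- unique(unlist(strsplit(
    c(config$cue_phrases, extra_cue_phrases), "\\s+")))
  cue_tokens <- setdiff(cue_tokens, c(desc, cont, fun))

  types <- data.frame(
    token = c(desc, cont, fun, cue_tokens),
    class = c(rep("descriptor", nd), rep("content", nc),
              rep("function", length(fun)), rep("cue", length(cue_tokens))),
    pos = c(rep_len(c("NOUN", "ADJ"), nd),
            rep_len(c("NOUN", "ADJ", "VERB", "ADV"), nc),
            rep_len(c("DET", "ADP", "PRON", "CCONJ"), length(fun)),
            vapply(cue_tokens, cue_word_pos, "")),
    label = c(rep(1L, nd), rep(0L, nc + length(fun) + length(cue_tokens))),
    stringsAsFactors = FALSE
  )

  vecs <- with_seed(seed, {
    dir <- stats::rnorm(d)
    dir <- dir / sqrt(sum(dir^2))
    mu <- (config$separation / 2) * dir
    n_all <- nrow(types)
    v <- matrix(stats::rnorm(n_all * d), n_all, d)
    v + outer(ifelse(types$label == 1L, 1, -1), mu)
  })
  types$ambiguous <- FALSE
  n_amb <- round(config$ambiguous_fraction * nd)
  if (n_amb > 0L) {
    amb_idx <- with_seed(seed + 1L, sample.int(nd, n_amb))
    types$ambiguous[amb_idx] <- TRUE
  }
  rownames(vecs) <- types$token
  dictionary <- stats::setNames(types$pos, types$token)
  list(store = embedding_store(vecs), types = types,
       dictionary = dictionary, config = config)
}

match_cue_before <- function(tokens, pos, cue_token_list) {
  # is the token at `pos` (1-based) immediately preceded by a full cue
  # phrase?
  for (cue in cue_token_list) {
    k <- length(cue)
    if (pos - k >= 1L &&
        identical(tokens[(pos - k):(pos - 1L)], cue)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Generate a synthetic labelled review corpus
#'
#' Sentences are assembled slot by slot: a slot carries a descriptor
#' type with probability `descriptor_density`, a standalone cue phrase
#' with probability `cue_rate`, and otherwise a function or content
#' word. Ambiguous descriptor types are emitted half the time behind a
#' cue phrase. After assembly, gold labels are computed from the
#' realised text: ordinary descriptor tokens are 1 everywhere, and an
#' ambiguous type is 1 exactly where a full cue phrase immediately
#' precedes it — so the label is decidable only from context.
#'
#' @param config A [synth_config()].
#' @param space Embedding space from [generate_embedding_space()];
#'   generated from `config` if omitted.
#' @param seed Seed for corpus assembly; default `config$seed + 1`.
#' @return list with `reviews` (data frame: review_id, source,
#'   reviewer, text), `gold` (data frame: review_id, sentence_index,
#'   position, token, label — positions are 0-based over
#'   non-punctuation tokens) and `space`.
#' @export
generate_corpus <- function(config, space = NULL,
                            seed = config$seed + 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(space)) space <- generate_embedding_space(config)
  types <- space$types
  desc_all <- types$token[types$class == "descriptor"]
  desc_amb <- types$token[types$class == "descriptor" & types$ambiguous]
  fun_words <- types$token[types$class == "function"]
  cont_words <- types$token[types$class == "content"]
  cue_token_list <- strsplit(config$cue_phrases, "\\s+")
  amb_set <- desc_amb
  p_desc <- config$descriptor_density
  p_cue <- config$cue_rate

  with_seed(seed, {
    reviews <- vector("list", config$n_reviews)
    gold <- vector("list", config$n_reviews)
    for (r in seq_len(config$n_reviews)) {
      rid <- sprintf("r%05d", r)
      n_sent <- sample(config$sentences_per_review[1]:
                         config$sentences_per_review[2], 1L)
      sent_txt <- character(n_sent)
      gold_r <- vector("list", n_sent)
      for (s in seq_len(n_sent)) {
        L <- sample(config$sentence_length[1]:config$sentence_length[2], 1L)
        toks <- character(0)
        for (slot in seq_len(L)) {
          u <- stats::runif(1)
          if (u < p_desc && length(desc_all)) {
            ty <- sample(desc_all, 1L)
            if (ty %in% amb_set && stats::runif(1) < 0.5 &&
                length(cue_token_list)) {
              cue <- cue_token_list[[sample.int(length(cue_token_list), 1L)]]
              toks <- c(toks, cue, ty)
            } else {
              toks <- c(toks, ty)
            }
          } else if (u < p_desc + p_cue && length(cue_token_list)) {
            cue <- cue_token_list[[sample.int(length(cue_token_list), 1L)]]
            toks <- c(toks, cue)
          } else if (stats::runif(1) < 0.6 && length(fun_words)) {
            toks <- c(toks, sample(fun_words, 1L))
          } else {
            toks <- c(toks, sample(cont_words, 1L))
          }
        }
        # gold labels from the realised token sequence
        lab <- integer(length(toks))
        is_desc <- toks %in% desc_all
        is_amb <- toks %in% amb_set
        lab[is_desc & !is_amb] <- 1L
        for (p in which(is_amb)) {
          lab[p] <- as.integer(match_cue_before(toks, p, cue_token_list))
        }
        sent_txt[s] <- paste0(paste(toks, collapse = " "), ".")
        gold_r[[s]] <- data.frame(
          review_id = rid, sentence_index = s - 1L,
          position = seq_along(toks) - 1L, token = toks, label = lab,
          stringsAsFactors = FALSE
        )
      }
      reviews[[r]] <- data.frame(
        review_id = rid, source = config$style, reviewer = NA_character_,
        text = paste(sent_txt, collapse = " "), stringsAsFactors = FALSE
      )
      gold[[r]] <- do.call(rbind, gold_r)
    }
    list(reviews = do.call(rbind, reviews), gold = do.call(rbind, gold),
         space = space)
  })
}

#' Generate two sub-corpora with contrasting writing styles
#'
#' Corpus A ("professional") and corpus B ("hobbyist") share the same
#' descriptor vocabulary and embedding space but differ in cue-phrase
#' inventory (disjoint by default) and sentence-length distribution —
#' the style contrast that degrades cross-corpus generalisation when
#' labels are context-dependent.
#'
#' @param config A [synth_config()]; used as the configuration of
#'   corpus A.
#' @param cue_phrases_b Cue inventory for corpus B; default
#'   `c("tastes like", "smells like")`, token-disjoint from the default
#'   A inventory.
#' @param sentence_length_b Sentence-length range for corpus B; default
#'   `c(3, 6)` (shorter, choppier sentences).
#' @return list with `space` (shared), `a` and `b` (each a
#'   [generate_corpus()] result), and `config_a`, `config_b`.
#' @export
generate_style_pair <- function(config,
                                cue_phrases_b = c("tastes like",
                                                  "smells like"),
                                sentence_length_b = c(3L, 6L)) {
  stopifnot(inherits(config, "synth_config"))
  space <- generate_embedding_space(config,
                                    extra_cue_phrases = cue_phrases_b)
  cfg_b <- config
  cfg_b$cue_phrases <- as.character(cue_phrases_b)
  cfg_b$sentence_length <- as.integer(sentence_length_b)
  cfg_b$style <- "hobbyist"
  a <- generate_corpus(config, space, seed = config$seed + 1L)
  b <- generate_corpus(cfg_b, space, seed = config$seed + 2L)
  list(space = space, a = a, b = b, config_a = config, config_b = cfg_b)
}

#' One-call synthetic study: embeddings, corpus, tagging, examples
#'
#' Convenience wrapper chaining [generate_embedding_space()],
#' [generate_corpus()], [tag_corpus()] with a dictionary-exact
#' [rule_tagger()], [index_instances_gold()] and
#' [assemble_examples()].
#'
#' @param config A [synth_config()].
#' @param n Context window size per side; default 3.
#' @param seed_space,seed_corpus Seeds for the two generators; default
#'   `config$seed` and `config$seed + 1`.
#' @return list with `space`, `reviews`, `gold`, `tokens`, `instances`
#'   and `examples`.
#' @export
simulate_study <- function(config, n = 3L, seed_space = config$seed,
                           seed_corpus = config$seed + 1L) {
  space <- generate_embedding_space(config, seed = seed_space)
  corpus <- generate_corpus(config, space, seed = seed_corpus)
  tagger <- rule_tagger(space$dictionary)
  tokens <- tag_corpus(corpus$reviews, tagger)
  instances <- index_instances_gold(tokens, corpus$gold)
  examples <- assemble_examples(tokens, instances, space$store, n = n)
  list(space = space, reviews = corpus$reviews, gold = corpus$gold,
       tokens = tokens, instances = instances, examples = examples)
}

#' Write synthetic gold labels to CSV
#'
#' Columns `review_id`, `sentence_index`, `position`, `token`, `label`.
#'
#' @param gold Gold-label data frame from [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold_labels <- function(gold, path) {
  utils::write.csv(gold, path, row.names = FALSE)
  invisible(path)
}
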