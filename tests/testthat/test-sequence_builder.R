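test_that("context extraction pads at sentence edges", {
  s <- c("rich", "sweet", "vanilla", "cream", "finish", "lingers", "nicely")
  ctx <- extract_context(s, position = 3, n = 3)
  expect_identical(ctx$before, c("rich", "sweet", "vanilla"))
  expect_identical(ctx$after, c("finish", "lingers", "nicely"))

  first <- extract_context(s, position = 0, n = 3)
  expect_identical(first$before, rep(PAD_TOKEN, 3))
  expect_identical(first$after, c("sweet", "vanilla", "cream"))

  solo <- extract_context("oak", position = 0, n = 3)
  expect_identical(solo$before, rep(PAD_TOKEN, 3))
  expect_identical(solo$after, rep(PAD_TOKEN, 3))

  expect_error(extract_context(s, position = 7, n = 3),
               class = "flavorlex_index_error")
  expect_error(extract_context(s, position = -1, n = 3),
               class = "flavorlex_index_error")
})

test_that("context extraction agrees with the slice-and-pad oracle", {
  set.seed(11)
  for (i in 1:1000) {
    len <- sample(1:10, 1)
    sent <- sample(letters, len, replace = TRUE)
    pos <- sample(0:(len - 1), 1)
    n <- sample(1:4, 1)
    got <- extract_context(sent, pos, n)
    want <- naive_context(sent, pos, n)
    expect_identical(got, want)
  }
})

test_that("instances address every occurrence of a labelled type", {
  tagger <- rule_tagger()
  reviews <- data.frame(
    review_id = c("r1", "r2"),
    text = c("Sweet vanilla cream. Vanilla again.", "More vanilla here."),
    stringsAsFactors = FALSE)
  tokens <- tag_corpus(reviews, tagger)
  lt <- data.frame(token_type = c("vanilla", "sweet"), label = c(1L, 1L))
  inst <- index_instances(tokens, lt)
  expect_identical(sum(inst$token_type == "vanilla"), 3L)
  addr <- paste(inst$review_id, inst$sentence_index, inst$filtered_position)
  expect_identical(anyDuplicated(addr), 0L)
  # address round-trip: the token at each address case-folds to the type
  for (i in seq_len(nrow(inst))) {
    hit <- tokens$review_id == inst$review_id[i] &
      tokens$sentence_index == inst$sentence_index[i] &
      !is.na(tokens$filtered_position) &
      tokens$filtered_position == inst$filtered_position[i]
    expect_identical(tolower(tokens$surface[hit]), inst$token_type[i])
  }
  # absent type yields no instances
  none <- index_instances(tokens, data.frame(token_type = "peat", label = 1L))
  expect_identical(nrow(none), 0L)
})

test_that("assembled examples have the contracted shapes and PAD zeros", {
  sim <- tiny_study()
  ex <- sim$examples
  N <- nrow(sim$instances)
  expect_identical(length(ex$label), N)
  expect_identical(dim(ex$context), c(N, 6L, 12L))
  expect_identical(dim(ex$word), c(N, 12L))
  # sentence-initial instances have three leading all-zero context vectors
  lead <- which(sim$instances$filtered_position == 0L)[1:10]
  for (i in lead) {
    expect_equal(ex$context[i, 1:3, ], matrix(0, 3, 12))
  }
  # word vectors equal a direct store lookup
  pick <- c(1L, N %/% 2L, N)
  v <- vector_for(sim$space$store, sim$instances$token_type[pick])
  expect_equal(ex$word[pick, ], v, ignore_attr = TRUE)
})

test_that("instance-level split is a seeded partition of the right size", {
  ex <- tiny_study()$examples
  N <- length(ex$label)
  sp <- split_examples(ex, 0.2, seed = 5)
  expect_identical(length(sp$test$label), as.integer(round(0.2 * N)))
  expect_identical(length(sp$train$label) + length(sp$test$label), N)
  key <- function(e) paste(e$instances$review_id, e$instances$sentence_index,
                           e$instances$filtered_position)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_setequal(c(key(sp$train), key(sp$test)),
                  paste(ex$instances$review_id, ex$instances$sentence_index,
                        ex$instances$filtered_position))
  sp2 <- split_examples(ex, 0.2, seed = 5)
  expect_identical(sp$test$instances, sp2$test$instances)
  expect_error(split_examples(ex, 1.2, seed = 1),
               class = "flavorlex_validation_error")
})

test_that("type-level split shares no word types across partitions", {
  ex <- tiny_study()$examples
  sp <- split_examples(ex, 0.2, seed = 5, level = "type")
  expect_length(intersect(unique(sp$train$instances$token_type),
                          unique(sp$test$instances$token_type)), 0)
  expect_identical(type_overlap_fraction(sp$train, sp$test), 0)
  # the instance-level split, by contrast, overlaps heavily
  spi <- split_examples(ex, 0.2, seed = 5)
  expect_gt(type_overlap_fraction(spi$train, spi$test), 0.5)
})

test_that("class ratio sums to one and matches direct counting", {
  r <- class_ratio(c(rep(1L, 11), rep(0L, 14)))
  expect_equal(unname(r), c(0.44, 0.56))
  expect_equal(sum(class_ratio(tiny_study()$examples)), 1)
  expect_equal(unname(class_ratio(rep(1L, 5))), c(1, 0))
  expect_error(class_ratio(integer()), class = "flavorlex_validation_error")
})

test_that("the instance table CSV carries the bookkeeping columns", {
  sim <- tiny_study()
  f <- withr::local_tempfile(fileext = ".csv")
  write_instance_table(sim$instances, f)
  back <- utils::read.csv(f, colClasses = c(token_type = "character",
                                            review_id = "character"))
  expect_identical(names(back),
                   c("token_type", "review_id", "sentence_index",
                     "position", "label"))
  expect_identical(nrow(back), nrow(sim$instances))
  expect_identical(back$position, sim$instances$filtered_position)
})
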