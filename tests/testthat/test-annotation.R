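test_that("annotation queue pages respect the frequency-then-lexical order", {
  set.seed(1)
  ft <- structure(
    data.frame(lemma = sprintf("w%03d", 1:120),
               count = sample(1:40, 120, replace = TRUE)),
    class = c("frequency_table", "data.frame"))
  pages <- build_annotation_queue(ft, page_size = 50)
  expect_identical(lengths(pages), c(50L, 50L, 20L))
  flat <- unlist(pages)
  ord <- ft[order(-ft$count, ft$lemma), ]
  expect_identical(flat, ord$lemma)
  # stable across runs
  expect_identical(pages, build_annotation_queue(ft, page_size = 50))

  tie <- structure(data.frame(lemma = c("a", "b", "c"), count = c(3, 5, 3)),
                   class = c("frequency_table", "data.frame"))
  expect_identical(unlist(build_annotation_queue(tie, 50)), c("b", "a", "c"))

  empty <- structure(data.frame(lemma = character(), count = integer()),
                     class = c("frequency_table", "data.frame"))
  expect_identical(build_annotation_queue(empty, 50), list())
  expect_error(build_annotation_queue(tie, 0),
               class = "flavorlex_validation_error")
})

test_that("two-of-three consensus matches full enumeration of vote patterns", {
  combos <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  for (i in seq_len(nrow(combos))) {
    v <- data.frame(lemma = "x", annotator_id = c("A", "B", "C"),
                    label = as.integer(combos[i, ]))
    got <- merge_consensus(v)$final_label
    expect_identical(got, as.integer(sum(combos[i, ]) >= 2),
                     info = paste(combos[i, ], collapse = ","))
  }
})

test_that("consensus is conservative with fewer than three votes", {
  one <- data.frame(lemma = "x", annotator_id = "A", label = 1)
  expect_identical(merge_consensus(one)$final_label, 0L)
  tie <- data.frame(lemma = "x", annotator_id = c("A", "B"), label = c(1, 0))
  expect_identical(merge_consensus(tie)$final_label, 0L)
  both <- data.frame(lemma = "x", annotator_id = c("A", "B"), label = c(1, 1))
  expect_identical(merge_consensus(both)$final_label, 1L)
})

test_that("consensus is invariant to annotator order and validates input", {
  v <- data.frame(lemma = rep(c("oak", "wet"), each = 3),
                  annotator_id = rep(c("A", "B", "C"), 2),
                  label = c(1, 1, 0, 0, 1, 0))
  shuffled <- v[c(4, 2, 6, 1, 3, 5), ]
  expect_identical(merge_consensus(v), merge_consensus(shuffled))
  expect_identical(merge_consensus(v)$n_positive, c(2L, 1L))
  expect_identical(merge_consensus(v)$final_label, c(1L, 0L))

  bad <- data.frame(lemma = "x", annotator_id = "A", label = 2)
  expect_error(merge_consensus(bad), "non-binary",
               class = "flavorlex_validation_error")
  dup <- data.frame(lemma = "x", annotator_id = c("A", "A"), label = c(1, 1))
  expect_error(merge_consensus(dup), "duplicate",
               class = "flavorlex_validation_error")
})

test_that("annotator CSVs feed consensus and the consensus CSV round-trips", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(lemma = c("oak", "wet"), label = c(1, 0)),
                   f1, row.names = FALSE)
  utils::write.csv(data.frame(lemma = c("oak", "wet"), label = c(1, 1)),
                   f2, row.names = FALSE)
  votes <- rbind(read_annotator_labels(f1, "A"), read_annotator_labels(f2, "B"))
  rec <- merge_consensus(votes)
  expect_identical(rec$final_label[rec$lemma == "oak"], 1L)
  expect_identical(rec$final_label[rec$lemma == "wet"], 0L)
  out <- withr::local_tempfile(fileext = ".csv")
  write_consensus(rec, out)
  back <- utils::read.csv(out)
  expect_identical(back$final_label, rec$final_label)
})

test_that("lemma labels project onto every surface token type", {
  tokens <- data.frame(
    review_id = "r1", sentence_index = 0L, raw_position = 0:5,
    filtered_position = 0:5,
    surface = c("fruity", "Fruits", "oak", "smoky", "SMOKY", "zesty"),
    pos = c("ADJ", "NOUN", "NOUN", "ADJ", "ADJ", "ADJ"),
    lemma = c("fruit", "fruit", "oak", "smoky", "smoky", "zesty"),
    stringsAsFactors = FALSE
  )
  rec <- structure(
    data.frame(lemma = c("fruit", "oak", "smoky"),
               n_votes = 3L, n_positive = c(3L, 0L, 2L),
               final_label = c(1L, 0L, 1L)),
    class = c("consensus_records", "data.frame"))
  lt <- project_labels_to_tokens(rec, tokens)
  # one entry per distinct case-folded surface type; "zesty" unlabeled
  expect_identical(sort(lt$token_type), c("fruits", "fruity", "oak", "smoky"))
  expect_identical(lt$label[lt$token_type %in% c("fruity", "fruits")],
                   c(1L, 1L))
  expect_identical(lt$label[lt$token_type == "oak"], 0L)
  # every lemma present in the corpus yields at least one type
  expect_true(all(rec$lemma %in% lt$source_lemma))

  none <- project_labels_to_tokens(
    structure(data.frame(lemma = "ghost", n_votes = 3L, n_positive = 3L,
                         final_label = 1L),
              class = c("consensus_records", "data.frame")),
    tokens)
  expect_identical(nrow(none), 0L)
})

test_that("conflicting lemma labels for one token type raise an error", {
  tokens <- data.frame(
    review_id = "r1", sentence_index = 0L, raw_position = 0:1,
    filtered_position = 0:1,
    surface = c("still", "still"),
    pos = c("NOUN", "ADJ"),
    lemma = c("still_n", "still_a"),
    stringsAsFactors = FALSE
  )
  rec <- structure(
    data.frame(lemma = c("still_n", "still_a"), n_votes = 3L,
               n_positive = c(3L, 0L), final_label = c(1L, 0L)),
    class = c("consensus_records", "data.frame"))
  expect_error(project_labels_to_tokens(rec, tokens),
               "still", class = "flavorlex_label_conflict")
})
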