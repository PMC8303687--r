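test_that("metrics follow the standard confusion-matrix definitions", {
  perfect <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  # TP=2 FP=1 FN=1 TN=6
  truth <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  m <- compute_metrics(truth, pred)
  expect_equal(unname(m$confusion), c(2, 1, 1, 6))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)

  # predicting all-positive on a 44%-positive set
  truth <- c(rep(1, 44), rep(0, 56))
  m <- compute_metrics(truth, rep(1, 100))
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 0.44)

  expect_error(compute_metrics(c(1, 0), 1),
               class = "flavorlex_validation_error")
  expect_error(compute_metrics(c(1, 2), c(1, 0)),
               class = "flavorlex_validation_error")
})

test_that("zero-denominator metrics are flagged degenerate, not errors", {
  m <- compute_metrics(c(0, 0, 0), c(0, 0, 0))
  expect_equal(m$accuracy, 1)
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_setequal(m$degenerate, c("precision", "recall", "f1"))
})

test_that("metrics agree with a brute-force tally on random vectors", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    truth <- sample(0:1, n, replace = TRUE)
    pred <- sample(0:1, n, replace = TRUE)
    m <- compute_metrics(truth, pred)
    o <- naive_metrics(truth, pred)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$precision, o$precision)
    expect_equal(m$recall, o$recall)
    expect_equal(m$f1, o$f1)
    expect_equal(unname(m$confusion), c(o$tp, o$fp, o$fn, o$tn))
  }
})

test_that("metrics JSON carries the agreed fields", {
  m <- compute_metrics(c(1, 0, 1), c(1, 1, 1))
  js <- jsonlite::fromJSON(metrics_to_json(m))
  expect_equal(js$accuracy, 2 / 3)
  expect_identical(js$positive_class, "descriptor")
  expect_equal(js$confusion$tp, 2)
})

test_that("POS baseline predicts descriptor for nouns and adjectives only", {
  expect_identical(pos_baseline_predict(c("NOUN", "ADJ", "VERB", "DET")),
                   c(1L, 1L, 0L, 0L))
  expect_error(pos_baseline_predict(c("NOUN", NA)),
               class = "flavorlex_validation_error")
  # every true descriptor a noun/adjective forces recall 1
  sim <- tiny_study()
  pred <- pos_baseline_predict(sim$instances)
  m <- compute_metrics(sim$instances$label, pred)
  expect_equal(m$recall, 1)
})

test_that("POS baseline accuracy matches its analytic value", {
  # without cue insertions the slot mix is iid: a token is a descriptor
  # with p, a function word with (1-p)*0.6, a content word otherwise;
  # the content POS cycle makes q of content types nouns/adjectives.
  cfg <- tiny_cfg(cue_rate = 0)
  sim <- simulate_study(cfg)
  p <- cfg$descriptor_density
  n_types <- cfg$n_nondescriptor_types
  q <- sum(rep_len(c(TRUE, TRUE, FALSE, FALSE), n_types)) / n_types
  expected <- p + (1 - p) * (0.6 + 0.4 * (1 - q))
  n <- nrow(sim$instances)
  acc <- mean(pos_baseline_predict(sim$instances) == sim$instances$label)
  expect_lt(abs(acc - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("2-D projection is deterministic and separates clear clusters", {
  sp <- generate_embedding_space(
    synth_config(n_descriptor_types = 30, n_nondescriptor_types = 30,
                 n_function_words = 4, embedding_dim = 10,
                 separation = 6, seed = 8))
  keep <- sp$types$class %in% c("descriptor", "content")
  vec <- sp$store$vectors[keep, ]
  lab <- sp$types$label[keep]
  xy <- project_2d(vec, seed = 1)
  expect_identical(dim(xy), c(nrow(vec), 2L))
  expect_identical(xy, project_2d(vec, seed = 1))

  # mean silhouette of the 2-D points against the true classes
  D <- as.matrix(stats::dist(xy))
  sil <- vapply(seq_len(nrow(D)), function(i) {
    same <- which(lab == lab[i] & seq_along(lab) != i)
    a <- mean(D[i, same])
    b <- mean(D[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, 1)
  expect_gt(mean(sil), 0.5)

  expect_error(project_2d(vec[1, , drop = FALSE]),
               class = "flavorlex_validation_error")
})

test_that("projection handles duplicate vectors and writes sidecar CSVs", {
  v <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(-1, -2, -3))
  xy <- project_2d(v, seed = 2)
  expect_identical(nrow(xy), 3L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_projection(xy, c(1, 1, 0), f)
  back <- utils::read.csv(f)
  expect_identical(nrow(back), 3L)
  expect_identical(back$label, c(1L, 1L, 0L))
})
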