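test_that("model configuration is validated", {
  expect_error(model_config(embedding_dim = 10, head_layout = c(32, 64)),
               class = "flavorlex_config_error")
  expect_error(model_config(embedding_dim = 10, lstm_units = 0),
               class = "flavorlex_validation_error")
  expect_error(model_config(embedding_dim = 10, validation_fraction = 1),
               class = "flavorlex_validation_error")
  cfg <- model_config(embedding_dim = 10)
  expect_identical(cfg$lstm_units, 256L)
  expect_identical(cfg$batch_size, 32L)
  expect_identical(cfg$epochs, 3L)
  expect_equal(cfg$learning_rate, 1e-4)
})

test_that("branch LSTM parameter counts match the closed form", {
  cfg <- model_config(embedding_dim = 300, context_length = 6)
  m <- build_model(cfg)
  d <- 300L; u <- 256L
  expect_identical(n_params(m, "ctx_lstm"), 4L * ((d + u) * u + u))
  expect_identical(n_params(m, "ctx_lstm"), 570368L)
  expect_identical(n_params(m, "wrd_lstm"), 570368L)
  # hand tally of the stored matrices
  p <- coef(m)
  expect_identical(length(p$ctx_W) + length(p$ctx_U) + length(p$ctx_b),
                   570368L)
  expect_identical(dim(p$ctx_W), c(300L, 1024L))
  expect_identical(dim(p$ctx_U), c(256L, 1024L))
  expect_identical(ncol(p$out_W), 2L)
})

test_that("softmax outputs are normalised and symmetric under zero weights", {
  ex <- tiny_study()$examples[1:40]
  cfg <- model_config(embedding_dim = ex$d, context_length = 6,
                      lstm_units = 8, branch_dense_units = 6,
                      head_layout = c(4, 3), seed = 9)
  m <- build_model(cfg)
  P <- flavorlex:::nn_predict_proba(m$params, ex)
  expect_equal(rowSums(P), rep(1, 40))
  expect_true(all(P >= 0))
  # equal logits force probability one half everywhere
  m$params$out_W[] <- 0
  m$params$out_b[] <- 0
  m$trained <- TRUE
  expect_equal(predict(m, ex, type = "prob"), rep(0.5, 40))
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  ns <- asNamespace("flavorlex")
  d <- 3L; u <- 4L; Tn <- 4L; B <- 3L
  p <- ns$nn_init_params(d, u, 5L, c(4L, 3L))
  # nudge away from exact-zero ReLU kinks created by zero bias init
  p <- lapply(p, function(x) x + stats::rnorm(length(x), sd = 0.05))
  Xctx <- lapply(1:Tn, function(t) matrix(stats::rnorm(B * d), B))
  Xw <- matrix(stats::rnorm(B * d), B)
  y <- c(0L, 1L, 1L)
  fwd <- ns$nn_forward(p, Xctx, Xw, TRUE)
  g <- ns$nn_backward(p, fwd, Xctx, Xw, y)
  lossfun <- function(q) ns$nn_loss_acc(ns$nn_forward(q, Xctx, Xw, FALSE)$P,
                                        y)$loss
  eps <- 1e-6
  for (nm in names(p)) {
    idx <- sample(length(p[[nm]]), min(8L, length(p[[nm]])))
    for (i in idx) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = paste("gradient of", nm))
    }
  }
})

test_that("training records history, holds out validation, reproduces", {
  sp <- tiny_split()
  N <- length(sp$train$label)
  fit <- tiny_model()
  h <- training_history(fit)
  expect_identical(nrow(h), 3L)
  expect_identical(names(h), c("epoch", "train_loss", "train_accuracy",
                               "val_loss", "val_accuracy"))
  expect_identical(fit$n_val, as.integer(round(0.2 * N)))
  expect_identical(fit$n_train, N - fit$n_val)
  # learning happened on the separable fixture
  expect_lt(h$train_loss[3], h$train_loss[1])
  # bit-reproducible refit
  fit2 <- descriptor_lstm(sp$train, lstm_units = 16, branch_dense_units = 8,
                          head_layout = c(6, 4), learning_rate = 1e-3,
                          epochs = 3, seed = 42)
  expect_identical(training_history(fit2), h)
  expect_identical(predict(fit2, sp$test), predict(fit, sp$test))
})

test_that("shape contracts are enforced between model and data", {
  fit <- tiny_model()
  other <- simulate_study(tiny_cfg(embedding_dim = 5))
  expect_error(predict(fit, other$examples),
               class = "flavorlex_contract_error")
  cfg <- model_config(embedding_dim = 99, context_length = 6,
                      lstm_units = 4, branch_dense_units = 3,
                      head_layout = 2)
  expect_error(train_model(build_model(cfg), tiny_split()$train),
               class = "flavorlex_contract_error")
})

test_that("classification thresholds filter low-confidence positives", {
  expect_identical(classify(c(0.71, 0.8), 0.75), c(0L, 1L))
  expect_identical(classify(0.5, 0.5), 1L)
  expect_error(classify(0.5, 0), class = "flavorlex_validation_error")
})

test_that("divergence detection picks the epoch before validation loss rises", {
  h <- data.frame(train_loss = c(0.5, 0.3, 0.2),
                  val_loss = c(0.50, 0.40, 0.45))
  expect_identical(detect_divergence_epoch(h), 2L)
  dec <- data.frame(train_loss = seq(0.5, 0.1, length.out = 5),
                    val_loss = seq(0.6, 0.2, length.out = 5))
  expect_identical(detect_divergence_epoch(dec), 5L)
  # val rise paired with a train rise is not divergence
  noisy <- data.frame(train_loss = c(0.5, 0.6, 0.4),
                      val_loss = c(0.5, 0.55, 0.45))
  expect_identical(detect_divergence_epoch(noisy), 3L)
  expect_error(detect_divergence_epoch(data.frame(train_loss = 1,
                                                  val_loss = 1)),
               class = "flavorlex_validation_error")
})

test_that("learning curve sessions use nested growing subsets", {
  sp <- tiny_split()
  cfg <- model_config(embedding_dim = sp$train$d, context_length = 6,
                      lstm_units = 8, branch_dense_units = 6,
                      head_layout = c(4, 3), epochs = 1, seed = 4)
  lc <- learning_curve(sp$train, cfg, fractions = c(0.1, 0.4, 1.0))
  expect_identical(nrow(lc$summary), 3L)
  expect_equal(lc$summary$n,
               c(ceiling(0.1 * length(sp$train$label)),
                 ceiling(0.4 * length(sp$train$label)),
                 length(sp$train$label)))
  expect_false(is.unsorted(lc$summary$n))
  expect_error(learning_curve(sp$train, cfg, fractions = c(0, 0.5)),
               class = "flavorlex_validation_error")
  expect_error(learning_curve(sp$train, cfg, fractions = 1.5),
               class = "flavorlex_validation_error")
})
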