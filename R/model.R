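#' Model configuration for the dual-branch LSTM descriptor classifier
#'
#' Collects and validates the architecture and training
#' hyperparameters. Defaults follow the reference protocol: 256 LSTM
#' units per branch, a 128-unit dense layer per branch, a decreasing
#' dense funnel of 64 then 32 units after concatenation, a 2-unit
#' softmax output, Adam at learning rate 1e-4, cross-entropy loss,
#' batch size 32, 3 epochs, and 20% of the training data held out for
#' per-epoch validation.
#'
#' @param embedding_dim Embedding dimension `d`.
#' @param context_length Number of context timesteps, `2n` (6 for the
#'   default n = 3 window).
#' @param lstm_units LSTM units per branch; default 256.
#' @param branch_dense_units Dense units after each branch LSTM;
#'   default 128.
#' @param head_layout Strictly decreasing widths of the dense funnel
#'   between the concatenated branches and the softmax; default
#'   `c(64, 32)`.
#' @param learning_rate Adam learning rate; default 1e-4.
#' @param batch_size Mini-batch size; default 32.
#' @param epochs Training epochs; default 3 (chosen where training and
#'   validation loss typically diverge; see
#'   [detect_divergence_epoch()]).
#' @param validation_fraction Fraction of the training set held out for
#'   validation, in (0, 1); default 0.2.
#' @param seed Integer seed driving parameter initialisation, the
#'   validation split and epoch shuffling.
#' @return A validated list of class `"model_config"`.
#' @export
model_config <- function(embedding_dim, context_length = 6L,
                         lstm_units = 256L, branch_dense_units = 128L,
                         head_layout = c(64L, 32L),
                         learning_rate = 1e-4, batch_size = 32L,
                         epochs = 3L, validation_fraction = 0.2,
                         seed = 1L) {
  embedding_dim <- assert_count(embedding_dim, "embedding_dim")
  context_length <- assert_count(context_length, "context_length")
  lstm_units <- assert_count(lstm_units, "lstm_units")
  branch_dense_units <- assert_count(branch_dense_units,
                                     "branch_dense_units")
  epochs <- assert_count(epochs, "epochs")
  batch_size <- assert_count(batch_size, "batch_size")
  assert_scalar_number(learning_rate, "learning_rate", 0, Inf,
                       open_lower = TRUE)
  assert_scalar_number(validation_fraction, "validation_fraction", 0, 1,
                       open_lower = TRUE, open_upper = TRUE)
  head_layout <- vapply(head_layout, assert_count, 1L,
                        name = "head_layout entries")
  if (length(head_layout) > 1L && any(diff(head_layout) >= 0L)) {
    stop_fl("head_layout must be strictly decreasing",
            class = "flavorlex_config_error")
  }
  seed <- assert_count(seed, "seed", lower = 0L)
  structure(
    list(embedding_dim = embedding_dim, context_length = context_length,
         lstm_units = lstm_units, branch_dense_units = branch_dense_units,
         head_layout = head_layout, learning_rate = learning_rate,
         batch_size = batch_size, epochs = epochs,
         validation_fraction = validation_fraction, seed = seed),
    class = "model_config"
  )
}

#' Build an untrained descriptor model
#'
#' Architecture: two inputs — the `2n`-step context sequence and the
#' single-step target word — each processed by its own unidirectional
#' LSTM and a ReLU dense layer; the branch outputs are concatenated and
#' funnelled through decreasing ReLU dense layers into a 2-unit softmax
#' that scores non-descriptor vs descriptor. Parameters are initialised
#' reproducibly from `config$seed` (Glorot-uniform weights, zero biases
#' except the forget gate at 1).
#'
#' @param config A [model_config()].
#' @return An object of class `"descriptor_model"` (untrained).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  params <- with_seed(config$seed, nn_init_params(
    config$embedding_dim, config$lstm_units,
    config$branch_dense_units, config$head_layout
  ))
  structure(
    list(params = params, config = config, trained = FALSE,
         history = NULL),
    class = "descriptor_model"
  )
}

#' Train a descriptor model
#'
#' Mini-batch Adam on cross entropy over one-hot 2-class targets. A
#' seeded `validation_fraction` share of the training examples is held
#' out; after each epoch, loss and accuracy on both partitions are
#' recorded. Training-set metrics are the running (batch-weighted)
#' means over the epoch, mirroring the usual framework convention.
#' Fully reproducible for a fixed config seed.
#'
#' @param model A `"descriptor_model"` from [build_model()].
#' @param train A `"descriptor_examples"` training set.
#' @param epochs Optional override of `config$epochs`.
#' @return The trained model; its `$history` is the per-epoch
#'   data frame (see [training_history()]).
#' @export
train_model <- function(model, train, epochs = NULL) {
  stopifnot(inherits(model, "descriptor_model"),
            inherits(train, "descriptor_examples"))
  cfg <- model$config
  if (!is.null(epochs)) cfg$epochs <- assert_count(epochs, "epochs")
  N <- length(train$label)
  if (N == 0L) {
    stop_fl("training set is empty", class = "flavorlex_validation_error")
  }
  if (dim(train$context)[2L] != cfg$context_length ||
      train$d != cfg$embedding_dim) {
    stop_fl("example shapes (2n = ", dim(train$context)[2L], ", d = ",
            train$d, ") do not match the model config (2n = ",
            cfg$context_length, ", d = ", cfg$embedding_dim, ")",
            class = "flavorlex_contract_error")
  }
  params <- model$params
  with_seed(cfg$seed + 1L, {
    n_val <- as.integer(round(cfg$validation_fraction * N))
    val_idx <- if (n_val > 0L) sample.int(N, n_val) else integer()
    fit_idx <- setdiff(seq_len(N), val_idx)
    val <- train[val_idx]
    state <- adam_init(params)
    hist <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(fit_idx)
      tl <- 0; ta <- 0; seen <- 0L
      at <- 1L
      while (at <= length(ord)) {
        idx <- ord[at:min(length(ord), at + cfg$batch_size - 1L)]
        b <- nn_batch_inputs(train, idx)
        y <- train$label[idx]
        fwd <- nn_forward(params, b$ctx, b$wrd, keep_cache = TRUE)
        la <- nn_loss_acc(fwd$P, y)
        grads <- nn_backward(params, fwd, b$ctx, b$wrd, y)
        upd <- adam_step(params, grads, state, cfg$learning_rate)
        params <- upd$params
        state <- upd$state
        nb <- length(idx)
        tl <- tl + la$loss * nb
        ta <- ta + la$acc * nb
        seen <- seen + nb
        at <- at + cfg$batch_size
      }
      if (n_val > 0L) {
        Pv <- nn_predict_proba(params, val)
        lav <- nn_loss_acc(Pv, val$label)
      } else {
        lav <- list(loss = NA_real_, acc = NA_real_)
      }
      hist[[ep]] <- data.frame(epoch = ep,
                               train_loss = tl / seen,
                               train_accuracy = ta / seen,
                               val_loss = lav$loss,
                               val_accuracy = lav$acc)
    }
  })
  model$params <- params
  model$config <- cfg
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  model$n_train <- length(fit_idx)
  model$n_val <- n_val
  model
}

#' Fit the dual-branch LSTM descriptor classifier
#'
#' The one-call fitting interface: configures, builds and trains the
#' model on a `"descriptor_examples"` training set. See
#' [model_config()] for hyperparameters and defaults, and
#' [assemble_examples()] for constructing the input.
#'
#' @param train A `"descriptor_examples"` training set.
#' @param ... Hyperparameters forwarded to [model_config()]
#'   (`embedding_dim` and `context_length` are taken from `train`).
#' @return A trained `"descriptor_model"` with per-epoch `$history`.
#' @examples
#' \donttest{
#' sim <- simulate_study(synth_config(n_reviews = 40, embedding_dim = 8,
#'                                    seed = 1))
#' sp <- split_examples(sim$examples, 0.2, seed = 1)
#' fit <- descriptor_lstm(sp$train, lstm_units = 16,
#'                        branch_dense_units = 8, head_layout = c(6, 4),
#'                        epochs = 2, seed = 1)
#' print(fit)
#' }
#' @export
descriptor_lstm <- function(train, ...) {
  stopifnot(inherits(train, "descriptor_examples"))
  cfg <- model_config(embedding_dim = train$d,
                      context_length = dim(train$context)[2L], ...)
  train_model(build_model(cfg), train)
}

#' Per-epoch training history of a fitted model
#'
#' @param model A trained `"descriptor_model"`.
#' @return data.frame with columns `epoch`, `train_loss`,
#'   `train_accuracy`, `val_loss`, `val_accuracy`.
#' @export
training_history <- function(model) {
  if (is.null(model$history)) {
    stop_fl("model has no training history (untrained?)",
            class = "flavorlex_validation_error")
  }
  model$history
}

#' Number of trainable parameters
#'
#' For reference, each branch LSTM contributes
#' `4 * ((d + u) * u + u)` parameters (four gates, each with a `d x u`
#' input map, a `u x u` recurrent map and a bias).
#'
#' @param model A `"descriptor_model"`.
#' @param component Optional component name (`"ctx_lstm"`, `"wrd_lstm"`,
#'   `"dense"`); default counts everything.
#' @return Integer parameter count.
#' @export
n_params <- function(model, component = NULL) {
  p <- model$params
  pick <- function(prefixes) {
    sum(vapply(p[grepl(paste0("^(", paste(prefixes, collapse = "|"), ")"),
                       names(p))], length, 1L))
  }
  if (is.null(component)) return(sum(vapply(p, length, 1L)))
  switch(component,
         ctx_lstm = pick("ctx_"),
         wrd_lstm = pick("wrd_"),
         dense = pick(c("dctx_", "dwrd_", "head", "out_")),
         stop_fl("unknown component '", component, "'",
                 class = "flavorlex_validation_error"))
}

#' @export
print.descriptor_model <- function(x, ...) {
  cfg <- x$config
  cat("Dual-branch LSTM descriptor classifier",
      if (x$trained) "(trained)" else "(untrained)", "\n")
  cat("  context: ", cfg$context_length, " x ", cfg$embedding_dim,
      "-d -> LSTM(", cfg$lstm_units, ") -> dense(",
      cfg$branch_dense_units, ")\n", sep = "")
  cat("  word:    1 x ", cfg$embedding_dim, "-d -> LSTM(",
      cfg$lstm_units, ") -> dense(", cfg$branch_dense_units, ")\n",
      sep = "")
  cat("  head:    concat -> ", paste(cfg$head_layout, collapse = " -> "),
      " -> softmax(2)\n", sep = "")
  cat("  parameters:", format(n_params(x), big.mark = ","), "\n")
  if (x$trained) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  after %d epoch(s): train acc %.4f, val acc %.4f\n",
                h$epoch, h$train_accuracy, h$val_accuracy))
  }
  invisible(x)
}

#' @export
summary.descriptor_model <- function(object, ...) {
  out <- list(
    config = object$config,
    n_params = n_params(object),
    n_params_ctx_lstm = n_params(object, "ctx_lstm"),
    n_params_wrd_lstm = n_params(object, "wrd_lstm"),
    n_params_dense = n_params(object, "dense"),
    trained = object$trained,
    history = object$history
  )
  class(out) <- "summary.descriptor_model"
  out
}

#' @export
print.summary.descriptor_model <- function(x, ...) {
  cat("Dual-branch LSTM descriptor classifier\n")
  cat("  total parameters:      ", format(x$n_params, big.mark = ","), "\n")
  cat("  context-branch LSTM:   ",
      format(x$n_params_ctx_lstm, big.mark = ","), "\n")
  cat("  word-branch LSTM:      ",
      format(x$n_params_wrd_lstm, big.mark = ","), "\n")
  cat("  dense layers:          ",
      format(x$n_params_dense, big.mark = ","), "\n")
  if (!is.null(x$history)) {
    cat("Training history:\n")
    print(x$history, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.descriptor_model <- function(object, ...) object$params

#' Plot training vs validation loss and accuracy by epoch
#'
#' @param x A trained `"descriptor_model"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.descriptor_model <- function(x, ...) {
  h <- training_history(x)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = 1:2, lty = 1:2, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), pch = 1:2,
                   lty = 1:2, col = c("black", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_accuracy, h$val_accuracy),
                    type = "b", pch = 1:2, lty = 1:2,
                    col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "accuracy", ...)
  invisible(x)
}

#' Descriptor probabilities or class labels for new examples
#'
#' @param object A trained `"descriptor_model"`.
#' @param newdata A `"descriptor_examples"` object with matching shapes.
#' @param type `"prob"` (default) for the descriptor-class softmax
#'   probability, `"class"` for thresholded 0/1 labels.
#' @param threshold Classification threshold on the descriptor
#'   probability; default 0.5.
#' @param ... Ignored.
#' @return Numeric probabilities in \[0, 1\], or integer 0/1 labels.
#' @export
predict.descriptor_model <- function(object, newdata,
                                     type = c("prob", "class"),
                                     threshold = 0.5, ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "descriptor_examples"))
  cfg <- object$config
  if (dim(newdata$context)[2L] != cfg$context_length ||
      newdata$d != cfg$embedding_dim) {
    stop_fl("newdata shapes do not match the model config",
            class = "flavorlex_contract_error")
  }
  P <- nn_predict_proba(object$params, newdata)
  prob <- P[, 2L]
  if (type == "prob") prob else classify(prob, threshold)
}

#' Threshold descriptor probabilities into 0/1 labels
#'
#' @param probabilities Numeric vector of descriptor probabilities.
#' @param threshold Scalar in (0, 1); a token is labelled descriptor
#'   iff its probability is `>= threshold`. Default 0.5; raising it
#'   filters out low-confidence positives (rare words, proper nouns).
#' @return Integer 0/1 vector.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  assert_scalar_number(threshold, "threshold", 0, 1,
                       open_lower = TRUE, open_upper = TRUE)
  as.integer(probabilities >= threshold)
}

#' Learning curve: train on nested increments of the training data
#'
#' Trains one fresh model per fraction of the training set (default 5%
#' increments up to 100%, i.e. 20 sessions). Subsets are nested — the
#' examples used at a smaller fraction are contained in every larger
#' one — so sessions differ only in how much data they saw.
#'
#' @param train A `"descriptor_examples"` training set.
#' @param config A [model_config()].
#' @param fractions Increasing fractions in (0, 1]; default
#'   `seq(0.05, 1, by = 0.05)`.
#' @param seed Seed for the single subsampling permutation.
#' @return Object of class `"learning_curve"`: a summary data frame
#'   (`fraction`, `n`, final train/val loss and accuracy) plus the full
#'   per-session histories.
#' @export
learning_curve <- function(train, config,
                           fractions = seq(0.05, 1, by = 0.05),
                           seed = config$seed) {
  stopifnot(inherits(train, "descriptor_examples"),
            inherits(config, "model_config"))
  if (!length(fractions) ||
      any(fractions <= 0) || any(fractions > 1)) {
    stop_fl("fractions must lie in (0, 1]",
            class = "flavorlex_validation_error")
  }
  N <- length(train$label)
  perm <- with_seed(seed, sample.int(N))
  sessions <- vector("list", length(fractions))
  rows <- vector("list", length(fractions))
  for (k in seq_along(fractions)) {
    n_k <- as.integer(max(2, ceiling(fractions[k] * N)))
    sub <- train[perm[seq_len(n_k)]]
    fit <- train_model(build_model(config), sub)
    h <- fit$history
    sessions[[k]] <- h
    last <- h[nrow(h), ]
    rows[[k]] <- data.frame(fraction = fractions[k], n = n_k,
                            train_loss = last$train_loss,
                            train_accuracy = last$train_accuracy,
                            val_loss = last$val_loss,
                            val_accuracy = last$val_accuracy)
  }
  structure(list(summary = do.call(rbind, rows), sessions = sessions),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("<learning_curve> ", nrow(x$summary), " training sessions\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Plot a learning curve
#'
#' @param x A `"learning_curve"`.
#' @param what `"loss"` or `"accuracy"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.learning_curve <- function(x, what = c("loss", "accuracy"), ...) {
  what <- match.arg(what)
  s <- x$summary
  cols <- if (what == "loss") c("train_loss", "val_loss") else
    c("train_accuracy", "val_accuracy")
  graphics::matplot(100 * s$fraction, s[, cols], type = "b", pch = 1:2,
                    lty = 1:2, col = c("black", "firebrick"),
                    xlab = "% of training data used", ylab = what, ...)
  graphics::legend("topright", c("train", "validation"), pch = 1:2,
                   lty = 1:2, col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Recommend a stopping epoch from train/validation loss divergence
#'
#' Overfitting shows as validation loss turning upward while training
#' loss keeps falling. Among epochs where the next epoch's validation
#' loss increases while training loss does not, the one with minimum
#' validation loss is recommended; if validation loss never increases,
#' the final epoch is returned.
#'
#' @param history A training-history data frame (or a trained model).
#' @return 1-based recommended epoch count.
#' @examples
#' h <- data.frame(train_loss = c(0.5, 0.3, 0.2),
#'                 val_loss = c(0.50, 0.40, 0.45))
#' detect_divergence_epoch(h)
#' @export
detect_divergence_epoch <- function(history) {
  if (inherits(history, "descriptor_model")) {
    history <- training_history(history)
  }
  E <- nrow(history)
  if (is.null(E) || E < 2L) {
    stop_fl("history must cover at least 2 epochs",
            class = "flavorlex_validation_error")
  }
  vl <- history$val_loss
  tl <- history$train_loss
  cand <- which(vl[-E] < vl[-1L] & tl[-1L] <= tl[-E])
  if (!length(cand)) return(E)
  cand[which.min(vl[cand])]
}
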