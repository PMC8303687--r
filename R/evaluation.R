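#' Binary classification metrics with the descriptor as positive class
#'
#' Accuracy, precision = TP/(TP+FP), recall = TP/(TP+FN) and the F1
#' harmonic mean, plus the raw confusion counts. A ratio with a zero
#' denominator is reported as 0 and flagged `degenerate` instead of
#' raising, so batch evaluation stays total.
#'
#' @param truth Integer 0/1 vector of true labels.
#' @param predicted Integer 0/1 vector of predicted labels, same length.
#' @return Object of class `"descriptor_metrics"`: a list with
#'   `accuracy`, `precision`, `recall`, `f1`, `confusion` (tp, fp, fn,
#'   tn), `n`, `degenerate` (names of zero-denominator metrics) and
#'   `positive_class = "descriptor"`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
#' @export
compute_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_fl("truth and predicted must have equal length",
            class = "flavorlex_validation_error")
  }
  if (!length(truth)) {
    stop_fl("cannot compute metrics on empty input",
            class = "flavorlex_validation_error")
  }
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stop_fl("labels must be binary 0/1",
            class = "flavorlex_validation_error")
  }
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  fn <- sum(truth == 1 & predicted == 0)
  tn <- sum(truth == 0 & predicted == 0)
  degenerate <- character()
  ratio <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else {
      num / den
    }
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- ratio(2 * precision * recall, precision + recall, "f1")
  structure(
    list(accuracy = (tp + tn) / length(truth),
         precision = precision, recall = recall, f1 = f1,
         confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
         n = length(truth), degenerate = degenerate,
         positive_class = "descriptor"),
    class = "descriptor_metrics"
  )
}

#' @export
print.descriptor_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f  (n = %d)\n",
    x$accuracy, x$precision, x$recall, x$f1, x$n))
  cat(sprintf("confusion: TP %d  FP %d  FN %d  TN %d\n",
              x$confusion["tp"], x$confusion["fp"],
              x$confusion["fn"], x$confusion["tn"]))
  if (length(x$degenerate)) {
    cat("degenerate (zero denominator):",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialise a metrics object to JSON
#'
#' @param metrics A `"descriptor_metrics"` object.
#' @param path Optional output path; if omitted the JSON string is
#'   returned.
#' @return The JSON string (invisibly if written to `path`).
#' @export
metrics_to_json <- function(metrics, path = NULL) {
  x <- list(accuracy = metrics$accuracy, precision = metrics$precision,
            recall = metrics$recall, f1 = metrics$f1,
            confusion = as.list(metrics$confusion), n = metrics$n,
            positive_class = metrics$positive_class)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Part-of-speech baseline: every noun and adjective is a descriptor
#'
#' The field's conventional comparator: predict 1 for instances tagged
#' NOUN or ADJ and 0 otherwise. Because almost all true descriptors are
#' nouns or adjectives, this baseline has near-perfect recall but poor
#' precision.
#'
#' @param instances Instance data frame carrying a `pos` column (or any
#'   data frame/character vector of POS tags).
#' @return Integer 0/1 predictions, one per instance.
#' @export
pos_baseline_predict <- function(instances) {
  pos <- if (is.character(instances)) instances else instances$pos
  if (is.null(pos) || anyNA(pos) || any(!nzchar(pos))) {
    stop_fl("instances must carry a complete pos column",
            class = "flavorlex_validation_error")
  }
  as.integer(pos %in% c("NOUN", "ADJ"))
}

#' Project embedding vectors to 2-D for cluster visualisation
#'
#' Produces one 2-D point per input vector, for scatter plots of the
#' embedding space coloured by label or prediction. The default method
#' is Sammon's nonlinear mapping (MASS), which preserves local
#' neighbourhood structure, initialised from classical MDS so the
#' result is deterministic up to the seed (used only to jitter exactly
#' duplicated rows, which the mapping cannot otherwise handle);
#' `"pca"` gives the plain first two principal components.
#'
#' @param vectors Numeric matrix (one row per token) or a
#'   `"descriptor_examples"` word matrix.
#' @param seed Integer seed (duplicate-row jitter only).
#' @param method `"sammon"` (default) or `"pca"`.
#' @return Numeric matrix with `nrow(vectors)` rows and 2 columns.
#' @export
project_2d <- function(vectors, seed = 1L, method = c("sammon", "pca")) {
  method <- match.arg(method)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) {
    stop_fl("need at least 2 vectors to project",
            class = "flavorlex_validation_error")
  }
  if (ncol(vectors) < 2L) {
    stop_fl("vectors must have dimension >= 2",
            class = "flavorlex_validation_error")
  }
  dup <- duplicated(vectors)
  if (any(dup)) {
    scale <- max(stats::sd(vectors), .Machine$double.eps)
    vectors[dup, ] <- vectors[dup, , drop = FALSE] +
      with_seed(seed, matrix(stats::rnorm(sum(dup) * ncol(vectors),
                                          sd = 1e-6 * scale),
                             ncol = ncol(vectors)))
  }
  pc <- stats::prcomp(vectors, rank. = 2L)$x
  if (ncol(pc) < 2L) pc <- cbind(pc, 0)
  if (method == "pca") {
    coords <- pc
  } else {
    coords <- MASS::sammon(stats::dist(vectors), y = pc, trace = FALSE)$points
  }
  dimnames(coords) <- list(rownames(vectors), c("x", "y"))
  coords
}

#' Scatter plot of a 2-D projection coloured by class
#'
#' Descriptors are drawn as crosses, non-descriptors as dots — the
#' conventional rendering of embedding-space label structure.
#'
#' @param coords 2-column matrix from [project_2d()].
#' @param labels Integer 0/1 labels (1 = descriptor).
#' @param ... Passed to [graphics::plot()].
#' @return `coords`, invisibly.
#' @export
plot_projection <- function(coords, labels, ...) {
  labels <- as.integer(labels)
  graphics::plot(coords, pch = ifelse(labels == 1L, 4L, 16L),
                 col = ifelse(labels == 1L, "sienna", "steelblue"),
                 xlab = "dim 1", ylab = "dim 2", ...)
  graphics::legend("topright", c("descriptor", "non-descriptor"),
                   pch = c(4L, 16L), col = c("sienna", "steelblue"),
                   bty = "n")
  invisible(coords)
}

#' Write projection coordinates and labels as a sidecar CSV
#'
#' @param coords 2-column matrix from [project_2d()].
#' @param labels Integer 0/1 labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(coords, labels, path) {
  utils::write.csv(
    data.frame(token = rownames(coords) %||% seq_len(nrow(coords)),
               x = coords[, 1L], y = coords[, 2L], label = labels),
    path, row.names = FALSE)
  invisible(path)
}
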