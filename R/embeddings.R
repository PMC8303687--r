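#' Load a word-embedding table in GloVe plain-text format
#'
#' One record per line: the token followed by `d` whitespace-separated
#' floats, no header. The dimension is inferred from the first line and
#' enforced on every subsequent line. Gzip-compressed files are read
#' transparently. Duplicate tokens keep their first occurrence (with a
#' warning), matching first-wins semantics of a lookup table.
#'
#' @param path Path to the embedding text file (optionally `.gz`).
#' @param lowercase Case-fold tokens before lookup (distributed GloVe
#'   vocabularies are predominantly lowercase). Default `TRUE`.
#' @param oov_policy `"zero"` (default): out-of-vocabulary tokens map to
#'   the zero vector — the same "no information" convention as PAD —
#'   with a per-store counter recording how often it happened. `"error"`
#'   raises on the first OOV lookup, for strict runs.
#' @return An object of class `"embedding_store"`.
#' @examples
#' f <- tempfile()
#' writeLines(c("sweet 0.1 0.2", "oak -1 0.5"), f)
#' store <- load_embedding_table(f)
#' vector_for(store, c("sweet", PAD_TOKEN))
#' @export
load_embedding_table <- function(path, lowercase = TRUE,
                                 oov_policy = c("zero", "error")) {
  oov_policy <- match.arg(oov_policy)
  if (!file.exists(path)) {
    stop_fl("no such file: ", path, class = "flavorlex_io_error")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    stop_fl("embedding file is empty: ", path, class = "flavorlex_format_error")
  }
  parts <- strsplit(lines, "[ \t]+")
  d <- length(parts[[1]]) - 1L
  if (d < 1L) {
    stop_fl("embedding file line 1 has no vector components",
            class = "flavorlex_format_error")
  }
  bad <- which(vapply(parts, length, 1L) != d + 1L)
  if (length(bad)) {
    stop_fl("embedding file line ", bad[1], " has ",
            length(parts[[bad[1]]]) - 1L, " floats, expected ", d,
            class = "flavorlex_format_error")
  }
  tokens <- vapply(parts, `[[`, "", 1L)
  if (lowercase) tokens <- tolower(tokens)
  vec <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))),
                ncol = d, byrow = TRUE)
  if (anyNA(vec)) {
    bad <- which(rowSums(is.na(vec)) > 0)[1]
    stop_fl("embedding file line ", bad, " has a non-numeric component",
            class = "flavorlex_format_error")
  }
  if (anyDuplicated(tokens)) {
    warning("duplicate embedding tokens; keeping first occurrence: ",
            paste(utils::head(unique(tokens[duplicated(tokens)]), 5),
                  collapse = ", "))
    keep <- !duplicated(tokens)
    tokens <- tokens[keep]
    vec <- vec[keep, , drop = FALSE]
  }
  rownames(vec) <- tokens
  embedding_store(vec, lowercase = lowercase, oov_policy = oov_policy)
}

#' Construct an embedding store from a token-by-dimension matrix
#'
#' @param vectors Numeric matrix with one row per token; rownames are
#'   the tokens.
#' @inheritParams load_embedding_table
#' @return An `"embedding_store"`: the lookup table, its dimension, the
#'   all-zero PAD convention, and lookup counters (hits, OOV, PAD).
#' @export
embedding_store <- function(vectors, lowercase = TRUE,
                            oov_policy = c("zero", "error")) {
  oov_policy <- match.arg(oov_policy)
  if (is.null(rownames(vectors))) {
    stop_fl("vectors must have tokens as rownames",
            class = "flavorlex_validation_error")
  }
  counts <- new.env(parent = emptyenv())
  counts$hit <- 0; counts$oov <- 0; counts$pad <- 0
  structure(
    list(dimension = ncol(vectors), vectors = vectors,
         lowercase = lowercase, oov_policy = oov_policy, counts = counts),
    class = "embedding_store"
  )
}

#' @export
print.embedding_store <- function(x, ...) {
  cat("<embedding_store> ", nrow(x$vectors), " tokens, dimension ",
      x$dimension, ", OOV policy '", x$oov_policy, "'\n", sep = "")
  invisible(x)
}

#' Look up embedding vectors, honouring the PAD and OOV conventions
#'
#' The PAD sentinel ([PAD_TOKEN]) always maps to the zero vector of
#' length `d`. In-vocabulary tokens return their stored row unchanged.
#' Out-of-vocabulary tokens return the zero vector under the `"zero"`
#' policy (incrementing the store's OOV counter) or raise under
#' `"error"`. Lookups never mutate the table; repeated lookups are
#' identical.
#'
#' @param store An `"embedding_store"`.
#' @param tokens Character vector of tokens (may include [PAD_TOKEN]).
#' @return Numeric matrix, `length(tokens)` rows by `d` columns.
#' @export
vector_for <- function(store, tokens) {
  stopifnot(inherits(store, "embedding_store"))
  toks <- as.character(tokens)
  is_pad <- toks == PAD_TOKEN
  if (store$lowercase) toks[!is_pad] <- tolower(toks[!is_pad])
  idx <- match(toks, rownames(store$vectors))
  idx[is_pad] <- NA_integer_
  out <- matrix(0, nrow = length(toks), ncol = store$dimension)
  hit <- !is.na(idx)
  out[hit, ] <- store$vectors[idx[hit], , drop = FALSE]
  oov <- !hit & !is_pad
  if (any(oov) && store$oov_policy == "error") {
    stop_fl("out-of-vocabulary token(s): ",
            paste(utils::head(unique(toks[oov]), 5), collapse = ", "),
            class = "flavorlex_lookup_error")
  }
  store$counts$hit <- store$counts$hit + sum(hit)
  store$counts$oov <- store$counts$oov + sum(oov)
  store$counts$pad <- store$counts$pad + sum(is_pad)
  rownames(out) <- tokens
  out
}

#' Lookup statistics accumulated by an embedding store
#'
#' @param store An `"embedding_store"`.
#' @return Named numeric vector with `hit`, `oov` and `pad` lookup
#'   counts since the store was created (or last [reset_lookup_stats()]).
#' @export
lookup_stats <- function(store) {
  c(hit = store$counts$hit, oov = store$counts$oov, pad = store$counts$pad)
}

#' @rdname lookup_stats
#' @export
reset_lookup_stats <- function(store) {
  store$counts$hit <- 0; store$counts$oov <- 0; store$counts$pad <- 0
  invisible(store)
}

#' Write an embedding store in GloVe plain-text format
#'
#' @param store An `"embedding_store"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(store, path) {
  v <- store$vectors
  lines <- paste(rownames(v),
                 apply(v, 1L, function(r) paste(format(r, scientific = FALSE,
                                                       trim = TRUE),
                                                collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
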