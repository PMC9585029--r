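# Content embeddings f(v): skip-gram with negative sampling over the walk
# corpus. Training is single-threaded and fully seeded so embedding tables
# are reproducible.

#' Train skip-gram embeddings over a walk corpus
#'
#' Learns a `d`-dimensional content vector for every token appearing in the
#' corpus using skip-gram with negative sampling (negatives drawn from the
#' unigram distribution raised to 3/4, linearly decaying learning rate).
#'
#' @param corpus Either a `typed_neighbors` object from [sample_all()] or a
#'   list of character vectors of node identifiers.
#' @param d Embedding dimension (>= 2).
#' @param window Context window half-width.
#' @param negatives Negative samples per positive pair.
#' @param epochs Passes over the corpus.
#' @param lr Initial learning rate (decays linearly to `lr / 25`).
#' @param seed Integer seed.
#' @return A list of class `content_embedding` with `ids`, the `n x d`
#'   matrix `vectors` (rownames = ids), and the training metadata.
#' @export
train_skipgram <- function(corpus, d = 128L, window = 5L, negatives = 5L,
                           epochs = 5L, lr = 0.025, seed = 1L) {
  if (inherits(corpus, "typed_neighbors")) corpus <- corpus$corpus_ids
  if (!is.list(corpus) || length(corpus) == 0) {
    abort("`corpus` must be a non-empty list of token sequences")
  }
  if (any(lengths(corpus) == 0)) abort("corpus contains an empty sequence")
  if (d < 2) abort("embedding dimension `d` must be >= 2")
  vocab <- sort(unique(unlist(corpus, use.names = FALSE)))
  seqs <- lapply(corpus, function(s) match(s, vocab) - 1L)
  M <- .skipgram_cpp(seqs, length(vocab), as.integer(d), as.integer(window),
                     as.integer(negatives), as.integer(epochs), lr, lr / 25,
                     as.numeric(seed))
  rownames(M) <- vocab
  structure(
    list(ids = vocab, vectors = M, d = as.integer(d), seed = as.integer(seed),
         window = as.integer(window), negatives = as.integer(negatives),
         epochs = as.integer(epochs)),
    class = "content_embedding"
  )
}

#' Look up content vectors
#'
#' @param table A `content_embedding`.
#' @param ids Node identifiers.
#' @param fallback If `TRUE`, identifiers absent from the table (isolated
#'   nodes never walked) receive a deterministic seeded random vector with a
#'   warning; if `FALSE`, unknown identifiers are an error.
#' @return A matrix with one row per requested identifier.
#' @export
embed_lookup <- function(table, ids, fallback = TRUE) {
  stopifnot(inherits(table, "content_embedding"))
  hit <- match(ids, table$ids)
  out <- matrix(0, length(ids), table$d, dimnames = list(ids, NULL))
  known <- !is.na(hit)
  out[known, ] <- table$vectors[hit[known], , drop = FALSE]
  if (any(!known)) {
    if (!fallback) {
      abort(paste0("node(s) absent from embedding table: ",
                   paste(head(ids[!known], 5), collapse = ", ")))
    }
    warn(sprintf("%d node(s) absent from corpus; assigning seeded random vectors",
                 sum(!known)))
    for (i in which(!known)) {
      out[i, ] <- fallback_vector(ids[i], table$d, table$seed)
    }
  }
  out
}

# Deterministic pseudo-random vector for a node missing from the corpus,
# keyed on the node identifier and the table seed.
fallback_vector <- function(id, d, seed) {
  h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(derive_seed(seed, h))
  runif(d, -0.5 / d, 0.5 / d)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Full content matrix aligned to the graph's node order (fallback rows for
# isolated nodes).
content_matrix <- function(table, graph) {
  suppressWarnings(embed_lookup(table, graph$nodes$id, fallback = TRUE))
}

#' Write an embedding table as TSV
#'
#' `node_id` followed by the `d` vector components.
#'
#' @param table A `content_embedding`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(table, path) {
  df <- data.frame(node_id = table$ids, table$vectors, check.names = FALSE)
  colnames(df) <- c("node_id", paste0("v", seq_len(table$d)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding table written by [write_embedding()]
#'
#' @param path TSV path.
#' @param seed Seed recorded for fallback vectors of unseen nodes.
#' @return A `content_embedding`.
#' @export
read_embedding <- function(path, seed = 1L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  structure(
    list(ids = df[[1]], vectors = M, d = ncol(M), seed = as.integer(seed),
         window = NA_integer_, negatives = NA_integer_,
         epochs = NA_integer_),
    class = "content_embedding"
  )
}
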