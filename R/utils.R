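# Internal helpers shared across modules.

# Deterministically derive a child seed from a base seed and an integer
# offset. Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(offset) * 7919 + 1
  as.integer(s %% 2147483629)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax over the columns of a matrix, numerically stabilised.
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

node_types <- function() c("lncRNA", "disease", "miRNA")

check_square_named <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(paste0(what, " must be a square matrix"))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(paste0(what, " must carry row and column names"))
  }
  if (!identical(rownames(m), colnames(m))) {
    abort(paste0(what, " row and column labels must match"))
  }
  invisible(m)
}

check_binary_matrix <- function(m, what) {
  if (!all(m %in% c(0, 1))) {
    abort(paste0(what, " must contain only 0/1 entries"))
  }
  invisible(m)
}
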