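# The association model: one bidirectional LSTM per neighbour type
# aggregates that type's sampled neighbour content embeddings into a type
# embedding f^t(v); an attention mechanism fuses the type embeddings with
# the node's own content embedding f(v) into the final embedding z(v); a
# pair (z_l, z_d) is mapped to a feature vector (product, concatenation or
# both — see `pair_mode`) and scored by a 2-class softmax layer trained
# with cross-entropy. All gradients are analytic (verified against finite
# differences in the test suite).
#
# Parameters are stored as a flat named list. LSTM gate matrices are stacked
# row-wise in the order input, forget, output, candidate: W is (4m x d) on
# the inputs, U is (4m x m) on the recurrent state, b is length 4m, with
# hidden size m = d/2 per direction so the forward||backward concatenation
# has dimension d.

TYPE_KEYS <- c(lncRNA = "lnc", disease = "dis", miRNA = "mi")

#' Initialise model parameters
#'
#' @param d Embedding dimension (even).
#' @param k Named integer vector of per-type neighbour budgets
#'   (`lncRNA`, `disease`, `miRNA`); recorded for shape checks.
#' @param variant `"full"`, `"noNeigh"` (final embedding is the content
#'   embedding itself) or `"noAttention"` (a dense layer over the
#'   concatenated self + type embeddings replaces attention).
#' @param act Activation applied to the fused embedding (`"relu"` or
#'   `"identity"`).
#' @param pair_mode Pair feature construction: `"hadamard"` (element-wise
#'   product of the two final embeddings; the classifier becomes a learned
#'   weighted inner product), `"concat"` (concatenation; an additive
#'   scorer), or `"both"`.
#' @param seed Integer seed for parameter initialisation.
#' @return A list of class `hgnnlda_model`.
#' @export
init_model <- function(d, k = c(lncRNA = 10L, disease = 10L, miRNA = 6L),
                       variant = c("full", "noNeigh", "noAttention"),
                       act = "relu",
                       pair_mode = c("hadamard", "concat", "both"),
                       seed = 1L) {
  variant <- match.arg(variant)
  pair_mode <- match.arg(pair_mode)
  if (d %% 2 != 0) abort("`d` must be even (hidden size is d/2 per direction)")
  m <- d %/% 2
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -r, r), nr, nc)
  }
  lstm_bias <- function(m) c(rep(0, m), rep(1, m), rep(0, 2 * m)) # forget=1

  params <- list()
  for (tk in TYPE_KEYS) {
    for (dir in c("f", "b")) {
      params[[paste0(tk, "_", dir, "_W")]] <- glorot(4 * m, d)
      params[[paste0(tk, "_", dir, "_U")]] <- glorot(4 * m, m)
      params[[paste0(tk, "_", dir, "_b")]] <- lstm_bias(m)
    }
  }
  params[["att_q"]] <- runif(2 * d, -0.1, 0.1)
  pf <- switch(pair_mode, concat = 2L, hadamard = 1L, both = 3L)
  params[["clf_W"]] <- glorot(2, pf * d)
  params[["clf_b"]] <- rep(0, 2)
  params[["fc_W"]] <- glorot(d, 4 * d)
  params[["fc_b"]] <- rep(0, d)

  structure(
    list(d = as.integer(d), m = m, k = k, variant = variant, act = act,
         pair_mode = pair_mode, seed = as.integer(seed), params = params,
         trained = FALSE),
    class = "hgnnlda_model"
  )
}

#' Switch a model between its ablation variants
#'
#' `"noNeigh"` uses the content embedding directly as the final embedding
#' (neighbour sets are ignored); `"noAttention"` replaces the attention
#' weights with a learned dense layer over the concatenated self and type
#' embeddings; `"full"` is the complete model.
#'
#' @param state An `hgnnlda_model`.
#' @param variant One of `"full"`, `"noNeigh"`, `"noAttention"`.
#' @return The model with the variant set.
#' @export
make_variant <- function(state, variant) {
  stopifnot(inherits(state, "hgnnlda_model"))
  if (!variant %in% c("full", "noNeigh", "noAttention")) {
    abort(sprintf("unknown variant '%s'", variant))
  }
  state$variant <- variant
  state
}

trainable_params <- function(state) {
  agg <- as.vector(outer(TYPE_KEYS, c("f", "b"), function(t, d)
    paste0(t, "_", d)))
  agg <- as.vector(outer(agg, c("_W", "_U", "_b"), paste0))
  switch(state$variant,
    full = c(agg, "att_q", "clf_W", "clf_b"),
    noAttention = c(agg, "fc_W", "fc_b", "clf_W", "clf_b"),
    noNeigh = c("clf_W", "clf_b")
  )
}

#' Number of trainable parameters of a model variant
#'
#' @param state An `hgnnlda_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(state) {
  sum(vapply(state$params[trainable_params(state)], length, integer(1)))
}

## ---- LSTM primitives (batched over rows) ----------------------------------

lstm_forward <- function(X, W, U, b) {
  k <- length(X)
  B <- nrow(X[[1]])
  m <- length(b) %/% 4
  H <- matrix(0, B, m); C <- matrix(0, B, m)
  Hs <- vector("list", k); cache <- vector("list", k)
  bmat <- matrix(b, B, 4 * m, byrow = TRUE)
  for (j in seq_len(k)) {
    A <- X[[j]] %*% t(W) + H %*% t(U) + bmat
    i <- sigmoid(A[, 1:m, drop = FALSE])
    f <- sigmoid(A[, (m + 1):(2 * m), drop = FALSE])
    o <- sigmoid(A[, (2 * m + 1):(3 * m), drop = FALSE])
    g <- tanh(A[, (3 * m + 1):(4 * m), drop = FALSE])
    Cn <- f * C + i * g
    tC <- tanh(Cn)
    Hn <- o * tC
    cache[[j]] <- list(i = i, f = f, o = o, g = g, C_prev = C, tC = tC,
                       H_prev = H)
    H <- Hn; C <- Cn
    Hs[[j]] <- H
  }
  list(H = Hs, cache = cache)
}

lstm_backward <- function(X, W, U, cache, dHext, want_dX = FALSE) {
  k <- length(X)
  B <- nrow(X[[1]])
  m <- ncol(cache[[1]]$i)
  dW <- matrix(0, 4 * m, ncol(W)); dU <- matrix(0, 4 * m, m)
  db <- numeric(4 * m)
  dH_next <- matrix(0, B, m); dC_next <- matrix(0, B, m)
  dX <- if (want_dX) vector("list", k) else NULL
  for (j in rev(seq_len(k))) {
    cc <- cache[[j]]
    dH <- dHext[[j]] + dH_next
    do <- dH * cc$tC
    dC <- dC_next + dH * cc$o * (1 - cc$tC^2)
    di <- dC * cc$g
    dg <- dC * cc$i
    df <- dC * cc$C_prev
    dC_next <- dC * cc$f
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dW <- dW + t(dA) %*% X[[j]]
    dU <- dU + t(dA) %*% cc$H_prev
    db <- db + colSums(dA)
    dH_next <- dA %*% U
    if (want_dX) dX[[j]] <- dA %*% W
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

# Bidirectional pass over a neighbour sequence; mean pooling of the
# position-wise forward||backward states. Because the pool averages every
# position, it equals rowMeans of each direction's states concatenated.
bilstm_forward <- function(state, tkey, X) {
  p <- state$params
  fw <- lstm_forward(X, p[[paste0(tkey, "_f_W")]], p[[paste0(tkey, "_f_U")]],
                     p[[paste0(tkey, "_f_b")]])
  bw <- lstm_forward(rev(X), p[[paste0(tkey, "_b_W")]],
                     p[[paste0(tkey, "_b_U")]], p[[paste0(tkey, "_b_b")]])
  k <- length(X)
  Hf <- Reduce(`+`, fw$H) / k
  Hb <- Reduce(`+`, bw$H) / k
  list(out = cbind(Hf, Hb), fw = fw, bw = bw)
}

bilstm_backward <- function(state, tkey, X, fwd, dOut, want_dX = FALSE) {
  k <- length(X)
  m <- state$m
  dHf <- dOut[, 1:m, drop = FALSE] / k
  dHb <- dOut[, (m + 1):(2 * m), drop = FALSE] / k
  p <- state$params
  gf <- lstm_backward(X, p[[paste0(tkey, "_f_W")]], p[[paste0(tkey, "_f_U")]],
                      fwd$fw$cache, rep(list(dHf), k), want_dX)
  gb <- lstm_backward(rev(X), p[[paste0(tkey, "_b_W")]],
                      p[[paste0(tkey, "_b_U")]], fwd$bw$cache,
                      rep(list(dHb), k), want_dX)
  grads <- setNames(
    list(gf$dW, gf$dU, gf$db, gb$dW, gb$dU, gb$db),
    paste0(tkey, c("_f_W", "_f_U", "_f_b", "_b_W", "_b_U", "_b_b"))
  )
  dX <- NULL
  if (want_dX) {
    dX <- lapply(seq_len(k), function(j) gf$dX[[j]] + gb$dX[[k - j + 1]])
  }
  list(grads = grads, dX = dX)
}

## ---- node embedding forward/backward --------------------------------------

# Forward pass producing final embeddings Z for a batch of node indices.
# F: full content matrix (n_all x d); nb: per-type neighbour index matrices.
node_forward <- function(state, F, nb, node_idx) {
  d <- state$d
  B <- length(node_idx)
  Fself <- F[node_idx, , drop = FALSE]

  if (state$variant == "noNeigh") {
    return(list(Z = Fself, Fself = Fself, members = NULL))
  }

  members <- list(self = list(out = Fself))
  for (tp in names(TYPE_KEYS)) {
    tk <- TYPE_KEYS[[tp]]
    Nt <- nb[[tp]][node_idx, , drop = FALSE]
    empty <- Nt[, 1] == 0L
    Ft <- Fself
    info <- list(out = Ft, empty = empty, rows = which(!empty))
    if (any(!empty)) {
      rows <- which(!empty)
      Nsub <- Nt[rows, , drop = FALSE]
      X <- lapply(seq_len(ncol(Nsub)),
                  function(j) F[Nsub[, j], , drop = FALSE])
      bl <- bilstm_forward(state, tk, X)
      Ft[rows, ] <- bl$out
      info <- list(out = Ft, empty = empty, rows = rows, X = X, bl = bl,
                   Nsub = Nsub)
    }
    members[[tp]] <- info
  }

  if (state$variant == "noAttention") {
    Xcat <- cbind(Fself, members$lncRNA$out, members$disease$out,
                  members$miRNA$out)
    U <- Xcat %*% t(state$params$fc_W) +
      matrix(state$params$fc_b, B, d, byrow = TRUE)
    Z <- if (state$act == "relu") relu(U) else U
    return(list(Z = Z, Fself = Fself, members = members, Xcat = Xcat, U = U))
  }

  # attention fusion over {self, lncRNA, disease, miRNA}
  q1 <- state$params$att_q[1:d]
  q2 <- state$params$att_q[(d + 1):(2 * d)]
  base <- as.numeric(Fself %*% q1)
  Alog <- vapply(members, function(mb) base + as.numeric(mb$out %*% q2),
                 numeric(B))
  Alog <- matrix(Alog, nrow = B)  # B x 4, columns in member order
  R <- relu(Alog)
  beta <- softmax_rows(R)
  U <- matrix(0, B, d)
  for (ki in seq_along(members)) {
    U <- U + beta[, ki] * members[[ki]]$out
  }
  Z <- if (state$act == "relu") relu(U) else U
  list(Z = Z, Fself = Fself, members = members, Alog = Alog, beta = beta,
       U = U)
}

# Backward from dZ (B x d) to parameter gradients (and optionally content
# gradients for fine-tuning). Returns a flat grad list.
node_backward <- function(state, F, nb, node_idx, fw, dZ,
                          want_content = FALSE) {
  d <- state$d
  B <- length(node_idx)
  grads <- list()
  dF <- if (want_content) matrix(0, nrow(F), d) else NULL
  add_content <- function(idx, val) {
    if (!want_content) return(invisible(NULL))
    # accumulate rows of `val` into dF at (possibly repeated) indices
    agg <- rowsum(val, idx)
    at <- as.integer(rownames(agg))
    dF[at, ] <<- dF[at, , drop = FALSE] + agg
    invisible(NULL)
  }

  if (state$variant == "noNeigh") {
    add_content(node_idx, dZ)
    return(list(grads = grads, dF = dF))
  }

  members <- fw$members
  if (state$variant == "noAttention") {
    dU <- if (state$act == "relu") dZ * (fw$U > 0) else dZ
    grads$fc_W <- t(dU) %*% fw$Xcat
    grads$fc_b <- colSums(dU)
    dXcat <- dU %*% state$params$fc_W
    dmember <- list(
      self = dXcat[, 1:d, drop = FALSE],
      lncRNA = dXcat[, (d + 1):(2 * d), drop = FALSE],
      disease = dXcat[, (2 * d + 1):(3 * d), drop = FALSE],
      miRNA = dXcat[, (3 * d + 1):(4 * d), drop = FALSE]
    )
  } else {
    dU <- if (state$act == "relu") dZ * (fw$U > 0) else dZ
    beta <- fw$beta
    nm <- names(members)
    dbeta <- vapply(seq_along(members), function(ki)
      rowSums(dU * members[[ki]]$out), numeric(B))
    dbeta <- matrix(dbeta, nrow = B)
    srow <- rowSums(beta * dbeta)
    dR <- beta * (dbeta - srow)
    dA <- dR * (fw$Alog > 0)
    q1 <- state$params$att_q[1:d]
    q2 <- state$params$att_q[(d + 1):(2 * d)]
    dq1 <- numeric(d); dq2 <- numeric(d)
    dmember <- list()
    dself_extra <- matrix(0, B, d)
    for (ki in seq_along(members)) {
      Fk <- members[[ki]]$out
      dq1 <- dq1 + as.numeric(t(fw$Fself) %*% dA[, ki])
      dq2 <- dq2 + as.numeric(t(Fk) %*% dA[, ki])
      dmember[[nm[ki]]] <- beta[, ki] * dU + outer(dA[, ki], q2)
      dself_extra <- dself_extra + outer(dA[, ki], q1)
    }
    dmember$self <- dmember$self + dself_extra
    grads$att_q <- c(dq1, dq2)
  }

  # self member -> content embedding of the centre
  add_content(node_idx, dmember$self)

  # type members -> Bi-LSTM parameters (non-empty rows) or content fallback
  for (tp in names(TYPE_KEYS)) {
    tk <- TYPE_KEYS[[tp]]
    mb <- members[[tp]]
    dFt <- dmember[[tp]]
    if (any(mb$empty)) {
      erows <- which(mb$empty)
      add_content(node_idx[erows], dFt[erows, , drop = FALSE])
    }
    if (length(mb$rows) > 0) {
      bb <- bilstm_backward(state, tk, mb$X, mb$bl,
                            dFt[mb$rows, , drop = FALSE],
                            want_dX = want_content)
      for (nmg in names(bb$grads)) {
        grads[[nmg]] <- if (is.null(grads[[nmg]])) bb$grads[[nmg]] else
          grads[[nmg]] + bb$grads[[nmg]]
      }
      if (want_content) {
        for (j in seq_along(bb$dX)) {
          add_content(mb$Nsub[, j], bb$dX[[j]])
        }
      }
    }
  }
  list(grads = grads, dF = dF)
}

## ---- pair scoring and loss -------------------------------------------------

# Full forward over labelled pairs; returns mean cross-entropy loss, scores
# and the caches needed for the backward pass.
model_forward <- function(state, F, nb, pairs_idx, labels = NULL) {
  node_idx <- sort(unique(as.integer(pairs_idx)))
  pl <- match(pairs_idx[, 1], node_idx)
  pd <- match(pairs_idx[, 2], node_idx)
  fw <- node_forward(state, F, nb, node_idx)
  Zl <- fw$Z[pl, , drop = FALSE]
  Zd <- fw$Z[pd, , drop = FALSE]
  X2 <- switch(state$pair_mode,
    concat = cbind(Zl, Zd),
    hadamard = Zl * Zd,
    both = cbind(Zl, Zd, Zl * Zd)
  )
  logits <- X2 %*% t(state$params$clf_W) +
    matrix(state$params$clf_b, nrow(X2), 2, byrow = TRUE)
  P <- softmax_rows(logits)
  scores <- P[, 2]
  loss <- NA_real_
  if (!is.null(labels)) {
    mx <- apply(logits, 1, max)
    lp <- logits - mx - log(rowSums(exp(logits - mx)))
    loss <- -mean(lp[cbind(seq_along(labels), labels + 1L)])
  }
  list(loss = loss, scores = scores, P = P, X2 = X2, Zl = Zl, Zd = Zd,
       fw = fw, node_idx = node_idx, pl = pl, pd = pd)
}

model_backward <- function(state, F, nb, pairs_idx, labels, mf,
                           want_content = FALSE) {
  n <- length(labels)
  d <- state$d
  Y <- matrix(0, n, 2)
  Y[cbind(seq_len(n), labels + 1L)] <- 1
  dlogits <- (mf$P - Y) / n
  grads <- list(
    clf_W = t(dlogits) %*% mf$X2,
    clf_b = colSums(dlogits)
  )
  dX2 <- dlogits %*% state$params$clf_W
  dzl_dzd <- switch(state$pair_mode,
    concat = list(dX2[, 1:d, drop = FALSE],
                  dX2[, (d + 1):(2 * d), drop = FALSE]),
    hadamard = list(dX2 * mf$Zd, dX2 * mf$Zl),
    both = list(dX2[, 1:d, drop = FALSE] +
                  dX2[, (2 * d + 1):(3 * d), drop = FALSE] * mf$Zd,
                dX2[, (d + 1):(2 * d), drop = FALSE] +
                  dX2[, (2 * d + 1):(3 * d), drop = FALSE] * mf$Zl)
  )
  B <- length(mf$node_idx)
  dZ <- matrix(0, B, d)
  agg_l <- rowsum(dzl_dzd[[1]], mf$pl)
  dZ[as.integer(rownames(agg_l)), ] <-
    dZ[as.integer(rownames(agg_l)), , drop = FALSE] + agg_l
  agg_d <- rowsum(dzl_dzd[[2]], mf$pd)
  dZ[as.integer(rownames(agg_d)), ] <-
    dZ[as.integer(rownames(agg_d)), , drop = FALSE] + agg_d
  nbk <- node_backward(state, F, nb, mf$node_idx, mf$fw, dZ, want_content)
  list(grads = c(grads, nbk$grads), dF = nbk$dF)
}

#' Aggregate one type's neighbour embeddings with its Bi-LSTM
#'
#' Runs the forward and backward LSTM passes of the given type's aggregator
#' over an ordered (frequency-descending) neighbour embedding sequence,
#' concatenates the per-position forward and backward hidden states (each
#' `d/2`-dimensional) and mean-pools over positions.
#'
#' @param state An `hgnnlda_model`.
#' @param type Neighbour node type (`"lncRNA"`, `"disease"` or `"miRNA"`).
#' @param neighbor_vectors A `k_t x d` matrix of neighbour content vectors
#'   (rows in frequency-descending order), or a zero-row matrix.
#' @param center Content vector of the centre node, returned unchanged when
#'   the type was never sampled (`neighbor_vectors` has no rows).
#' @return A `d`-dimensional type embedding.
#' @export
aggregate_type <- function(state, type, neighbor_vectors, center = NULL) {
  stopifnot(inherits(state, "hgnnlda_model"))
  tk <- TYPE_KEYS[[match.arg(type, names(TYPE_KEYS))]]
  if (is.null(dim(neighbor_vectors))) {
    neighbor_vectors <- matrix(neighbor_vectors, nrow = 1)
  }
  if (nrow(neighbor_vectors) == 0) {
    if (is.null(center)) abort("empty neighbour set requires `center`")
    return(as.numeric(center))
  }
  if (ncol(neighbor_vectors) != state$d) {
    abort("neighbour vectors must have dimension `d`")
  }
  X <- lapply(seq_len(nrow(neighbor_vectors)), function(j)
    neighbor_vectors[j, , drop = FALSE])
  as.numeric(bilstm_forward(state, tk, X)$out)
}

#' Fuse self and type embeddings with attention
#'
#' Attention logit for member `k` is `ReLU(q^T [f(v) || f^k(v)])`; weights
#' `beta` are their softmax over the members present (the node itself plus
#' every supplied type embedding), and the fused embedding is
#' `ReLU(sum_k beta_k f^k(v))`.
#'
#' @param f_self The node's own `d`-dimensional content embedding.
#' @param f_types Named list of up to three type embeddings.
#' @param q Attention vector of length `2d`.
#' @param act Outer activation (`"relu"`, the default, or `"identity"`).
#' @return A list with the fused embedding `z` and the attention weights
#'   `betas` (named, summing to 1).
#' @export
attention_fuse <- function(f_self, f_types, q, act = "relu") {
  d <- length(f_self)
  if (length(q) != 2 * d) abort("`q` must have length 2d")
  bad <- vapply(f_types, function(v) length(v) != d, logical(1))
  if (any(bad)) abort("all type embeddings must have dimension d")
  members <- c(list(self = f_self), f_types)
  logits <- vapply(members, function(fk)
    relu(sum(q * c(f_self, fk))), numeric(1))
  e <- exp(logits - max(logits))
  betas <- e / sum(e)
  u <- Reduce(`+`, Map(`*`, betas, members))
  z <- if (act == "relu") relu(u) else u
  list(z = as.numeric(z), betas = betas)
}

#' Score one lncRNA-disease pair
#'
#' Builds the pair feature vector (by default the concatenation of the two
#' final embeddings), applies the 2-class linear layer and softmax, and
#' returns the positive-class probability.
#'
#' @param z_l,z_d Final embeddings of the lncRNA and the disease.
#' @param W Classifier weights, `2 x 2d` for `"concat"`, `2 x d` for
#'   `"hadamard"`, `2 x 3d` for `"both"`.
#' @param b Length-2 bias.
#' @param mode Pair feature construction (see [hgnnlda_config()]).
#' @return The association score in `[0, 1]` (its complement is the
#'   negative-class probability).
#' @export
score_pair <- function(z_l, z_d, W, b = c(0, 0),
                       mode = c("concat", "hadamard", "both")) {
  mode <- match.arg(mode)
  if (length(z_l) != length(z_d)) abort("embeddings must share dimension")
  x <- switch(mode, concat = c(z_l, z_d), hadamard = z_l * z_d,
              both = c(z_l, z_d, z_l * z_d))
  if (ncol(W) != length(x)) abort("`W` has the wrong width for this mode")
  logits <- as.numeric(W %*% x + b)
  e <- exp(logits - max(logits))
  (e / sum(e))[2]
}

#' Cross-entropy loss of association scores
#'
#' Two-class cross-entropy
#' `-sum_i [ y_i log s_i + (1 - y_i) log(1 - s_i) ]`. Scores exactly 0 or 1
#' are clamped at `1e-12` with a warning.
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels 0/1 labels of the same length.
#' @return The (non-negative) total loss.
#' @export
cross_entropy_loss <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length")
  }
  eps <- 1e-12
  if (any(scores <= 0 | scores >= 1)) {
    warn("score(s) at 0 or 1 clamped to avoid log(0)")
    scores <- pmin(pmax(scores, eps), 1 - eps)
  }
  -sum(labels * log(scores) + (1 - labels) * log(1 - scores))
}

## ---- training ---------------------------------------------------------------

adam_init <- function(params, keys) {
  list(m = lapply(params[keys], function(p) p * 0),
       v = lapply(params[keys], function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(opt$m)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

#' Train the association model
#'
#' Mini-batch Adam on the two-class cross-entropy of labelled
#' lncRNA-disease pairs. Content embeddings are frozen inputs unless
#' `fine_tune` is set in the configuration. Fully deterministic given the
#' seed.
#'
#' @param state An `hgnnlda_model` from [init_model()].
#' @param F Content matrix (`n_nodes x d`) aligned to graph node indices.
#' @param nb Per-type neighbour index matrices (from [sample_all()]
#'   `$index`).
#' @param pairs_idx Two-column integer matrix of (lncRNA, disease) node
#'   indices.
#' @param labels 0/1 labels per pair.
#' @param config An [hgnnlda_config()] (uses `epochs`, `lr`, `batch_size`,
#'   `fine_tune`).
#' @param seed Training seed (defaults to the config seed).
#' @return A list with the trained `state`, the (possibly fine-tuned) `F`,
#'   and `trajectory`, a tibble of mean per-pair loss by epoch.
#' @export
train_model <- function(state, F, nb, pairs_idx, labels,
                        config = hgnnlda_config(), seed = config$seed) {
  stopifnot(inherits(state, "hgnnlda_model"))
  if (max(pairs_idx) > nrow(F)) abort("pair references unknown node index")
  n <- length(labels)
  keys <- trainable_params(state)
  opt <- adam_init(state$params, keys)
  optF <- if (config$fine_tune) list(m = F * 0, v = F * 0, t = 0) else NULL
  bs <- if (!is.finite(config$batch_size)) n else
    min(as.integer(config$batch_size), n)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  losses <- numeric(config$epochs)
  avg_tail <- config$avg_tail %||% 0
  avg_from <- if (avg_tail > 0) {
    max(1L, config$epochs - as.integer(ceiling(avg_tail * config$epochs)) + 1L)
  } else config$epochs + 1L
  avg_sum <- NULL; avg_n <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (b0 in seq(1, n, by = bs)) {
      sel <- ord[b0:min(b0 + bs - 1, n)]
      mf <- model_forward(state, F, nb, pairs_idx[sel, , drop = FALSE],
                          labels[sel])
      bk <- model_backward(state, F, nb, pairs_idx[sel, , drop = FALSE],
                           labels[sel], mf, want_content = config$fine_tune)
      st <- adam_step(state$params, bk$grads, opt, config$lr)
      state$params <- st$params; opt <- st$opt
      if (config$fine_tune) {
        optF$t <- optF$t + 1
        optF$m <- 0.9 * optF$m + 0.1 * bk$dF
        optF$v <- 0.999 * optF$v + 0.001 * bk$dF^2
        F <- F - config$lr * (optF$m / (1 - 0.9^optF$t)) /
          (sqrt(optF$v / (1 - 0.999^optF$t)) + 1e-8)
      }
      tot <- tot + mf$loss * length(sel)
    }
    losses[ep] <- tot / n
    if (ep >= avg_from) {
      keys_avg <- trainable_params(state)
      if (is.null(avg_sum)) {
        avg_sum <- state$params[keys_avg]
      } else {
        for (nm in keys_avg) {
          avg_sum[[nm]] <- avg_sum[[nm]] + state$params[[nm]]
        }
      }
      avg_n <- avg_n + 1L
    }
  }
  if (avg_n > 0L) {
    for (nm in names(avg_sum)) {
      state$params[[nm]] <- avg_sum[[nm]] / avg_n
    }
  }
  state$trained <- TRUE
  list(state = state, F = F,
       trajectory = tibble::tibble(epoch = seq_len(config$epochs),
                                   loss = losses))
}

#' Score lncRNA-disease pairs with a trained model
#'
#' @param state A trained `hgnnlda_model`.
#' @param F Content matrix aligned to graph node indices.
#' @param nb Per-type neighbour index matrices.
#' @param pairs_idx Two-column integer matrix of (lncRNA, disease) node
#'   indices.
#' @return Numeric scores in `[0, 1]`, one per pair (batch-order
#'   invariant).
#' @export
predict_pairs <- function(state, F, nb, pairs_idx) {
  stopifnot(inherits(state, "hgnnlda_model"))
  if (nrow(pairs_idx) == 0) return(numeric(0))
  if (max(pairs_idx) > nrow(F)) abort("pair references unknown node index")
  model_forward(state, F, nb, pairs_idx)$scores
}

#' Compare analytic and finite-difference gradients
#'
#' Central finite differences of the mean cross-entropy loss with respect to
#' every trainable parameter, compared with the analytic backward pass.
#'
#' @param state An `hgnnlda_model` (small `d` recommended).
#' @param F,nb,pairs_idx,labels As in [train_model()].
#' @param eps Finite-difference step.
#' @return A tibble with per-parameter maximum relative error
#'   (`|ga - gn| / max(|ga| + |gn|, 1e-6)`).
#' @export
check_gradients <- function(state, F, nb, pairs_idx, labels, eps = 1e-5) {
  mf <- model_forward(state, F, nb, pairs_idx, labels)
  bk <- model_backward(state, F, nb, pairs_idx, labels, mf)
  keys <- trainable_params(state)
  loss_at <- function(st) {
    model_forward(st, F, nb, pairs_idx, labels)$loss
  }
  purrr::map_dfr(keys, function(nm) {
    p <- state$params[[nm]]
    ga <- bk$grads[[nm]]
    if (is.null(ga)) ga <- p * 0
    gn <- p * 0
    for (i in seq_along(p)) {
      sp <- state; sp$params[[nm]][i] <- p[i] + eps
      sm <- state; sm$params[[nm]][i] <- p[i] - eps
      gn[i] <- (loss_at(sp) - loss_at(sm)) / (2 * eps)
    }
    # floor the denominator at 1e-6: central differences carry O(eps^2)
    # truncation noise (~1e-10 here), which would otherwise dominate the
    # relative error of genuinely-zero gradients
    rel <- abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-6)
    tibble::tibble(param = nm, max_rel_error = max(rel),
                   max_abs_error = max(abs(ga - gn)))
  })
}

#' @export
print.hgnnlda_model <- function(x, ...) {
  cat(sprintf("<hgnnlda_model> variant=%s d=%d trainable parameters=%d%s\n",
              x$variant, x$d, n_parameters(x),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}
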