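# Restart random walk sampling of typed strong-correlation neighbours.

#' Restart random walk from one node
#'
#' Walks the heterogeneous graph from `start`. At each step the walk jumps
#' back to `start` with probability `p`; otherwise it moves to a neighbour
#' drawn with probability proportional to edge weight times a node2vec-style
#' in-out bias (`1/q` for candidates not adjacent to the previous node,
#' 1 otherwise; `q = 1` is an unbiased restart walk). The walk ends once
#' `collect_size` non-start visits are banked and every node type has at
#' least `min_per_type` banked visits, or at `max_steps` steps, in which case
#' the result is flagged and downstream padding applies.
#'
#' @param graph A `hetero_graph`.
#' @param start Node identifier (or index) to walk from; must have at least
#'   one edge.
#' @param config An [hgnnlda_config()] supplying `p`, `q`, `collect_size`,
#'   `min_per_type` and `max_steps`.
#' @param seed Integer seed for this walk (defaults to the config seed).
#' @return A list with `sequence` (visited identifiers in order, start
#'   first), `counts` (tibble `node`, `type`, `count` of banked visits),
#'   `steps` and `flagged`.
#' @export
restart_random_walk <- function(graph, start, config = hgnnlda_config(),
                                seed = config$seed) {
  stopifnot(inherits(graph, "hetero_graph"))
  start_idx <- resolve_node(graph, start)
  if (graph$adj$degree[start_idx] == 0) {
    abort(sprintf("start node '%s' is isolated and cannot be walked from",
                  graph$nodes$id[start_idx]))
  }
  res <- .rrw_walk_cpp(graph$adj$offsets, graph$adj$idx, graph$adj$weights,
                       graph$adj$node_type, start_idx - 1L,
                       config$p, config$q, config$collect_size,
                       config$min_per_type, config$max_steps,
                       as.numeric(seed))
  visited <- which(res$counts > 0)
  counts <- tibble::tibble(
    node = graph$nodes$id[visited],
    type = graph$nodes$type[visited],
    count = res$counts[visited]
  )
  list(sequence = graph$nodes$id[res$sequence + 1L],
       counts = counts, steps = res$steps, flagged = res$flagged)
}

resolve_node <- function(graph, node) {
  if (is.numeric(node)) {
    idx <- as.integer(node)
    if (idx < 1 || idx > nrow(graph$nodes)) abort("node index out of range")
    return(idx)
  }
  idx <- match(node, graph$nodes$id)
  if (is.na(idx)) abort(sprintf("unknown node '%s'", node))
  idx
}

#' Exact visiting distribution of the restart walk
#'
#' Test oracle for the sampler in the unbiased (`q = 1`) case: solves
#' `pi = p * e_start + (1 - p) * t(W) pi` by power iteration, where `W` is
#' the weight-normalised transition matrix. For `p = 0` on an undirected
#' graph the stationary distribution is the closed-form strength-weighted
#' distribution, which is returned directly (power iteration need not
#' converge on periodic graphs).
#'
#' @param graph A `hetero_graph`.
#' @param start Start node identifier or index.
#' @param p Restart probability.
#' @param tol Convergence tolerance on the max-norm change.
#' @param max_iter Iteration cap.
#' @return A named probability vector over all nodes (sums to 1).
#' @export
exact_visit_distribution <- function(graph, start, p, tol = 1e-10,
                                     max_iter = 100000L) {
  stopifnot(inherits(graph, "hetero_graph"))
  start_idx <- resolve_node(graph, start)
  n <- nrow(graph$nodes)
  if (p >= 1) {
    pi <- numeric(n); pi[start_idx] <- 1
    return(setNames(pi, graph$nodes$id))
  }
  W <- transition_matrix(graph)
  if (p == 0) {
    strength <- rowSums(weight_matrix(graph))
    return(setNames(strength / sum(strength), graph$nodes$id))
  }
  e <- numeric(n); e[start_idx] <- 1
  pi <- e
  tW <- t(W)
  for (it in seq_len(max_iter)) {
    nxt <- p * e + (1 - p) * as.numeric(tW %*% pi)
    if (max(abs(nxt - pi)) <= tol) {
      return(setNames(nxt / sum(nxt), graph$nodes$id))
    }
    pi <- nxt
  }
  abort("power iteration did not converge within `max_iter`")
}

weight_matrix <- function(graph) {
  n <- nrow(graph$nodes)
  W <- matrix(0, n, n)
  e <- graph$edges
  W[cbind(e$from, e$to)] <- e$weight
  W[cbind(e$to, e$from)] <- e$weight
  W
}

transition_matrix <- function(graph) {
  W <- weight_matrix(graph)
  rs <- rowSums(W)
  rs[rs == 0] <- 1
  W / rs
}

#' Select the top-k typed neighbours from banked walk visits
#'
#' Per node type, neighbours are ranked by visit frequency (descending, ties
#' by identifier) and the top `k_t` kept. A type with fewer than `k_t`
#' distinct neighbours is padded by cycling its sampled list; a type with no
#' sampled neighbour is returned empty (the model substitutes the centre's
#' own content embedding).
#'
#' @param counts Tibble with columns `node`, `type`, `count` as returned in
#'   [restart_random_walk()]`$counts`.
#' @param config An [hgnnlda_config()] supplying `k_lnc`, `k_dis`, `k_mi`.
#' @return A named list over types, each a tibble `neighbor`, `frequency`,
#'   `rank` of exactly `k_t` rows (or zero rows when the type was never
#'   sampled).
#' @export
select_typed_neighbors <- function(counts, config = hgnnlda_config()) {
  k <- c(lncRNA = config$k_lnc, disease = config$k_dis, miRNA = config$k_mi)
  out <- lapply(node_types(), function(tp) {
    kt <- k[[tp]]
    sub <- counts[counts$type == tp, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(tibble::tibble(neighbor = character(0), frequency = integer(0),
                            rank = integer(0)))
    }
    sub <- sub[order(-sub$count, sub$node), , drop = FALSE]
    sel <- head(seq_len(nrow(sub)), kt)
    idx <- rep_len(sel, kt)  # cycling pad when fewer than k_t distinct
    tibble::tibble(neighbor = sub$node[idx], frequency = sub$count[idx],
                   rank = seq_len(kt))
  })
  setNames(out, node_types())
}

#' Sample typed neighbour sets for every node
#'
#' Runs one restart random walk per non-isolated node (each with a seed
#' derived deterministically from the configuration seed and the node
#' index), selects per-type top-k neighbour lists, and returns the walk
#' sequences as the corpus for skip-gram embedding.
#'
#' @param graph A `hetero_graph`.
#' @param config An [hgnnlda_config()].
#' @return A list of class `typed_neighbors` with:
#'   * `table`: tidy tibble `center`, `type`, `rank`, `neighbor`, `frequency`;
#'   * `index`: per type, an `n_nodes x k_t` matrix of neighbour node
#'     indices (0 marks an empty type for that centre);
#'   * `corpus`: list of walk sequences (identifier vectors);
#'   * `flagged`, `skipped`: identifiers of quota-unmet walks and isolated
#'     nodes.
#' @export
sample_all <- function(graph, config = hgnnlda_config()) {
  stopifnot(inherits(graph, "hetero_graph"))
  n <- nrow(graph$nodes)
  k <- c(lncRNA = config$k_lnc, disease = config$k_dis, miRNA = config$k_mi)
  index <- lapply(k, function(kt) matrix(0L, n, kt))
  freqs <- lapply(k, function(kt) matrix(0L, n, kt))
  corpus <- vector("list", n)
  flagged <- character(0)
  skipped <- isolated_nodes(graph)
  ntype <- as.integer(graph$nodes$type)

  for (v in seq_len(n)) {
    if (graph$adj$degree[v] == 0) next
    res <- .rrw_walk_cpp(graph$adj$offsets, graph$adj$idx,
                         graph$adj$weights, graph$adj$node_type, v - 1L,
                         config$p, config$q, config$collect_size,
                         config$min_per_type, config$max_steps,
                         as.numeric(derive_seed(config$seed, v)))
    corpus[[v]] <- res$sequence + 1L
    if (res$flagged) flagged <- c(flagged, graph$nodes$id[v])
    visited <- which(res$counts > 0)
    cnt <- res$counts[visited]
    vt <- ntype[visited]
    for (ti in 1:3) {
      tp <- node_types()[ti]
      kt <- k[[tp]]
      cand <- visited[vt == ti]
      if (length(cand) == 0) next
      ccnt <- cnt[vt == ti]
      o <- order(-ccnt, graph$nodes$id[cand])
      sel <- rep_len(o[seq_len(min(kt, length(o)))], kt)
      index[[tp]][v, ] <- cand[sel]
      freqs[[tp]][v, ] <- ccnt[sel]
    }
  }

  # tidy table assembled once from the index matrices
  tab <- dplyr::bind_rows(lapply(node_types(), function(tp) {
    im <- index[[tp]]
    fm <- freqs[[tp]]
    hit <- which(im != 0L, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    out <- tibble::tibble(center = graph$nodes$id[hit[, 1]], type = tp,
                          rank = hit[, 2],
                          neighbor = graph$nodes$id[im[hit]],
                          frequency = fm[hit])
    out[order(out$center, out$rank), , drop = FALSE]
  }))

  structure(
    list(table = tab,
         index = index,
         corpus = corpus[!vapply(corpus, is.null, logical(1))],
         corpus_ids = lapply(corpus[!vapply(corpus, is.null, logical(1))],
                             function(s) graph$nodes$id[s]),
         node_ids = graph$nodes$id,
         flagged = flagged, skipped = skipped),
    class = "typed_neighbors"
  )
}

#' Write a walk corpus as plain text
#'
#' One whitespace-separated node-identifier sequence per line.
#'
#' @param neighbors A `typed_neighbors` object from [sample_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(neighbors, path) {
  lines <- vapply(neighbors$corpus_ids, paste, character(1), collapse = " ")
  writeLines(lines, path)
  invisible(path)
}
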