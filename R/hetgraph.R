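# Heterogeneous network over lncRNA, disease and miRNA nodes with three edge
# types: lncRNA-disease and lncRNA-miRNA association edges (weight 1) and
# lncRNA-lncRNA similarity edges (weight = functional similarity).

#' Assemble the heterogeneous network
#'
#' Builds the typed, weighted, undirected network `G = (N, E, NT, ET)` from
#' the lncRNA functional similarity matrix and the two association matrices.
#' Association edges are taken where the matrix entry is 1; the dense
#' similarity layer is sparsified to each lncRNA's `lnc_topk` most similar
#' partners (ties broken by identifier order, self-pairs excluded, zero
#' similarities dropped), or by a fixed threshold in `"threshold"` mode.
#'
#' @param lfs Symmetric lncRNA functional similarity matrix.
#' @param ld Binary lncRNA-by-disease association matrix.
#' @param lm Binary lncRNA-by-miRNA association matrix.
#' @param lnc_topk Partners kept per lncRNA in `"topk"` mode.
#' @param mode `"topk"` (default) or `"threshold"` similarity sparsification.
#' @param threshold Similarity cutoff for `"threshold"` mode.
#' @return A list of class `hetero_graph` with `nodes` (tibble: `id`,
#'   `type`, `index`), `edges` (tibble: `from`, `to`, `weight`,
#'   `edge_type`, ids in `from_id`/`to_id`) and a CSR adjacency used by the
#'   walker.
#' @export
build_hetero_graph <- function(lfs, ld, lm, lnc_topk = 10L,
                               mode = c("topk", "threshold"),
                               threshold = 0.5) {
  mode <- match.arg(mode)
  check_square_named(lfs, "lfs")
  check_binary_matrix(ld, "ld")
  check_binary_matrix(lm, "lm")
  if (!identical(rownames(lfs), rownames(ld)) ||
      !identical(rownames(lfs), rownames(lm))) {
    abort("lncRNA labels of `lfs`, `ld` and `lm` must be identical")
  }

  lnc_ids <- rownames(ld)
  dis_ids <- colnames(ld)
  mi_ids <- colnames(lm)
  nodes <- tibble::tibble(
    id = c(lnc_ids, dis_ids, mi_ids),
    type = factor(rep(node_types(),
                      times = c(length(lnc_ids), length(dis_ids),
                                length(mi_ids))),
                  levels = node_types())
  )
  if (anyDuplicated(nodes$id)) {
    abort("node identifiers must be unique across all three types")
  }
  nodes$index <- seq_len(nrow(nodes))
  idx_of <- setNames(nodes$index, nodes$id)

  # association edges
  ld_hits <- which(ld == 1, arr.ind = TRUE)
  lm_hits <- which(lm == 1, arr.ind = TRUE)
  e_ld <- tibble::tibble(
    from = unname(idx_of[lnc_ids[ld_hits[, 1]]]),
    to = unname(idx_of[dis_ids[ld_hits[, 2]]]),
    weight = rep(1, nrow(ld_hits)),
    edge_type = rep("lncRNA-disease", nrow(ld_hits))
  )
  e_lm <- tibble::tibble(
    from = unname(idx_of[lnc_ids[lm_hits[, 1]]]),
    to = unname(idx_of[mi_ids[lm_hits[, 2]]]),
    weight = rep(1, nrow(lm_hits)),
    edge_type = rep("lncRNA-miRNA", nrow(lm_hits))
  )

  # similarity edges: per-lncRNA selection, stored once per unordered pair
  sim <- lfs
  diag(sim) <- 0
  pick <- matrix(FALSE, nrow(sim), ncol(sim))
  for (i in seq_len(nrow(sim))) {
    s <- sim[i, ]
    if (mode == "topk") {
      keep <- order(-s, lnc_ids)       # ties by identifier order
      keep <- keep[seq_len(min(lnc_topk, length(keep)))]
      keep <- keep[s[keep] > 0]
    } else {
      keep <- which(s >= threshold)
    }
    pick[i, keep] <- TRUE
  }
  sel <- which(pick | t(pick), arr.ind = TRUE)
  sel <- sel[sel[, 1] < sel[, 2], , drop = FALSE]
  e_ll <- tibble::tibble(
    from = unname(idx_of[lnc_ids[sel[, 1]]]),
    to = unname(idx_of[lnc_ids[sel[, 2]]]),
    weight = sim[sel],
    edge_type = rep("lncRNA-lncRNA", nrow(sel))
  )

  edges <- dplyr::bind_rows(e_ld, e_ll, e_lm)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  edges$from_id <- nodes$id[edges$from]
  edges$to_id <- nodes$id[edges$to]

  g <- structure(
    list(nodes = nodes, edges = edges, adj = build_csr(nodes, edges)),
    class = "hetero_graph"
  )
  iso <- isolated_nodes(g)
  if (length(iso) > 0) {
    warn(sprintf("%d isolated node(s) cannot be walked from (e.g. %s)",
                 length(iso), paste(head(iso, 3), collapse = ", ")))
  }
  g
}

# Compressed sparse rows over the undirected edge set, 0-based for C++.
# Neighbour lists are sorted by index (required by the walker's adjacency
# bisection and the documented tie behaviour).
build_csr <- function(nodes, edges) {
  n <- nrow(nodes)
  from <- c(edges$from, edges$to)
  to <- c(edges$to, edges$from)
  w <- c(edges$weight, edges$weight)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; w <- w[o]
  deg <- tabulate(from, nbins = n)
  offsets <- c(0L, cumsum(deg))
  list(offsets = as.integer(offsets), idx = as.integer(to - 1L),
       weights = as.numeric(w), node_type = as.integer(nodes$type),
       degree = deg)
}

isolated_nodes <- function(graph) {
  graph$nodes$id[graph$adj$degree == 0]
}

#' Per-type degree summary of a heterogeneous graph
#'
#' @param graph A [build_hetero_graph()] result.
#' @return A tibble with one row per node type: `n`, `min_degree`,
#'   `median_degree`, `max_degree`, `n_isolated` and an `isolated` list
#'   column of identifiers.
#' @export
degree_report <- function(graph) {
  stopifnot(inherits(graph, "hetero_graph"))
  deg <- graph$adj$degree
  purrr::map_dfr(node_types(), function(tp) {
    sel <- graph$nodes$type == tp
    d <- deg[sel]
    tibble::tibble(
      type = tp,
      n = sum(sel),
      min_degree = if (any(sel)) min(d) else 0L,
      median_degree = if (any(sel)) median(d) else 0,
      max_degree = if (any(sel)) max(d) else 0L,
      n_isolated = sum(d == 0),
      isolated = list(graph$nodes$id[sel][d == 0])
    )
  })
}

#' Export a heterogeneous graph as a typed edge-list tibble
#'
#' @param graph A `hetero_graph`.
#' @return A tibble with columns `from`, `to`, `weight`, `edge_type`
#'   (identifiers, one row per undirected edge).
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "hetero_graph"))
  tibble::tibble(from = graph$edges$from_id, to = graph$edges$to_id,
                 weight = graph$edges$weight,
                 edge_type = graph$edges$edge_type)
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("<hetero_graph> %d nodes (%s), %d undirected edges\n",
              nrow(x$nodes),
              paste(sprintf("%s: %d", levels(x$nodes$type),
                            tabulate(x$nodes$type)), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}
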