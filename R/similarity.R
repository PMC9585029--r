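# Disease semantic similarity (Wang-style DAG contribution decay) and lncRNA
# functional similarity derived from it.

#' Construct a disease ontology
#'
#' Validates a child-to-parent edge list as a directed acyclic graph and
#' fixes the semantic contribution decay factor used by [compute_dss()].
#'
#' @param edges A data frame with columns `child` and `parent`, each edge
#'   pointing from a more specific disease term to a more general one.
#' @param terms Optional character vector of all terms (defaults to the union
#'   of edge endpoints); terms absent from `edges` are isolated roots.
#' @param delta Semantic contribution decay factor, strictly between 0 and 1.
#'   Each step away from a disease along the DAG multiplies that disease's
#'   contribution by `delta`; 0.5 is the conventional value.
#' @return A list of class `disease_ontology`.
#' @export
disease_ontology <- function(edges, terms = NULL, delta = 0.5) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("child", "parent") %in% names(edges))) {
    abort("`edges` must have columns `child` and `parent`")
  }
  if (delta <= 0 || delta >= 1) {
    abort("`delta` must lie strictly between 0 and 1")
  }
  terms <- terms %||% sort(unique(c(edges$child, edges$parent)))
  unknown <- setdiff(c(edges$child, edges$parent), terms)
  if (length(unknown) > 0) {
    abort(paste0("edge references unknown term(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE,
                                       vertices = data.frame(name = terms))
    if (!igraph::is_dag(g)) abort("cycle detected: ontology must be acyclic")
  }
  parents <- split(edges$parent, edges$child)
  children <- split(edges$child, edges$parent)
  structure(
    list(terms = terms, edges = edges, delta = delta,
         parents = parents, children = children),
    class = "disease_ontology"
  )
}

# Semantic contribution of every ancestor of `d` (including d itself):
# D_d(d) = 1; D_d(t) = delta * max over children of t lying on a path to d.
semantic_contributions <- function(ontology, d) {
  delta <- ontology$delta
  contrib <- c(setNames(1, d))
  frontier <- d
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (t in frontier) {
      for (p in ontology$parents[[t]] %||% character(0)) {
        cand <- delta * contrib[[t]]
        if (!(p %in% names(contrib)) || cand > contrib[[p]]) {
          contrib[p] <- cand
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  contrib
}

#' Disease semantic similarity from an ontology
#'
#' For each disease `d`, every ancestor term `t` contributes
#' `D_d(t) = delta^depth` along the best path (`D_d(d) = 1`), giving the
#' semantic value `DV(d) = sum_t D_d(t)`. The similarity of two diseases is
#' the summed contribution of their shared ancestors relative to their
#' semantic values:
#' `DSS(d1, d2) = sum_{t in T(d1) & T(d2)} (D_d1(t) + D_d2(t)) / (DV(d1) + DV(d2))`.
#'
#' @param ontology A [disease_ontology()].
#' @param diseases Terms to score (default: all ontology terms).
#' @return A symmetric similarity matrix with unit diagonal, class
#'   `dss` attribute-free plain matrix.
#' @export
compute_dss <- function(ontology, diseases = NULL) {
  if (!inherits(ontology, "disease_ontology")) {
    abort("`ontology` must be a disease_ontology")
  }
  diseases <- diseases %||% ontology$terms
  unknown <- setdiff(diseases, ontology$terms)
  if (length(unknown) > 0) {
    abort(paste0("unknown disease term(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  contribs <- lapply(diseases, function(d) semantic_contributions(ontology, d))
  names(contribs) <- diseases
  dv <- vapply(contribs, sum, numeric(1))
  n <- length(diseases)
  dss <- diag(1, n)
  dimnames(dss) <- list(diseases, diseases)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      ci <- contribs[[i]]
      for (j in (i + 1):n) {
        cj <- contribs[[j]]
        shared <- intersect(names(ci), names(cj))
        if (length(shared) > 0) {
          val <- sum(ci[shared] + cj[shared]) / (dv[i] + dv[j])
          dss[i, j] <- dss[j, i] <- val
        }
      }
    }
  }
  dss
}

#' Functional similarity of two lncRNAs from their disease sets
#'
#' Best-match average of cross-set disease semantic similarities:
#' `( sum_i max_j DSS(d1i, d2j) + sum_j max_i DSS(d2j, d1i) ) / (m + n)`.
#' Symmetric in its two arguments and bounded by the range of `dss`.
#'
#' @param d1,d2 Character vectors of disease identifiers associated with the
#'   two lncRNAs.
#' @param dss Disease semantic similarity matrix covering all identifiers.
#' @return A similarity value in `[0, 1]`. When both sets are empty the
#'   value is defined as 0 (with a warning), avoiding a 0/0 division.
#' @export
lncrna_pair_similarity <- function(d1, d2, dss) {
  d1 <- unique(as.character(d1))
  d2 <- unique(as.character(d2))
  m <- length(d1); n <- length(d2)
  if (m + n == 0) {
    warn("both disease sets empty; defining functional similarity as 0")
    return(0)
  }
  unknown <- setdiff(c(d1, d2), rownames(dss))
  if (length(unknown) > 0) {
    abort(paste0("disease(s) absent from similarity matrix: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (m == 0 || n == 0) return(0)
  sub <- dss[d1, d2, drop = FALSE]
  (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) / (m + n)
}

#' lncRNA functional similarity matrix
#'
#' Applies [lncrna_pair_similarity()] to every pair of lncRNAs, using each
#' lncRNA's associated-disease set from the association matrix. An lncRNA
#' with no known disease gets similarity 0 to every other lncRNA and 1 to
#' itself (degenerate-input convention).
#'
#' @param ld Binary lncRNA-by-disease association matrix with dimnames.
#' @param dss Disease semantic similarity matrix covering all of `ld`'s
#'   disease columns.
#' @return A symmetric lncRNA-by-lncRNA similarity matrix with unit diagonal.
#' @export
build_lfs <- function(ld, dss) {
  check_binary_matrix(ld, "ld")
  check_square_named(dss, "dss")
  missing <- setdiff(colnames(ld), rownames(dss))
  if (length(missing) > 0) {
    abort(paste0("disease(s) in `ld` absent from `dss`: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  lnc <- rownames(ld)
  nl <- length(lnc)
  sets <- lapply(seq_len(nl), function(i) colnames(ld)[ld[i, ] == 1])
  sizes <- lengths(sets)
  lfs <- diag(1, nl)
  dimnames(lfs) <- list(lnc, lnc)
  if (nl >= 2) {
    # cache per-set row-max lookups pairwise; sets are small in practice
    for (i in 1:(nl - 1)) {
      di <- sets[[i]]
      if (sizes[i] == 0) next
      for (j in (i + 1):nl) {
        dj <- sets[[j]]
        if (sizes[j] == 0) next
        sub <- dss[di, dj, drop = FALSE]
        val <- (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
          (sizes[i] + sizes[j])
        lfs[i, j] <- lfs[j, i] <- val
      }
    }
  }
  lfs
}
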