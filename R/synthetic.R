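# Planted-block synthetic data: lncRNAs, diseases and miRNAs are assigned to
# shared communities; associations are dense within a community and sparse
# across, and disease semantic similarity is high within a disease community.
# This emulates the guilt-by-association premise the model relies on
# (similar diseases associate with functionally similar lncRNAs) so every
# pipeline stage is testable and link prediction is learnable offline.

#' Synthetic dataset configuration
#'
#' @param n_lnc,n_dis,n_mi Node counts per type.
#' @param n_blocks Number of planted communities; nodes are split into
#'   near-equal contiguous blocks (remainder spread over the first blocks).
#' @param p_in,p_out Association probability for (lncRNA, disease) and
#'   (lncRNA, miRNA) pairs in the same / different blocks; `p_in > p_out`.
#' @param dss_in,dss_out Disease semantic similarity within / across disease
#'   blocks; `dss_in > dss_out`.
#' @param holdout_frac Fraction of generated positive lncRNA-disease cells
#'   removed from the released matrix and kept as held-out truth (0 by
#'   default).
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_lnc, n_dis, n_mi, n_blocks = 4L,
                             p_in = 0.3, p_out = 0.01,
                             dss_in = 0.8, dss_out = 0.1,
                             holdout_frac = 0, seed = 1L) {
  if (!(p_in > p_out && p_out >= 0)) abort("need p_in > p_out >= 0")
  if (!(dss_in > dss_out && dss_out >= 0)) abort("need dss_in > dss_out >= 0")
  if (holdout_frac < 0 || holdout_frac >= 1) {
    abort("`holdout_frac` must lie in [0, 1)")
  }
  structure(
    list(n_lnc = as.integer(n_lnc), n_dis = as.integer(n_dis),
         n_mi = as.integer(n_mi), n_blocks = as.integer(n_blocks),
         p_in = p_in, p_out = p_out, dss_in = dss_in, dss_out = dss_out,
         holdout_frac = holdout_frac, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' The canonical desk-scale benchmark configuration
#'
#' 60 lncRNAs, 80 diseases, 50 miRNAs in 4 planted blocks with
#' `p_in = 0.30`, `p_out = 0.01`, `dss_in = 0.8`, `dss_out = 0.1`,
#' seed 1 (expected positive count about 396).
#'
#' @return A `synthetic_config`.
#' @export
default_benchmark <- function() {
  synthetic_config(n_lnc = 60L, n_dis = 80L, n_mi = 50L, n_blocks = 4L,
                   p_in = 0.30, p_out = 0.01, dss_in = 0.8, dss_out = 0.1,
                   seed = 1L)
}

block_assign <- function(n, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n))
}

#' Generate a synthetic dataset with planted block structure
#'
#' @param config A [synthetic_config()].
#' @return A list of class `hgnnlda_sim` with binary matrices `ld`
#'   (lncRNA x disease) and `lm` (lncRNA x miRNA), the disease similarity
#'   matrix `dss`, and `truth` holding per-node block assignments and the
#'   held-out positive list.
#' @export
generate_synthetic <- function(config = default_benchmark()) {
  stopifnot(inherits(config, "synthetic_config"))
  with(config, {
    exp_pos <- n_lnc * n_dis *
      (p_in / n_blocks + p_out * (n_blocks - 1) / n_blocks)
    if (exp_pos < 1) abort("configuration implies (almost surely) no positives")

    lnc_ids <- sprintf("L%03d", seq_len(n_lnc))
    dis_ids <- sprintf("D%03d", seq_len(n_dis))
    mi_ids <- sprintf("M%03d", seq_len(n_mi))
    b_l <- block_assign(n_lnc, n_blocks)
    b_d <- block_assign(n_dis, n_blocks)
    b_m <- block_assign(n_mi, n_blocks)

    old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)

    prob_ld <- ifelse(outer(b_l, b_d, `==`), p_in, p_out)
    ld <- matrix(rbinom(n_lnc * n_dis, 1, prob_ld), n_lnc, n_dis,
                 dimnames = list(lnc_ids, dis_ids))
    prob_lm <- ifelse(outer(b_l, b_m, `==`), p_in, p_out)
    lm <- matrix(rbinom(n_lnc * n_mi, 1, prob_lm), n_lnc, n_mi,
                 dimnames = list(lnc_ids, mi_ids))
    dss <- ifelse(outer(b_d, b_d, `==`), dss_in, dss_out)
    diag(dss) <- 1
    dimnames(dss) <- list(dis_ids, dis_ids)

    if (sum(ld) == 0) abort("generated dataset has no positive associations")

    held_out <- tibble::tibble(lncrna = character(0), disease = character(0))
    if (holdout_frac > 0) {
      ones <- which(ld == 1, arr.ind = TRUE)
      n_hold <- floor(nrow(ones) * holdout_frac)
      if (n_hold > 0) {
        sel <- sample(nrow(ones), n_hold)
        held_out <- tibble::tibble(lncrna = lnc_ids[ones[sel, 1]],
                                   disease = dis_ids[ones[sel, 2]])
        ld[ones[sel, , drop = FALSE]] <- 0L
      }
    }

    blocks <- tibble::tibble(
      id = c(lnc_ids, dis_ids, mi_ids),
      type = rep(node_types(), times = c(n_lnc, n_dis, n_mi)),
      block = c(b_l, b_d, b_m)
    )
    structure(
      list(ld = ld, lm = lm, dss = dss,
           truth = list(blocks = blocks, held_out = held_out),
           config = config),
      class = "hgnnlda_sim"
    )
  })
}

#' Emit a disease DAG realising the planted similarity structure
#'
#' Builds a star-of-stars ontology: one global root, one hub term per
#' disease block, and every disease a child of its block hub. With decay
#' `delta`, [compute_dss()] on this DAG yields a two-level similarity
#' (within-block versus across-block), so the DAG route through the
#' similarity module can be exercised end to end.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `child` and `parent`.
#' @export
synthetic_disease_dag <- function(config = default_benchmark()) {
  stopifnot(inherits(config, "synthetic_config"))
  dis_ids <- sprintf("D%03d", seq_len(config$n_dis))
  b_d <- block_assign(config$n_dis, config$n_blocks)
  hubs <- sprintf("BLOCK%d", seq_len(config$n_blocks))
  dplyr::bind_rows(
    tibble::tibble(child = dis_ids, parent = hubs[b_d]),
    tibble::tibble(child = hubs, parent = "ROOT")
  )
}

#' @export
print.hgnnlda_sim <- function(x, ...) {
  cat(sprintf(paste0("<hgnnlda_sim> %d lncRNAs x %d diseases x %d miRNAs, ",
                     "%d blocks, %d LD positives, %d LM positives, ",
                     "%d held out\n"),
              nrow(x$ld), ncol(x$ld), ncol(x$lm), x$config$n_blocks,
              sum(x$ld), sum(x$lm), nrow(x$truth$held_out)))
  invisible(x)
}
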