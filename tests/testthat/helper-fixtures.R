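# Small graphs and datasets built in code, shared across test files.

# 2 lncRNAs, 1 disease, 1 miRNA; LD = [[1],[0]], LM = [[0],[1]],
# LFS off-diagonal 0.7. With lnc_topk = 1 this yields exactly three edges,
# one of each type.
toy_graph <- function(lnc_topk = 1L) {
  ld <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("l1", "l2"), "d1"))
  lm <- matrix(c(0L, 1L), 2, 1, dimnames = list(c("l1", "l2"), "m1"))
  lfs <- matrix(c(1, 0.7, 0.7, 1), 2, 2,
                dimnames = list(c("l1", "l2"), c("l1", "l2")))
  build_hetero_graph(lfs, ld, lm, lnc_topk = lnc_topk)
}

# Connected 6-node heterogeneous graph used for the walk-distribution
# oracle checks (3 lncRNAs, 2 diseases, 1 miRNA).
six_node_graph <- function() {
  lnc <- c("l1", "l2", "l3")
  ld <- matrix(c(1L, 1L, 0L,
                 0L, 1L, 1L), 3, 2,
               dimnames = list(lnc, c("d1", "d2")))
  lm <- matrix(c(1L, 0L, 1L), 3, 1, dimnames = list(lnc, "m1"))
  lfs <- matrix(c(1, 0.8, 0.2,
                  0.8, 1, 0.5,
                  0.2, 0.5, 1), 3, 3, byrow = TRUE,
                dimnames = list(lnc, lnc))
  suppressWarnings(build_hetero_graph(lfs, ld, lm, lnc_topk = 2L))
}

# Small planted-block dataset for fast end-to-end tests.
small_sim <- function(seed = 7L, holdout_frac = 0) {
  generate_synthetic(synthetic_config(
    n_lnc = 24L, n_dis = 24L, n_mi = 15L, n_blocks = 3L,
    p_in = 0.5, p_out = 0.02, dss_in = 0.8, dss_out = 0.1,
    holdout_frac = holdout_frac, seed = seed))
}

# Fast model/evaluation configuration for unit tests.
fast_config <- function(...) {
  defaults <- list(d = 16L, collect_size = 60L, min_per_type = 3L,
                   k_lnc = 5L, k_dis = 5L, k_mi = 3L,
                   embed_epochs = 5L, epochs = 25L, lr = 1e-2,
                   batch_size = Inf)
  do.call(hgnnlda_config, utils::modifyList(defaults, list(...)))
}

# Random content matrix + neighbour index matrices for model-only tests:
# n nodes of alternating types with k-neighbour lists drawn from the pool.
random_model_inputs <- function(n = 12L, d = 8L,
                                k = c(lncRNA = 3L, disease = 3L, miRNA = 2L),
                                seed = 42L) {
  set.seed(seed)
  F <- matrix(rnorm(n * d, sd = 0.5), n, d)
  types <- rep_len(1:3, n)
  nb <- lapply(seq_along(k), function(ti) {
    pool <- which(types == ti)
    t(vapply(seq_len(n), function(v) sample(pool, k[[ti]], replace = TRUE),
             integer(k[[ti]])))
  })
  names(nb) <- names(k)
  list(F = F, nb = nb, types = types)
}
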