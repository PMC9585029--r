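#' Pipeline configuration
#'
#' Bundles the tunable parameters of every pipeline stage into one list. All
#' randomness downstream is driven by a single `seed`, so a run is fully
#' reproducible from its configuration.
#'
#' @param lnc_topk Number of most-similar partners kept per lncRNA when the
#'   dense functional-similarity matrix is sparsified into walk edges.
#' @param lnc_mode `"topk"` (default) or `"threshold"` sparsification of the
#'   lncRNA similarity layer.
#' @param lnc_threshold Similarity cutoff used when `lnc_mode = "threshold"`.
#' @param p Restart probability of the random walk, in `[0, 1]`.
#' @param q Breadth/depth bias of the walk (> 0); `q = 1` is a pure restart
#'   walk, `q > 1` favours breadth, `q < 1` depth.
#' @param collect_size Number of banked (non-start) visits each walk collects.
#' @param min_per_type Minimum banked visits required per node type before a
#'   walk may stop.
#' @param k_lnc,k_dis,k_mi Per-type neighbour budgets: the top-k most
#'   frequently visited neighbours kept per type.
#' @param max_steps Hard cap on walk steps; defaults to `10 * collect_size`.
#' @param d Embedding size shared by the skip-gram vectors and the model.
#' @param window,negatives,embed_epochs,embed_lr Skip-gram hyperparameters.
#' @param epochs,lr,batch_size Training schedule of the association model.
#'   `batch_size = Inf` trains full-batch.
#' @param act Activation applied to the fused node embedding (`"relu"`,
#'   the printed form, or `"identity"`).
#' @param pair_mode Pair feature construction for the classifier:
#'   `"hadamard"` (default, element-wise product of the two final
#'   embeddings, a learned weighted inner product), `"concat"`
#'   (concatenation, an additive scorer), or `"both"`. See the methods
#'   vignette for why the additive form is degenerate for interaction-driven
#'   association structure.
#' @param normalize_content Whether content embeddings are L2-normalised
#'   row-wise before entering the model (default `TRUE`); the block signal
#'   of skip-gram vectors lives in their direction, and normalisation
#'   removes frequency-driven magnitude noise.
#' @param avg_tail Fraction of final training epochs whose parameters are
#'   averaged into the returned model (stochastic weight averaging; 0
#'   disables, default 0.25). Smooths optimisation noise in the scores.
#' @param n_model_seeds Number of independently initialised and trained
#'   models whose predicted probabilities are averaged at scoring time
#'   (1 disables ensembling). Averaging over a few seeds reduces
#'   optimisation noise in the scores.
#' @param fine_tune Whether content embeddings receive gradient updates
#'   during model training (frozen by default).
#' @param n_folds Number of cross-validation folds.
#' @param leakage_mode `"strict"` rebuilds graph, walks and embeddings per
#'   fold from training-fold associations only; `"paper"` builds them once
#'   from all known associations.
#' @param seed Master seed for every random stage.
#'
#' @return A list of class `hgnnlda_config`.
#' @export
hgnnlda_config <- function(lnc_topk = 10L, lnc_mode = "topk",
                           lnc_threshold = 0.5,
                           p = 0.5, q = 1.0, collect_size = 100L,
                           min_per_type = 5L, k_lnc = 10L, k_dis = 10L,
                           k_mi = 6L, max_steps = 10L * collect_size,
                           d = 128L, window = 5L, negatives = 5L,
                           embed_epochs = 5L, embed_lr = 0.025,
                           epochs = 50L, lr = 1e-3, batch_size = 64,
                           pair_mode = c("hadamard", "concat", "both"),
                           act = c("relu", "identity"),
                           normalize_content = TRUE, avg_tail = 0.25,
                           n_model_seeds = 1L, fine_tune = FALSE,
                           n_folds = 5L, leakage_mode = "strict",
                           seed = 1L) {
  if (p < 0 || p > 1) abort("restart probability `p` must lie in [0, 1]")
  if (q <= 0) abort("walk bias `q` must be positive")
  if (3L * min_per_type > collect_size) {
    abort("`collect_size` must be at least 3 * `min_per_type`")
  }
  if (d < 2L || d %% 2L != 0L) {
    abort("embedding size `d` must be an even integer >= 2")
  }
  structure(
    list(
      lnc_topk = as.integer(lnc_topk), lnc_mode = lnc_mode,
      lnc_threshold = lnc_threshold,
      p = p, q = q, collect_size = as.integer(collect_size),
      min_per_type = as.integer(min_per_type),
      k_lnc = as.integer(k_lnc), k_dis = as.integer(k_dis),
      k_mi = as.integer(k_mi), max_steps = as.integer(max_steps),
      d = as.integer(d), window = as.integer(window),
      negatives = as.integer(negatives),
      embed_epochs = as.integer(embed_epochs), embed_lr = embed_lr,
      epochs = as.integer(epochs), lr = lr, batch_size = batch_size,
      pair_mode = match.arg(pair_mode, c("hadamard", "concat", "both")),
      act = match.arg(act, c("relu", "identity")),
      normalize_content = isTRUE(normalize_content), avg_tail = avg_tail,
      n_model_seeds = as.integer(n_model_seeds),
      fine_tune = isTRUE(fine_tune),
      n_folds = as.integer(n_folds),
      leakage_mode = match.arg(leakage_mode, c("strict", "paper")),
      seed = as.integer(seed)
    ),
    class = "hgnnlda_config"
  )
}

#' Desk-scale benchmark configuration
#'
#' The configuration used throughout the package for cross-validated
#' evaluation on the planted-block benchmark: `d = 64`, full-batch Adam with
#' a raised learning rate, and otherwise the package defaults. Chosen so the
#' whole strict-mode cross-validation completes in seconds per fold on one
#' CPU; see the methods vignette.
#'
#' @param ... Overrides forwarded to [hgnnlda_config()].
#' @return A list of class `hgnnlda_config`.
#' @export
benchmark_config <- function(...) {
  defaults <- list(d = 64L, epochs = 60L, lr = 5e-3, batch_size = Inf,
                   embed_epochs = 15L, n_model_seeds = 3L)
  args <- utils::modifyList(defaults, list(...))
  do.call(hgnnlda_config, args)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the package defaults.
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [hgnnlda_config()].
#' @return A list of class `hgnnlda_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(hgnnlda_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("unknown configuration keys: ", paste(bad, collapse = ", ")))
  }
  do.call(hgnnlda_config, vals)
}

#' @export
print.hgnnlda_config <- function(x, ...) {
  cat("<hgnnlda_config>\n")
  for (nm in names(x)) cat(sprintf("  %-13s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
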