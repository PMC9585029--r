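# Negative sampling, cross-validation, ROC/PR metrics, ablation and sweep
# harnesses, and the two case-study ranking protocols.

as_lda_data <- function(data) {
  if (inherits(data, "hgnnlda_sim")) {
    return(list(ld = data$ld, lm = data$lm, dss = data$dss))
  }
  if (is.list(data) && all(c("ld", "lm", "dss") %in% names(data))) {
    return(data[c("ld", "lm", "dss")])
  }
  abort("`data` must be an hgnnlda_sim or a list with `ld`, `lm`, `dss`")
}

#' Build a balanced labelled sample set
#'
#' All known associations become positive samples; `n` negatives are drawn
#' uniformly without replacement from the zero cells of the association
#' matrix (so positives and negatives are disjoint by construction).
#'
#' @param ld Binary lncRNA-by-disease association matrix.
#' @param n Number of negatives (default: one per positive).
#' @param seed Integer seed.
#' @return A tibble with columns `lncrna`, `disease`, `label` (1 for the
#'   positives, then 0 for the sampled negatives).
#' @export
negative_sample <- function(ld, n = sum(ld), seed = 1L) {
  check_binary_matrix(ld, "ld")
  zeros <- which(ld == 0, arr.ind = TRUE)
  if (n > nrow(zeros)) {
    abort(sprintf("requested %d negatives but only %d zero cells exist",
                  n, nrow(zeros)))
  }
  ones <- which(ld == 1, arr.ind = TRUE)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sel <- sample.int(nrow(zeros), n)
  out <- dplyr::bind_rows(
    tibble::tibble(lncrna = rownames(ld)[ones[, 1]],
                   disease = colnames(ld)[ones[, 2]], label = 1L),
    tibble::tibble(lncrna = rownames(ld)[zeros[sel, 1]],
                   disease = colnames(ld)[zeros[sel, 2]], label = 0L)
  )
  attr(out, "seed") <- as.integer(seed)
  out
}

# Fold assignment: shuffled round robin, sizes differing by at most one.
make_folds <- function(n, k = 5L, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  folds <- integer(n)
  folds[sample.int(n)] <- rep_len(seq_len(k), n)
  folds
}

#' ROC and precision-recall metrics for scored pairs
#'
#' Thresholds sweep the distinct scores in descending order. True/false
#' positive rates use the standard definitions `TPR = TP / (TP + FN)`,
#' `FPR = FP / (FP + TN)`, `Precision = TP / (TP + FP)`. AUC is the
#' trapezoidal area under the ROC curve (equal to pairwise concordance with
#' half credit for ties); AUPR is the step-wise (non-interpolated)
#' integral of precision over recall.
#'
#' @param scores Numeric scores, higher meaning more likely associated.
#' @param labels 0/1 labels; both classes must be present.
#' @return A list of class `metric_report` with `auc`, `aupr`, and tibbles
#'   `roc` (`threshold`, `fpr`, `tpr`) and `pr` (`threshold`, `recall`,
#'   `precision`).
#' @export
compute_metrics <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length")
  }
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    abort("metrics undefined: both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last index per tie group
  tp <- cumsum(y == 1)[grp_end]
  fp <- cumsum(y == 0)[grp_end]
  tpr <- tp / P; fpr <- fp / N
  precision <- tp / (tp + fp)
  recall <- tpr

  roc <- tibble::tibble(threshold = c(Inf, s[grp_end]),
                        fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  pr <- tibble::tibble(threshold = s[grp_end], recall = recall,
                       precision = precision)
  aupr <- sum(diff(c(0, recall)) * precision)

  structure(list(auc = auc, aupr = aupr, roc = roc, pr = pr,
                 n_positive = P, n_negative = N),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> AUC = %.4f, AUPR = %.4f (%d pos / %d neg)\n",
              x$auc, x$aupr, x$n_positive, x$n_negative))
  invisible(x)
}

## ---- pipeline assembly ------------------------------------------------------

# Graph + walks + content embeddings from one association snapshot. The
# `seed` drives walker and skip-gram seeds deterministically.
build_pipeline <- function(ld, lm, dss, config, seed) {
  lfs <- build_lfs(ld, dss)
  graph <- suppressWarnings(build_hetero_graph(
    lfs, ld, lm, lnc_topk = config$lnc_topk, mode = config$lnc_mode,
    threshold = config$lnc_threshold))
  cfg_w <- config
  cfg_w$seed <- derive_seed(seed, 1L)
  walks <- sample_all(graph, cfg_w)
  emb <- train_skipgram(walks, d = config$d, window = config$window,
                        negatives = config$negatives,
                        epochs = config$embed_epochs, lr = config$embed_lr,
                        seed = derive_seed(seed, 2L))
  F <- suppressWarnings(content_matrix(emb, graph))
  if (config$normalize_content) {
    F <- F / pmax(sqrt(rowSums(F^2)), 1e-12)
  }
  list(graph = graph, walks = walks, emb = emb, F = F, nb = walks$index)
}

pairs_to_idx <- function(graph, pairs) {
  il <- match(pairs$lncrna, graph$nodes$id)
  id <- match(pairs$disease, graph$nodes$id)
  if (anyNA(il) || anyNA(id)) {
    abort("pair references a node absent from the graph")
  }
  cbind(il, id)
}

#' Five-fold cross-validation of the full pipeline
#'
#' Builds a balanced sample set (all positives plus an equal number of
#' sampled negatives), splits it into `n_folds` disjoint near-equal folds,
#' and per fold trains on the remaining folds and scores the held-out one.
#' In `"strict"` leakage mode the heterogeneous graph, walks and content
#' embeddings are rebuilt per fold using only training-fold positive edges,
#' and the absence of every test positive from the fold's graph is asserted.
#' In `"paper"` mode graph, walks and embeddings are built once from all
#' known associations.
#'
#' @param data An `hgnnlda_sim` or a list with `ld`, `lm`, `dss`.
#' @param config An [hgnnlda_config()].
#' @param seed Evaluation seed (defaults to the config seed).
#' @param variant Model variant (`"full"`, `"noNeigh"`, `"noAttention"`).
#' @param leakage_mode Overrides the config's leakage mode.
#' @return A list of class `hgnnlda_cv` with per-fold metrics, pooled
#'   score table, mean AUC/AUPR and the leakage-check outcome.
#' @export
five_fold_cv <- function(data, config = hgnnlda_config(),
                         seed = config$seed, variant = "full",
                         leakage_mode = config$leakage_mode) {
  dat <- as_lda_data(data)
  leakage_mode <- match.arg(leakage_mode, c("strict", "paper"))
  samples <- negative_sample(dat$ld, seed = derive_seed(seed, 11L))
  folds <- make_folds(nrow(samples), config$n_folds,
                      seed = derive_seed(seed, 12L))
  k_budget <- c(lncRNA = config$k_lnc, disease = config$k_dis,
                miRNA = config$k_mi)

  pipe_all <- NULL
  if (leakage_mode == "paper") {
    pipe_all <- build_pipeline(dat$ld, dat$lm, dat$dss, config,
                               derive_seed(seed, 99L))
  }

  fold_rows <- list()
  score_rows <- list()
  leakage_ok <- TRUE
  for (f in seq_len(config$n_folds)) {
    test <- samples[folds == f, , drop = FALSE]
    train <- samples[folds != f, , drop = FALSE]
    if (leakage_mode == "strict") {
      ld_f <- dat$ld
      tp <- test[test$label == 1, , drop = FALSE]
      ld_f[cbind(match(tp$lncrna, rownames(ld_f)),
                 match(tp$disease, colnames(ld_f)))] <- 0L
      pipe <- build_pipeline(ld_f, dat$lm, dat$dss, config,
                             derive_seed(seed, 100L + f))
      leakage_ok <- leakage_ok &&
        !fold_has_leakage(pipe$graph, tp)
    } else {
      pipe <- pipe_all
    }
    train_idx <- pairs_to_idx(pipe$graph, train)
    test_idx <- pairs_to_idx(pipe$graph, test)
    sc <- 0
    for (r in seq_len(config$n_model_seeds)) {
      state <- init_model(config$d, k = k_budget, variant = variant,
                          act = config$act, pair_mode = config$pair_mode,
                          seed = derive_seed(seed, 200L + 10L * f + r))
      tr <- train_model(state, pipe$F, pipe$nb, train_idx, train$label,
                        config, seed = derive_seed(seed, 300L + 10L * f + r))
      sc <- sc + predict_pairs(tr$state, tr$F, pipe$nb, test_idx)
    }
    sc <- sc / config$n_model_seeds
    if (length(unique(test$label)) < 2) {
      fold_rows[[f]] <- tibble::tibble(fold = f, auc = NA_real_,
                                       aupr = NA_real_, n_test = nrow(test))
      next
    }
    mr <- compute_metrics(sc, test$label)
    fold_rows[[f]] <- tibble::tibble(fold = f, auc = mr$auc, aupr = mr$aupr,
                                     n_test = nrow(test))
    score_rows[[f]] <- dplyr::mutate(test, fold = f, score = sc)
  }

  folds_tbl <- dplyr::bind_rows(fold_rows)
  structure(
    list(folds = folds_tbl,
         scores = dplyr::bind_rows(score_rows),
         mean_auc = mean(folds_tbl$auc, na.rm = TRUE),
         mean_aupr = mean(folds_tbl$aupr, na.rm = TRUE),
         leakage_mode = leakage_mode,
         leakage_ok = if (leakage_mode == "strict") leakage_ok else NA,
         variant = variant, seed = as.integer(seed), config = config),
    class = "hgnnlda_cv"
  )
}

# TRUE when any held-out positive pair appears as a graph edge.
fold_has_leakage <- function(graph, test_positives) {
  if (nrow(test_positives) == 0) return(FALSE)
  edges <- graph$edges
  key_e <- paste(edges$from_id, edges$to_id)
  key_p <- c(paste(test_positives$lncrna, test_positives$disease),
             paste(test_positives$disease, test_positives$lncrna))
  any(key_p %in% key_e)
}

#' @export
print.hgnnlda_cv <- function(x, ...) {
  cat(sprintf(
    "<hgnnlda_cv> %s/%s: mean AUC = %.4f, mean AUPR = %.4f over %d folds\n",
    x$variant, x$leakage_mode, x$mean_auc, x$mean_aupr, nrow(x$folds)))
  invisible(x)
}

## ---- full-data fit and case-study protocols --------------------------------

#' Fit the pipeline on all known associations
#'
#' Builds the heterogeneous graph from every known association, samples
#' walks, trains content embeddings, and trains the association model on all
#' positives plus an equal number of sampled negatives. Used by the ranking
#' protocols and for scoring novel candidate pairs.
#'
#' @param data An `hgnnlda_sim` or a list with `ld`, `lm`, `dss`.
#' @param config An [hgnnlda_config()].
#' @param seed Fit seed (defaults to the config seed).
#' @param variant Model variant.
#' @return A list of class `hgnnlda_fit`.
#' @export
fit_hgnnlda <- function(data, config = hgnnlda_config(), seed = config$seed,
                        variant = "full") {
  dat <- as_lda_data(data)
  samples <- negative_sample(dat$ld, seed = derive_seed(seed, 21L))
  pipe <- build_pipeline(dat$ld, dat$lm, dat$dss, config,
                         derive_seed(seed, 22L))
  k_budget <- c(lncRNA = config$k_lnc, disease = config$k_dis,
                miRNA = config$k_mi)
  pair_idx <- pairs_to_idx(pipe$graph, samples)
  states <- vector("list", config$n_model_seeds)
  trajectory <- NULL
  for (r in seq_len(config$n_model_seeds)) {
    state <- init_model(config$d, k = k_budget, variant = variant,
                        act = config$act, pair_mode = config$pair_mode,
                        seed = derive_seed(seed, 230L + r))
    tr <- train_model(state, pipe$F, pipe$nb, pair_idx, samples$label,
                      config, seed = derive_seed(seed, 240L + r))
    states[[r]] <- tr$state
    if (r == 1L) trajectory <- tr$trajectory
  }
  structure(
    list(state = states[[1]], states = states, F = pipe$F, pipe = pipe,
         data = dat, samples = samples, trajectory = trajectory,
         config = config, seed = as.integer(seed), variant = variant),
    class = "hgnnlda_fit"
  )
}

#' Score lncRNA-disease pairs with a fitted pipeline
#'
#' @param object An `hgnnlda_fit`.
#' @param pairs A data frame with columns `lncrna` and `disease`.
#' @param ... Unused.
#' @return `pairs` as a tibble with a `score` column appended.
#' @export
predict.hgnnlda_fit <- function(object, pairs, ...) {
  pairs <- tibble::as_tibble(pairs)
  idx <- pairs_to_idx(object$pipe$graph, pairs)
  states <- object$states %||% list(object$state)
  sc <- 0
  for (st in states) sc <- sc + predict_pairs(st, object$F, object$pipe$nb,
                                              idx)
  dplyr::mutate(pairs, score = sc / length(states))
}

#' Rank candidate lncRNAs for a disease
#'
#' Scores every lncRNA not already known to associate with the disease and
#' returns them in descending score order (ties broken by identifier).
#'
#' @param fit An [fit_hgnnlda()] result.
#' @param disease Disease identifier.
#' @param top_n Optional cut of the ranking.
#' @return A tibble `rank`, `lncrna`, `score`.
#' @export
rank_for_disease <- function(fit, disease, top_n = NULL) {
  stopifnot(inherits(fit, "hgnnlda_fit"))
  ld <- fit$data$ld
  if (!disease %in% colnames(ld)) {
    abort(sprintf("unknown disease '%s'", disease))
  }
  candidates <- rownames(ld)[ld[, disease] == 0]
  scored <- predict(fit, tibble::tibble(lncrna = candidates,
                                        disease = disease))
  scored <- scored[order(-scored$score, scored$lncrna), , drop = FALSE]
  out <- tibble::tibble(rank = seq_len(nrow(scored)),
                        lncrna = scored$lncrna, score = scored$score)
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Rank all lncRNAs for a disease treated as novel
#'
#' Masks every known association of the disease (in the association matrix
#' and hence in the rebuilt graph), refits the whole pipeline, and ranks all
#' lncRNAs as candidates.
#'
#' @param data An `hgnnlda_sim` or a list with `ld`, `lm`, `dss`.
#' @param disease Disease identifier with at least one known association.
#' @param config An [hgnnlda_config()].
#' @param seed Fit seed.
#' @param variant Model variant.
#' @return A tibble `rank`, `lncrna`, `score` covering every lncRNA, with
#'   the refit stored in attribute `fit`.
#' @export
novel_disease_rank <- function(data, disease, config = hgnnlda_config(),
                               seed = config$seed, variant = "full") {
  dat <- as_lda_data(data)
  if (!disease %in% colnames(dat$ld)) {
    abort(sprintf("unknown disease '%s'", disease))
  }
  if (sum(dat$ld[, disease]) == 0) {
    abort(sprintf("disease '%s' has no known association to mask", disease))
  }
  dat$ld[, disease] <- 0L
  fit <- fit_hgnnlda(dat, config, seed = seed, variant = variant)
  scored <- predict(fit, tibble::tibble(lncrna = rownames(dat$ld),
                                        disease = disease))
  scored <- scored[order(-scored$score, scored$lncrna), , drop = FALSE]
  out <- tibble::tibble(rank = seq_len(nrow(scored)),
                        lncrna = scored$lncrna, score = scored$score)
  attr(out, "fit") <- fit
  out
}

## ---- ablation and sweep harnesses ------------------------------------------

#' Cross-validated comparison of the model variants
#'
#' @param data An `hgnnlda_sim` or a list with `ld`, `lm`, `dss`.
#' @param config An [hgnnlda_config()].
#' @param seeds Evaluation seeds averaged over.
#' @param variants Variants to compare.
#' @return A tibble of class `hgnnlda_ablation`: `variant`, `seed`,
#'   `mean_auc`, `mean_aupr`.
#' @export
run_ablation <- function(data, config = hgnnlda_config(), seeds = 1:3,
                         variants = c("full", "noNeigh", "noAttention")) {
  out <- purrr::map_dfr(variants, function(v) {
    purrr::map_dfr(seeds, function(s) {
      cv <- five_fold_cv(data, config, seed = s, variant = v)
      tibble::tibble(variant = v, seed = s, mean_auc = cv$mean_auc,
                     mean_aupr = cv$mean_aupr)
    })
  })
  class(out) <- c("hgnnlda_ablation", class(out))
  out
}

#' Cross-validated AUC as a function of embedding size
#'
#' @param data An `hgnnlda_sim` or a list with `ld`, `lm`, `dss`.
#' @param sizes Even embedding sizes to evaluate.
#' @param config An [hgnnlda_config()]; its `d` is overridden per size.
#' @param seeds Evaluation seeds (identical across sizes).
#' @return A tibble of class `hgnnlda_sweep`: `d`, `seed`, `mean_auc`,
#'   `mean_aupr`.
#' @export
embedding_size_sweep <- function(data, sizes = c(8L, 16L, 32L, 64L, 128L,
                                                 256L),
                                 config = hgnnlda_config(), seeds = 1L) {
  if (any(sizes %% 2 != 0)) {
    abort("embedding sizes must be even (hidden size is d/2 per direction)")
  }
  out <- purrr::map_dfr(sizes, function(sz) {
    cfg <- config
    cfg$d <- as.integer(sz)
    purrr::map_dfr(seeds, function(s) {
      cv <- five_fold_cv(data, cfg, seed = s)
      tibble::tibble(d = as.integer(sz), seed = s, mean_auc = cv$mean_auc,
                     mean_aupr = cv$mean_aupr)
    })
  })
  class(out) <- c("hgnnlda_sweep", class(out))
  out
}
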