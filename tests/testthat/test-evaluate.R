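test_that("negative sampling is exhaustive, disjoint and reproducible", {
  ld <- matrix(c(1L, 0L, 1L,
                 0L, 1L, 0L,
                 1L, 0L, 0L), 3, 3, byrow = TRUE,
               dimnames = list(paste0("l", 1:3), paste0("d", 1:3)))
  # 4 ones -> 5 zero cells; requesting all 5 must return exactly those
  ss <- negative_sample(ld, n = 5L, seed = 1L)
  neg <- ss[ss$label == 0, ]
  expect_equal(nrow(neg), 5L)
  expect_true(all(ld[cbind(neg$lncrna, neg$disease)] == 0))
  pos <- ss[ss$label == 1, ]
  expect_equal(nrow(pos), 4L)
  expect_equal(nrow(dplyr::inner_join(pos[1:2], neg[1:2],
                                      by = c("lncrna", "disease"))), 0L)
  expect_error(negative_sample(ld, n = 6L), "only 5")

  # balanced by default, and seeded
  s1 <- negative_sample(ld, seed = 7L)
  s2 <- negative_sample(ld, seed = 7L)
  expect_identical(s1, s2)
  expect_equal(sum(s1$label == 0), sum(s1$label == 1))
})

test_that("fold assignment is disjoint, exhaustive and balanced", {
  folds <- hgnnlda:::make_folds(23L, 5L, seed = 2L)
  expect_length(folds, 23L)
  expect_setequal(unique(folds), 1:5)
  sizes <- tabulate(folds)
  expect_lte(diff(range(sizes)), 1L)
})

test_that("metrics match hand cases and the concordance brute force", {
  # perfectly separating scores
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$aupr, 1)
  # 3 of 4 positive-negative pairs correctly ordered
  m2 <- compute_metrics(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  expect_equal(m2$auc, 0.75)
  # full ties: half credit
  m3 <- compute_metrics(c(0.3, 0.3), c(1, 0))
  expect_equal(m3$auc, 0.5)
  expect_error(compute_metrics(c(0.1, 0.2), c(1, 1)), "both classes")

  # ROC endpoints
  expect_equal(unlist(m2$roc[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(m2$roc[nrow(m2$roc), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))

  # brute-force pairwise concordance with half-credit ties
  concordance <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(6:30, 1)
    scores <- round(runif(n), 2)   # rounded to force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(compute_metrics(scores, labels)$auc,
                 concordance(scores, labels), tolerance = 1e-12)
  }
})

test_that("our AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.5)
  expect_equal(compute_metrics(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("random scores on balanced labels give chance-level AUC", {
  set.seed(33)
  reps <- 40
  aucs <- replicate(reps, {
    n <- 200
    compute_metrics(runif(n), rep(c(0, 1), n / 2))$auc
  })
  # SE of a single AUC with 100/100 split is about 0.033; the mean of 40
  # replicates must sit within 3 SE of 0.5
  expect_lt(abs(mean(aucs) - 0.5), 3 * 0.033 / sqrt(reps))
})

test_that("cross-validation folds are leakage-free and well-formed", {
  sim <- small_sim()
  cfg <- fast_config(seed = 1L)
  cv <- five_fold_cv(sim, cfg, seed = 1L)
  expect_s3_class(cv, "hgnnlda_cv")
  expect_equal(nrow(cv$folds), 5L)
  expect_true(cv$leakage_ok)
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
  # folds disjoint and exhaustive over the sample set
  expect_equal(sum(cv$folds$n_test),
               nrow(negative_sample(sim$ld,
                                    seed = hgnnlda:::derive_seed(1L, 11L))))
  expect_equal(nrow(dplyr::distinct(cv$scores[c("lncrna", "disease",
                                                "label")])),
               nrow(cv$scores))
  # tidiers
  expect_equal(nrow(tidy(cv)), 5L)
  expect_equal(glance(cv)$mean_auc, cv$mean_auc)
})

test_that("strict mode removes every test positive from the fold graph", {
  sim <- small_sim()
  cfg <- fast_config(seed = 2L)
  samples <- negative_sample(sim$ld, seed = hgnnlda:::derive_seed(2L, 11L))
  folds <- hgnnlda:::make_folds(nrow(samples), 5L,
                                seed = hgnnlda:::derive_seed(2L, 12L))
  for (f in 1:2) {
    test <- samples[folds == f & samples$label == 1, ]
    ld_f <- sim$ld
    ld_f[cbind(match(test$lncrna, rownames(ld_f)),
               match(test$disease, colnames(ld_f)))] <- 0L
    pipe <- hgnnlda:::build_pipeline(ld_f, sim$lm, sim$dss, cfg,
                                     hgnnlda:::derive_seed(2L, 100L + f))
    expect_false(hgnnlda:::fold_has_leakage(pipe$graph, test))
  }
  # and the leakage detector does fire on a leaky graph
  pipe_full <- hgnnlda:::build_pipeline(sim$ld, sim$lm, sim$dss, cfg, 9L)
  some_pos <- samples[samples$label == 1, ][1:5, ]
  expect_true(hgnnlda:::fold_has_leakage(pipe_full$graph, some_pos))
})

test_that("disease ranking excludes known associations and orders by score", {
  sim <- small_sim()
  cfg <- fast_config(seed = 3L, epochs = 10L)
  fit <- fit_hgnnlda(sim, cfg, seed = 3L)
  dis <- colnames(sim$ld)[which.max(colSums(sim$ld))]
  rk <- rank_for_disease(fit, dis)
  known <- rownames(sim$ld)[sim$ld[, dis] == 1]
  expect_false(any(rk$lncrna %in% known))
  expect_equal(nrow(rk), nrow(sim$ld) - length(known))
  expect_true(all(diff(rk$score) <= 1e-12))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_error(rank_for_disease(fit, "nope"), "unknown disease")
})

test_that("novel-disease protocol masks the column before refitting", {
  sim <- small_sim()
  cfg <- fast_config(seed = 4L, epochs = 10L)
  dis <- colnames(sim$ld)[which.max(colSums(sim$ld))]
  rk <- novel_disease_rank(sim, dis, cfg, seed = 4L)
  expect_equal(nrow(rk), nrow(sim$ld))      # every lncRNA is a candidate
  fit <- attr(rk, "fit")
  expect_equal(sum(fit$data$ld[, dis]), 0L) # masked everywhere
  expect_false(any(paste(fit$pipe$graph$edges$from_id,
                         fit$pipe$graph$edges$to_id) %in%
                   c(paste(rownames(sim$ld), dis),
                     paste(dis, rownames(sim$ld)))))
  empty <- colnames(sim$ld)[colSums(sim$ld) == 0]
  if (length(empty) > 0) {
    expect_error(novel_disease_rank(sim, empty[1], cfg), "no known")
  }
})

test_that("sweep harness validates sizes and reports one row per run", {
  sim <- small_sim()
  cfg <- fast_config(seed = 5L, epochs = 5L)
  expect_error(embedding_size_sweep(sim, sizes = c(7L), config = cfg),
               "even")
  sw <- embedding_size_sweep(sim, sizes = c(8L, 16L), config = cfg,
                             seeds = 1L)
  expect_equal(nrow(sw), 2L)
  expect_s3_class(sw, "hgnnlda_sweep")
  sw2 <- embedding_size_sweep(sim, sizes = c(8L, 16L), config = cfg,
                              seeds = 1L)
  expect_identical(sw$mean_auc, sw2$mean_auc)
})
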