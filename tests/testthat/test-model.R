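test_that("type aggregation honours its shape and pooling contracts", {
  st <- init_model(8L, seed = 1L)
  nv <- matrix(rnorm(3 * 8), 3, 8)
  out <- aggregate_type(st, "disease", nv)
  expect_length(out, 8L)

  # single neighbour: mean over one position is the concatenated
  # forward/backward hidden state itself
  one <- nv[1, , drop = FALSE]
  out1 <- aggregate_type(st, "disease", one)
  bl <- hgnnlda:::bilstm_forward(st, "dis", list(one))
  expect_equal(out1, as.numeric(bl$out), tolerance = 1e-12)

  # empty neighbour list falls back to the centre's own embedding
  centre <- rnorm(8)
  expect_equal(aggregate_type(st, "miRNA", matrix(0, 0, 8), centre), centre)
})

test_that("all-zero LSTM parameters propagate to a zero embedding", {
  st <- init_model(8L, seed = 1L)
  for (nm in names(st$params)) st$params[[nm]] <- st$params[[nm]] * 0
  nv <- matrix(rnorm(4 * 8), 4, 8)
  # sigma(0) gates with tanh(0) candidate keep the cell at zero throughout
  expect_equal(aggregate_type(st, "lncRNA", nv), rep(0, 8))
})

test_that("attention weights form a probability vector with its symmetries", {
  d <- 8L
  f <- rnorm(d)
  q <- rnorm(2 * d)
  types <- list(lncRNA = rnorm(d), disease = rnorm(d), miRNA = rnorm(d))
  res <- attention_fuse(f, types, q)
  expect_equal(sum(res$betas), 1, tolerance = 1e-6)
  expect_length(res$z, d)

  # identical members: uniform weights, exactly 1/4
  same <- attention_fuse(f, list(lncRNA = f, disease = f, miRNA = f), q)
  expect_equal(unname(same$betas), rep(0.25, 4))

  # q touching only the self half: logits equal, betas uniform, and z is
  # the ReLU of the plain average of the members
  d2 <- 2L
  q2 <- c(1, 0, 0, 0)
  fv <- c(2, 0)
  tys <- list(lncRNA = c(0.3, -0.1), disease = c(-0.2, 0.4),
              miRNA = c(0.1, 0.2))
  r2 <- attention_fuse(fv, tys, q2)
  expect_equal(unname(r2$betas), rep(0.25, 4))
  avg <- (fv + tys$lncRNA + tys$disease + tys$miRNA) / 4
  expect_equal(r2$z, pmax(avg, 0), tolerance = 1e-12)
})

test_that("pair scoring matches hand-computed softmax values", {
  d <- 4L
  W0 <- matrix(0, 2, 2 * d)
  expect_identical(score_pair(rnorm(d), rnorm(d), W0), 0.5)

  # saturation towards the negative class
  blarge <- c(0, -50)
  expect_lt(score_pair(rnorm(d), rnorm(d), W0, blarge), 1e-20)

  # d = 1, W = I2, x = (2, 0): positive-class (first coordinate) probability
  # e^2 / (e^2 + 1); our positive class is the second logit, so swap rows
  W <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  s <- score_pair(2, 0, W, c(0, 0))
  expect_equal(s, exp(2) / (exp(2) + 1), tolerance = 1e-12)

  # softmax outputs sum to one
  set.seed(1)
  Wr <- matrix(rnorm(2 * 2 * d), 2, 2 * d)
  br <- rnorm(2)
  sp <- score_pair(rnorm(d), rnorm(d), Wr, br)
  sn <- 1 - sp
  expect_equal(sp + sn, 1, tolerance = 1e-7)
})

test_that("cross-entropy loss matches closed forms", {
  expect_equal(cross_entropy_loss(rep(0.5, 7), rep(c(0, 1), length.out = 7)),
               7 * log(2), tolerance = 1e-9)
  expect_equal(cross_entropy_loss(c(0.9, 0.2), c(1, 0)),
               -(log(0.9) + log(0.8)), tolerance = 1e-12)
  eps <- 1e-12
  expect_lt(cross_entropy_loss(c(1 - eps, eps), c(1, 0)), 1e-9)
  expect_warning(cross_entropy_loss(c(1, 0), c(1, 0)), "clamped")
  expect_error(cross_entropy_loss(0.5, c(1, 0)), "equal length")
})

test_that("analytic gradients match finite differences on a mini model", {
  inp <- random_model_inputs(n = 10L, d = 8L, seed = 5L)
  pairs_idx <- cbind(c(1L, 4L, 7L, 1L), c(2L, 5L, 8L, 5L))
  labels <- c(1L, 0L, 1L, 0L)
  for (variant in c("full", "noAttention", "noNeigh")) {
    st <- init_model(8L, variant = variant, pair_mode = "hadamard",
                     seed = 11L)
    chk <- check_gradients(st, inp$F, inp$nb, pairs_idx, labels)
    expect_lt(max(chk$max_rel_error), 1e-4)
  }
  # the printed concatenation form as well
  st <- init_model(8L, variant = "full", pair_mode = "concat", seed = 12L)
  chk <- check_gradients(st, inp$F, inp$nb, pairs_idx, labels)
  expect_lt(max(chk$max_rel_error), 1e-4)
})

test_that("training reduces the loss and is seed-reproducible", {
  inp <- random_model_inputs(n = 12L, d = 8L, seed = 9L)
  set.seed(31)
  pairs_idx <- cbind(sample(1:12, 20, replace = TRUE),
                     sample(1:12, 20, replace = TRUE))
  labels <- rbinom(20, 1, 0.5)
  labels[1] <- 1L; labels[2] <- 0L
  cfg <- hgnnlda_config(d = 8L, epochs = 30L, lr = 1e-2, batch_size = Inf)
  st <- init_model(8L, pair_mode = cfg$pair_mode, seed = 2L)
  tr1 <- train_model(st, inp$F, inp$nb, pairs_idx, labels, cfg, seed = 3L)
  expect_lt(tail(tr1$trajectory$loss, 1), tr1$trajectory$loss[1])
  tr2 <- train_model(st, inp$F, inp$nb, pairs_idx, labels, cfg, seed = 3L)
  expect_identical(tr1$state$params, tr2$state$params)
  expect_identical(predict_pairs(tr1$state, inp$F, inp$nb, pairs_idx),
                   predict_pairs(tr2$state, inp$F, inp$nb, pairs_idx))
})

test_that("a separable frozen-embedding problem is fit to 100% accuracy", {
  # noNeigh reduces to a softmax classifier on the content features; on a
  # linearly separable toy it must reach perfect training accuracy, as a
  # plain logistic regression on the same features does
  d <- 4L
  set.seed(8)
  n <- 16L
  F <- matrix(rnorm(n * d), n, d)
  pairs_idx <- cbind(1:8, 9:16)
  margin <- F[pairs_idx[, 1], 1] + F[pairs_idx[, 2], 1]
  labels <- as.integer(margin > median(margin))
  glm_fit <- suppressWarnings(
    glm.fit(cbind(1, F[pairs_idx[, 1], ], F[pairs_idx[, 2], ]), labels,
            family = binomial()))
  expect_true(all((glm_fit$fitted.values > 0.5) == (labels == 1)))

  nb <- random_model_inputs(n = n, d = d, seed = 1L)$nb
  cfg <- hgnnlda_config(d = d, epochs = 400L, lr = 5e-2, batch_size = Inf,
                        pair_mode = "concat", avg_tail = 0)
  st <- init_model(d, variant = "noNeigh", pair_mode = "concat", seed = 4L)
  tr <- train_model(st, F, nb, pairs_idx, labels, cfg, seed = 5L)
  sc <- predict_pairs(tr$state, F, nb, pairs_idx)
  expect_true(all((sc > 0.5) == (labels == 1)))
})

test_that("prediction is batch-order invariant and bounded", {
  inp <- random_model_inputs(n = 9L, d = 8L, seed = 3L)
  st <- init_model(8L, seed = 6L)
  pairs_idx <- cbind(c(1L, 4L, 1L), c(2L, 5L, 2L))
  sc <- predict_pairs(st, inp$F, inp$nb, pairs_idx)
  expect_equal(sc[1], sc[3], tolerance = 1e-12)  # duplicated pair
  perm <- c(2L, 3L, 1L)
  sc_perm <- predict_pairs(st, inp$F, inp$nb, pairs_idx[perm, ])
  expect_equal(sc_perm, sc[perm], tolerance = 1e-12)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(predict_pairs(st, inp$F, inp$nb, cbind(1L, 99L)), "unknown")
})

test_that("variants differ in parameter count and neighbour sensitivity", {
  st <- init_model(8L, seed = 1L)
  expect_error(make_variant(st, "bogus"), "unknown variant")
  full <- make_variant(st, "full")
  noatt <- make_variant(st, "noAttention")
  noneigh <- make_variant(st, "noNeigh")
  expect_false(n_parameters(full) == n_parameters(noatt))
  expect_lt(n_parameters(noneigh), n_parameters(full))

  inp <- random_model_inputs(n = 10L, d = 8L, seed = 2L)
  pairs_idx <- cbind(c(1L, 4L), c(2L, 5L))
  sc1 <- predict_pairs(noneigh, inp$F, inp$nb, pairs_idx)
  nb2 <- inp$nb
  nb2$disease[] <- nb2$disease[nrow(nb2$disease):1, ]  # scramble neighbours
  sc2 <- predict_pairs(noneigh, inp$F, nb2, pairs_idx)
  expect_identical(sc1, sc2)
  # the full model does react to neighbour perturbation
  sc3 <- predict_pairs(full, inp$F, inp$nb, pairs_idx)
  sc4 <- predict_pairs(full, inp$F, nb2, pairs_idx)
  expect_false(isTRUE(all.equal(sc3, sc4)))
})
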