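test_that("semantic similarity matches hand-evaluated DAG contributions", {
  # d1 and d2 are both children of a common parent a, delta = 0.5:
  # D_d1 = {d1: 1, a: 0.5}, DV = 1.5 each, shared ancestor {a},
  # DSS = (0.5 + 0.5) / (1.5 + 1.5) = 1/3
  ont <- disease_ontology(
    tibble::tibble(child = c("d1", "d2"), parent = c("a", "a")),
    delta = 0.5)
  dss <- compute_dss(ont)
  expect_equal(dss["d1", "d2"], 1 / 3, tolerance = 1e-12)
  expect_equal(unname(diag(dss)), rep(1, 3))

  # isolated term: self-similarity 1
  ont2 <- disease_ontology(
    tibble::tibble(child = "x", parent = "r"),
    terms = c("x", "r", "lonely"), delta = 0.5)
  dss2 <- compute_dss(ont2)
  expect_identical(dss2["lonely", "lonely"], 1)

  # disconnected components share no ancestors
  ont3 <- disease_ontology(
    tibble::tibble(child = c("d1", "d2"), parent = c("a", "b")),
    delta = 0.5)
  expect_identical(compute_dss(ont3)["d1", "d2"], 0)
})

test_that("deeper DAGs use the best path and decay multiplicatively", {
  # chain d -> p -> g plus shortcut d -> g: contribution of g must be the
  # max over paths, i.e. delta (direct), not delta^2
  ont <- disease_ontology(
    tibble::tibble(child = c("d", "p", "d"), parent = c("p", "g", "g")),
    delta = 0.4)
  contrib <- hgnnlda:::semantic_contributions(ont, "d")
  expect_equal(contrib[["g"]], 0.4, tolerance = 1e-12)
  expect_equal(contrib[["p"]], 0.4, tolerance = 1e-12)
})

test_that("ontology construction rejects cycles and unknown terms", {
  expect_error(disease_ontology(
    tibble::tibble(child = c("a", "b"), parent = c("b", "a"))), "cycle")
  expect_error(disease_ontology(
    tibble::tibble(child = "a", parent = "b"), terms = c("a")), "unknown")
  expect_error(disease_ontology(
    tibble::tibble(child = "a", parent = "b"), delta = 1), "delta")
})

test_that("lncRNA pair similarity reproduces hand-evaluated values", {
  dss <- matrix(c(1, 0.4, 0.6,
                  0.4, 1, 0.2,
                  0.6, 0.2, 1), 3, 3, byrow = TRUE,
                dimnames = list(c("d1", "d2", "d3"), c("d1", "d2", "d3")))
  expect_identical(lncrna_pair_similarity("d1", "d1", dss), 1)
  expect_equal(lncrna_pair_similarity("d1", "d2", dss), 0.4,
               tolerance = 1e-12)
  # D1 = {d1, d2}, D2 = {d3}: (0.6 + 0.2 + max(0.6, 0.2)) / 3 = 1.4/3
  expect_equal(lncrna_pair_similarity(c("d1", "d2"), "d3", dss), 1.4 / 3,
               tolerance = 1e-12)
  expect_warning(v <- lncrna_pair_similarity(character(0), character(0), dss),
                 "empty")
  expect_identical(v, 0)
})

test_that("pair similarity is symmetric and monotone under shared diseases", {
  set.seed(11)
  nd <- 8
  ids <- paste0("d", seq_len(nd))
  M <- matrix(runif(nd * nd), nd, nd, dimnames = list(ids, ids))
  dss <- (M + t(M)) / 2
  diag(dss) <- 1
  for (rep in 1:20) {
    D1 <- sample(ids, sample(1:4, 1))
    D2 <- sample(ids, sample(1:4, 1))
    a <- lncrna_pair_similarity(D1, D2, dss)
    expect_equal(a, lncrna_pair_similarity(D2, D1, dss), tolerance = 1e-12)
    expect_gte(a, 0); expect_lte(a, 1 + 1e-12)
    # appending a shared disease with self-similarity 1 never decreases Eq-2
    shared <- sample(setdiff(ids, union(D1, D2)), 1)
    b <- lncrna_pair_similarity(c(D1, shared), c(D2, shared), dss)
    expect_gte(b, a - 1e-12)
  }
})

test_that("functional similarity matrix agrees with per-pair brute force", {
  dss <- matrix(c(1, 0.4, 0.6,
                  0.4, 1, 0.2,
                  0.6, 0.2, 1), 3, 3, byrow = TRUE,
                dimnames = list(c("d1", "d2", "d3"), c("d1", "d2", "d3")))
  ld <- matrix(c(1L, 1L, 0L,
                 0L, 0L, 1L,
                 1L, 0L, 1L), 3, 3, byrow = TRUE,
               dimnames = list(c("l1", "l2", "l3"), c("d1", "d2", "d3")))
  lfs <- build_lfs(ld, dss)
  sets <- list(l1 = c("d1", "d2"), l2 = "d3", l3 = c("d1", "d3"))
  for (i in 1:3) for (j in 1:3) {
    expected <- if (i == j) 1 else
      lncrna_pair_similarity(sets[[i]], sets[[j]], dss)
    expect_equal(lfs[i, j], expected, tolerance = 1e-12)
  }
  expect_equal(lfs, t(lfs), tolerance = 1e-12)
})

test_that("lncRNAs without diseases get zero similarity but unit diagonal", {
  dss <- diag(1, 2)
  dimnames(dss) <- list(c("d1", "d2"), c("d1", "d2"))
  ld <- matrix(c(1L, 0L, 0L, 0L), 2, 2, byrow = TRUE,
               dimnames = list(c("l1", "l2"), c("d1", "d2")))
  lfs <- build_lfs(ld, dss)
  expect_identical(lfs["l2", "l1"], 0)
  expect_identical(lfs["l2", "l2"], 1)
})

test_that("synthetic disease DAG reproduces a two-level similarity", {
  cfg <- synthetic_config(n_lnc = 6L, n_dis = 8L, n_mi = 4L, n_blocks = 2L,
                          p_in = 0.5, p_out = 0.05, seed = 3L)
  dag <- synthetic_disease_dag(cfg)
  ont <- disease_ontology(dag, delta = 0.5)
  dss <- compute_dss(ont, sprintf("D%03d", 1:8))
  same <- outer(rep(1:2, each = 4), rep(1:2, each = 4), `==`)
  off <- !diag(8) & same
  expect_gt(min(dss[off]), max(dss[!same]))
  expect_equal(dss, t(dss), tolerance = 1e-12)
})
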