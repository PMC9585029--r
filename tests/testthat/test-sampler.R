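test_that("p = 1 never leaves the start and is flagged", {
  g <- toy_graph()
  cfg <- hgnnlda_config(p = 1, collect_size = 9L, min_per_type = 3L,
                        max_steps = 50L)
  res <- restart_random_walk(g, "l1", cfg, seed = 1)
  expect_true(all(res$sequence == "l1"))
  expect_true(res$flagged)
  expect_equal(res$steps, 50L)
})

test_that("walks only reach nodes connected to the start", {
  # path graph l1 - d1 - l2 (no miRNA edges, no similarity edges)
  ld <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("l1", "l2"), "d1"))
  lm <- matrix(0L, 2, 1, dimnames = list(c("l1", "l2"), "m1"))
  lfs <- diag(1, 2)
  dimnames(lfs) <- list(c("l1", "l2"), c("l1", "l2"))
  g <- suppressWarnings(build_hetero_graph(lfs, ld, lm))
  cfg <- hgnnlda_config(p = 0, q = 1, collect_size = 30L, min_per_type = 0L,
                        max_steps = 200L)
  res <- restart_random_walk(g, "l1", cfg, seed = 3)
  expect_true(all(res$sequence %in% c("l1", "d1", "l2")))
  expect_error(restart_random_walk(g, "m1", cfg), "isolated")
})

test_that("exact visiting distribution has its closed forms", {
  g <- toy_graph()
  pi1 <- exact_visit_distribution(g, "l1", p = 1)
  expect_equal(unname(pi1), c(1, 0, 0, 0))
  # p = 0 on an undirected graph: strength-weighted stationary distribution
  ld <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("l1", "l2"), "d1"))
  lm <- matrix(0L, 2, 1, dimnames = list(c("l1", "l2"), "m1"))
  lfs <- diag(1, 2)
  dimnames(lfs) <- list(c("l1", "l2"), c("l1", "l2"))
  g2 <- suppressWarnings(build_hetero_graph(lfs, ld, lm))
  pi0 <- exact_visit_distribution(g2, "l1", p = 0)
  expect_equal(unname(pi0[c("l1", "d1")]), c(0.5, 0.5))
})

test_that("power iteration agrees with a direct linear solve", {
  g <- six_node_graph()
  p <- 0.5
  pi_pow <- exact_visit_distribution(g, "l1", p = p)
  W <- hgnnlda:::transition_matrix(g)
  n <- nrow(W)
  e <- numeric(n); e[1] <- 1
  pi_solve <- solve(diag(n) - (1 - p) * t(W), p * e)
  pi_solve <- pi_solve / sum(pi_solve)
  expect_lt(max(abs(pi_pow - pi_solve)), 1e-10)
})

test_that("empirical visit frequencies approach the exact distribution", {
  g <- six_node_graph()
  cfg <- hgnnlda_config(p = 0.5, q = 1, collect_size = 100000L,
                        min_per_type = 0L, max_steps = 100000L)
  res <- restart_random_walk(g, "l1", cfg, seed = 17)
  emp <- table(factor(res$sequence, levels = g$nodes$id))
  emp <- as.numeric(emp) / sum(emp)
  pi <- exact_visit_distribution(g, "l1", p = 0.5)
  tv <- 0.5 * sum(abs(emp - pi))
  expect_lt(tv, 0.05)
})

test_that("typed neighbour selection ranks, tie-breaks and pads", {
  cfg <- hgnnlda_config(k_lnc = 2L, k_dis = 3L, k_mi = 1L)
  counts <- tibble::tibble(
    node = c("a", "b", "c", "d9", "x", "y"),
    type = c("lncRNA", "lncRNA", "lncRNA", "disease", "miRNA", "miRNA"),
    count = c(5L, 3L, 1L, 2L, 3L, 3L))
  sel <- select_typed_neighbors(counts, cfg)
  expect_equal(sel$lncRNA$neighbor, c("a", "b"))
  # single sampled disease cycled to k_dis = 3
  expect_equal(sel$disease$neighbor, c("d9", "d9", "d9"))
  # tie x/y broken lexicographically at k_mi = 1
  expect_equal(sel$miRNA$neighbor, "x")
  # [a,b] cycled to length 5
  cfg2 <- hgnnlda_config(k_lnc = 5L)
  sel2 <- select_typed_neighbors(counts[1:2, ], cfg2)
  expect_equal(sel2$lncRNA$neighbor, c("a", "b", "a", "b", "a"))
  expect_equal(nrow(sel2$disease), 0L)
})

test_that("sample_all is deterministic, type-pure and bookkeeps visits", {
  sim <- small_sim()
  lfs <- build_lfs(sim$ld, sim$dss)
  g <- suppressWarnings(build_hetero_graph(lfs, sim$ld, sim$lm))
  cfg <- fast_config(seed = 5L)
  w1 <- sample_all(g, cfg)
  w2 <- sample_all(g, cfg)
  expect_identical(w1$table, w2$table)
  expect_identical(w1$corpus, w2$corpus)

  tp <- setNames(as.character(g$nodes$type), g$nodes$id)
  expect_true(all(tp[w1$table$neighbor] == w1$table$type))

  # banked visits sum to collect_size when no per-type quota applies
  cfg0 <- fast_config(seed = 5L)
  cfg0$min_per_type <- 0L
  cfg0$collect_size <- 10L
  res <- restart_random_walk(g, "L001", cfg0, seed = 2)
  expect_equal(sum(res$counts$count), 10L)
})

test_that("neighbour sets respect reachability through cut vertices", {
  # d1's only route to the miRNA layer is through l1
  ld <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("l1", "l2"), "d1"))
  lm <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("l1", "l2"), "m1"))
  lfs <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
                dimnames = list(c("l1", "l2"), c("l1", "l2")))
  g <- build_hetero_graph(lfs, ld, lm, lnc_topk = 1L)
  cfg <- hgnnlda_config(collect_size = 30L, min_per_type = 1L,
                        k_lnc = 2L, k_dis = 1L, k_mi = 1L,
                        max_steps = 500L)
  res <- restart_random_walk(g, "d1", cfg, seed = 9)
  mi <- res$counts[res$counts$type == "miRNA", ]
  # every miRNA banked from d1 is adjacent to some lncRNA on a d1 path
  expect_true(all(mi$node == "m1"))
})
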