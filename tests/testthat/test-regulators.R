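test_that("neighborhood hit counts match hand-traced graphs", {
  path <- interaction_network(data.frame(
    a = c("a", "b", "c", "d"), b = c("b", "c", "d", "e"),
    stringsAsFactors = FALSE))
  # path a-b-c-d-e from c: all four others are within distance 2
  expect_identical(neighborhood_hit_count(path, "c",
                                          c("a", "b", "d", "e")), 4L)
  expect_identical(neighborhood_hit_count(path, "a", c("d", "e")), 0L)

  star <- interaction_network(data.frame(
    a = rep("hub", 5), b = paste0("l", 1:5), stringsAsFactors = FALSE))
  expect_identical(neighborhood_hit_count(star, "hub", paste0("l", 1:5)),
                   5L)
  # a leaf sees the hub and, at distance 2, the other leaves - not itself
  expect_identical(neighborhood_hit_count(star, "l1",
                                          c("l1", "l2", "hub")), 2L)

  iso <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices("solo")
  expect_identical(neighborhood_hit_count(iso, "solo", c("a", "b")), 0L)
  expect_error(neighborhood_hit_count(star, "nope", "l1"), "nearest")
})

test_that("neighborhood counts agree with an adjacency-algebra oracle", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.05, 0.3))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    gene_set <- sample(igraph::V(g)$name, max(2, n %/% 3))
    reg <- sample(igraph::V(g)$name, 1)
    expect_identical(neighborhood_hit_count(g, reg, gene_set),
                     brute_force_n12_hits(g, reg, gene_set))
  }
})

test_that("hub empirical p matches the hypergeometric on the neighborhood", {
  set.seed(17)
  g <- igraph::sample_gnp(40, 0.12)
  igraph::V(g)$name <- paste0("v", 1:40)
  universe <- igraph::V(g)$name
  core <- sample(universe, 12)
  res <- suppressWarnings(test_hub_significance(
    g, universe, core, universe, n_resamples = 30000L, seed = 5))
  # the resampling null is exactly hypergeometric in |N1 u N2|
  for (i in seq_len(nrow(res))) {
    p_exact <- hypergeometric_oracle(res$statistic[i], 12,
                                     res$neighborhood_size[i], 40)
    se <- sqrt(p_exact * (1 - p_exact) / 30000) + 1 / 30001
    expect_lt(abs(res$empirical_p[i] - p_exact), 4 * se + 1e-12)
  }
})

test_that("key-TF selection keeps enriched TFs and honors alpha", {
  universe <- paste0("g", 1:200)
  core <- universe[1:40]
  tfs <- list(hit = c(core[1:20], universe[51:60]),  # half its targets in core
              miss = universe[101:130],
              outside = paste0("zz", 1:5))
  res <- suppressWarnings(identify_key_tfs(
    tfs, core, universe, n_resamples = 5000L, seed = 3, alpha = 0.01))
  expect_true(res$selected[res$gene_id == "hit"])
  expect_false(res$selected[res$gene_id == "miss"])
  # a TF with no targets in the universe is excluded with p = 1
  expect_false(res$selected[res$gene_id == "outside"])
  expect_identical(res$empirical_p[res$gene_id == "outside"], 1)

  # alpha = 1 returns every TF as a row; only p = 1 rows stay unselected
  all_in <- suppressWarnings(identify_key_tfs(
    tfs[1:2], core, universe, n_resamples = 200L, seed = 3, alpha = 1))
  expect_setequal(all_in$gene_id, c("hit", "miss"))
  expect_true(all(all_in$selected[all_in$empirical_p < 1]))
})

test_that("candidates are ranked by p, then statistic, then id per module", {
  cand <- data.frame(
    gene_id = c("b", "a", "c", "d"), category = "ppi_hub",
    statistic = c(7L, 12L, 12L, 3L),
    empirical_p = c(0.001, 0.001, 0.001, 0.02),
    stringsAsFactors = FALSE)
  modules <- list(M1 = c("a", "b", "c", "d"), M2 = c("d"))
  out <- prioritize_candidates(cand, modules)
  m1 <- out[out$module_id == "M1", ]
  # equal p: the larger statistic first; equal statistic: lexicographic id
  expect_identical(m1$gene_id, c("a", "c", "b", "d"))
  expect_identical(m1$rank_within_module, 1:4)
  m2 <- out[out$module_id == "M2", ]
  expect_identical(m2$gene_id, "d")
  expect_identical(m2$rank_within_module, 1L)
  top <- attr(out, "top_per_module")
  expect_setequal(top$gene_id[top$module_id == "M1"], "a")

  # TFs associate with modules through their targets
  tf <- data.frame(gene_id = "TF1", category = "tf", statistic = 5L,
                   empirical_p = 0.005, stringsAsFactors = FALSE)
  out_tf <- prioritize_candidates(tf, modules,
                                  tf_target_map = list(TF1 = c("d", "x")))
  expect_setequal(out_tf$module_id, c("M1", "M2"))
})
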