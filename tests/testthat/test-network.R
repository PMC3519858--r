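test_that("edge loading deduplicates and drops self-loops", {
  d <- withr::local_tempdir()
  f <- write_edges_tsv(list(c("A", "B"), c("B", "A"), c("A", "A")),
                       file.path(d, "e.tsv"))
  g <- load_interactions(f)
  expect_identical(igraph::ecount(g), 1)
  rep <- attr(g, "load_report")
  expect_identical(rep$n_self_loops, 1L)
  expect_identical(rep$n_duplicates, 1L)

  sif <- file.path(d, "n.sif")
  writeLines("A pp B", sif)
  gs <- load_interactions(sif)
  expect_setequal(igraph::V(gs)$name, c("A", "B"))
  expect_identical(igraph::E(gs)$source, "pp")

  writeLines(c("A\tB", "oops"), file.path(d, "bad.tsv"))
  expect_error(load_interactions(file.path(d, "bad.tsv")), "line")

  file.create(file.path(d, "empty.tsv"))
  expect_warning(ge <- load_interactions(file.path(d, "empty.tsv")),
                 "empty")
  expect_identical(igraph::vcount(ge), 0)
})

test_that("perturbed-network reconstruction follows the seed/interactor rule", {
  ppi <- interaction_network(data.frame(
    a = c("A", "B", "C"), b = c("C", "E", "D"),
    stringsAsFactors = FALSE))
  ann <- list(M1 = c("A", "B"))
  core <- c("A", "B", "C", "D")
  net <- reconstruct_perturbed_network(core, ann, ppi)
  expect_setequal(igraph::V(net)$name, c("A", "B", "C"))
  roles <- setNames(igraph::V(net)$role, igraph::V(net)$name)
  expect_identical(unname(roles["C"]), "interactor")
  expect_identical(unname(roles["A"]), "seed")  # annotated -> always a seed

  # every interactor keeps at least one seed neighbor in the subgraph
  for (v in igraph::V(net)$name[igraph::V(net)$role == "interactor"]) {
    nb <- names(igraph::neighbors(net, v))
    expect_true(any(roles[nb] == "seed"))
  }
  expect_error(reconstruct_perturbed_network("Z", ann, ppi), "no core gene")
})

test_that("reconstruction is invariant to input edge order", {
  edges <- data.frame(a = c("A", "B", "C", "D"), b = c("C", "C", "E", "A"),
                      stringsAsFactors = FALSE)
  ann <- list(M = c("A", "B"))
  core <- c("A", "B", "C", "E")
  n1 <- reconstruct_perturbed_network(core, ann, interaction_network(edges))
  n2 <- reconstruct_perturbed_network(core, ann,
                                      interaction_network(edges[4:1, ]))
  expect_setequal(igraph::V(n1)$name, igraph::V(n2)$name)
  e1 <- apply(igraph::as_edgelist(n1), 1, function(e)
    paste(sort(e), collapse = "-"))
  e2 <- apply(igraph::as_edgelist(n2), 1, function(e)
    paste(sort(e), collapse = "-"))
  expect_setequal(e1, e2)
})

test_that("module assignment covers annotated nodes and interactors", {
  ppi <- interaction_network(data.frame(
    a = c("s1", "s2", "s3", "s1", "t1", "t2"),
    b = c("i1", "i1", "i1", "i2", "i2", "x"),
    stringsAsFactors = FALSE))
  ann <- list(MR = c("s1", "s2"), CC = c("s3", "t1", "t2"))
  net <- reconstruct_perturbed_network(
    c("s1", "s2", "s3", "t1", "t2", "i1", "i2"), ann, ppi)
  mods <- assign_network_modules(net, ann)
  expect_true("s1" %in% mods$MR)
  # i1 borders 2 MR seeds and 1 CC seed -> MR only (majority)
  expect_true("i1" %in% mods$MR)
  expect_false("i1" %in% mods$CC)
  # i2 borders 1 MR and 1 CC seed -> tie -> both
  expect_true("i2" %in% mods$MR && "i2" %in% mods$CC)
})

test_that("MES is the module coverage over the network-to-core ratio", {
  # module of 10, 5 in overlay, network 242, core 983
  s <- module_enrichment_score(paste0("m", 1:10), paste0("m", 1:5),
                               network_size = 242, core_set_size = 983)
  expect_equal(s$score, 2.0310, tolerance = 1e-4)
  expect_identical(s$overlap_count, 5L)

  none <- module_enrichment_score(paste0("m", 1:10), "zz", 242, 983)
  expect_identical(none$score, 0)

  full <- module_enrichment_score(c("a", "b"), c("a", "b"), 100, 100)
  expect_equal(full$score, 1)

  # scale consistency: doubling overlap and module size leaves MES fixed
  s2 <- module_enrichment_score(paste0("m", 1:20), paste0("m", 1:10),
                                242, 983)
  expect_equal(s2$score, s$score)
  expect_error(module_enrichment_score(character(), "a", 242, 983),
               "empty")
  # the reciprocal-background variant inverts the normalization
  conv <- module_enrichment_score(paste0("m", 1:10), paste0("m", 1:5),
                                  242, 983, conventional = TRUE)
  expect_equal(conv$score, 0.5 / (983 / 242))
})

test_that("target enrichment score is the covered fraction of the module", {
  mod <- paste0("g", 1:8)
  expect_identical(target_enrichment_score(mod, "zz")$score, 0)
  expect_equal(target_enrichment_score(mod, mod[1:2])$score, 0.25)
  expect_equal(target_enrichment_score(mod, c(mod, "extra"))$score, 1)
})

test_that("overlaying a signature flags nodes and reports the fraction", {
  g <- interaction_network(data.frame(a = c("A", "B", "C"),
                                      b = c("B", "C", "D"),
                                      stringsAsFactors = FALSE))
  o <- overlay_signature(g, c("A", "C"), label = "fls")
  sm <- attr(o, "overlay_summary")
  expect_equal(sm$fraction, 0.5)
  expect_identical(sum(igraph::vertex_attr(o, "fls")), 2L)
  empty <- overlay_signature(g, character())
  expect_equal(attr(empty, "overlay_summary")$fraction, 0)
  all_in <- overlay_signature(g, c("A", "B", "C", "D"))
  expect_equal(attr(all_in, "overlay_summary")$fraction, 1)
})

test_that("network exports round-trip through SIF and GraphML", {
  d <- withr::local_tempdir()
  g <- interaction_network(data.frame(a = c("A", "B"), b = c("B", "C"),
                                      stringsAsFactors = FALSE))
  igraph::V(g)$role <- c("seed", "seed", "interactor")
  sif <- file.path(d, "n.sif")
  write_sif(g, sif)
  back <- load_interactions(sif)
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  expect_identical(igraph::ecount(back), igraph::ecount(g))

  gml <- file.path(d, "n.graphml")
  write_graphml(g, gml)
  gback <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(gback)$role, igraph::V(g)$role)
})
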