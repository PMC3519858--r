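test_that("expression generation is deterministic and well-structured", {
  a <- generate_multistudy_expression(n_studies = 2, n_genes = 120,
                                      samples_per_arm = 3, seed = 5)
  b <- generate_multistudy_expression(n_studies = 2, n_genes = 120,
                                      samples_per_arm = 3, seed = 5)
  expect_identical(a$studies[[1]]$values, b$studies[[1]]$values)
  expect_identical(a$truth$planted_groups, b$truth$planted_groups)
  c2 <- generate_multistudy_expression(n_studies = 2, n_genes = 120,
                                       samples_per_arm = 3, seed = 6)
  expect_false(identical(a$studies[[1]]$values, c2$studies[[1]]$values))

  groups <- a$truth$planted_groups
  expect_identical(sort(unique(unlist(groups))),
                   sort(unname(a$probe_to_gene)))
  # groups are pairwise disjoint
  expect_identical(anyDuplicated(unlist(groups)), 0L)
  expect_error(generate_multistudy_expression(
    n_genes = 10, group_sizes = c(shared_up = 20, dominant_up = 0,
                                  shared_down = 0, dominant_down = 0)),
    "group sizes")
})

test_that("dominant-up genes shift by the effect size in the primary arm", {
  eff <- 2
  sim <- generate_multistudy_expression(n_studies = 3, n_genes = 2000,
                                        samples_per_arm = 5,
                                        effect_size = eff, noise_sd = 0.5,
                                        scale_jitter = 0, seed = 2)
  du <- sim$truth$planted_groups$dominant_up
  fcs <- unlist(lapply(sim$studies, function(st) {
    fc <- compute_fold_changes(st, "disease_primary")
    fc$values[paste0("p_", du), ]
  }))
  n <- length(fcs)
  expect_lt(abs(mean(fcs) - eff), 3 * 0.6 / sqrt(n) + 0.02)
  # comparator arm carries no dominant shift
  fcc <- unlist(lapply(sim$studies, function(st) {
    fc <- compute_fold_changes(st, "disease_comparator")
    fc$values[paste0("p_", du), ]
  }))
  expect_lt(abs(mean(fcc)), 0.1)
})

test_that("interaction generator plants a tree and biased hubs", {
  genes <- sprintf("n%03d", 1:80)
  tree <- generate_interaction_network(genes, attach_m = 1L, n_hubs = 0L,
                                       seed = 3)
  expect_identical(igraph::ecount(tree$network), 79)

  core <- genes[1:30]
  net <- generate_interaction_network(genes, attach_m = 1L, n_hubs = 2L,
                                      core_genes = core, core_bias = 1,
                                      seed = 3)
  for (h in net$truth$planted_hubs) {
    # bias 1 forces an edge to every core gene
    expect_gte(neighborhood_hit_count(net$network, h, core),
               length(setdiff(core, h)))
  }
  unbiased <- generate_interaction_network(genes, attach_m = 1L,
                                           n_hubs = 2L, core_genes = core,
                                           core_bias = 0, seed = 3)
  expect_identical(igraph::ecount(unbiased$network), 79)
})

test_that("TF map plants hypergeometrically enriched TFs", {
  universe <- sprintf("g%04d", 1:1000)
  core <- universe[1:100]
  tf <- generate_tf_target_map(universe, n_tfs = 10, targets_per_tf = 50,
                               n_planted = 2, core_genes = core,
                               core_overlap_fraction = 0.4, seed = 8)
  for (p in tf$truth$planted_tfs) {
    ov <- length(intersect(tf$tf_targets[[p]], core))
    expect_lt(hypergeometric_oracle(ov, 50, 100, 1000), 1e-6)
  }
  empty <- generate_tf_target_map(universe, n_tfs = 0)
  expect_identical(length(empty$tf_targets), 0L)
})

test_that("annotation and overlay generators respect their construction", {
  labels <- c("AP", "TC", "BC", "IG", "CA", "NK", "IC", "CK", "CMH", "TLR",
              "AF", "JS", "CC", "CDS", "ECM", "MR")
  universe <- sprintf("g%04d", 1:1500)
  grp <- universe[1:150]
  ann <- generate_annotation_sets(labels, universe, grp,
                                  genes_per_module = 8,
                                  from_group_fraction = 0.75,
                                  disjoint = TRUE, seed = 2)
  expect_identical(length(ann$annotations), 16L)
  expect_identical(anyDuplicated(unlist(ann$annotations)), 0L)
  # planted association: the target group is enriched in each term
  for (m in names(ann$annotations)) {
    ov <- length(intersect(ann$annotations[[m]], grp))
    expect_lt(hypergeometric_oracle(ov, 8, length(grp), 1500), 0.01)
  }

  full <- generate_overlay_signatures(ann$annotations, "sig",
                                      coverage_per_module = 1, seed = 1)
  expect_setequal(full$sig, unique(unlist(ann$annotations)))
  none <- generate_overlay_signatures(ann$annotations, "sig",
                                      coverage_per_module = 0, seed = 1)
  expect_identical(none$sig, character())
})

test_that("simulated inputs round-trip through the writers and readers", {
  d <- withr::local_tempdir()
  sim <- simulate_ra_inputs(seed = 3, out_dir = d, n_studies = 2,
                            n_genes = 150, samples_per_arm = 3,
                            n_tfs = 6, n_hubs = 2)
  expect_identical(read_gmt(sim$files$tf_gmt), sim$tf_targets,
                   ignore_attr = FALSE)
  expect_identical(read_gene_list(sim$files$universe), sim$universe)
  g <- load_interactions(sim$files$ppi)
  expect_identical(igraph::ecount(g), igraph::ecount(sim$network))
  sheet <- read_sample_sheet(sim$files$samples)
  expect_identical(nrow(sheet), 2L * 9L)
  expr <- read_expression_tsv(sim$files$expr_study1)
  expect_equal(expr, sim$studies[[1]]$values)
  truth <- jsonlite::read_json(sim$files$truth, simplifyVector = TRUE)
  expect_setequal(truth$planted_groups$dominant_up,
                  sim$truth$planted_groups$dominant_up)
})
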