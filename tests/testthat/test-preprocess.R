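test_that("fold-changes subtract the normal median per probe", {
  st <- toy_study()
  fc <- compute_fold_changes(st, "disease_primary")
  # p1: normal intensities 5,6,7 (median 6); disease samples 6 and 8
  expect_equal(unname(fc$values["p1", ]), c(0, 2))
  expect_equal(colnames(fc$values), c("s1_4", "s1_5"))
  expect_identical(fc$level, "probe")

  # the comparator arm gives its own separate matrix
  fc2 <- compute_fold_changes(st, "disease_comparator")
  expect_equal(unname(fc2$values["p3", ]), c(2, 2))
  expect_equal(ncol(fc2$values), 2L)
})

test_that("fold-change preconditions are enforced", {
  vals <- matrix(1:4, 2, dimnames = list(c("p1", "p2"), c("a", "b")))
  st <- expression_study("x", vals, c("disease_primary", "disease_primary"))
  expect_error(compute_fold_changes(st, "disease_primary"), "normal")
  st2 <- expression_study("x", vals, c("normal", "disease_primary"))
  expect_error(compute_fold_changes(st2, "treated"), "treated")
})

test_that("expression_study validates its inputs", {
  vals <- matrix(c(1, NA, 3, 4), 2,
                 dimnames = list(c("p1", "p2"), c("a", "b")))
  expect_error(expression_study("x", vals, c("normal", "normal")),
               "non-finite")
  vals2 <- matrix(1:4, 2, dimnames = list(c("p1", "p1"), c("a", "b")))
  expect_error(expression_study("x", vals2, c("normal", "normal")),
               "unique")
  vals3 <- matrix(1:4, 2, dimnames = list(c("p1", "p2"), c("a", "b")))
  expect_error(expression_study("x", vals3, c("normal", "weird")),
               "condition")
})

test_that("probe collapse keeps the largest-|fold-change| probe per gene", {
  vals <- rbind(pa = c(1.5, -0.2), pb = c(-2.5, 0.1), pc = c(0.3, 0.4))
  colnames(vals) <- c("d1", "d2")
  fc <- make_fcm(vals, level = "probe")
  map <- c(pa = "G1", pb = "G1", pc = "G2")
  out <- collapse_probes_to_genes(fc, map)
  # G1's representative is pb (max |value| 2.5 beats 1.5), full row kept
  expect_equal(unname(out$values["G1", ]), c(-2.5, 0.1))
  expect_equal(rownames(out$values), c("G1", "G2"))  # ordered by gene id
  expect_identical(out$level, "gene")
})

test_that("probe collapse handles single probes, ties and unmapped probes", {
  vals <- rbind(pa = c(1, 2), pz = c(-1, -2), pq = c(9, 9))
  colnames(vals) <- c("d1", "d2")
  fc <- make_fcm(vals, level = "probe")
  out <- collapse_probes_to_genes(fc, c(pa = "G1", pz = "G1"))
  # |values| tie between pa and pz: lexicographically smaller probe id wins
  expect_equal(unname(out$values["G1", ]), c(1, 2))
  expect_identical(attr(out, "dropped_probes"), 1L)

  single <- collapse_probes_to_genes(fc, c(pq = "G9"))
  expect_equal(unname(single$values["G9", ]), c(9, 9))
  expect_error(collapse_probes_to_genes(fc, character()), "empty")
  expect_error(collapse_probes_to_genes(fc, c(nope = "G")), "covered")
})

test_that("quantile normalization matches the order-statistic reference", {
  m1 <- make_fcm(matrix(c(1, 2, 3), 1, dimnames = list("g", NULL)))
  m2 <- make_fcm(matrix(c(4, 5, 6), 1, dimnames = list("g", NULL)),
                 study_id = "t")
  out <- cross_study_quantile_normalize(list(m1, m2))
  expect_equal(as.vector(out[[1]]$values), c(2.5, 3.5, 4.5))
  expect_equal(as.vector(out[[2]]$values), c(2.5, 3.5, 4.5))
})

test_that("quantile normalization is idempotent and fixes identical inputs", {
  set.seed(11)
  mats <- lapply(1:5, function(i)
    make_fcm(matrix(rnorm(12), 3, dimnames = list(letters[1:3], NULL)),
             study_id = paste0("s", i)))
  same <- lapply(1:5, function(i) mats[[1]])
  out_same <- cross_study_quantile_normalize(same)
  for (o in out_same) expect_equal(o$values, mats[[1]]$values)

  once <- cross_study_quantile_normalize(mats)
  twice <- cross_study_quantile_normalize(once)
  for (i in 1:5)
    expect_equal(twice[[i]]$values, once[[i]]$values, tolerance = 1e-9)
  # all output vectors share the same sorted values (equal lengths)
  sorted <- lapply(once, function(o) sort(as.vector(o$values)))
  for (i in 2:5) expect_equal(sorted[[i]], sorted[[1]])
})

test_that("equal-length quantile normalization agrees with limma", {
  skip_if_not_installed("limma")
  set.seed(7)
  vecs <- replicate(4, rnorm(30), simplify = FALSE)
  mats <- lapply(seq_along(vecs), function(i)
    make_fcm(matrix(vecs[[i]], 5, dimnames = list(letters[1:5], NULL)),
             study_id = paste0("s", i)))
  ours <- cross_study_quantile_normalize(mats)
  ref <- limma::normalizeQuantiles(do.call(cbind, vecs))
  for (i in seq_along(vecs))
    expect_equal(as.vector(ours[[i]]$values), ref[, i], tolerance = 1e-9)
})

test_that("combining matrices concatenates columns over the gene match", {
  a <- make_fcm(matrix(1:4, 2, dimnames = list(c("A", "B"), c("x", "y"))),
                study_id = "s1")
  b <- make_fcm(matrix(1:6, 2, dimnames = list(c("A", "B"),
                                               c("u", "v", "w"))),
                study_id = "s2")
  comb <- combine_matrices(list(a, b))
  expect_equal(dim(comb$values), c(2L, 5L))
  expect_equal(comb$samples$study_id, c("s1", "s1", "s2", "s2", "s2"))

  c2 <- make_fcm(matrix(1:4, 2, dimnames = list(c("B", "C"), c("x", "y"))),
                 study_id = "s3")
  inter <- combine_matrices(list(a, c2))
  expect_equal(inter$gene_ids, "B")
  uni <- combine_matrices(list(a, c2), match = "union")
  expect_setequal(uni$gene_ids, c("A", "B", "C"))
  expect_true(attr(uni, "n_missing") > 0)
  expect_error(combine_matrices(list(a, a)), "duplicate")
})

test_that("readers and writers round-trip expression tables and maps", {
  d <- withr::local_tempdir()
  vals <- matrix(rnorm(6), 2,
                 dimnames = list(c("p1", "p2"), c("a", "b", "c")))
  f <- file.path(d, "e.tsv")
  write_expression_tsv(vals, f)
  expect_equal(read_expression_tsv(f), vals)

  g <- file.path(d, "genes.txt")
  write_gene_list(c("g1", "g2"), g)
  expect_equal(read_gene_list(g), c("g1", "g2"))

  gmt <- file.path(d, "x.gmt")
  sets <- list(T1 = c("a", "b"), T2 = c("c"))
  attr(sets, "description") <- c(T1 = "process", T2 = "disease")
  write_gmt(sets, gmt)
  back <- read_gmt(gmt)
  expect_equal(back[["T1"]], c("a", "b"))
  expect_equal(attr(back, "description")[["T2"]], "disease")
})
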