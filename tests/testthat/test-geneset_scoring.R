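test_that("module score is zero on a constant matrix and location-free", {
  m <- matrix(3L, nrow = 60, ncol = 10)
  sce <- tiny_sce(m, normalize = FALSE)
  SingleCellExperiment::logcounts(sce) <- methods::as(
    matrix(1.7, nrow = 60, ncol = 10,
           dimnames = dimnames(SummarizedExperiment::assay(sce, "counts"))),
    "CsparseMatrix")
  sc <- module_score(sce, rownames(sce)[1:5], seed = 1)
  expect_true(all(sc$score == 0))

  # adding a constant to the whole normalized layer leaves scores unchanged
  ds <- generate_dataset(generator_params(n_cell_types = 1,
                                          cells_per_group_per_type = 25,
                                          n_genes = 300, seed = 6))
  sce <- normalize_counts(ds$sce)
  genes <- program_genes(ds$truth, "T1")[1:15]
  s1 <- module_score(sce, genes, seed = 3)
  shifted <- sce
  SingleCellExperiment::logcounts(shifted) <-
    SummarizedExperiment::assay(sce, "logcounts") + 1
  s2 <- module_score(shifted, genes, seed = 3)
  expect_equal(s1$score, s2$score, tolerance = 1e-9)
})

test_that("module score is seed-deterministic and seed-stable", {
  sce <- demo_norm()
  ds <- demo_dataset()
  genes <- program_genes(ds$truth, "T1", "up")
  a <- module_score(sce, genes, seed = 10)
  b <- module_score(sce, genes, seed = 10)
  c <- module_score(sce, genes, seed = 11)
  expect_identical(a$score, b$score)
  expect_lt(mean(abs(a$score - c$score)), 0.05)  # control draw noise only
  expect_error(module_score(sce, c("absent1", "absent2")), "no genes")
  expect_warning(module_score(sce, c(genes, "absent1"), seed = 1), "absent")
})

test_that("planted inflammatory-style programs order the groups Aiso > Ahet > Yiso", {
  ds <- generate_dataset(generator_params(seed = 19, prop_up = 1,
                                          rescue_magnitude = 0.5))
  sce <- normalize_counts(qc_filter(ds$sce))
  sub <- sce[, SummarizedExperiment::colData(sce)$cell_type == "T1"]
  sc <- module_score(sub, program_genes(ds$truth, "T1", "up"), seed = 1)
  m <- tapply(sc$score, SummarizedExperiment::colData(sub)$group, mean)
  expect_gt(m[["Aiso"]], m[["Ahet"]])
  expect_gt(m[["Ahet"]], m[["Yiso"]])
})

test_that("rank-AUC score hits its extremes and ignores monotone transforms", {
  G <- 200
  m <- matrix(0, nrow = G, ncol = 2,
              dimnames = list(sprintf("g%03d", 1:G), c("c1", "c2")))
  m[1:10, 1] <- 100:91          # set occupies the top ranks in c1
  m[101:110, 2] <- 50           # set far below the top fraction in c2...
  sce <- tiny_sce(m)
  top_set <- sprintf("g%03d", 1:10)
  sc <- auc_score(sce, top_set, top_fraction = 0.05)   # top 10 ranks
  expect_equal(unname(sc$score[["c1"]]), 1)
  low_set <- sprintf("g%03d", 150:159)                 # all-zero in both cells
  # zero-expression genes rank below the expressed ones; with 10 expressed
  # genes in c2 occupying the top 10, the low set cannot enter the top ranks
  sc2 <- auc_score(sce, low_set, top_fraction = 0.05)
  expect_equal(unname(sc2$score[["c2"]]), 0)

  ds <- generate_dataset(generator_params(n_cell_types = 1,
                                          cells_per_group_per_type = 10,
                                          n_genes = 300, seed = 12))
  sce <- normalize_counts(ds$sce)
  genes <- program_genes(ds$truth, "T1")[1:20]
  s1 <- auc_score(sce, genes)
  mono <- sce
  SingleCellExperiment::logcounts(mono) <-
    methods::as(sqrt(as.matrix(SummarizedExperiment::assay(sce, "logcounts"))),
                "CsparseMatrix")
  s2 <- auc_score(mono, genes)
  expect_equal(s1$score, s2$score)
  expect_error(auc_score(sce, genes, top_fraction = 0), "top_fraction")
})

test_that("rank-AUC of a random set matches its null expectation", {
  set.seed(33)
  G <- 400; ncell <- 1000
  m <- matrix(stats::runif(G * ncell), nrow = G,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("c%04d", 1:ncell)))
  sce <- tiny_sce(m, normalize = FALSE)
  SingleCellExperiment::logcounts(sce) <- methods::as(m, "CsparseMatrix")
  S <- 25
  genes <- sample(rownames(m), S)
  sc <- auc_score(sce, genes, top_fraction = 0.1)
  top <- ceiling(0.1 * G)
  # under a uniform random ranking E[hits at rank k] = k S / G
  exp_auc <- (S / G) * top * (top + 1) / 2
  max_auc <- sum(pmin(seq_len(top), min(S, top)))
  expected <- exp_auc / max_auc
  se <- stats::sd(sc$score) / sqrt(ncell)
  expect_lt(abs(mean(sc$score) - expected), 3 * se + 1e-3)
})

test_that("score comparisons use the rank-sum test with BH across pairs", {
  ds <- demo_dataset()
  sce <- demo_norm()
  sub <- sce[, SummarizedExperiment::colData(sce)$cell_type == "T2"]
  sc <- module_score(sub, program_genes(ds$truth, "T2", "up"), seed = 2)
  cmp <- compare_scores(sc, sub, list(c("Aiso", "Yiso"), c("Ahet", "Aiso"),
                                      c("Yhet", "Yiso")))
  expect_equal(cmp$p_adjusted, bh_adjust(cmp$p_value))
  expect_lt(cmp$p_adjusted[cmp$case == "Aiso"], 0.05)  # planted separation
  expect_gt(cmp$delta_mean[cmp$case == "Aiso"], 0)

  # identical (constant) score vectors in both groups -> p = 1
  const <- sc; const$score[] <- 1
  expect_equal(compare_scores(const, sub,
                              list(c("Aiso", "Yiso")))$p_value, 1)
  expect_error(compare_scores(sc, sub, list(c("Aiso", "Nope"))), "Nope")
})

test_that("null group means of module scores stay near zero", {
  ds <- null_dataset(generator_params(n_cell_types = 1,
                                      cells_per_group_per_type = 100,
                                      n_genes = 400, seed = 14))
  sce <- normalize_counts(ds$sce)
  set.seed(2)
  genes <- sample(rownames(sce), 25)
  sc <- module_score(sce, genes, seed = 5)
  grp <- SummarizedExperiment::colData(sce)$group
  centered <- sc$score - mean(sc$score)  # remove the fixed control-draw offset
  for (g in unique(grp)) {
    v <- centered[grp == g]
    expect_lt(abs(mean(v)), 3 * stats::sd(v) / sqrt(length(v)))
  }
})
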