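test_that("the generator is deterministic and leaves user RNG untouched", {
  p <- generator_params(n_cell_types = 2, cells_per_group_per_type = 20,
                        n_genes = 300, markers_per_type = 10,
                        program_size = 30, seed = 9)
  set.seed(123); before <- runif(1)
  ds1 <- generate_dataset(p)
  ds2 <- generate_dataset(p)
  expect_identical(as.matrix(SummarizedExperiment::assay(ds1$sce, "counts")),
                   as.matrix(SummarizedExperiment::assay(ds2$sce, "counts")))
  expect_identical(ds1$annotation, ds2$annotation)
  expect_identical(ds1$truth$genes, ds2$truth$genes)
  set.seed(123)
  expect_identical(runif(1), before)  # generator restored the RNG stream
})

test_that("planted ground truth obeys its structural invariants", {
  ds <- demo_dataset()
  tg <- ds$truth$genes
  p <- ds$truth$params

  # rescue rule: Ahet effect is minus rescue_magnitude x aging effect on
  # rescued genes and exactly 0 elsewhere; symmetric rule for Yhet
  expect_equal(tg$ahet_effect[tg$rescued],
               -p$rescue_magnitude * tg$aging_effect[tg$rescued])
  expect_true(all(tg$ahet_effect[!tg$rescued] == 0))
  expect_equal(tg$yhet_effect[tg$accelerated],
               p$accel_magnitude * tg$aging_effect[tg$accelerated])
  expect_true(all(tg$yhet_effect[!tg$accelerated] == 0))

  # aging programs disjoint from markers, per cell type
  for (tp in unique(tg$cell_type)) {
    sub <- tg[tg$cell_type == tp, ]
    expect_length(intersect(sub$gene[sub$membership == "marker"],
                            sub$gene[sub$membership == "aging"]), 0)
    expect_equal(sum(sub$membership == "aging"), p$program_size)
  }

  # hub gene planted and rescued in exactly hub_n_types programs
  hub_rows <- tg[tg$gene == ds$truth$hub$gene & tg$membership == "aging", ]
  expect_equal(nrow(hub_rows), p$hub_n_types)
  expect_true(all(hub_rows$rescued))

  # counts are non-negative integers with no duplicate ids
  cm <- SummarizedExperiment::assay(ds$sce, "counts")
  expect_true(all(cm@x >= 0), all(cm@x == floor(cm@x)))
  expect_false(anyDuplicated(rownames(ds$sce)) > 0)
  expect_false(anyDuplicated(colnames(ds$sce)) > 0)
})

test_that("null datasets are flat: background truth, no hub, calibrated groups", {
  p <- generator_params(n_cell_types = 1, cells_per_group_per_type = 500,
                        n_genes = 400, seed = 5)
  ds <- null_dataset(p)
  expect_true(all(ds$truth$genes$membership == "background"))
  expect_true(all(ds$truth$genes$aging_effect == 0))
  expect_length(ds$truth$hub$cell_types, 0)

  # common-depth normalization so the per-gene fold change (package
  # pseudocount convention) is on the count scale
  sce <- normalize_counts(ds$sce, scale = p$mean_libsize)
  ln <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  grp <- SummarizedExperiment::colData(sce)$group
  lr <- vapply(seq_len(nrow(ln)), function(i) {
    log2_fold_change(ln[i, grp == "Aiso"], ln[i, grp == "Yiso"])
  }, numeric(1))
  expect_gte(mean(abs(lr) < 0.1), 0.95)

  # overdispersion: variance clearly exceeds the Poisson variance for
  # well-expressed genes
  cm <- as.matrix(SummarizedExperiment::assay(ds$sce, "counts"))
  mu <- rowMeans(cm); v <- apply(cm, 1, var)
  hi <- mu > 1
  expect_gt(mean(v[hi] > mu[hi]), 0.95)
})

test_that("empirical group log2 ratios converge to the planted effects", {
  lr_err <- vapply(c(60, 240), function(n_per) {
    ds <- generate_dataset(generator_params(
      n_cell_types = 1, cells_per_group_per_type = n_per, n_genes = 400,
      rescue_fraction = 1, seed = 11))
    sce <- normalize_counts(ds$sce)
    ln <- SummarizedExperiment::assay(sce, "logcounts")
    grp <- SummarizedExperiment::colData(sce)$group
    tg <- ds$truth$genes
    prog <- tg[tg$membership == "aging", ]
    a <- rowMeans(expm1(as.matrix(ln[prog$gene, grp == "Aiso"])))
    y <- rowMeans(expm1(as.matrix(ln[prog$gene, grp == "Yiso"])))
    mean(abs(log2(a / y) - prog$aging_effect))
  }, numeric(1))
  expect_lt(lr_err[2], lr_err[1])   # error shrinks with more cells
  expect_lt(lr_err[2], 0.2)
})

test_that("a planted effect of +1 with full rescue reproduces +1 / -1 ratios", {
  ds <- generate_dataset(generator_params(
    n_cell_types = 1, cells_per_group_per_type = 500, n_genes = 300,
    rescue_fraction = 1, rescue_magnitude = 1, seed = 2))
  sce <- normalize_counts(ds$sce)
  ln <- SummarizedExperiment::assay(sce, "logcounts")
  grp <- SummarizedExperiment::colData(sce)$group
  prog <- program_genes(ds$truth, "T1", "up")   # planted +1, all rescued
  gm <- function(g) rowMeans(expm1(as.matrix(ln[prog, grp == g, drop = FALSE])))
  aged_ratio <- mean(log2(gm("Aiso") / gm("Yiso")))
  resc_ratio <- mean(log2(gm("Ahet") / gm("Aiso")))
  expect_equal(aged_ratio, 1, tolerance = 0.2)
  expect_equal(resc_ratio, -1, tolerance = 0.2)
})

test_that("invalid generator parameters are rejected", {
  expect_error(generator_params(rescue_fraction = 1.2), "\\[0, 1\\]")
  expect_error(generator_params(dispersion = 0), "positive")
  expect_error(generator_params(hub_n_types = 5, n_cell_types = 3), "hub_n_types")
  expect_error(generate_dataset(generator_params(n_genes = 120,
                                                 markers_per_type = 30)),
               "pool too small")
})
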