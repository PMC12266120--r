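test_that("collection overlap keeps exact provenance and matches brute force", {
  c1 <- gene_set_collection("dbA", list(s1 = c("a", "b"), s2 = c("b", "c")))
  c2 <- gene_set_collection("dbB", list(s3 = c("c", "d")))
  ov <- overlap_with_collections(c("a", "b", "c", "z"), list(c1, c2))
  expect_setequal(unique(ov$gene), c("a", "b", "c"))
  expect_setequal(ov$collection[ov$gene == "c"], c("dbA", "dbB"))
  expect_equal(sum(ov$gene == "b"), 2L)   # both sets of dbA

  expect_equal(nrow(overlap_with_collections("zz", c1)), 0L)
  expect_warning(overlap_with_collections(character(0), c1), "empty query")

  # brute-force double-loop oracle on random sets
  set.seed(9)
  universe <- paste0("g", 1:200)
  cols <- lapply(1:5, function(i) {
    sets <- lapply(1:10, function(j) sample(universe, sample(3:15, 1)))
    names(sets) <- paste0("set", 1:10)
    gene_set_collection(paste0("db", i), sets)
  })
  query <- sample(universe, 40)
  ov <- overlap_with_collections(query, cols)
  brute <- list()
  for (col in cols) for (nm in names(col$sets)) for (g in query) {
    if (g %in% col$sets[[nm]]$genes) {
      brute[[length(brute) + 1]] <- c(g, col$name, nm)
    }
  }
  brute <- do.call(rbind, brute)
  expect_equal(nrow(ov), nrow(brute))
  expect_setequal(paste(ov$gene, ov$collection, ov$set),
                  paste(brute[, 1], brute[, 2], brute[, 3]))
})

test_that("frequency ranking counts distinct cell types with deterministic ties", {
  mk <- function(gene, ct, contrast, lfc) {
    data.frame(gene = gene, cell_type = ct, contrast = contrast, log2fc = lfc,
               p_value = 0.001, p_adjusted = 0.01,
               direction = ifelse(lfc > 0, "up", "down"),
               stringsAsFactors = FALSE)
  }
  degs <- rbind(
    mk("hub", paste0("T", 1:5), "Aged", 1),        # 5 cell types
    mk("hub", "T1", "Ahet", -1),                   # same type again: counts once
    mk("g1", c("T1", "T2"), "Aged", 0.6),
    mk("g2", c("T1", "T2"), "Aged", 0.4),          # tie on frequency with g1
    mk("g3", "T1", "Yhet", 2))                     # out of default scope
  tab <- frequency_rank(c("hub", "g1", "g2", "g3"), degs)
  expect_equal(tab$gene, c("hub", "g1", "g2"))     # g3 has no in-scope record
  expect_equal(tab$n_cell_types, c(5L, 2L, 2L))
  expect_gt(tab$tie_break_score[2], tab$tie_break_score[3])  # 1.2 vs 0.8
  expect_equal(frequency_rank("g3", degs, contrasts = "Yhet")$n_cell_types, 1L)

  # brute-force frequency oracle on random inputs
  set.seed(17)
  for (i in 1:20) {
    genes <- paste0("g", 1:15)
    degs <- mk(sample(genes, 60, replace = TRUE),
               sample(paste0("T", 1:6), 60, replace = TRUE),
               sample(c("Aged", "Ahet"), 60, replace = TRUE),
               stats::rnorm(60) + 0.1)
    degs <- degs[!duplicated(degs[c("gene", "cell_type", "contrast")]), ]
    tab <- frequency_rank(genes, degs)
    for (r in seq_len(nrow(tab))) {
      g <- tab$gene[r]
      cnt <- 0L
      for (tp in unique(degs$cell_type)) {
        hit <- any(degs$gene == g & degs$cell_type == tp)
        if (hit) cnt <- cnt + 1L
      }
      expect_equal(tab$n_cell_types[r], cnt)
    }
  }
})

test_that("hypergeometric enrichment is exact and agrees with two references", {
  h <- hypergeom_enrich(paste0("q", 1:4),
                        annotation_set = paste0("q", c(1:3, 5, 7)),
                        universe = paste0("q", 1:10))
  expect_equal(h$overlap_count, 3L)
  expect_equal(h$p_value, 55 / 210, tolerance = 1e-12)

  # overlap 0 -> p = 1; query == annotation == universe -> p = 1
  expect_equal(hypergeom_enrich("a", "b", c("a", "b"))$p_value, 1)
  expect_equal(hypergeom_enrich(letters[1:5], letters[1:5],
                                letters[1:5])$p_value, 1)
  expect_error(hypergeom_enrich(c("a", "zz"), "a", letters[1:5]), "zz")

  set.seed(3)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    universe <- paste0("u", seq_len(N))
    K <- sample.int(N, 1); n <- sample.int(N, 1)
    ann <- sample(universe, K); query <- sample(universe, n)
    h <- hypergeom_enrich(query, ann, universe)
    k <- h$overlap_count
    expect_equal(h$p_value,
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
    ft <- stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                             alternative = "greater")
    expect_equal(h$p_value, ft$p.value, tolerance = 1e-10)
  }
})

test_that("the planted hub gene tops the candidate table", {
  ds <- demo_dataset()
  sce <- demo_norm()
  degs <- find_degs_all(sce, cell_types = c("T1", "T2", "T3"),
                        contrasts = c("Aged", "Ahet"))
  pr <- unlist(lapply(c("T1", "T2", "T3"), function(tp) {
    classify_rescued(degs[degs$cell_type == tp & degs$contrast == "Aged", ],
                     degs[degs$cell_type == tp & degs$contrast == "Ahet", ])$gene
  }))
  coll <- synthetic_aging_collection(ds$truth, seed = 1)
  cand <- frequency_rank(overlap_with_collections(unique(pr), coll), degs)
  expect_equal(cand$gene[1], ds$truth$hub$gene)
  expect_equal(cand$n_cell_types[1], length(ds$truth$hub$cell_types))
  expect_match(cand$collections_hit[1], "synthetic_aging_db")
})
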