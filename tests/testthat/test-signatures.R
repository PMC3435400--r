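fake_records <- function(probe_id, z_diff, called, target_id = NULL) {
  df <- data.frame(probe_id = probe_id, z_diff = z_diff, called = called,
                   stringsAsFactors = FALSE)
  if (!is.null(target_id)) df$target_id <- target_id
  df
}

test_that("signatures collect called probes with their directions and genes", {
  rec <- fake_records(paste0("p", 1:5), c(2.5, -3, 0.5, 2.2, -2.8),
                      c(TRUE, TRUE, FALSE, TRUE, FALSE),
                      target_id = c("KRT5_P23_F", "CD2_E10_R", "A_P1_F",
                                    "STAT5A_E42_F", "B_P2_R"))
  sig <- build_signature(rec, "celltype")
  expect_equal(sig$cpg_ids, c("p1", "p2", "p4"))
  expect_equal(unname(sig$direction_of),
               c("more_methylated", "less_methylated", "more_methylated"))
  expect_setequal(sig$genes, c("KRT5", "CD2", "STAT5A"))
  expect_equal(length(sig), 3L)

  empty <- build_signature(fake_records("p1", 2, FALSE), "none")
  expect_equal(length(empty), 0L)

  one <- build_signature(fake_records("p1", 2.5, TRUE), "one")
  expect_equal(unname(one$direction_of), "more_methylated")
})

test_that("relaxed thresholds recover the full probe universe as a signature", {
  set.seed(61)
  V <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(sprintf("p%02d", 1:30), sprintf("s%02d", 1:8)))
  res <- call_differential(V, rep(c("a", "b"), each = 4), q_threshold = 1,
                           d_threshold = 0)
  sig <- build_signature(res, "all")
  expect_setequal(sig$cpg_ids, rownames(V))
})

test_that("Venn decomposition matches hand enumeration", {
  v <- venn_decompose(list(h = c("a", "b", "c"), at = c("b", "c", "d"),
                           as = c("c", "e")))
  expect_equal(v$core, "c")
  expect_equal(v$unique_per_name, list(h = "a", at = "d", as = "e"))
  expect_equal(v$pairwise_only[["h&at"]], "b")
  expect_equal(v$pairwise_only[["h&as"]], character())
  expect_equal(v$counts$size, c(3L, 3L, 2L))

  # identical sets: everything is core
  v2 <- venn_decompose(list(a = letters[1:5], b = letters[1:5],
                            c = letters[1:5]))
  expect_equal(sort(v2$core), letters[1:5])
  expect_equal(unname(v2$counts$unique), c(0L, 0L, 0L))

  # pairwise-disjoint sets: no core, all unique
  v3 <- venn_decompose(list(a = letters[1:3], b = letters[4:6],
                            c = letters[7:8]))
  expect_equal(v3$core, character())
  expect_equal(unname(v3$counts$unique), c(3L, 3L, 2L))
})

test_that("Venn counts always partition each set", {
  set.seed(62)
  for (i in 1:20) {
    sets <- lapply(1:3, function(k) sample(letters, sample(0:15, 1)))
    names(sets) <- c("x", "y", "z")
    v <- venn_decompose(sets)
    expect_equal(v$counts$size,
                 v$counts$core + v$counts$pairwise + v$counts$unique)
  }
})

test_that("enrichment p-values are exact hypergeometric right tails", {
  ref <- paste0("g", 1:10)
  ann <- data.frame(gene = paste0("g", 1:5), function_label = "f1")
  # all five signature genes annotated: p = 1 / C(10, 5)
  res <- fisher_enrichment(paste0("g", 1:5), ann, ref)
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)

  # no overlap: P(X >= 0) = 1
  res0 <- fisher_enrichment(paste0("g", 6:10), ann, ref)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$k_in, 0L)

  # every reference gene annotated: overlap is certain, p = 1
  ann_all <- data.frame(gene = ref, function_label = "f")
  expect_equal(fisher_enrichment(paste0("g", 1:3), ann_all, ref)$p_value, 1)
})

test_that("enrichment matches a brute-force combinatorial sum on small universes", {
  brute_tail <- function(k, K, N, n) {
    kk <- k:min(K, n)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
  }
  set.seed(63)
  for (i in 1:20) {
    N <- sample(5:30, 1)
    ref <- paste0("g", seq_len(N))
    K <- sample(1:N, 1)
    ann <- data.frame(gene = sample(ref, K), function_label = "f")
    n <- sample(1:N, 1)
    sig <- sample(ref, n)
    res <- fisher_enrichment(sig, ann, ref)
    k <- length(intersect(sig, ann$gene))
    expect_equal(res$p_value, brute_tail(k, K, N, n), tolerance = 1e-10)
  }
})

test_that("enrichment validates its inputs and sorts by p", {
  ref <- paste0("g", 1:20)
  ann <- data.frame(gene = rep(ref[1:10], 2),
                    function_label = rep(c("f1", "f2"), each = 10))
  expect_error(fisher_enrichment("not_in_ref", ann, ref), "subset")
  expect_error(fisher_enrichment("g1", ann, character()), "empty reference")
  res <- fisher_enrichment(ref[1:6], ann, ref, adjust = TRUE)
  expect_false(is.unsorted(res$p_value))
  expect_equal(res$p_adjusted,
               stats::p.adjust(res$p_value, method = "BH"))
})

test_that("heatmap export restricts and orders by cell type then phenotype", {
  sim <- simulate_dataset(sim_config(n_probes = 30, n_x_probes = 2,
                                     n_snp_probes = 2,
                                     n_celltype_diff_probes = 3,
                                     n_phenotype_diff_probes = 0, seed = 64))
  z <- zscore_standardize(compute_m_values(sim$dataset))
  sig <- build_signature(
    fake_records(sim$truth$probe_id, 1, TRUE), "ct")
  hm <- signature_heatmap_matrix(z, sig, sim$dataset$samples)
  expect_equal(nrow(hm), 3L)
  ct <- sim$dataset$samples$cell_type[match(colnames(hm),
                                            sim$dataset$samples$sample_id)]
  expect_false(is.unsorted(ct))            # AEC block before PBMC block
})
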