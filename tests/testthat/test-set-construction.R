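toy_truth <- function(n_causal = 4, snps_per = 2, maf = 0.01, beta = 1) {
  genes <- sprintf("C%02d", seq_len(n_causal))
  truth_model(tibble::tibble(
    variant_id = sprintf("cv%03d", seq_len(n_causal * snps_per)),
    gene = rep(genes, each = snps_per),
    maf = maf, beta = beta))
}

fake_gene_results <- function(genes, n_rep, sig_joint = integer(0),
                              sig_ws_only = integer(0), alpha = 0.05) {
  # p-values above alpha everywhere except planted significant replicates
  purrr::map_dfr(seq_along(genes), function(i) {
    ws <- rep(0.5, n_rep); cmc <- rep(0.5, n_rep)
    k <- if (length(sig_joint) >= i) sig_joint[i] else 0L
    if (k > 0) { ws[seq_len(k)] <- 0.01; cmc[seq_len(k)] <- 0.01 }
    kw <- if (length(sig_ws_only) >= i) sig_ws_only[i] else 0L
    if (kw > 0) ws[seq_len(kw)] <- 0.01
    tibble::tibble(unit_id = genes[i],
                   method = rep(c("WS", "CMC"), each = n_rep),
                   replicate = rep(seq_len(n_rep), 2),
                   p_value = c(ws, cmc))
  })
}

test_that("the spurious rule is a strict joint count threshold", {
  truth <- toy_truth()
  genes <- c(truth$causal_genes, sprintf("N%02d", 1:5))
  # N01: 16 joint-significant replicates (> 15 -> spurious)
  # N02: exactly 15 (not spurious, strict inequality)
  # N03: 30 WS-only significant, 0 CMC (not spurious under the joint rule)
  res <- fake_gene_results(genes, 200,
                           sig_joint = c(rep(0L, 4), 16L, 15L, 0L, 0L, 0L),
                           sig_ws_only = c(rep(0L, 6), 30L, 0L, 0L))
  sp <- detect_spurious(res, truth, alpha = 0.05, count_threshold = 15,
                        n_replicates = 200)
  expect_equal(sp, "N01")
  # marginal mode flags genes whose per-method counts each exceed the bound
  sp_m <- detect_spurious(res, truth, mode = "marginal",
                          n_replicates = 200)
  expect_equal(sp_m, "N01")
})

test_that("detect_spurious never returns a causal gene and validates coverage", {
  truth <- toy_truth()
  genes <- c(truth$causal_genes, "N01")
  res <- fake_gene_results(genes, 50, sig_joint = rep(50L, 5))
  sp <- detect_spurious(res, truth, n_replicates = 50, count_threshold = 3)
  expect_false(any(sp %in% truth$causal_genes))
  expect_equal(sp, "N01")
  expect_error(detect_spurious(res[res$method == "WS", ], truth,
                               n_replicates = 50),
               class = "rvpath_validation_error")
  expect_error(detect_spurious(res[res$replicate != 3 | res$unit_id != "N01", ],
                               truth, n_replicates = 50),
               class = "rvpath_validation_error")
})

test_that("build_sets produces the requested design with exact category counts", {
  truth <- toy_truth(n_causal = 30)
  all_genes <- c(truth$causal_genes, sprintf("N%03d", 1:120))
  nonspur <- setdiff(setdiff(all_genes, truth$causal_genes),
                     sprintf("N%03d", 1:10))
  sets <- build_sets(truth, all_genes, nonspurious_genes = nonspur,
                     set_size = 25, causal_counts = c(5, 10, 15, 20, 25),
                     sets_per_count = 10, n_null_sets = 50, seed = 3)
  expect_equal(nrow(sets), 50 + 50 + 50 + 50)
  expect_equal(as.integer(table(sets$category)[c("causal_mix", "null",
                                                 "null_nonspurious",
                                                 "causal_mix_nonspurious")]),
               c(50L, 50L, 50L, 50L))
  expect_true(all(lengths(sets$genes) == 25))
  # category-1/4 sets contain exactly their labeled C causal genes
  for (i in which(sets$category %in% c("causal_mix",
                                       "causal_mix_nonspurious"))) {
    C <- as.integer(sub(".*_C(\\d+)_.*", "\\1", sets$set_id[i]))
    expect_equal(sum(sets$genes[[i]] %in% truth$causal_genes), C)
  }
  # null sets have no causal genes; nonspurious sets avoid spurious genes
  for (i in which(sets$category == "null")) {
    expect_equal(sum(sets$genes[[i]] %in% truth$causal_genes), 0)
  }
  for (i in which(sets$category == "null_nonspurious")) {
    expect_false(any(sets$genes[[i]] %in% sprintf("N%03d", 1:10)))
  }
  # category 4 reuses the category-1 causal draws
  c1 <- sets[sets$category == "causal_mix", ]
  c4 <- sets[sets$category == "causal_mix_nonspurious", ]
  for (i in seq_len(nrow(c1))) {
    expect_setequal(intersect(c1$genes[[i]], truth$causal_genes),
                    intersect(c4$genes[[i]], truth$causal_genes))
    expect_false(any(c4$genes[[i]] %in% sprintf("N%03d", 1:10)))
  }
  # no duplicates within any set
  expect_true(all(vapply(sets$genes, anyDuplicated, 0L) == 0L))
})

test_that("build_sets is deterministic per seed and errors on small pools", {
  truth <- toy_truth(n_causal = 26)
  all_genes <- c(truth$causal_genes, sprintf("N%03d", 1:60))
  s1 <- build_sets(truth, all_genes, sets_per_count = 3, n_null_sets = 5,
                   seed = 11)
  s2 <- build_sets(truth, all_genes, sets_per_count = 3, n_null_sets = 5,
                   seed = 11)
  expect_identical(s1$genes, s2$genes)
  s3 <- build_sets(truth, all_genes, sets_per_count = 3, n_null_sets = 5,
                   seed = 12)
  expect_false(identical(s1$genes, s3$genes))
  expect_error(build_sets(truth, c(truth$causal_genes, "N1", "N2")),
               class = "rvpath_validation_error")
  expect_error(build_sets(toy_truth(n_causal = 3), all_genes),
               class = "rvpath_validation_error")
})

test_that("set features implement the five explanatory variables", {
  truth <- truth_model(tibble::tibble(
    variant_id = c("s1", "s2", "s3"),
    gene = c("C1", "C1", "C2"),
    maf = c(0.01, 0.02, 0.005),
    beta = c(2.0, 0.0, 1.0)))
  gene_map <- tibble::tibble(
    variant_id = c("s1", "s2", "s3", "n1", "n2", "n3"),
    gene = c("C1", "C1", "C2", "N1", "N1", "N2"))
  sets <- gene_sets(c("mix", "null"),
                    list(c("C1", "C2", "N1"), c("N1", "N2")),
                    category = c("causal_mix", "null"))
  f <- set_features(sets, truth, gene_map)
  mix <- f[f$set_id == "mix", ]
  expect_equal(mix$n_causal_genes, 2)
  expect_equal(mix$n_causal_snps, 3)
  expect_equal(mix$n_total_snps, 5)
  # causal-SNP MAFs summed within gene (C1: 0.03, C2: 0.005), then averaged
  expect_equal(mix$avg_maf_causal_genes, mean(c(0.03, 0.005)))
  expect_equal(mix$weighted_risk_score,
               0.01 * 2.0 + 0.02 * 0.0 + 0.005 * 1.0)
  nul <- f[f$set_id == "null", ]
  expect_equal(nul$n_causal_genes, 0)
  expect_equal(nul$n_causal_snps, 0)
  expect_equal(nul$weighted_risk_score, 0)
  expect_equal(nul$avg_maf_causal_genes, 0)
})

test_that("the weighted risk score is additive over disjoint causal-SNP unions", {
  truth <- toy_truth(n_causal = 6, snps_per = 2, maf = 0.02, beta = 1.5)
  gene_map <- tibble::tibble(variant_id = truth$causal_snps$variant_id,
                             gene = truth$causal_snps$gene)
  sA <- gene_sets("A", list(truth$causal_genes[1:2]), "causal_mix")
  sB <- gene_sets("B", list(truth$causal_genes[3:6]), "causal_mix")
  sAB <- gene_sets("AB", list(truth$causal_genes[1:6]), "causal_mix")
  w <- function(s) set_features(s, truth, gene_map)$weighted_risk_score
  expect_equal(w(sAB), w(sA) + w(sB), tolerance = 1e-12)
})

test_that("truth models validate and round-trip through TSV", {
  expect_error(truth_model(tibble::tibble(variant_id = "v", gene = "G",
                                          maf = 0.1, beta = Inf)),
               class = "rvpath_validation_error")
  tr <- toy_truth()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(tr, path)
  back <- read_truth(path)
  expect_equal(back$causal_snps, tr$causal_snps)
  expect_equal(back$causal_genes, tr$causal_genes)
})
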