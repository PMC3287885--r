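test_that("Fisher's method matches the closed-form even-df chi-square tail", {
  r <- fisher_combined(rep(0.05, 25))
  expect_equal(r$statistic, -50 * log(0.05), tolerance = 1e-12)
  expect_equal(r$p_value, oracle_chisq_sf_even(-50 * log(0.05), 50),
               tolerance = 1e-10)
  # boundary and k = 1 identity
  expect_equal(fisher_combined(c(1, 1, 1))$statistic, 0)
  expect_equal(fisher_combined(c(1, 1, 1))$p_value, 1)
  expect_equal(fisher_combined(0.5)$statistic, -2 * log(0.5),
               tolerance = 1e-12)
  expect_equal(fisher_combined(0.5)$p_value, 0.5, tolerance = 1e-12)
  withr::with_seed(3, {
    for (i in 1:20) {
      p <- runif(sample(1:8, 1))
      expect_equal(fisher_combined(p)$p_value,
                   oracle_chisq_sf_even(-2 * sum(log(p)), 2 * length(p)),
                   tolerance = 1e-9)
    }
  })
})

test_that("Fisher's statistic is additive over disjoint p-value lists and rejects bad input", {
  withr::with_seed(11, {
    a <- runif(5); b <- runif(7)
    expect_equal(fisher_combined(c(a, b))$statistic,
                 fisher_combined(a)$statistic + fisher_combined(b)$statistic,
                 tolerance = 1e-12)
  })
  expect_error(fisher_combined(numeric(0)), class = "rvpath_validation_error")
  expect_error(fisher_combined(c(0.5, 0)), class = "rvpath_validation_error")
})

test_that("Fisher p-values are uniform under uniform inputs", {
  p <- withr::with_seed(19, {
    vapply(seq_len(10000), function(i) {
      fisher_combined(runif(10))$p_value
    }, 0)
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("adding a p = 1 gene never increases Fisher significance", {
  withr::with_seed(7, {
    for (i in 1:10) {
      p <- runif(sample(2:20, 1))
      expect_gte(fisher_combined(c(p, 1))$p_value,
                 fisher_combined(p)$p_value - 1e-15)
    }
  })
})

make_profile <- function(scores, genes = sprintf("g%03d", seq_along(scores))) {
  out <- tibble::tibble(gene = genes, p_value = exp(-scores), score = scores)
  class(out) <- c("gene_profile", class(out))
  out
}

test_that("KS set test agrees with stats::ks.test and handles the boundary cases", {
  withr::with_seed(23, {
    prof <- make_profile(c(rexp(25, 1 / 2), rexp(275)))
    set <- prof$gene[1:25]
    r <- ks_set_test(prof, set)
    ref <- suppressWarnings(ks.test(prof$score[1:25], prof$score[-(1:25)]))
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-8)
    n_eff <- 25 * 275 / 300
    expect_equal(r$p_value,
                 suppressWarnings(ks.test(prof$score[1:25],
                                          prof$score[-(1:25)],
                                          exact = FALSE))$p.value,
                 tolerance = 1e-8)
  })
  # identical score multisets in and out of the set: D = 0, p = 1
  prof2 <- make_profile(rep(c(1, 2, 3, 4), 10))
  r2 <- ks_set_test(prof2, prof2$gene[1:4])
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  # complete separation: D = 1
  prof3 <- make_profile(c(rep(5, 10), rep(1, 30)))
  r3 <- ks_set_test(prof3, prof3$gene[1:10])
  expect_equal(r3$statistic, 1)
  expect_error(ks_set_test(prof3, prof3$gene),
               class = "rvpath_validation_error")
})

test_that("the enrichment score equals the exhaustive running-sum oracle", {
  withr::with_seed(31, {
    for (i in 1:200) {
      n <- sample(3:10, 1)
      k <- sample(1:(n - 1), 1)
      scores <- round(rexp(n, 1 / 3), 2)  # rounding induces ties
      genes <- sprintf("g%02d", sample(n))
      set <- sample(genes, k)
      w <- sample(c(0, 0.5, 1, 2), 1)
      prof <- make_profile(scores, genes)
      es <- suppressWarnings(gsea_enrichment_score(prof, set, w))
      expect_equal(es$es, oracle_es(genes, scores, set, w),
                   tolerance = 1e-12)
      expect_lte(abs(es$es), 1 + 1e-12)
    }
  })
})

test_that("ES is 1 when all in-set genes with positive scores lead the ranking", {
  prof <- make_profile(c(5, 4, 3, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05, 0.01))
  es <- gsea_enrichment_score(prof, prof$gene[1:3], weight_exponent = 1)
  expect_equal(es$es, 1, tolerance = 1e-12)
})

test_that("weight exponent 0 reduces to the unweighted KS running statistic on ranks", {
  withr::with_seed(37, {
    scores <- rexp(12)
    prof <- make_profile(scores)
    set <- prof$gene[c(2, 5, 7)]
    es0 <- gsea_enrichment_score(prof, set, weight_exponent = 0)
    # unweighted: hits contribute 1/|set| each
    expect_equal(es0$es, oracle_es(prof$gene, scores, set, 0),
                 tolerance = 1e-12)
    hit_steps <- es0$running - c(0, head(es0$running, -1))
    expect_true(all(abs(hit_steps[hit_steps > 0] - 1 / 3) < 1e-12))
  })
})

test_that("an all-zero profile yields uniform hit weights with a warning", {
  prof <- make_profile(rep(0, 8))
  expect_warning(es <- gsea_enrichment_score(prof, prof$gene[1:2]),
                 "uniform")
  expect_lte(abs(es$es), 1)
})

test_that("gene profiles transform p-values to -log p and score degenerate genes 0", {
  g <- toy_genotypes(n = 30, genes = c(A = 2, B = 2, C = 1), seed = 41)
  g$dosages[, 5] <- 0L  # gene C has no variation
  g <- rv_genotypes(g$dosages, individual_ids(g),
                    variant_info(g)$variant_id, gene = variant_info(g)$gene)
  y <- toy_phenotype(30, 12, seed = 4)
  expect_warning(prof <- gene_pvalue_profile(g, y, "CMC"), "no testable")
  expect_equal(prof$score[prof$gene == "C"], 0)
  ok <- !is.na(prof$p_value)
  expect_equal(prof$score[ok], -log(prof$p_value[ok]), tolerance = 1e-12)
  profw <- gene_pvalue_profile(g, y, "WS", n_permutations = 100, seed = 2)
  expect_true(all(is.finite(profw$score)))
  expect_true(all(profw$p_value >= 1 / 101))
})

test_that("a GSEA test on genotypes carrying no signal is conservative and degenerate data gives p = 1", {
  g <- toy_genotypes(n = 24, genes = c(A = 2, B = 2, C = 2, D = 2), seed = 43)
  g$dosages[] <- 0L
  g$dosages[1, c(1, 3, 5, 7)] <- 1L  # minimal variation, same individual
  g <- rv_genotypes(g$dosages, individual_ids(g),
                    variant_info(g)$variant_id, gene = variant_info(g)$gene)
  y <- toy_phenotype(24, 10, seed = 5)
  res <- gsea_test(g, y, c("A", "B"), method = "CMC", n_permutations = 30,
                   seed = 6)
  expect_gte(res$p_value, 1 / 31)
  # fully constant genotypes: every permuted profile identical -> p = 1
  g0 <- toy_genotypes(n = 24, genes = c(A = 2, B = 2), seed = 44)
  g0$dosages[] <- 0L
  g0$dosages[1:2, 1] <- 1L
  g0 <- rv_genotypes(g0$dosages, individual_ids(g0),
                     variant_info(g0)$variant_id, gene = variant_info(g0)$gene)
  res0 <- suppressWarnings(
    gsea_test(g0, y, "A", method = "WS", n_permutations = 20,
              inner_permutations = 20, seed = 7))
  expect_gte(res0$p_value, 1 / 21)
})

test_that("nested and shared-inner-null GSEA modes are both deterministic under a seed", {
  g <- toy_genotypes(n = 20, genes = c(A = 2, B = 2, C = 2), seed = 47)
  y <- toy_phenotype(20, 8, seed = 6)
  r1 <- gsea_test(g, y, "A", method = "WS", n_permutations = 10,
                  inner_permutations = 20, seed = 9)
  r2 <- gsea_test(g, y, "A", method = "WS", n_permutations = 10,
                  inner_permutations = 20, seed = 9)
  expect_identical(r1, r2)
  r3 <- gsea_test(g, y, "A", method = "WS", n_permutations = 10,
                  inner_permutations = 20, seed = 9, nested = TRUE)
  expect_equal(r3$statistic, r1$statistic, tolerance = 1e-12)
})

test_that("direct set tests pool SNPs: one-gene sets equal the gene-level tests", {
  g <- toy_genotypes(n = 30, genes = c(A = 3, B = 2), seed = 53)
  y <- toy_phenotype(30, 12, seed = 7)
  dws <- direct_set_test(g, y, "A", "WS", n_permutations = 100, seed = 3,
                         unit_id = "A")
  gws <- ws_test(g, y, gene_group(g, "A", label = "A"),
                 n_permutations = 100, seed = 3)
  expect_equal(dws$p_value, gws$p_value)
  expect_equal(dws$statistic, gws$statistic)
  dcmc <- direct_set_test(g, y, "A", "CMC", rare_threshold = 0.5,
                          unit_id = "A")
  gcmc <- cmc_test(g, y, gene_group(g, "A", label = "A"),
                   rare_threshold = 0.5)
  expect_equal(dcmc$p_value, gcmc$p_value, tolerance = 1e-12)
})

test_that("CMC set-vs-gene grouping changes the design dimension as expected", {
  dos <- cbind(c(1L, rep(0L, 19)), c(0L, 1L, rep(0L, 18)),
               c(rep(0L, 2), 1L, rep(0L, 17)), c(rep(0L, 3), 1L, rep(0L, 16)))
  g <- rv_genotypes(dos, sprintf("i%02d", 1:20), paste0("v", 1:4),
                    gene = c("A", "A", "B", "B"))
  d_gene <- cmc_design(g, gene_group(g, c("A", "B"), label = "S"),
                       grouping = "gene")
  d_set <- cmc_design(g, gene_group(g, c("A", "B"), label = "S"),
                      grouping = "set")
  expect_equal(ncol(d_gene$X), 2)
  expect_equal(ncol(d_set$X), 1)
})

test_that("set_test dispatches all eight methods and reuses profiles", {
  g <- toy_genotypes(n = 30, genes = c(A = 2, B = 2, C = 2, D = 2), seed = 59)
  y <- toy_phenotype(30, 12, seed = 8)
  prof <- gene_pvalue_profile(g, y, "CMC")
  for (m in RV_METHODS) {
    r <- set_test(g, y, c("A", "B"), method = m, profile =
                    if (m %in% c("CMC_Fisher", "CMC_KS")) prof else NULL,
                  n_permutations = 30, inner_permutations = 30, seed = 10,
                  unit_id = "S")
    expect_s3_class(r, "tbl_df")
    expect_equal(r$method, m)
    expect_true(r$p_value > 0 && r$p_value <= 1)
  }
  # supplied profile gives the same answer as a recomputed one
  r1 <- set_test(g, y, c("A", "B"), "CMC_Fisher", profile = prof)
  r2 <- set_test(g, y, c("A", "B"), "CMC_Fisher")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})
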