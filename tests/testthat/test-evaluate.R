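eval_fixture <- function(seed = 101, n_rep = 4) {
  cfg <- desk_profile(n_individuals = 80L, n_genes = 12L, snps_per_gene = 3,
                      n_causal_genes = 4L, n_causal_snps = 8L,
                      n_replicates = n_rep, seed = seed)
  st <- simulate_study(cfg)
  genes <- unique(st$gene_map$gene)
  noncausal <- setdiff(genes, st$truth$causal_genes)
  sets <- gene_sets(
    c("causal", "null"),
    list(c(st$truth$causal_genes[1:3], noncausal[1:2]), noncausal[1:5]),
    category = c("causal_mix", "null"))
  list(st = st, sets = sets)
}

test_that("evaluate_methods returns coherent rates, best calls and features", {
  fx <- eval_fixture()
  ev <- evaluate_methods(
    fx$st$genotypes, fx$st$phenotypes, fx$sets,
    params = eval_params(ws_permutations = 60, gsea_permutations = 20),
    truth = fx$st$truth, gene_map = fx$st$gene_map, seed = 5)
  expect_s3_class(ev, "rv_evaluation")
  expect_equal(sort(unique(ev$results$method)), sort(RV_METHODS))
  expect_equal(nrow(ev$results), 2 * 8 * 4)
  expect_true(all(ev$rates$rate >= 0 & ev$rates$rate <= 1))
  expect_true(all(ev$results$p_value > 0 & ev$results$p_value <= 1,
                  na.rm = TRUE))
  # best-method calls: argmax of significant-replicate counts, ties co-best
  counts <- dplyr::count(
    dplyr::filter(ev$best, .data$set_id == "causal", .data$is_best))
  expect_gte(counts$n, 1)
  by_set <- split(ev$best, ev$best$set_id)
  for (b in by_set) {
    expect_true(all(b$n_significant[b$is_best] == max(b$n_significant)))
  }
  expect_equal(nrow(ev$features), 2)
  expect_equal(ev$features$n_causal_genes[ev$features$set_id == "null"], 0)
  # tidy/glance accessors
  expect_identical(tidy(ev), ev$rates)
  expect_equal(glance(ev)$n_sets, 2)
})

test_that("the harness reproduces standalone test results for each method", {
  fx <- eval_fixture(seed = 103)
  st <- fx$st
  ev <- evaluate_methods(
    st$genotypes, st$phenotypes, fx$sets,
    methods = c("WS", "CMC", "CMC_Fisher", "CMC_KS"),
    params = eval_params(ws_permutations = 50), seed = 9)
  y <- phenotype_replicate(st$phenotypes, 2)
  # direct WS: same derived stream as ws_test with the set label
  ws_ref <- ws_test(st$genotypes, y,
                    gene_group(st$genotypes, fx$sets$genes[[1]],
                               label = "causal"),
                    n_permutations = 50, seed = 9, replicate = 2)
  got <- ev$results[ev$results$method == "WS" &
                      ev$results$set_id == "causal" &
                      ev$results$replicate == 2, ]
  expect_equal(got$p_value, ws_ref$p_value)
  # CMC_Fisher: recompute from a fresh gene profile
  prof <- gene_pvalue_profile(st$genotypes, y, "CMC", replicate = 2)
  fisher_ref <- fisher_combined(
    prof$p_value[prof$gene %in% fx$sets$genes[[2]] & !is.na(prof$p_value)],
    method = "CMC_Fisher")
  got_f <- ev$results[ev$results$method == "CMC_Fisher" &
                        ev$results$set_id == "null" &
                        ev$results$replicate == 2, ]
  expect_equal(got_f$p_value, fisher_ref$p_value, tolerance = 1e-12)
})

test_that("a supplied gene cache reproduces the internally computed evaluation", {
  fx <- eval_fixture(seed = 105)
  st <- fx$st
  params <- eval_params(ws_permutations = 40)
  cache <- gene_level_results(st$genotypes, st$phenotypes, params = params,
                              seed = 3)
  ev1 <- evaluate_methods(st$genotypes, st$phenotypes, fx$sets,
                          methods = c("WS_Fisher", "CMC_Fisher", "WS_KS"),
                          params = params, gene_cache = cache, seed = 3)
  ev2 <- evaluate_methods(st$genotypes, st$phenotypes, fx$sets,
                          methods = c("WS_Fisher", "CMC_Fisher", "WS_KS"),
                          params = params, seed = 3)
  expect_equal(ev1$results, ev2$results, tolerance = 1e-12)
})

test_that("vectorized enrichment scores equal the single-set implementation", {
  fx <- eval_fixture(seed = 107)
  st <- fx$st
  genes <- unique(st$gene_map$gene)
  withr::with_seed(8, {
    scores <- rexp(length(genes))
  })
  prof <- tibble::tibble(gene = genes, score = scores)
  membership <- vapply(fx$sets$genes, function(g) genes %in% g,
                       logical(length(genes)))
  es_vec <- rvpath:::es_for_sets(scores, genes, membership, 1)
  for (i in 1:2) {
    expect_equal(es_vec[i],
                 gsea_enrichment_score(prof, fx$sets$genes[[i]], 1)$es,
                 tolerance = 1e-12)
  }
})

test_that("power is 1 when every replicate is significant and the regression rejects constant outcomes", {
  rates <- tibble::tibble(set_id = "s", method = "WS", alpha = 0.05,
                          rate = 1, n_replicates = 10)
  expect_equal(rates$rate, 1)  # boundary by construction of mean(p <= a)
  feats <- tibble::tibble(ws_best = TRUE, n_causal_genes = 1:5,
                          n_causal_snps = 1:5, n_total_snps = 1:5,
                          avg_maf_causal_genes = 0.1,
                          weighted_risk_score = 0.1)
  expect_error(best_method_regression(feats),
               class = "rvpath_degenerate_error")
})

test_that("the best-method regression recovers planted coefficient signs", {
  n <- 500
  df <- withr::with_seed(13, {
    d <- tibble::tibble(
      n_causal_genes = sample(0:25, n, TRUE),
      n_causal_snps = sample(0:60, n, TRUE),
      n_total_snps = sample(40:120, n, TRUE),
      avg_maf_causal_genes = runif(n, 0, 0.1),
      weighted_risk_score = runif(n, 0, 0.6))
    eta <- -1 + 0.08 * d$n_causal_snps - 6 * d$weighted_risk_score
    d$ws_best <- rbinom(n, 1, plogis(eta)) == 1
    d
  })
  fit <- best_method_regression(df)
  td <- tidy(fit)
  expect_gt(td$estimate[td$term == "n_causal_snps"], 0)
  expect_lt(td$estimate[td$term == "weighted_risk_score"], 0)
  expect_lt(td$p.value[td$term == "n_causal_snps"], 0.01)
  expect_lt(td$p.value[td$term == "weighted_risk_score"], 0.01)
  expect_false(glance(fit)$separated)
})

test_that("separation is flagged and handled with a penalized fallback", {
  skip_if_not_installed("glmnet")
  n <- 80
  df <- withr::with_seed(17, {
    d <- tibble::tibble(
      n_causal_genes = sample(0:25, n, TRUE),
      n_causal_snps = sample(0:60, n, TRUE),
      n_total_snps = sample(40:120, n, TRUE),
      avg_maf_causal_genes = runif(n, 0, 0.1),
      weighted_risk_score = runif(n, 0, 0.6))
    d$ws_best <- d$n_causal_snps > 30  # perfectly separable
    d
  })
  expect_warning(fit <- best_method_regression(df), "separation")
  expect_true(glance(fit)$separated)
  expect_true(glance(fit)$penalized)
  td <- tidy(fit)
  expect_gt(td$estimate[td$term == "n_causal_snps"], 0)
})

test_that("power curves summarise rejection rates by causal-gene count", {
  fx <- eval_fixture(seed = 109)
  ev <- evaluate_methods(
    fx$st$genotypes, fx$st$phenotypes, fx$sets,
    methods = c("WS", "CMC_Fisher"),
    params = eval_params(ws_permutations = 40),
    truth = fx$st$truth, gene_map = fx$st$gene_map, seed = 4)
  pc <- power_by_causal_count(ev, alpha = 0.05)
  expect_setequal(unique(pc$n_causal_genes),
                  c(0, 3))
  plt <- plot_power_curve(ev)
  expect_s3_class(plt, "ggplot")
  expect_s3_class(autoplot(ev), "ggplot")
})
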