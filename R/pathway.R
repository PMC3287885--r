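# ---- internal fast kernels shared by gsea_test and evaluate_methods ----

# named list: gene -> integer vector of variant column indices
gene_index_list <- function(genotypes) {
  gene <- genotypes$variants$gene
  if (anyNA(gene)) {
    stop_rvpath("genotypes have no gene annotation; attach_gene_map() first.",
                "rvpath_validation_error")
  }
  split(seq_along(gene), gene)
}

# WS p-values for every gene under the observed labeling and, optionally,
# under each outer (permuted) labeling. One inner permutation null of size
# `n_inner` is drawn per gene and shared across the outer labelings:
# permutations of a permuted label vector are exactly permutations of the
# original, so the inner reference distribution is unchanged.
ws_profiles <- function(genotypes, phenotype, gene_idx, n_inner, seed,
                        replicate = 1L, outer_Y = NULL) {
  G <- genotypes$dosages
  n <- nrow(G)
  n_outer <- if (is.null(outer_Y)) 0L else ncol(outer_Y)
  p_obs <- numeric(length(gene_idx))
  p_outer <- if (n_outer) matrix(NA_real_, length(gene_idx), n_outer) else NULL
  names(p_obs) <- names(gene_idx)
  for (g in seq_along(gene_idx)) {
    idx <- gene_idx[[g]]
    Y_in <- with_seed(derive_seed(seed, "ws", names(gene_idx)[g], replicate),
                      .perm_matrix(phenotype, n_inner))
    Ycols <- cbind(phenotype, Y_in, outer_Y)
    x <- ws_kernel(G[, idx, drop = FALSE], Ycols)$x
    x_in <- x[2:(n_inner + 1)]
    p_obs[g] <- (1 + sum(x_in >= x[1] - 1e-12)) / (n_inner + 1)
    if (n_outer) {
      x_out <- x[(n_inner + 2):length(x)]
      p_outer[g, ] <- (1 + vapply(x_out, function(v) {
        sum(x_in >= v - 1e-12)
      }, 0)) / (n_inner + 1)
    }
  }
  list(p_obs = p_obs, p_outer = p_outer)
}

# CMC designs per gene, built once (they do not depend on the phenotype);
# genes whose design is entirely constant get NULL and are scored 0 later.
cmc_gene_designs <- function(genotypes, gene_idx, rare_threshold = 0.05) {
  lapply(seq_along(gene_idx), function(g) {
    d <- tryCatch(
      suppressWarnings(cmc_design(
        genotypes, variant_group(names(gene_idx)[g], gene_idx[[g]]),
        rare_threshold = rare_threshold, grouping = "gene")),
      rvpath_degenerate_error = function(e) NULL)
    if (is.null(d)) return(NULL)
    list(X = d$X, SS_tot = crossprod(d$X), cs_tot = colSums(d$X))
  })
}

# matrix of CMC p-values: genes x labelings (NA where the design is degenerate)
cmc_p_for_labels <- function(designs, Ycols) {
  K <- ncol(Ycols)
  out <- matrix(NA_real_, length(designs), K)
  for (g in seq_along(designs)) {
    d <- designs[[g]]
    if (is.null(d)) next
    for (k in seq_len(K)) {
      h <- hotelling_stat(d$X, Ycols[, k], SS_tot = d$SS_tot,
                          cs_tot = d$cs_tot, warn_singular = FALSE)
      out[g, k] <- h$p
    }
  }
  out
}

profile_scores <- function(p) {
  s <- -log(pmax(p, .P_FLOOR))
  s[is.na(p)] <- 0
  s
}

# ---- user-facing operations ----

#' Per-gene rare-variant p-value profile
#'
#' Applies the WS or CMC method to every gene and returns the gene scores
#' `-log(p)` used by the aggregation tests (Fisher, KS, GSEA). Genes whose
#' test is degenerate (no genotype variation) receive score 0 with a
#' warning.
#'
#' @inheritParams ws_statistic
#' @param method `"WS"` (permutation significance) or `"CMC"` (asymptotic
#'   Hotelling T-squared).
#' @param n_permutations Phenotype permutations per gene for WS.
#' @param rare_threshold CMC rare/common MAF cutoff.
#' @param seed Master seed for the WS permutation streams.
#' @param replicate Replicate index recorded in the profile.
#' @return A tibble of class `gene_profile` with columns `gene`, `p_value`,
#'   `score` and attributes `method` and `replicate`.
#' @export
gene_pvalue_profile <- function(genotypes, phenotype, method = c("WS", "CMC"),
                                n_permutations = 1000L, rare_threshold = 0.05,
                                seed = 1L, replicate = 1L) {
  method <- match.arg(method)
  phenotype <- assert_binary_phenotype(phenotype, nrow(genotypes$dosages))
  gene_idx <- gene_index_list(genotypes)
  if (length(gene_idx) < 2L) {
    stop_rvpath("a gene profile needs at least 2 genes.",
                "rvpath_validation_error")
  }
  if (method == "WS") {
    p <- ws_profiles(genotypes, phenotype, gene_idx, n_permutations,
                     seed, replicate)$p_obs
  } else {
    designs <- cmc_gene_designs(genotypes, gene_idx, rare_threshold)
    p <- drop(cmc_p_for_labels(designs, matrix(phenotype, ncol = 1L)))
    names(p) <- names(gene_idx)
  }
  if (anyNA(p)) {
    warn(sprintf("%d gene(s) had no testable variation; scored 0.",
                 sum(is.na(p))))
  }
  out <- tibble::tibble(gene = names(gene_idx), p_value = unname(p),
                        score = unname(profile_scores(p)))
  attr(out, "method") <- method
  attr(out, "replicate") <- replicate
  class(out) <- c("gene_profile", class(out))
  out
}

#' Fisher's combined probability test
#'
#' Combines independent p-values as `X^2 = -2 sum(log p)`, referred to a
#' chi-square distribution with `2k` degrees of freedom (upper tail), `k`
#' the number of p-values.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param unit_id Label recorded in the result.
#' @param method Method tag for the result row (`"WS_Fisher"` or
#'   `"CMC_Fisher"`).
#' @param replicate Replicate index recorded in the result.
#' @return A one-row [test_result()] tibble; `statistic` holds X-squared.
#' @examples
#' fisher_combined(c(0.5))$p_value  # 0.5: a single p-value is recovered
#' @export
fisher_combined <- function(p_values, unit_id = "set", method = "WS_Fisher",
                            replicate = 1L) {
  if (length(p_values) == 0L) {
    stop_rvpath("`p_values` is empty.", "rvpath_validation_error")
  }
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    stop_rvpath("all p-values must lie in (0, 1].", "rvpath_validation_error")
  }
  x2 <- -2 * sum(log(p_values))
  p <- pchisq(x2, df = 2 * length(p_values), lower.tail = FALSE)
  test_result(unit_id, method, x2, max(p, .P_FLOOR), replicate)
}

# two-sided asymptotic Kolmogorov tail: Q(t) = 2 sum (-1)^{k-1} exp(-2k^2t^2)
kolmogorov_sf <- function(t) {
  if (t < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, .P_FLOOR), 1)
}

#' Two-sample KS test of in-set versus out-of-set gene scores
#'
#' Compares the `-log p` score distribution of genes in the set against all
#' other genes with the two-sample Kolmogorov-Smirnov statistic
#' `D = max |F_in - F_out|`, using the asymptotic Kolmogorov distribution
#' with effective sample size `n1 n2 / (n1 + n2)`.
#'
#' @param profile A `gene_profile` from [gene_pvalue_profile()].
#' @param set_genes Character vector of gene symbols in the set (must be a
#'   strict, non-empty subset of the profile's genes).
#' @param unit_id Label recorded in the result.
#' @param method Method tag (`"WS_KS"` or `"CMC_KS"`).
#' @param alternative `"two.sided"` (default) or `"greater"` (in-set scores
#'   stochastically larger, one-sided `D+`).
#' @param replicate Replicate index recorded in the result.
#' @return A one-row [test_result()] tibble; `statistic` holds D.
#' @export
ks_set_test <- function(profile, set_genes, unit_id = "set",
                        method = "WS_KS",
                        alternative = c("two.sided", "greater"),
                        replicate = 1L) {
  alternative <- match.arg(alternative)
  in_set <- profile$gene %in% set_genes
  if (!any(in_set)) {
    stop_rvpath("no profile gene belongs to the set.",
                "rvpath_validation_error")
  }
  if (all(in_set)) {
    stop_rvpath("the set covers every profiled gene; the complement is empty.",
                "rvpath_validation_error")
  }
  x <- profile$score[in_set]
  y <- profile$score[!in_set]
  n1 <- length(x)
  n2 <- length(y)
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(v) mean(x <= v), 0)
  Fy <- vapply(grid, function(v) mean(y <= v), 0)
  diffs <- Fy - Fx           # positive where in-set scores are larger
  n_eff <- n1 * n2 / (n1 + n2)
  if (alternative == "two.sided") {
    D <- max(abs(diffs))
    p <- kolmogorov_sf(sqrt(n_eff) * D)
  } else {
    D <- max(diffs)
    p <- exp(-2 * n_eff * max(D, 0)^2)
  }
  test_result(unit_id, method, D, min(max(p, .P_FLOOR), 1), replicate)
}

#' Weighted-KS (GSEA) enrichment score
#'
#' Genes are ranked by score (descending, ties broken by gene id for
#' determinism). Walking down the ranked list, an in-set gene increments the
#' running sum by `score^weight_exponent / sum(in-set score^weight_exponent)`
#' and an out-of-set gene decrements it by `1 / (N - |set|)`. The enrichment
#' score is the running-sum value of maximal absolute deviation from zero
#' (signed). When every in-set weighted score is zero the hit increments
#' fall back to the uniform `1/|set|` with a warning.
#'
#' @inheritParams ks_set_test
#' @param weight_exponent Non-negative weighting power (default 1; 0 gives
#'   the classic unweighted KS running statistic on ranks).
#' @return A list of class `gsea_es` with elements `es`, `weight_exponent`
#'   and the `running` sum vector.
#' @export
gsea_enrichment_score <- function(profile, set_genes, weight_exponent = 1) {
  if (weight_exponent < 0) {
    stop_rvpath("`weight_exponent` must be >= 0.", "rvpath_validation_error")
  }
  in_set <- profile$gene %in% set_genes
  if (!any(in_set) || all(in_set)) {
    stop_rvpath("the set must be a strict, non-empty subset of profiled genes.",
                "rvpath_validation_error")
  }
  ord <- order(-profile$score, profile$gene)
  hits <- in_set[ord]
  scores <- profile$score[ord]
  wts <- scores^weight_exponent
  nr <- sum(wts[hits])
  if (nr == 0) {
    warn("all in-set weighted scores are zero; weighting hits uniformly.")
    inc <- as.numeric(hits) / sum(hits)
  } else {
    inc <- ifelse(hits, wts / nr, 0)
  }
  dec <- as.numeric(!hits) / (length(hits) - sum(hits))
  running <- cumsum(inc - dec)
  # extremum of the running sum; near-ties (float noise between a positive
  # and a negative excursion of equal size) resolve to the earlier position
  idx <- which(abs(running) >= max(abs(running)) - 1e-9)[1]
  es <- running[idx]
  structure(list(es = es, weight_exponent = weight_exponent,
                 running = running),
            class = "gsea_es")
}

#' GSEA set test with phenotype-permutation significance
#'
#' Computes the observed enrichment score from the real phenotype, then for
#' each permutation shuffles the phenotype labels, recomputes the entire
#' per-gene p-value profile, and recomputes the enrichment score. The
#' one-sided p-value is `(1 + #\{ES* >= ES_obs\}) / (n_permutations + 1)`.
#'
#' For WS gene scores, each gene's inner permutation null is drawn once and
#' reused across the outer phenotype permutations (permutations of a
#' permuted labeling are exactly permutations of the original labeling, so
#' the reference distribution is identical); `nested = TRUE` instead redraws
#' the inner null for every outer permutation at multiplicative cost.
#'
#' @inheritParams ws_statistic
#' @param set_genes Character vector of gene symbols in the set.
#' @param method Gene-scoring method, `"WS"` or `"CMC"`.
#' @param n_permutations Outer phenotype permutations (default 100).
#' @param inner_permutations WS permutations per gene when `method = "WS"`
#'   (default 100; coarse-grained gene p-values, see Details).
#' @param weight_exponent GSEA weighting power.
#' @param rare_threshold CMC rare/common MAF cutoff.
#' @param seed Master seed.
#' @param replicate Replicate index.
#' @param unit_id Label recorded in the result.
#' @param nested Redraw WS inner permutation nulls per outer permutation.
#' @return A one-row [test_result()] tibble with method `"WS_GSEA"` or
#'   `"CMC_GSEA"`; `statistic` holds the observed enrichment score.
#' @export
gsea_test <- function(genotypes, phenotype, set_genes, method = c("WS", "CMC"),
                      n_permutations = 100L, inner_permutations = 100L,
                      weight_exponent = 1, rare_threshold = 0.05,
                      seed = 1L, replicate = 1L, unit_id = "set",
                      nested = FALSE) {
  method <- match.arg(method)
  if (n_permutations < 1L) {
    stop_rvpath("`n_permutations` must be at least 1.",
                "rvpath_validation_error")
  }
  phenotype <- assert_binary_phenotype(phenotype, nrow(genotypes$dosages))
  gene_idx <- gene_index_list(genotypes)
  outer_Y <- with_seed(derive_seed(seed, "gsea", unit_id, replicate),
                       .perm_matrix(phenotype, n_permutations))
  if (method == "WS") {
    if (nested) {
      prof <- ws_profiles(genotypes, phenotype, gene_idx,
                          inner_permutations, seed, replicate)
      p_obs <- prof$p_obs
      p_outer <- vapply(seq_len(n_permutations), function(o) {
        ws_profiles(genotypes, outer_Y[, o], gene_idx, inner_permutations,
                    derive_seed(seed, "nested", o), replicate)$p_obs
      }, p_obs)
    } else {
      prof <- ws_profiles(genotypes, phenotype, gene_idx,
                          inner_permutations, seed, replicate,
                          outer_Y = outer_Y)
      p_obs <- prof$p_obs
      p_outer <- prof$p_outer
    }
  } else {
    designs <- cmc_gene_designs(genotypes, gene_idx, rare_threshold)
    p_all <- cmc_p_for_labels(designs, cbind(phenotype, outer_Y))
    p_obs <- p_all[, 1]
    p_outer <- p_all[, -1, drop = FALSE]
    names(p_obs) <- names(gene_idx)
  }
  base_profile <- tibble::tibble(gene = names(gene_idx),
                                 score = profile_scores(unname(p_obs)))
  es_obs <- gsea_enrichment_score(base_profile, set_genes,
                                  weight_exponent)$es
  es_perm <- vapply(seq_len(n_permutations), function(o) {
    prof_o <- tibble::tibble(gene = names(gene_idx),
                             score = profile_scores(p_outer[, o]))
    suppressWarnings(
      gsea_enrichment_score(prof_o, set_genes, weight_exponent)$es)
  }, 0)
  p <- (1 + sum(es_perm >= es_obs - 1e-12)) / (n_permutations + 1)
  test_result(unit_id, paste0(method, "_GSEA"), es_obs, p, replicate,
              n_permutations = n_permutations)
}

#' Direct burden test on the pooled SNPs of a gene set
#'
#' Builds one variant group pooling every SNP of every gene in the set and
#' applies WS (phenotype-permutation significance) or CMC (asymptotic
#' Hotelling T-squared; by default one collapsing indicator per gene plus
#' the common variants) to it.
#'
#' @inheritParams ws_statistic
#' @param set_genes Character vector of gene symbols.
#' @param method `"WS"` or `"CMC"`.
#' @param n_permutations WS phenotype permutations.
#' @param rare_threshold CMC rare/common MAF cutoff.
#' @param grouping CMC collapsing unit, `"gene"` (default) or `"set"`.
#' @param seed Master seed (WS only).
#' @param replicate Replicate index.
#' @param unit_id Label recorded in the result; defaults to the set genes.
#' @return A one-row [test_result()] tibble with method `"WS"` or `"CMC"`.
#' @export
direct_set_test <- function(genotypes, phenotype, set_genes,
                            method = c("WS", "CMC"),
                            n_permutations = 1000L, rare_threshold = 0.05,
                            grouping = c("gene", "set"), seed = 1L,
                            replicate = 1L, unit_id = NULL) {
  method <- match.arg(method)
  grouping <- match.arg(grouping)
  label <- unit_id %||% paste(set_genes, collapse = "+")
  group <- gene_group(genotypes, set_genes, label = label)
  if (method == "WS") {
    ws_test(genotypes, phenotype, group, n_permutations = n_permutations,
            seed = seed, replicate = replicate)
  } else {
    cmc_test(genotypes, phenotype, group, rare_threshold = rare_threshold,
             grouping = grouping, replicate = replicate)
  }
}

#' Test one gene set with any of the eight pathway methods
#'
#' Dispatcher over the two strategies: direct burden testing of the pooled
#' SNPs (`WS`, `CMC`) and aggregation of gene-level p-values
#' (`WS_Fisher`, `CMC_Fisher`, `WS_KS`, `CMC_KS`, `WS_GSEA`, `CMC_GSEA`).
#' For the Fisher and KS aggregators a precomputed [gene_pvalue_profile()]
#' can be supplied to avoid recomputation across sets.
#'
#' @inheritParams direct_set_test
#' @param method One of the eight method tags in [RV_METHODS].
#' @param profile Optional precomputed `gene_profile` matching the method's
#'   gene-scoring half.
#' @param inner_permutations WS permutations per gene inside profiles.
#' @param weight_exponent GSEA weighting power.
#' @return A one-row [test_result()] tibble.
#' @export
set_test <- function(genotypes, phenotype, set_genes, method = RV_METHODS,
                     profile = NULL, n_permutations = 1000L,
                     inner_permutations = 100L, weight_exponent = 1,
                     rare_threshold = 0.05, grouping = c("gene", "set"),
                     seed = 1L, replicate = 1L, unit_id = "set") {
  method <- match.arg(method)
  if (method %in% c("WS", "CMC")) {
    return(direct_set_test(genotypes, phenotype, set_genes, method,
                           n_permutations = n_permutations,
                           rare_threshold = rare_threshold,
                           grouping = grouping, seed = seed,
                           replicate = replicate, unit_id = unit_id))
  }
  base <- sub("_.*$", "", method)
  kind <- sub("^.*_", "", method)
  if (kind == "GSEA") {
    return(gsea_test(genotypes, phenotype, set_genes, method = base,
                     n_permutations = n_permutations,
                     inner_permutations = inner_permutations,
                     weight_exponent = weight_exponent,
                     rare_threshold = rare_threshold, seed = seed,
                     replicate = replicate, unit_id = unit_id))
  }
  if (is.null(profile)) {
    profile <- gene_pvalue_profile(
      genotypes, phenotype, method = base,
      n_permutations = inner_permutations,
      rare_threshold = rare_threshold, seed = seed, replicate = replicate)
  }
  if (kind == "Fisher") {
    p_in <- profile$p_value[profile$gene %in% set_genes]
    p_in <- p_in[!is.na(p_in)]
    fisher_combined(p_in, unit_id = unit_id, method = method,
                    replicate = replicate)
  } else {
    ks_set_test(profile, set_genes, unit_id = unit_id, method = method,
                replicate = replicate)
  }
}
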