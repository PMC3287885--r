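#' Evaluation parameters
#'
#' Tuning knobs for [evaluate_methods()] and [gene_level_results()].
#'
#' @param ws_permutations Phenotype permutations for WS tests (gene-level
#'   and direct; default 200 at desk scale).
#' @param gsea_permutations Outer phenotype permutations for GSEA (default
#'   100).
#' @param inner_permutations WS permutations per gene inside GSEA profiles;
#'   defaults to `ws_permutations`.
#' @param rare_threshold CMC rare/common MAF cutoff.
#' @param weight_exponent GSEA weighting power.
#' @param ks_alternative Sidedness of the KS aggregation test.
#' @return A list of parameters.
#' @export
eval_params <- function(ws_permutations = 200L, gsea_permutations = 100L,
                        inner_permutations = NULL, rare_threshold = 0.05,
                        weight_exponent = 1,
                        ks_alternative = c("two.sided", "greater")) {
  list(ws_permutations = as.integer(ws_permutations),
       gsea_permutations = as.integer(gsea_permutations),
       inner_permutations = as.integer(inner_permutations %||%
                                         ws_permutations),
       rare_threshold = rare_threshold,
       weight_exponent = weight_exponent,
       ks_alternative = match.arg(ks_alternative))
}

#' Gene-level WS and CMC p-values across all replicates
#'
#' Runs the WS (permutation) and/or CMC (asymptotic) test on every gene for
#' every phenotype replicate. This is the shared first pass of the
#' aggregation pathway methods and the input to [detect_spurious()];
#' [evaluate_methods()] accepts its output as a cache so the pass is done
#' once.
#'
#' @param genotypes A gene-annotated [rv_genotypes].
#' @param phenotypes An [rv_phenotypes] aligned to the genotypes.
#' @param methods Subset of `c("WS", "CMC")`.
#' @param params An [eval_params()] list.
#' @param seed Master seed for the WS permutation streams.
#' @return A tibble with columns `unit_id` (gene), `method`, `replicate`,
#'   `p_value`.
#' @export
gene_level_results <- function(genotypes, phenotypes,
                               methods = c("WS", "CMC"),
                               params = eval_params(), seed = 1L) {
  gene_idx <- gene_index_list(genotypes)
  R <- n_replicates(phenotypes)
  out <- list()
  if ("WS" %in% methods) {
    p <- vapply(seq_len(R), function(r) {
      ws_profiles(genotypes, phenotype_replicate(phenotypes, r), gene_idx,
                  params$ws_permutations, seed, replicate = r)$p_obs
    }, numeric(length(gene_idx)))
    out$WS <- p
  }
  if ("CMC" %in% methods) {
    designs <- cmc_gene_designs(genotypes, gene_idx, params$rare_threshold)
    p <- cmc_p_for_labels(designs, phenotypes$status)
    rownames(p) <- names(gene_idx)
    out$CMC <- p
  }
  purrr::map_dfr(names(out), function(m) {
    tibble::tibble(unit_id = rep(names(gene_idx), times = R),
                   method = m,
                   replicate = rep(seq_len(R), each = length(gene_idx)),
                   p_value = as.vector(out[[m]]))
  })
}

# gene x replicate matrix from a gene_level_results tibble
cache_matrix <- function(cache, method, genes, R) {
  sub <- cache[cache$method == method, ]
  m <- matrix(NA_real_, length(genes), R, dimnames = list(genes, NULL))
  m[cbind(match(sub$unit_id, genes), sub$replicate)] <- sub$p_value
  m
}

# enrichment scores of every set for one profile, vectorized over sets
es_for_sets <- function(scores, genes, membership, weight_exponent) {
  ord <- order(-scores, genes)
  hitM <- membership[ord, , drop = FALSE]
  wts <- scores[ord]^weight_exponent
  nr <- colSums(hitM * wts)
  k <- colSums(hitM)
  N <- length(scores)
  inc <- hitM * outer(wts, 1 / pmax(nr, .Machine$double.eps)) -
    (1 - hitM) * matrix(1 / (N - k), N, ncol(hitM), byrow = TRUE)
  zero <- nr == 0
  if (any(zero)) {
    inc[, zero] <- hitM[, zero, drop = FALSE] /
      matrix(k[zero], N, sum(zero), byrow = TRUE) -
      (1 - hitM[, zero, drop = FALSE]) *
      matrix(1 / (N - k[zero]), N, sum(zero), byrow = TRUE)
  }
  run <- apply(inc, 2L, cumsum)
  idx <- apply(abs(run), 2L, function(a) which(a >= max(a) - 1e-9)[1])
  run[cbind(idx, seq_along(idx))]
}

#' Evaluate pathway methods over sets and replicates
#'
#' The central harness: computes a p-value for every (set, method,
#' replicate) combination, empirical rejection rates at each `alpha`
#' (type I error for null sets, power for causal sets), and per-set
#' best-method calls by the count of significant replicates at
#' `alpha = 0.05` (ties reported as co-best). Gene-level p-values are
#' computed once per (gene, method, replicate) and reused by all
#' aggregation methods; pass a precomputed [gene_level_results()] cache to
#' reuse it across calls. GSEA phenotype permutations are likewise shared
#' across sets within a replicate.
#'
#' @inheritParams gene_level_results
#' @param sets A [gene_sets()] tibble.
#' @param methods Methods to evaluate (default all eight, see [RV_METHODS]).
#' @param alphas Nominal significance levels (default 0.05 and 0.005).
#' @param truth Optional [truth_model()]; when supplied together with
#'   `gene_map`, per-set features are attached.
#' @param gene_map Optional gene map tibble for the feature computation.
#' @param gene_cache Optional precomputed [gene_level_results()] tibble.
#' @param seed Master seed.
#' @return An `rv_evaluation` object: list with `results` (long tibble of
#'   p-values), `rates`, `best` (per-set best-method calls), `features` (or
#'   `NULL`) and `params`.
#' @export
evaluate_methods <- function(genotypes, phenotypes, sets,
                             methods = RV_METHODS,
                             alphas = c(0.05, 0.005),
                             params = eval_params(), truth = NULL,
                             gene_map = NULL, gene_cache = NULL,
                             seed = 1L) {
  methods <- match.arg(methods, RV_METHODS, several.ok = TRUE)
  if (nrow(sets) == 0L) {
    stop_rvpath("`sets` is empty.", "rvpath_validation_error")
  }
  R <- n_replicates(phenotypes)
  gene_idx <- gene_index_list(genotypes)
  genes <- names(gene_idx)
  membership <- vapply(sets$genes, function(g) genes %in% g,
                       logical(length(genes)))
  bases_needed <- unique(sub("_.*$", "", grep("_", methods, value = TRUE)))
  ws_gsea <- "WS_GSEA" %in% methods
  cmc_gsea <- "CMC_GSEA" %in% methods
  need_gsea <- ws_gsea || cmc_gsea

  # WS gene p-values are recomputed alongside the GSEA outer permutations
  # when WS_GSEA runs (identical values: same derived streams), so the
  # upfront pass is only needed for the other aggregators.
  p_gene <- list()
  cache_bases <- setdiff(bases_needed, if (ws_gsea) "WS" else character(0))
  if (length(cache_bases)) {
    if (is.null(gene_cache)) {
      gene_cache <- gene_level_results(genotypes, phenotypes,
                                       methods = cache_bases,
                                       params = params, seed = seed)
    }
    for (b in intersect(cache_bases, unique(gene_cache$method))) {
      p_gene[[b]] <- cache_matrix(gene_cache, b, genes, R)
    }
    for (b in setdiff(cache_bases, names(p_gene))) {
      extra <- gene_level_results(genotypes, phenotypes, methods = b,
                                  params = params, seed = seed)
      p_gene[[b]] <- cache_matrix(extra, b, genes, R)
    }
  }
  if (ws_gsea) p_gene[["WS"]] <- matrix(NA_real_, length(genes), R,
                                        dimnames = list(genes, NULL))
  gene_designs <- if ("CMC" %in% bases_needed) {
    cmc_gene_designs(genotypes, gene_idx, params$rare_threshold)
  } else NULL
  cmc_set_designs <- NULL
  if ("CMC" %in% methods) {
    cmc_set_designs <- lapply(seq_len(nrow(sets)), function(s) {
      tryCatch(
        suppressWarnings(cmc_design(
          genotypes, gene_group(genotypes, sets$genes[[s]],
                                label = sets$set_id[s]),
          rare_threshold = params$rare_threshold, grouping = "gene")),
        rvpath_degenerate_error = function(e) NULL)
    })
  }

  rows <- vector("list", R)
  for (r in seq_len(R)) {
    y <- phenotype_replicate(phenotypes, r)
    rep_rows <- list()
    if (need_gsea) {
      outer_Y <- with_seed(derive_seed(seed, "gsea_outer", r),
                           .perm_matrix(y, params$gsea_permutations))
      for (b in c("WS", "CMC")) {
        tag <- paste0(b, "_GSEA")
        if (!tag %in% methods) next
        if (b == "WS") {
          prof <- ws_profiles(genotypes, y, gene_idx,
                              params$inner_permutations, seed,
                              replicate = r, outer_Y = outer_Y)
          p_gene[["WS"]][, r] <- prof$p_obs
          sc_obs <- profile_scores(prof$p_obs)
          sc_out <- apply(prof$p_outer, 2L, profile_scores)
        } else {
          p_all <- cmc_p_for_labels(gene_designs, cbind(y, outer_Y))
          sc_obs <- profile_scores(p_all[, 1])
          sc_out <- apply(p_all[, -1, drop = FALSE], 2L, profile_scores)
        }
        es_obs <- es_for_sets(sc_obs, genes, membership,
                              params$weight_exponent)
        es_perm <- vapply(seq_len(ncol(sc_out)), function(o) {
          es_for_sets(sc_out[, o], genes, membership,
                      params$weight_exponent)
        }, es_obs)
        hits <- rowSums(es_perm >= es_obs - 1e-12)
        p_gsea <- (1 + hits) / (params$gsea_permutations + 1)
        rep_rows[[tag]] <- tibble::tibble(
          set_id = sets$set_id, method = tag, replicate = r,
          statistic = es_obs, p_value = p_gsea)
      }
    }
    for (b in bases_needed) {
      sc <- profile_scores(p_gene[[b]][, r])
      prof <- tibble::tibble(gene = genes, p_value = p_gene[[b]][, r],
                             score = sc)
      tag_f <- paste0(b, "_Fisher")
      if (tag_f %in% methods) {
        rep_rows[[tag_f]] <- purrr::map_dfr(seq_len(nrow(sets)), function(s) {
          p_in <- p_gene[[b]][membership[, s], r]
          p_in <- p_in[!is.na(p_in)]
          fr <- fisher_combined(p_in, unit_id = sets$set_id[s],
                                method = tag_f, replicate = r)
          fr[, c("unit_id", "method", "replicate", "statistic", "p_value")]
        })
        names(rep_rows[[tag_f]])[1] <- "set_id"
      }
      tag_k <- paste0(b, "_KS")
      if (tag_k %in% methods) {
        rep_rows[[tag_k]] <- purrr::map_dfr(seq_len(nrow(sets)), function(s) {
          kr <- ks_set_test(prof, sets$genes[[s]], unit_id = sets$set_id[s],
                            method = tag_k,
                            alternative = params$ks_alternative,
                            replicate = r)
          kr[, c("unit_id", "method", "replicate", "statistic", "p_value")]
        })
        names(rep_rows[[tag_k]])[1] <- "set_id"
      }
    }
    if ("WS" %in% methods) {
      rep_rows[["WS"]] <- purrr::map_dfr(seq_len(nrow(sets)), function(s) {
        wr <- ws_test(genotypes, y,
                      gene_group(genotypes, sets$genes[[s]],
                                 label = sets$set_id[s]),
                      n_permutations = params$ws_permutations, seed = seed,
                      replicate = r)
        wr[, c("unit_id", "method", "replicate", "statistic", "p_value")]
      })
      names(rep_rows[["WS"]])[1] <- "set_id"
    }
    if ("CMC" %in% methods) {
      rep_rows[["CMC"]] <- purrr::map_dfr(seq_len(nrow(sets)), function(s) {
        d <- cmc_set_designs[[s]]
        if (is.null(d)) {
          return(tibble::tibble(set_id = sets$set_id[s], method = "CMC",
                                replicate = r, statistic = NA_real_,
                                p_value = NA_real_))
        }
        hr <- suppressWarnings(hotelling_t2(d, y, replicate = r))
        out <- hr[, c("unit_id", "method", "replicate", "statistic",
                      "p_value")]
        names(out)[1] <- "set_id"
        out
      })
    }
    rows[[r]] <- dplyr::bind_rows(rep_rows)
  }
  results <- dplyr::bind_rows(rows)

  rates <- purrr::map_dfr(alphas, function(a) {
    dplyr::summarise(
      dplyr::group_by(results, .data$set_id, .data$method),
      alpha = a, rate = mean(.data$p_value <= a, na.rm = TRUE),
      n_replicates = sum(!is.na(.data$p_value)), .groups = "drop")
  })
  best <- dplyr::summarise(
    dplyr::group_by(results, .data$set_id, .data$method),
    n_significant = sum(.data$p_value <= 0.05, na.rm = TRUE),
    .groups = "drop")
  best <- dplyr::mutate(
    dplyr::group_by(best, .data$set_id),
    is_best = .data$n_significant == max(.data$n_significant))
  best <- dplyr::ungroup(best)

  features <- NULL
  if (!is.null(truth) && !is.null(gene_map)) {
    features <- set_features(sets, truth, gene_map)
  }
  structure(list(results = results, rates = rates, best = best,
                 features = features, sets = sets, params = params,
                 alphas = alphas),
            class = "rv_evaluation")
}

#' @export
print.rv_evaluation <- function(x, ...) {
  cat(sprintf("<rv_evaluation> %d sets x %d methods x %d replicates\n",
              length(unique(x$results$set_id)),
              length(unique(x$results$method)),
              max(x$results$replicate)))
  invisible(x)
}

#' Rejection-rate summary of an evaluation
#'
#' @param x An `rv_evaluation` from [evaluate_methods()].
#' @param ... Unused.
#' @return The tibble of per-set, per-method, per-alpha rejection rates.
#' @export
tidy.rv_evaluation <- function(x, ...) x$rates

#' One-row evaluation overview
#' @inheritParams tidy.rv_evaluation
#' @return A tibble with counts of sets, methods, replicates.
#' @export
glance.rv_evaluation <- function(x, ...) {
  tibble::tibble(n_sets = length(unique(x$results$set_id)),
                 n_methods = length(unique(x$results$method)),
                 n_replicates = max(x$results$replicate))
}

#' Mean rejection rate by number of causal genes (power-curve data)
#'
#' @param evaluation An `rv_evaluation` whose features were computed (call
#'   [evaluate_methods()] with `truth` and `gene_map`).
#' @param alpha Significance level to summarise at.
#' @return A tibble with `n_causal_genes`, `method`, `power`.
#' @export
power_by_causal_count <- function(evaluation, alpha = 0.05) {
  if (is.null(evaluation$features)) {
    stop_rvpath("evaluation has no set features; rerun with `truth` and `gene_map`.",
                "rvpath_validation_error")
  }
  df <- dplyr::inner_join(
    evaluation$rates[evaluation$rates$alpha == alpha, ],
    evaluation$features[, c("set_id", "n_causal_genes")], by = "set_id")
  dplyr::summarise(
    dplyr::group_by(df, .data$n_causal_genes, .data$method),
    power = mean(.data$rate), .groups = "drop")
}

#' Power curve across causal-gene counts
#'
#' @inheritParams power_by_causal_count
#' @return A ggplot object: mean rejection rate versus the number of causal
#'   genes per set, one line per method.
#' @export
plot_power_curve <- function(evaluation, alpha = 0.05) {
  df <- power_by_causal_count(evaluation, alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_causal_genes,
                                   y = .data$power,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Causal genes in set", y = "Power",
                  colour = "Method",
                  title = sprintf("Power at alpha = %g", alpha)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_power_curve
#' @param object An `rv_evaluation`.
#' @param ... Passed to [plot_power_curve()].
#' @export
autoplot.rv_evaluation <- function(object, ...) {
  plot_power_curve(object, ...)
}
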