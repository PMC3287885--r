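#' Truth model of the simulated disease architecture
#'
#' Records which genes and SNPs causally drive the phenotype, with each
#' causal SNP's minor allele frequency and log-odds effect size beta.
#'
#' @param causal_snps Tibble with columns `variant_id`, `gene`, `maf`,
#'   `beta` (one row per causal SNP).
#' @param causal_genes Character vector of causal gene symbols; defaults to
#'   the genes hosting the causal SNPs.
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(causal_snps, causal_genes = unique(causal_snps$gene)) {
  need <- c("variant_id", "gene", "maf", "beta")
  if (!all(need %in% names(causal_snps))) {
    stop_rvpath("`causal_snps` needs variant_id, gene, maf and beta columns.",
                "rvpath_validation_error")
  }
  if (!all(is.finite(causal_snps$beta))) {
    stop_rvpath("every causal-SNP beta must be finite.",
                "rvpath_validation_error")
  }
  if (!all(causal_snps$gene %in% causal_genes)) {
    stop_rvpath("every causal SNP must lie in a causal gene.",
                "rvpath_validation_error")
  }
  structure(list(causal_genes = as.character(causal_genes),
                 causal_snps = tibble::as_tibble(causal_snps[, need])),
            class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat(sprintf("<truth_model> %d causal SNPs in %d causal genes\n",
              nrow(x$causal_snps), length(x$causal_genes)))
  invisible(x)
}

#' Read / write a truth model TSV (variant_id, gene, maf, beta)
#' @param path File to read.
#' @return A [truth_model()].
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) {
    stop_rvpath(sprintf("file '%s' does not exist.", path), "rvpath_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  truth_model(tibble::as_tibble(df))
}

#' @rdname read_truth
#' @param truth A [truth_model()].
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$causal_snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Detect spuriously associated noncausal genes
#'
#' A noncausal gene is flagged as spurious when it is repeatedly significant
#' across phenotype replicates despite having no causal SNPs: the number of
#' replicates in which the gene's p-value is below `alpha` for both the WS
#' and CMC methods (default reading: simultaneously in the same replicate)
#' exceeds `count_threshold`. With `mode = "marginal"` each method's count
#' must exceed the threshold separately.
#'
#' @param per_gene_results Tibble of gene-level [test_result()] rows covering
#'   every gene for both methods on every replicate.
#' @param truth A [truth_model()]; causal genes are never flagged.
#' @param alpha Per-gene significance level (default 0.05).
#' @param count_threshold Strict lower bound on the significant-replicate
#'   count (default 15, i.e. "more than 15 of 200").
#' @param n_replicates Expected replicate count; coverage is validated
#'   against it.
#' @param mode `"joint"` (both methods significant in the same replicate) or
#'   `"marginal"` (each method's own count exceeds the threshold).
#' @return Character vector of spurious gene symbols.
#' @export
detect_spurious <- function(per_gene_results, truth, alpha = 0.05,
                            count_threshold = 15L, n_replicates = 200L,
                            mode = c("joint", "marginal")) {
  mode <- match.arg(mode)
  res <- per_gene_results
  genes <- unique(res$unit_id)
  wide <- tidyr::pivot_wider(
    res[res$method %in% c("WS", "CMC"),
        c("unit_id", "replicate", "method", "p_value")],
    names_from = "method", values_from = "p_value")
  if (!all(c("WS", "CMC") %in% names(wide)) ||
      nrow(wide) != length(genes) * n_replicates) {
    stop_rvpath(
      "results must cover every gene x replicate for both WS and CMC.",
      "rvpath_validation_error")
  }
  # degenerate genes carry NA p-values; they are never significant
  sig <- function(p) !is.na(p) & p < alpha
  counts <- dplyr::summarise(
    dplyr::group_by(wide, .data$unit_id),
    joint = sum(sig(.data$WS) & sig(.data$CMC)),
    ws = sum(sig(.data$WS)),
    cmc = sum(sig(.data$CMC)),
    .groups = "drop")
  flagged <- if (mode == "joint") {
    counts$unit_id[counts$joint > count_threshold]
  } else {
    counts$unit_id[counts$ws > count_threshold &
                     counts$cmc > count_threshold]
  }
  setdiff(flagged, truth$causal_genes)
}

#' Build the four benchmark gene-set categories
#'
#' Constructs the evaluation collection: (1) `causal_mix` sets containing
#' `C` causal genes (for each value in `causal_counts`, `sets_per_count`
#' sets) topped up to `set_size` with noncausal genes; (2) `null` sets drawn
#' entirely from noncausal genes; (3) `null_nonspurious` sets drawn from
#' noncausal genes that are also not spurious; (4) `causal_mix_nonspurious`
#' sets reusing the category-1 causal draws with the noncausal members
#' redrawn from the nonspurious pool. Sampling is without replacement within
#' a set and deterministic given `seed`.
#'
#' @param truth A [truth_model()].
#' @param all_genes Character vector of every gene in the experiment.
#' @param nonspurious_genes Noncausal genes that passed the spurious filter
#'   (see [detect_spurious()]); defaults to all noncausal genes.
#' @param set_size Genes per set (default 25).
#' @param causal_counts Values of `C` (default 5, 10, 15, 20, 25).
#' @param sets_per_count Category-1 sets per value of `C` (default 100).
#' @param n_null_sets Sets in each of categories 2 and 3 (default 500).
#' @param seed Integer seed.
#' @return A [gene_sets()] tibble; with the defaults, 2,000 sets of 25
#'   genes.
#' @export
build_sets <- function(truth, all_genes,
                       nonspurious_genes = NULL,
                       set_size = 25L,
                       causal_counts = c(5L, 10L, 15L, 20L, 25L),
                       sets_per_count = 100L, n_null_sets = 500L,
                       seed = 1L) {
  causal <- intersect(all_genes, truth$causal_genes)
  noncausal <- setdiff(all_genes, truth$causal_genes)
  if (is.null(nonspurious_genes)) nonspurious_genes <- noncausal
  nonspurious <- setdiff(intersect(nonspurious_genes, noncausal), character(0))
  if (max(causal_counts) > length(causal)) {
    stop_rvpath(sprintf(
      "causal pool too small: need %d causal genes, have %d.",
      max(causal_counts), length(causal)), "rvpath_validation_error")
  }
  need_nc <- set_size - min(causal_counts)
  if (need_nc > length(noncausal) || set_size > length(noncausal)) {
    stop_rvpath(sprintf(
      "noncausal pool too small: need %d genes, have %d.",
      max(need_nc, set_size), length(noncausal)), "rvpath_validation_error")
  }
  if (need_nc > length(nonspurious) || set_size > length(nonspurious)) {
    stop_rvpath(sprintf(
      "nonspurious pool too small: need %d genes, have %d.",
      max(need_nc, set_size), length(nonspurious)),
      "rvpath_validation_error")
  }
  with_seed(derive_seed(seed, "build_sets"), {
    ids <- character(0); genes <- list(); cat <- character(0)
    causal_draws <- list()
    for (C in causal_counts) {
      for (s in seq_len(sets_per_count)) {
        id <- sprintf("causal_C%02d_%03d", C, s)
        cg <- sample(causal, C)
        ng <- if (C < set_size) sample(noncausal, set_size - C) else character(0)
        causal_draws[[id]] <- cg
        ids <- c(ids, id); genes <- c(genes, list(c(cg, ng)))
        cat <- c(cat, "causal_mix")
      }
    }
    for (s in seq_len(n_null_sets)) {
      ids <- c(ids, sprintf("null_%03d", s))
      genes <- c(genes, list(sample(noncausal, set_size)))
      cat <- c(cat, "null")
    }
    for (s in seq_len(n_null_sets)) {
      ids <- c(ids, sprintf("nonspurious_null_%03d", s))
      genes <- c(genes, list(sample(nonspurious, set_size)))
      cat <- c(cat, "null_nonspurious")
    }
    for (id in names(causal_draws)) {
      cg <- causal_draws[[id]]
      C <- length(cg)
      ng <- if (C < set_size) sample(nonspurious, set_size - C) else character(0)
      ids <- c(ids, sub("^causal_", "nonspurious_causal_", id))
      genes <- c(genes, list(c(cg, ng)))
      cat <- c(cat, "causal_mix_nonspurious")
    }
    gene_sets(ids, genes, category = cat)
  })
}

#' Per-set explanatory features
#'
#' The five set characteristics used to explain which method wins: number of
#' causal genes, number of causal SNPs, total number of SNPs, average MAF of
#' the causal genes (causal-SNP MAFs summed within each causal gene, then
#' averaged over the set's causal genes; 0 when the set has none), and the
#' weighted risk score `sum(MAF * beta)` over the set's causal SNPs.
#'
#' @param sets A [gene_sets()] tibble.
#' @param truth A [truth_model()].
#' @param gene_map Tibble (`variant_id`, `gene`) covering the experiment;
#'   used for total SNP counts.
#' @return A tibble with one row per set: `set_id`, `category`,
#'   `n_causal_genes`, `n_causal_snps`, `n_total_snps`,
#'   `avg_maf_causal_genes`, `weighted_risk_score`.
#' @export
set_features <- function(sets, truth, gene_map) {
  validate_gene_map(gene_map)
  snps_per_gene <- table(gene_map$gene)
  cs <- truth$causal_snps
  purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    g <- sets$genes[[i]]
    in_set <- cs[cs$gene %in% g, , drop = FALSE]
    cg <- intersect(g, truth$causal_genes)
    avg_maf <- if (length(cg)) {
      per_gene <- vapply(cg, function(gg) sum(in_set$maf[in_set$gene == gg]), 0)
      mean(per_gene)
    } else 0
    tibble::tibble(
      set_id = sets$set_id[i],
      category = sets$category[i],
      n_causal_genes = length(cg),
      n_causal_snps = nrow(in_set),
      n_total_snps = sum(snps_per_gene[g], na.rm = TRUE),
      avg_maf_causal_genes = avg_maf,
      weighted_risk_score = sum(in_set$maf * in_set$beta))
  })
}
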