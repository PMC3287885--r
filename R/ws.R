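#' Define a variant group for burden testing
#'
#' A labelled collection of genotype-matrix column indices (a gene, or the
#' pooled SNPs of a gene set).
#'
#' @param label Gene or set name.
#' @param variant_indices Integer column indices into a genotype matrix.
#' @return A `variant_group` object.
#' @export
variant_group <- function(label, variant_indices) {
  variant_indices <- as.integer(variant_indices)
  if (length(variant_indices) == 0L) {
    stop_rvpath(sprintf("variant group '%s' is empty.", label),
                "rvpath_validation_error")
  }
  if (anyDuplicated(variant_indices)) {
    stop_rvpath(sprintf("variant group '%s' repeats an index.", label),
                "rvpath_validation_error")
  }
  structure(list(label = as.character(label),
                 variant_indices = variant_indices),
            class = "variant_group")
}

#' Build the variant group spanning one or more genes
#'
#' @param genotypes An [rv_genotypes] object with gene annotation attached.
#' @param genes Character vector of gene symbols.
#' @param label Group label; defaults to the genes pasted together.
#' @return A [variant_group()] pooling every variant of every listed gene.
#' @export
gene_group <- function(genotypes, genes, label = paste(genes, collapse = "+")) {
  idx <- which(genotypes$variants$gene %in% genes)
  if (length(idx) == 0L) {
    stop_rvpath(sprintf("no variants found for gene(s) %s.",
                        paste(genes, collapse = ", ")),
                "rvpath_validation_error")
  }
  variant_group(label, idx)
}

resolve_group <- function(genotypes, group) {
  if (is.character(group)) group <- gene_group(genotypes, group)
  if (!inherits(group, "variant_group")) {
    stop_rvpath("`group` must be a variant_group or gene name(s).",
                "rvpath_validation_error")
  }
  if (max(group$variant_indices) > ncol(genotypes$dosages) ||
      min(group$variant_indices) < 1L) {
    stop_rvpath(sprintf("variant group '%s' indexes outside the matrix.",
                        group$label), "rvpath_validation_error")
  }
  group
}

# Weighted-sum machinery, vectorized over phenotype labelings.
#
# G: n x m dosage matrix (NA allowed); Y: n x K matrix whose columns are 0/1
# phenotype labelings (observed and/or permuted). For labeling k, variant i:
#   q_ik = (m_i^U + 1) / (2 n_i^U + 2)   (minor alleles / genotyped among
#                                         the unaffected, add-one smoothed)
#   w_ik = sqrt(n_i q_ik (1 - q_ik))     (n_i = genotyped individuals, all)
#   gamma_jk = sum_i g_ij / w_ik         (missing dosages contribute 0)
#   x_k = sum over affected of midrank(gamma_jk)
# Returns q, w (m x K), gamma (n x K) and the rank-sum vector x (length K).
ws_kernel <- function(G, Y) {
  miss <- is.na(G)
  G0 <- G
  if (any(miss)) G0[miss] <- 0L
  storage.mode(G0) <- "double"
  M <- 1 - miss
  storage.mode(M) <- "double"
  U <- 1 - Y
  mU <- crossprod(G0, U)              # m x K minor-allele counts, unaffected
  nU <- crossprod(M, U)               # m x K genotyped unaffected
  q <- (mU + 1) / (2 * nU + 2)
  n_i <- colSums(M)                   # genotyped individuals per variant
  w <- sqrt(n_i * q * (1 - q))
  gamma <- G0 %*% (1 / w)
  storage.mode(Y) <- "double"
  x <- .case_ranksums(gamma, Y)
  list(q = q, w = w, gamma = gamma, x = x)
}

#' Weighted-sum statistic for one variant group
#'
#' Computes the weighted-sum burden statistic: per-variant minor-allele
#' frequencies among the unaffected with add-one smoothing,
#' `q_i = (m_i^U + 1) / (2 n_i^U + 2)`; weights
#' `w_i = sqrt(n_i q_i (1 - q_i))` with `n_i` the number of genotyped
#' individuals; per-individual genetic scores
#' `gamma_j = sum_i g_ij / w_i` over the group's variants (missing dosages
#' contribute 0); and the rank sum `x` of the affected individuals' scores,
#' using midranks for ties.
#'
#' @param genotypes An [rv_genotypes] object.
#' @param phenotype 0/1 vector, 1 = affected, aligned to the genotype rows.
#' @param group A [variant_group()] or character vector of gene names.
#' @return A list of class `ws_computation` with elements `q`, `w`, `gamma`,
#'   `rank_sum` and `label`.
#' @examples
#' g <- rv_genotypes(matrix(c(2L, 0L), 2, 1), c("case", "ctrl"), "v1")
#' ws_statistic(g, c(1, 0), variant_group("v1", 1))$rank_sum  # case ranks 2nd
#' @export
ws_statistic <- function(genotypes, phenotype, group) {
  group <- resolve_group(genotypes, group)
  phenotype <- assert_binary_phenotype(phenotype, nrow(genotypes$dosages))
  G <- genotypes$dosages[, group$variant_indices, drop = FALSE]
  k <- ws_kernel(G, matrix(phenotype, ncol = 1L))
  structure(list(q = unname(drop(k$q)), w = unname(drop(k$w)),
                 gamma = unname(drop(k$gamma)),
                 rank_sum = k$x[[1]], label = group$label),
            class = "ws_computation")
}

# all distinct case/control assignments with the observed case count,
# as an n x choose(n, n_case) 0/1 matrix (includes the observed labeling)
all_relabelings <- function(n, n_case) {
  combos <- utils::combn(n, n_case)
  Y <- matrix(0L, nrow = n, ncol = ncol(combos))
  Y[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = n_case))] <- 1L
  Y
}

#' Weighted-sum permutation test
#'
#' Significance of the weighted-sum rank statistic by phenotype permutation:
#' for each permutation the affected/unaffected labels are shuffled and the
#' frequencies, weights, scores and rank sum are all recomputed (the weights
#' depend on who is unaffected). The one-sided p-value is
#' `(1 + #\{x* >= x_obs\}) / (n_permutations + 1)`.
#'
#' With `exhaustive = TRUE` all distinct case/control relabelings with the
#' observed case count are enumerated instead and the p-value is the exact
#' proportion of relabelings (including the observed one) whose statistic
#' reaches the observed value.
#'
#' @inheritParams ws_statistic
#' @param n_permutations Number of phenotype permutations (default 1000).
#' @param seed Integer seed; the permutation stream is derived from
#'   `(seed, group label, replicate)` so results are order-independent.
#' @param replicate Replicate index recorded in the result and used in seed
#'   derivation.
#' @param exhaustive Enumerate all relabelings instead of sampling.
#' @return A one-row [test_result()] tibble with method `"WS"`.
#' @export
ws_test <- function(genotypes, phenotype, group, n_permutations = 1000L,
                    seed = 1L, replicate = 1L, exhaustive = FALSE) {
  group <- resolve_group(genotypes, group)
  phenotype <- assert_binary_phenotype(phenotype, nrow(genotypes$dosages))
  G <- genotypes$dosages[, group$variant_indices, drop = FALSE]
  n <- length(phenotype)
  if (exhaustive) {
    n_case <- sum(phenotype)
    if (choose(n, n_case) > 2e5) {
      stop_rvpath("exhaustive enumeration is limited to 200,000 relabelings.",
                  "rvpath_validation_error")
    }
    Y <- all_relabelings(n, n_case)
    x <- ws_kernel(G, cbind(phenotype, Y))$x
    x_obs <- x[1]
    x_perm <- x[-1]
    p <- mean(x_perm >= x_obs - 1e-12)
    return(test_result(group$label, "WS", x_obs, p, replicate,
                       n_permutations = ncol(Y)))
  }
  if (n_permutations < 1L) {
    stop_rvpath("`n_permutations` must be at least 1.",
                "rvpath_validation_error")
  }
  Y <- with_seed(derive_seed(seed, "ws", group$label, replicate),
                 .perm_matrix(phenotype, n_permutations))
  x <- ws_kernel(G, cbind(phenotype, Y))$x
  x_obs <- x[1]
  b <- sum(x[-1] >= x_obs - 1e-12)
  p <- (1 + b) / (n_permutations + 1)
  test_result(group$label, "WS", x_obs, p, replicate,
              n_permutations = n_permutations)
}
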