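#' Build a CMC design matrix for a variant group
#'
#' Combined multivariate collapsing: variants with MAF below
#' `rare_threshold` are collapsed into a 0/1 presence indicator (1 if the
#' individual carries any rare minor allele in the collapsing unit), while
#' common variants are retained as separate dosage columns. With
#' `grouping = "gene"` each gene in the group is its own collapsing unit;
#' with `grouping = "set"` all rare variants in the group collapse into one
#' indicator. Missing dosages count as 0. Columns constant across
#' individuals carry no information and are dropped with a warning.
#'
#' @inheritParams ws_statistic
#' @param rare_threshold MAF cutoff in (0, 0.5] separating rare from common
#'   variants (default 0.05).
#' @param grouping `"gene"` or `"set"`.
#' @return A `cmc_design` object: list with the design matrix `X`
#'   (individuals x columns), `label`, `rare_threshold`, `grouping`.
#' @export
cmc_design <- function(genotypes, group, rare_threshold = 0.05,
                       grouping = c("gene", "set")) {
  grouping <- match.arg(grouping)
  group <- resolve_group(genotypes, group)
  if (rare_threshold <= 0 || rare_threshold > 0.5) {
    stop_rvpath("`rare_threshold` must be in (0, 0.5].",
                "rvpath_validation_error")
  }
  idx <- group$variant_indices
  G <- genotypes$dosages[, idx, drop = FALSE]
  G[is.na(G)] <- 0L
  maf <- genotypes$variants$maf[idx]
  gene <- genotypes$variants$gene[idx]
  rare <- maf < rare_threshold
  cols <- list()
  if (any(rare)) {
    unit <- if (grouping == "gene") gene[rare] else rep(group$label, sum(rare))
    Gr <- G[, rare, drop = FALSE]
    for (u in unique(unit)) {
      ind <- as.integer(rowSums(Gr[, unit == u, drop = FALSE]) > 0)
      cols[[paste0("rare.", u)]] <- ind
    }
  }
  if (any(!rare)) {
    Gc <- G[, !rare, drop = FALSE]
    for (j in seq_len(ncol(Gc))) {
      cols[[colnames(Gc)[j] %||% paste0("common.", j)]] <- Gc[, j]
    }
  }
  X <- do.call(cbind, cols)
  keep <- apply(X, 2L, function(v) length(unique(v)) > 1L)
  if (!any(keep)) {
    stop_rvpath(sprintf(
      "group '%s': every design column is constant; nothing to test.",
      group$label), "rvpath_degenerate_error")
  }
  if (any(!keep)) {
    warn(sprintf("group '%s': dropped %d constant design column(s).",
                 group$label, sum(!keep)))
    X <- X[, keep, drop = FALSE]
  }
  structure(list(X = X, label = group$label,
                 rare_threshold = rare_threshold, grouping = grouping),
            class = "cmc_design")
}

# Hotelling T^2 for one 0/1 phenotype split of the rows of X.
# Precomputed total cross-moments let the harness reuse them across
# phenotype permutations. Singular pooled covariance falls back to the
# Moore-Penrose pseudo-inverse with rank-adjusted degrees of freedom.
hotelling_stat <- function(X, y, SS_tot = crossprod(X),
                           cs_tot = colSums(X), warn_singular = TRUE) {
  n <- nrow(X)
  p <- ncol(X)
  n1 <- sum(y)
  n2 <- n - n1
  cs1 <- drop(crossprod(X, y))
  m1 <- cs1 / n1
  m2 <- (cs_tot - cs1) / n2
  SS1 <- crossprod(X, X * y)
  S1 <- SS1 - n1 * tcrossprod(m1)
  S2 <- (SS_tot - SS1) - n2 * tcrossprod(m2)
  Sp <- (S1 + S2) / (n - 2)
  d <- m1 - m2
  solved <- tryCatch(list(v = solve(Sp, d), rank = p),
                     error = function(e) NULL)
  rank_deficient <- is.null(solved)
  if (rank_deficient) {
    if (warn_singular) {
      warn("pooled covariance is singular; using pseudo-inverse with rank-adjusted df.")
    }
    gi <- MASS::ginv(Sp)
    solved <- list(v = drop(gi %*% d),
                   rank = qr(Sp)$rank)
  }
  p_eff <- max(solved$rank, 1L)
  t2 <- (n1 * n2 / n) * sum(d * solved$v)
  t2 <- max(t2, 0)
  df2 <- n1 + n2 - p_eff - 1
  Fstat <- t2 * df2 / (p_eff * (n1 + n2 - 2))
  pval <- pf(Fstat, p_eff, df2, lower.tail = FALSE)
  list(t2 = t2, F = Fstat, df1 = p_eff, df2 = df2,
       p = max(pval, .P_FLOOR), rank_deficient = rank_deficient)
}

#' Hotelling's T-squared test on a CMC design
#'
#' Compares the case and control mean vectors of the design columns:
#' `T^2 = (n1 n2 / (n1 + n2)) d' S^-1 d` with `d` the mean-difference vector
#' and `S` the pooled covariance; `F = T^2 (n1 + n2 - p - 1) / (p (n1 + n2 -
#' 2))` is referred to an F(p, n1 + n2 - p - 1) distribution (upper tail).
#' A singular pooled covariance is handled with the Moore-Penrose
#' pseudo-inverse, degrees of freedom taken from the matrix rank, with a
#' warning.
#'
#' @param design A [cmc_design()] object.
#' @param phenotype 0/1 vector aligned to the design rows.
#' @param replicate Replicate index recorded in the result.
#' @return A one-row [test_result()] tibble with method `"CMC"`; the
#'   `statistic` column holds T-squared.
#' @export
hotelling_t2 <- function(design, phenotype, replicate = 1L) {
  if (!inherits(design, "cmc_design")) {
    stop_rvpath("`design` must come from cmc_design().",
                "rvpath_validation_error")
  }
  phenotype <- assert_binary_phenotype(phenotype, nrow(design$X))
  n1 <- sum(phenotype)
  n2 <- length(phenotype) - n1
  if (n1 < 2 || n2 < 2) {
    stop_rvpath("Hotelling's T-squared needs >=2 cases and >=2 controls.",
                "rvpath_validation_error")
  }
  if (n1 + n2 - 2 <= ncol(design$X)) {
    stop_rvpath(sprintf(
      "sample size too small for %d design columns (need n - 2 > p).",
      ncol(design$X)), "rvpath_validation_error")
  }
  h <- hotelling_stat(design$X, phenotype)
  test_result(design$label, "CMC", h$t2, h$p, replicate)
}

#' CMC test for one variant group
#'
#' Composition of [cmc_design()] and [hotelling_t2()]: collapse rare
#' variants, keep common variants, compare case/control mean vectors with
#' the asymptotic Hotelling T-squared distribution.
#'
#' @inheritParams cmc_design
#' @inheritParams hotelling_t2
#' @return A one-row [test_result()] tibble with method `"CMC"`.
#' @export
cmc_test <- function(genotypes, phenotype, group, rare_threshold = 0.05,
                     grouping = c("gene", "set"), replicate = 1L) {
  design <- cmc_design(genotypes, group, rare_threshold, grouping)
  hotelling_t2(design, phenotype, replicate = replicate)
}
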