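# Independent reference implementations used as oracles. These are written
# deliberately as plain loops over the textbook formulas and share no code
# with the package internals.

# weighted-sum rank statistic, loop form
oracle_ws_rank_sum <- function(G, y) {
  n <- nrow(G)
  m <- ncol(G)
  gamma <- numeric(n)
  for (i in seq_len(m)) {
    gi <- G[, i]
    obs <- !is.na(gi)
    unaff <- obs & y == 0
    mU <- sum(gi[unaff])
    nU <- sum(unaff)
    q <- (mU + 1) / (2 * nU + 2)
    w <- sqrt(sum(obs) * q * (1 - q))
    contrib <- ifelse(obs, gi / w, 0)
    gamma <- gamma + ifelse(is.na(contrib), 0, contrib)
  }
  r <- rank(gamma, ties.method = "average")
  sum(r[y == 1])
}

# exact p over all case/control relabelings with the observed case count
oracle_ws_exhaustive_p <- function(G, y) {
  n <- length(y)
  combos <- utils::combn(n, sum(y))
  x_obs <- oracle_ws_rank_sum(G, y)
  xs <- apply(combos, 2, function(idx) {
    yy <- integer(n)
    yy[idx] <- 1L
    oracle_ws_rank_sum(G, yy)
  })
  mean(xs >= x_obs - 1e-9)
}

# Hotelling T^2 and its F-based p-value, direct matrix formula
oracle_hotelling <- function(X, y) {
  X1 <- X[y == 1, , drop = FALSE]
  X2 <- X[y == 0, , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2); p <- ncol(X)
  d <- colMeans(X1) - colMeans(X2)
  S1 <- cov(X1) * (n1 - 1)
  S2 <- cov(X2) * (n2 - 1)
  Sp <- (S1 + S2) / (n1 + n2 - 2)
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(Sp) %*% d)
  Fstat <- t2 * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))
  list(t2 = t2, p = pf(Fstat, p, n1 + n2 - p - 1, lower.tail = FALSE))
}

# GSEA running sum walked gene by gene
oracle_es <- function(genes, scores, set_genes, w = 1) {
  ord <- order(-scores, genes)
  genes <- genes[ord]; scores <- scores[ord]
  hit <- genes %in% set_genes
  nr <- sum(scores[hit]^w)
  running <- 0
  best <- 0
  for (i in seq_along(genes)) {
    if (hit[i]) {
      running <- running + if (nr > 0) scores[i]^w / nr else 1 / sum(hit)
    } else {
      running <- running - 1 / (length(genes) - sum(hit))
    }
    if (abs(running) > abs(best) + 1e-9) best <- running
  }
  best
}

# upper tail of chi-square with even df, closed form:
# P(X > x) = exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!,  k = df/2
oracle_chisq_sf_even <- function(x, df) {
  k <- df / 2
  stopifnot(df %% 2 == 0)
  j <- 0:(k - 1)
  exp(-x / 2) * sum(exp(j * log(x / 2) - lgamma(j + 1)))
}

# small dense genotype fixture with gene labels
toy_genotypes <- function(n = 40, genes = c(A = 3, B = 2), maf = 0.2,
                          seed = 1) {
  withr::with_seed(seed, {
    m <- sum(genes)
    dos <- matrix(rbinom(n * m, 2, maf), n, m)
    # guarantee variation in every column
    for (j in seq_len(m)) {
      if (length(unique(dos[, j])) == 1L) dos[1, j] <- dos[1, j] + 1L
    }
    rv_genotypes(dos,
                 individual_ids = sprintf("i%02d", seq_len(n)),
                 variant_ids = sprintf("v%02d", seq_len(m)),
                 gene = rep(names(genes), genes))
  })
}

toy_phenotype <- function(n = 40, n_case = 15, seed = 2) {
  withr::with_seed(seed, sample(c(rep(1L, n_case), rep(0L, n - n_case))))
}
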