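#' Simulation configuration for the synthetic mini-exome
#'
#' Defaults emulate the structure of the GAW17-style benchmark this package
#' is designed around: 697 unrelated individuals, 3,205 genes, a
#' rare-dominated MAF spectrum with floor 7.17e-4, 160 causal SNPs in 36
#' causal genes driving a dichotomous phenotype, and 200 phenotype
#' replicates simulated on one fixed genotype matrix. [desk_profile()]
#' provides a scaled-down configuration for interactive work and testing.
#'
#' @param n_individuals Number of individuals.
#' @param n_genes Number of genes.
#' @param snps_per_gene Mean SNPs per gene (counts are `1 + Poisson(mean - 1)`
#'   so every gene has at least one SNP).
#' @param maf_spectrum List with `shape1`, `shape2`, `floor`: per-variant MAF
#'   is `floor + (0.5 - floor) * Beta(shape1, shape2)`. The default
#'   Beta(0.2, 2) is dominated by rare variants.
#' @param n_causal_genes Number of causal genes.
#' @param n_causal_snps Total causal SNPs (each causal gene hosts at least
#'   one; must be at least `n_causal_genes`).
#' @param beta_distribution List with `dist` (`"uniform"`, `"fixed"` or
#'   `"lognormal"`) and its parameters; causal log-odds effect sizes.
#' @param target_prevalence Population disease prevalence the intercept is
#'   calibrated to.
#' @param n_replicates Phenotype replicates.
#' @param ld_spurious_genes Number of noncausal genes whose columns are
#'   copied from causal SNPs (inducing linkage-disequilibrium-like
#'   correlation and hence spurious association); 0 disables.
#' @param ld_fidelity Per-allele copy fidelity in (0, 1]; each allele of a
#'   copied column is flipped with probability `1 - ld_fidelity`.
#' @param seed Master integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 697L, n_genes = 3205L,
                       snps_per_gene = 7.6,
                       maf_spectrum = list(shape1 = 0.2, shape2 = 2.0,
                                           floor = 7.17e-4),
                       n_causal_genes = 36L, n_causal_snps = 160L,
                       beta_distribution = list(dist = "uniform",
                                                min = 0.5, max = 2.0),
                       target_prevalence = 0.3, n_replicates = 200L,
                       ld_spurious_genes = 0L, ld_fidelity = 0.98,
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_genes = as.integer(n_genes),
              snps_per_gene = snps_per_gene,
              maf_spectrum = maf_spectrum,
              n_causal_genes = as.integer(n_causal_genes),
              n_causal_snps = as.integer(n_causal_snps),
              beta_distribution = beta_distribution,
              target_prevalence = target_prevalence,
              n_replicates = as.integer(n_replicates),
              ld_spurious_genes = as.integer(ld_spurious_genes),
              ld_fidelity = ld_fidelity,
              seed = as.integer(seed))
  if (cfg$target_prevalence <= 0 || cfg$target_prevalence >= 1) {
    stop_rvpath("`target_prevalence` must lie in (0, 1).",
                "rvpath_validation_error")
  }
  if (cfg$maf_spectrum$floor <= 0 || cfg$maf_spectrum$floor >= 0.5) {
    stop_rvpath("the MAF floor must lie in (0, 0.5).",
                "rvpath_validation_error")
  }
  if (cfg$n_causal_snps < cfg$n_causal_genes) {
    stop_rvpath("`n_causal_snps` must be >= `n_causal_genes` so every causal gene hosts a causal SNP.",
                "rvpath_validation_error")
  }
  if (cfg$ld_fidelity <= 0 || cfg$ld_fidelity > 1) {
    stop_rvpath("`ld_fidelity` must lie in (0, 1].", "rvpath_validation_error")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Desk-scale simulation profile
#'
#' A scaled-down configuration (500 individuals, 300 genes, mean 3 SNPs per
#' gene, 72 causal SNPs in 36 causal genes, 50 replicates) sized so that a
#' full eight-method evaluation completes in minutes on one CPU while
#' preserving the benchmark's qualitative structure.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config` list.
#' @export
desk_profile <- function(...) {
  defaults <- list(n_individuals = 500L, n_genes = 300L, snps_per_gene = 3,
                   n_causal_genes = 36L, n_causal_snps = 72L,
                   n_replicates = 50L)
  do.call(sim_config, modifyList(defaults, list(...)))
}

draw_betas <- function(spec, k) {
  switch(spec$dist,
         uniform = runif(k, spec$min, spec$max),
         fixed = rep(spec$value, k),
         lognormal = stats::rlnorm(k, spec$meanlog, spec$sdlog),
         stop_rvpath(sprintf("unknown beta distribution '%s'.", spec$dist),
                     "rvpath_validation_error"))
}

#' Simulate a mini-exome genotype matrix with a planted disease model
#'
#' Per-variant MAFs are drawn from the configured spectrum; dosages are two
#' independent allele draws per individual (Hardy-Weinberg, variants
#' independent). Causal genes and SNPs are selected and log-odds effect
#' sizes assigned. When `ld_spurious_genes > 0`, that many noncausal genes
#' have their columns replaced by copies of randomly chosen causal-SNP
#' columns with per-allele flip probability `1 - ld_fidelity`, inducing the
#' correlation that creates spurious association. Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `genotypes` ([rv_genotypes], gene-annotated),
#'   `gene_map` (tibble), `truth` ([truth_model()], MAFs are the generating
#'   population values) and `ld_genes` (symbols of the LD-copy genes).
#' @export
simulate_genotypes <- function(config) {
  cfg <- config
  with_seed(derive_seed(cfg$seed, "genotypes"), {
    counts <- 1L + rpois(cfg$n_genes, max(cfg$snps_per_gene - 1, 0))
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    gene_of <- rep(genes, counts)
    M <- length(gene_of)
    vids <- sprintf("v%05d", seq_len(M))
    sp <- cfg$maf_spectrum
    maf <- sp$floor + (0.5 - sp$floor) * rbeta(M, sp$shape1, sp$shape2)
    n <- cfg$n_individuals
    dos <- matrix(rbinom(n * M, 2L, rep(maf, each = n)), nrow = n)
    causal_genes <- sort(sample(genes, cfg$n_causal_genes))
    in_causal <- which(gene_of %in% causal_genes)
    if (length(in_causal) < cfg$n_causal_snps) {
      stop_rvpath(sprintf(
        "infeasible config: %d causal SNPs requested but the %d causal genes hold only %d SNPs.",
        cfg$n_causal_snps, cfg$n_causal_genes, length(in_causal)),
        "rvpath_validation_error")
    }
    first <- vapply(causal_genes,
                    function(g) sample(rep(which(gene_of == g), 2), 1), 0L)
    extra <- sample(setdiff(in_causal, first),
                    cfg$n_causal_snps - length(first))
    causal_idx <- sort(c(first, extra))
    beta <- draw_betas(cfg$beta_distribution, length(causal_idx))
    ld_genes <- character(0)
    if (cfg$ld_spurious_genes > 0L) {
      pool <- setdiff(genes, causal_genes)
      ld_genes <- sort(sample(pool, cfg$ld_spurious_genes))
      # source SNPs weighted by their risk contribution (MAF x beta): a
      # copy only creates spurious association if it carries association
      src_w <- maf[causal_idx] * beta
      if (all(src_w <= 0)) src_w <- rep(1, length(causal_idx))
      for (g in ld_genes) {
        for (j in which(gene_of == g)) {
          src <- dos[, sample(rep(causal_idx, 2), 1,
                              prob = rep(src_w, 2))]
          a1 <- as.integer(src >= 1L)
          a2 <- as.integer(src == 2L)
          flip <- 1 - cfg$ld_fidelity
          if (flip > 0) {
            a1 <- ifelse(runif(n) < flip, 1L - a1, a1)
            a2 <- ifelse(runif(n) < flip, 1L - a2, a2)
          }
          dos[, j] <- a1 + a2
        }
      }
    }
    genotypes <- rv_genotypes(dos, individual_ids = sprintf("ind%04d", 1:n),
                              variant_ids = vids, gene = gene_of)
    gene_map <- tibble::tibble(variant_id = vids, gene = gene_of)
    truth <- truth_model(
      tibble::tibble(variant_id = vids[causal_idx],
                     gene = gene_of[causal_idx],
                     maf = maf[causal_idx], beta = beta),
      causal_genes = causal_genes)
    list(genotypes = genotypes, gene_map = gene_map, truth = truth,
         ld_genes = ld_genes)
  })
}

causal_linear_predictor <- function(truth, genotypes) {
  idx <- match(truth$causal_snps$variant_id,
               genotypes$variants$variant_id)
  if (anyNA(idx)) {
    stop_rvpath("a causal SNP is missing from the genotype matrix.",
                "rvpath_validation_error")
  }
  G <- genotypes$dosages[, idx, drop = FALSE]
  G[is.na(G)] <- 0L
  drop(G %*% truth$causal_snps$beta)
}

#' Calibrate the disease-model intercept to a target prevalence
#'
#' Finds `beta0` such that the mean over individuals of
#' `plogis(beta0 + sum(beta_i g_ij))` equals `target_prevalence` to within
#' 1e-6, by monotone root bracketing on [-50, 50].
#'
#' @param truth A [truth_model()].
#' @param genotypes An [rv_genotypes] containing the causal SNPs.
#' @param target_prevalence Desired mean disease probability in (0, 1).
#' @return The intercept `beta0` (log-odds scale).
#' @export
calibrate_intercept <- function(truth, genotypes, target_prevalence) {
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stop_rvpath("`target_prevalence` must lie in (0, 1).",
                "rvpath_validation_error")
  }
  eta <- causal_linear_predictor(truth, genotypes)
  f <- function(b0) mean(plogis(b0 + eta)) - target_prevalence
  if (f(-50) > 0 || f(50) < 0) {
    stop_rvpath("no intercept in [-50, 50] achieves the target prevalence.",
                "rvpath_validation_error")
  }
  uniroot(f, c(-50, 50), tol = 1e-9)$root
}

#' Simulate phenotype replicates on fixed genotypes
#'
#' Each replicate draws disease status independently per individual as
#' `Bernoulli(plogis(beta0 + sum(beta_i g_ij)))` on the same genotype
#' matrix. A replicate with no cases or no controls is redrawn once; a
#' second degenerate draw is an error.
#'
#' @param truth A [truth_model()].
#' @param genotypes An [rv_genotypes].
#' @param beta0 Disease-model intercept (see [calibrate_intercept()]).
#' @param n_replicates Number of replicates.
#' @param seed Integer seed.
#' @return An [rv_phenotypes] object.
#' @export
simulate_phenotypes <- function(truth, genotypes, beta0, n_replicates,
                                seed = 1L) {
  if (!is.finite(beta0)) {
    stop_rvpath("`beta0` must be finite.", "rvpath_validation_error")
  }
  prob <- plogis(beta0 + causal_linear_predictor(truth, genotypes))
  n <- length(prob)
  with_seed(derive_seed(seed, "phenotypes"), {
    status <- vapply(seq_len(n_replicates), function(r) {
      y <- rbinom(n, 1L, prob)
      if (sum(y) == 0L || sum(y) == n) y <- rbinom(n, 1L, prob)
      if (sum(y) == 0L || sum(y) == n) {
        stop_rvpath(sprintf(
          "replicate %d degenerate twice (prevalence too extreme).", r),
          "rvpath_validation_error")
      }
      y
    }, integer(n))
    rv_phenotypes(status, individual_ids = individual_ids(genotypes))
  })
}

#' Simulate a complete study: genotypes, truth and phenotype replicates
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [calibrate_intercept()] and [simulate_phenotypes()] from one config.
#'
#' @param config A [sim_config()].
#' @return A list with `genotypes`, `gene_map`, `truth`, `ld_genes`,
#'   `beta0`, `phenotypes` and the `config`.
#' @export
simulate_study <- function(config) {
  sim <- simulate_genotypes(config)
  beta0 <- calibrate_intercept(sim$truth, sim$genotypes,
                               config$target_prevalence)
  phen <- simulate_phenotypes(sim$truth, sim$genotypes, beta0,
                              config$n_replicates, seed = config$seed)
  c(sim, list(beta0 = beta0, phenotypes = phen, config = config))
}
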