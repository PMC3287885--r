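#' Genotype matrix container
#'
#' Bundles an individuals-by-variants minor-allele dosage matrix with
#' per-variant metadata (variant id, host gene, minor allele frequency).
#' Dosages count copies of the minor allele, so each non-missing entry is 0,
#' 1 or 2; missing genotypes are `NA`. The stored MAF must agree with the MAF
#' recomputed from the dosages over non-missing individuals,
#' `min(f, 1 - f)` with `f = sum(dosage) / (2 * n_non_missing)`.
#'
#' @param dosages Integer matrix, individuals in rows, variants in columns.
#' @param individual_ids Character vector of unique individual ids.
#' @param variant_ids Character vector of unique variant ids.
#' @param gene Character vector assigning each variant to one gene, or `NULL`.
#' @param maf Optional per-variant MAF; recomputed from `dosages` when `NULL`
#'   and validated against the dosages when supplied.
#' @return An object of class `rv_genotypes`: a list with elements `dosages`
#'   (matrix with ids as dimnames) and `variants` (a tibble with columns
#'   `variant_id`, `gene`, `maf`).
#' @examples
#' g <- rv_genotypes(matrix(c(0L, 2L), 2, 1), c("i1", "i2"), "v1")
#' variant_info(g)$maf  # 0.5: symmetric allele counts
#' @export
rv_genotypes <- function(dosages, individual_ids = rownames(dosages),
                         variant_ids = colnames(dosages),
                         gene = NULL, maf = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(individual_ids) || is.null(variant_ids)) {
    stop_rvpath("individual and variant ids are required.",
                "rvpath_validation_error")
  }
  individual_ids <- as.character(individual_ids)
  variant_ids <- as.character(variant_ids)
  if (anyDuplicated(individual_ids)) {
    stop_rvpath("individual ids must be unique.", "rvpath_validation_error")
  }
  if (anyDuplicated(variant_ids)) {
    stop_rvpath("variant ids must be unique.", "rvpath_validation_error")
  }
  if (nrow(dosages) != length(individual_ids) ||
      ncol(dosages) != length(variant_ids)) {
    stop_rvpath("dosage matrix dimensions do not match the id vectors.",
                "rvpath_validation_error")
  }
  bad <- !is.na(dosages) & !(dosages %in% c(0L, 1L, 2L))
  if (any(bad)) {
    stop_rvpath(sprintf(
      "dosages must be 0, 1, 2 or NA; found value %s at [%d, %d].",
      dosages[which(bad)[1]],
      row(dosages)[which(bad)[1]], col(dosages)[which(bad)[1]]),
      "rvpath_validation_error")
  }
  recomputed <- compute_maf(dosages)
  if (is.null(maf)) {
    maf <- recomputed
  } else {
    off <- abs(maf - recomputed)
    if (any(off > 1e-9, na.rm = TRUE)) {
      i <- which.max(off)
      stop_rvpath(sprintf(
        "stored MAF %.6g for variant '%s' disagrees with recomputed %.6g.",
        maf[i], variant_ids[i], recomputed[i]), "rvpath_validation_error")
    }
  }
  dimnames(dosages) <- list(individual_ids, variant_ids)
  gene <- if (is.null(gene)) NA_character_ else as.character(gene)
  structure(
    list(
      dosages = dosages,
      variants = tibble::tibble(variant_id = variant_ids,
                                gene = gene, maf = as.numeric(maf))
    ),
    class = "rv_genotypes"
  )
}

# per-column MAF over non-missing entries; NaN when a column is all-missing
compute_maf <- function(dosages) {
  n_obs <- colSums(!is.na(dosages))
  f <- colSums(dosages, na.rm = TRUE) / (2 * n_obs)
  pmin(f, 1 - f)
}

#' @export
print.rv_genotypes <- function(x, ...) {
  cat(sprintf("<rv_genotypes> %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  genes <- unique(x$variants$gene)
  cat(sprintf("  genes: %d; MAF range: [%.3g, %.3g]; missing: %d\n",
              sum(!is.na(genes)), min(x$variants$maf), max(x$variants$maf),
              sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.rv_genotypes <- function(x) dim(x$dosages)

#' Per-variant metadata of a genotype matrix
#'
#' @param genotypes An [rv_genotypes] object.
#' @return A tibble with columns `variant_id`, `gene`, `maf`.
#' @export
variant_info <- function(genotypes) genotypes$variants

#' Individual ids of a genotype matrix
#' @param genotypes An [rv_genotypes] object.
#' @return Character vector of individual ids.
#' @export
individual_ids <- function(genotypes) rownames(genotypes$dosages)

#' Attach a SNP-to-gene map to a genotype matrix
#'
#' Every variant must be covered by the map; each variant belongs to exactly
#' one gene.
#'
#' @param genotypes An [rv_genotypes] object.
#' @param gene_map A tibble with columns `variant_id` and `gene`, as returned
#'   by [read_gene_map()].
#' @return The genotype object with the `gene` column of [variant_info()]
#'   filled in.
#' @export
attach_gene_map <- function(genotypes, gene_map) {
  validate_gene_map(gene_map)
  idx <- match(genotypes$variants$variant_id, gene_map$variant_id)
  if (anyNA(idx)) {
    missing <- genotypes$variants$variant_id[which(is.na(idx))[1]]
    stop_rvpath(sprintf("variant '%s' is not covered by the gene map.",
                        missing), "rvpath_validation_error")
  }
  genotypes$variants$gene <- gene_map$gene[idx]
  genotypes
}

#' Read a genotype matrix from TSV or VCF
#'
#' The TSV dialect is individual-major: one row per individual, first column
#' `individual_id`, remaining columns one per variant (header row carries the
#' variant ids), entries the minor-allele dosage 0/1/2 with missing genotypes
#' written as `NA`. VCF input (4.x, via the vcfR parser) uses the GT field:
#' `0/0` maps to 0, `0/1` and `1/0` to 1, `1/1` to 2 and `./.` to missing;
#' dosages are re-oriented to count the in-sample minor allele when the ALT
#' allele is the major one. Multi-allelic records are rejected.
#'
#' @param path File to read.
#' @param format `"tsv"` or `"vcf"`.
#' @return An [rv_genotypes] object.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_rvpath(sprintf("file '%s' does not exist.", path), "rvpath_io_error")
  }
  switch(format,
         tsv = read_genotypes_tsv(path),
         vcf = read_genotypes_vcf(path))
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) {
    stop_rvpath(sprintf("'%s': need an id column plus >=1 variant column.",
                        path), "rvpath_parse_error")
  }
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "integer")
  raw <- as.matrix(df[, -1, drop = FALSE])
  introduced <- is.na(mat) & !(raw %in% c("NA", "")) & !is.na(raw)
  if (any(introduced)) {
    bad <- which(introduced, arr.ind = TRUE)[1, ]
    stop_rvpath(sprintf(
      "'%s' line %d: non-numeric dosage '%s' for variant '%s'.",
      path, bad[1] + 1L, raw[introduced][1], colnames(raw)[bad[2]]),
      "rvpath_parse_error")
  }
  rv_genotypes(mat, individual_ids = ids, variant_ids = colnames(df)[-1])
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_rvpath("VCF input requires the vcfR package.", "rvpath_io_error")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- if (is.null(dim(fix))) matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix))) else fix
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop_rvpath(sprintf(
      "multi-allelic record at %s:%s is not supported.",
      fix[multi, "CHROM"][1], fix[multi, "POS"][1]),
      "rvpath_unsupported_record")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dos[gt %in% c("0/0", "0")] <- 0L
  dos[gt %in% c("0/1", "1/0")] <- 1L
  dos[gt %in% c("1/1", "1")] <- 2L
  unknown <- !is.na(gt) & is.na(dos) & !(gt %in% c("./.", "."))
  if (any(unknown)) {
    stop_rvpath(sprintf("unparseable GT value '%s' in '%s'.",
                        gt[unknown][1], path), "rvpath_parse_error")
  }
  dos <- t(dos)  # individuals x variants
  ids <- colnames(gt)
  vids <- fix[, "ID"]
  nameless <- is.na(vids) | vids == "."
  vids[nameless] <- paste0(fix[nameless, "CHROM"], ":", fix[nameless, "POS"])
  # orient to the in-sample minor allele
  f_alt <- colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
  flip <- which(!is.na(f_alt) & f_alt > 0.5)
  if (length(flip)) dos[, flip] <- 2L - dos[, flip]
  rv_genotypes(dos, individual_ids = ids, variant_ids = vids)
}

#' Write a genotype matrix as TSV
#'
#' Inverse of [read_genotypes()] with `format = "tsv"`; missing dosages are
#' written as `NA`.
#'
#' @param genotypes An [rv_genotypes] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(individual_id = individual_ids(genotypes),
                   genotypes$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
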