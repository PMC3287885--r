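#' Phenotype replicate container
#'
#' A binary individuals-by-replicates disease-status matrix (1 = affected).
#' Every replicate column must contain at least one affected and one
#' unaffected individual so that case/control tests are defined.
#'
#' @param status Integer 0/1 matrix, individuals in rows, replicates in
#'   columns.
#' @param individual_ids Character vector of unique individual ids.
#' @return An object of class `rv_phenotypes` wrapping the status matrix.
#' @export
rv_phenotypes <- function(status, individual_ids = rownames(status)) {
  status <- as.matrix(status)
  storage.mode(status) <- "integer"
  if (is.null(individual_ids)) {
    stop_rvpath("individual ids are required.", "rvpath_validation_error")
  }
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(individual_ids)) {
    stop_rvpath("individual ids must be unique.", "rvpath_validation_error")
  }
  if (nrow(status) != length(individual_ids)) {
    stop_rvpath("status matrix rows do not match individual ids.",
                "rvpath_validation_error")
  }
  if (anyNA(status) || !all(status %in% c(0L, 1L))) {
    stop_rvpath("phenotype status must be 0/1 with no missing values.",
                "rvpath_validation_error")
  }
  cs <- colSums(status)
  degen <- cs == 0L | cs == nrow(status)
  if (any(degen)) {
    stop_rvpath(sprintf(
      "replicate %d has no %s individuals.", which(degen)[1],
      if (cs[which(degen)[1]] == 0L) "affected" else "unaffected"),
      "rvpath_validation_error")
  }
  rownames(status) <- individual_ids
  if (is.null(colnames(status))) {
    colnames(status) <- paste0("rep", seq_len(ncol(status)))
  }
  structure(list(status = status), class = "rv_phenotypes")
}

#' @export
print.rv_phenotypes <- function(x, ...) {
  cat(sprintf("<rv_phenotypes> %d individuals x %d replicates; mean prevalence %.3f\n",
              nrow(x$status), ncol(x$status), mean(x$status)))
  invisible(x)
}

#' @export
dim.rv_phenotypes <- function(x) dim(x$status)

#' Number of phenotype replicates
#' @param phenotypes An [rv_phenotypes] object.
#' @return Integer count of replicate columns.
#' @export
n_replicates <- function(phenotypes) ncol(phenotypes$status)

#' Extract one phenotype replicate as a 0/1 vector
#' @param phenotypes An [rv_phenotypes] object.
#' @param replicate Column index.
#' @return Named integer vector of disease status.
#' @export
phenotype_replicate <- function(phenotypes, replicate = 1L) {
  phenotypes$status[, replicate]
}

#' Align phenotype replicates to a genotype matrix
#'
#' Reorders phenotype rows to match the genotype individual order; every
#' genotyped individual must be present.
#'
#' @param phenotypes An [rv_phenotypes] object.
#' @param genotypes An [rv_genotypes] object.
#' @return The phenotype object with rows in genotype order.
#' @export
align_phenotypes <- function(phenotypes, genotypes) {
  ids <- individual_ids(genotypes)
  idx <- match(ids, rownames(phenotypes$status))
  if (anyNA(idx)) {
    stop_rvpath(sprintf("individual '%s' has genotypes but no phenotype.",
                        ids[which(is.na(idx))[1]]), "rvpath_validation_error")
  }
  if (length(idx) != nrow(phenotypes$status)) {
    stop_rvpath("phenotype rows do not match the genotyped individuals.",
                "rvpath_validation_error")
  }
  rv_phenotypes(phenotypes$status[idx, , drop = FALSE], individual_ids = ids)
}

#' Read phenotype replicates from TSV
#'
#' One row per individual: first column `individual_id`, remaining columns
#' one 0/1 status per replicate.
#'
#' @param path File to read.
#' @return An [rv_phenotypes] object.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) {
    stop_rvpath(sprintf("file '%s' does not exist.", path), "rvpath_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rv_phenotypes(mat, individual_ids = df[[1]])
}

#' Write phenotype replicates as TSV
#' @param phenotypes An [rv_phenotypes] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- data.frame(individual_id = rownames(phenotypes$status),
                   phenotypes$status, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
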