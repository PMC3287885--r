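#' Read a SNP-to-gene map
#'
#' Two-column tab-separated file (`variant_id`, `gene`), with or without a
#' header row. Each variant must map to exactly one gene; duplicated
#' identical rows are collapsed, conflicting assignments are an error.
#'
#' @param path File to read.
#' @return A tibble with columns `variant_id` and `gene`.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) {
    stop_rvpath(sprintf("file '%s' does not exist.", path), "rvpath_io_error")
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    stop_rvpath(sprintf("gene map '%s' is empty.", path),
                "rvpath_validation_error")
  }
  has_header <- grepl("^variant_id\t", first)
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0) {
    stop_rvpath(sprintf("gene map '%s' is empty.", path),
                "rvpath_validation_error")
  }
  if (ncol(df) != 2) {
    stop_rvpath(sprintf("gene map '%s' must have exactly 2 columns, found %d.",
                        path, ncol(df)), "rvpath_parse_error")
  }
  names(df) <- c("variant_id", "gene")
  map <- tibble::as_tibble(unique(df))
  validate_gene_map(map)
  map
}

validate_gene_map <- function(map) {
  if (!all(c("variant_id", "gene") %in% names(map))) {
    stop_rvpath("a gene map needs `variant_id` and `gene` columns.",
                "rvpath_validation_error")
  }
  dup <- duplicated(map$variant_id)
  if (any(dup)) {
    stop_rvpath(sprintf("variant '%s' is assigned to more than one gene.",
                        map$variant_id[dup][1]), "rvpath_validation_error")
  }
  invisible(map)
}

#' Write a SNP-to-gene map as TSV
#' @param gene_map Tibble with columns `variant_id`, `gene`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(gene_map, path) {
  validate_gene_map(gene_map)
  utils::write.table(gene_map[, c("variant_id", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
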