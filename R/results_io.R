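#' Assemble a test-result row
#'
#' Every gene- or set-level test in rvpath returns a one-row tibble in this
#' shape so results can be bound, filtered and written uniformly.
#'
#' @param unit_id Gene or set identifier.
#' @param method One of `WS`, `CMC`, `WS_Fisher`, `CMC_Fisher`, `WS_GSEA`,
#'   `CMC_GSEA`, `WS_KS`, `CMC_KS`.
#' @param statistic Test statistic value.
#' @param p_value P-value in (0, 1].
#' @param replicate Phenotype replicate index.
#' @param n_permutations Number of permutations, or `NA` for asymptotic
#'   tests.
#' @return A one-row tibble with those columns.
#' @export
test_result <- function(unit_id, method, statistic, p_value,
                        replicate = 1L, n_permutations = NA_integer_) {
  method <- match.arg(method, RV_METHODS)
  if (!is.na(p_value) && (p_value <= 0 || p_value > 1)) {
    stop_rvpath(sprintf("p-value %g outside (0, 1].", p_value),
                "rvpath_validation_error")
  }
  tibble::tibble(unit_id = as.character(unit_id), method = method,
                 replicate = as.integer(replicate),
                 statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value),
                 n_permutations = as.integer(n_permutations))
}

#' The eight pathway/gene testing methods
#'
#' Direct burden methods (`WS`, `CMC`) and gene-level aggregation methods
#' (Fisher, KS and GSEA applied to WS or CMC gene p-values).
#' @export
RV_METHODS <- c("WS", "CMC", "WS_Fisher", "CMC_Fisher",
                "WS_GSEA", "CMC_GSEA", "WS_KS", "CMC_KS")

#' Write test results or evaluation rates as TSV
#'
#' Test-result tables are written with fixed column order
#' `unit_id, method, replicate, statistic, p_value, n_permutations`;
#' rate summaries (from [evaluate_methods()]) with
#' `set, method, alpha, rate, n_replicates`. Floats are written at 6
#' significant digits.
#'
#' @param results A non-empty tibble of test results or summary rates.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    stop_rvpath("`results` is empty; nothing to write.",
                "rvpath_validation_error")
  }
  if (all(c("unit_id", "method", "p_value") %in% names(results))) {
    cols <- c("unit_id", "method", "replicate", "statistic", "p_value",
              "n_permutations")
    df <- as.data.frame(results[, intersect(cols, names(results))])
  } else if (all(c("set_id", "method", "alpha", "rate") %in% names(results))) {
    cols <- c("set_id", "method", "alpha", "rate", "n_replicates")
    df <- as.data.frame(results[, intersect(cols, names(results))])
  } else {
    stop_rvpath("unrecognized results table shape.", "rvpath_validation_error")
  }
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    stop_rvpath(sprintf("could not write '%s'.", path), "rvpath_io_error")
  }
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#' @param path File to read.
#' @return A tibble.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    stop_rvpath(sprintf("file '%s' does not exist.", path), "rvpath_io_error")
  }
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
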