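SET_CATEGORIES <- c("causal_mix", "null", "null_nonspurious",
                    "causal_mix_nonspurious", "user")

#' Construct a gene-set collection tibble
#'
#' Gene sets are held as a tibble with one row per set: `set_id`, `category`
#' and a `genes` list-column of character vectors. Genes must be unique
#' within a set and every set non-empty.
#'
#' @param set_id Character vector of unique set names.
#' @param genes List of character vectors of gene symbols.
#' @param category Set category; one of `"causal_mix"`, `"null"`,
#'   `"null_nonspurious"`, `"causal_mix_nonspurious"`, `"user"`. Recycled.
#' @return A `gene_sets` tibble.
#' @export
gene_sets <- function(set_id, genes, category = "user") {
  if (anyDuplicated(set_id)) {
    stop_rvpath(sprintf("duplicate set name '%s'.",
                        set_id[duplicated(set_id)][1]),
                "rvpath_validation_error")
  }
  if (!all(category %in% SET_CATEGORIES)) {
    stop_rvpath(sprintf("unknown set category '%s'.",
                        setdiff(category, SET_CATEGORIES)[1]),
                "rvpath_validation_error")
  }
  genes <- lapply(genes, as.character)
  empty <- lengths(genes) == 0L
  if (any(empty)) {
    stop_rvpath(sprintf("set '%s' is empty.", set_id[empty][1]),
                "rvpath_validation_error")
  }
  dup_in <- vapply(genes, anyDuplicated, 0L) > 0L
  if (any(dup_in)) {
    stop_rvpath(sprintf("set '%s' lists a gene twice.", set_id[dup_in][1]),
                "rvpath_validation_error")
  }
  out <- tibble::tibble(set_id = as.character(set_id),
                        category = rep_len(category, length(set_id)),
                        genes = genes)
  class(out) <- c("gene_sets", class(out))
  out
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#' Duplicate symbols within a line are removed with a warning; duplicate set
#' names across lines are an error. All sets read this way get category
#' `"user"`.
#'
#' @param path GMT file to read.
#' @return A `gene_sets` tibble (see [gene_sets()]).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) {
    stop_rvpath(sprintf("file '%s' does not exist.", path), "rvpath_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop_rvpath(sprintf("'%s' line %d: a GMT line needs name, description and >=1 gene.",
                        path, which(short)[1]), "rvpath_parse_error")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  genes <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warn(sprintf("set '%s': duplicate gene symbols removed.", f[[1]]))
      g <- unique(g)
    }
    g
  })
  gene_sets(nm, genes, category = "user")
}

#' Write gene sets as a GMT file
#'
#' The set category is stored in the GMT description field.
#'
#' @param sets A `gene_sets` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_id[i], sets$category[i], sets$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
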