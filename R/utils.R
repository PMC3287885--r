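#' @importFrom rlang abort warn .data
#' @importFrom stats pchisq pf plogis qlogis rbeta rbinom rpois runif
#'   uniroot var glm binomial coef vcov setNames
#' @importFrom utils head modifyList
NULL

# floor applied to asymptotic p-values before -log transforms
.P_FLOOR <- 1e-300

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_rvpath <- function(msg, class) {
  abort(msg, class = c(class, "rvpath_error"))
}

assert_binary_phenotype <- function(phenotype, n = NULL) {
  if (anyNA(phenotype) || !all(phenotype %in% c(0, 1))) {
    stop_rvpath("`phenotype` must be a 0/1 vector without missing values.",
                "rvpath_validation_error")
  }
  if (!is.null(n) && length(phenotype) != n) {
    stop_rvpath(sprintf(
      "`phenotype` has length %d but the genotype matrix has %d individuals.",
      length(phenotype), n), "rvpath_validation_error")
  }
  if (sum(phenotype) == 0L || sum(phenotype) == length(phenotype)) {
    stop_rvpath("`phenotype` must contain both affected and unaffected individuals.",
                "rvpath_validation_error")
  }
  as.integer(phenotype)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in rvpath flows from one master seed; subordinate random
#' streams (per gene, per set, per replicate) use seeds derived by hashing the
#' master seed together with string/integer tags, so results do not depend on
#' the order in which units are processed.
#'
#' @param seed Master integer seed.
#' @param ... Additional tags (strings or integers) identifying the stream.
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "\r")
  bytes <- utf8ToInt(tags)
  h <- 104729
  m <- 2147483647
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# midranks of each column; returns matrix of same shape
col_midranks <- function(x) {
  if (is.null(dim(x))) return(rank(x, ties.method = "average"))
  apply(x, 2L, rank, ties.method = "average")
}
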