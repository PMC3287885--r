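#' Logistic characterization of when the WS method wins
#'
#' Fits a maximum-likelihood logistic regression of the indicator "WS was
#' the best method for this set" (WS belongs to the argmax of
#' significant-replicate counts at alpha = 0.05) on the five set features
#' from [set_features()]: number of causal genes, number of causal SNPs,
#' total SNPs, average causal-gene MAF and the weighted risk score. Under
#' complete separation the fit is flagged and refitted with a small ridge
#' penalty (glmnet) as a fallback; penalized coefficients carry no standard
#' errors.
#'
#' @param summary Either an `rv_evaluation` with features attached, or a
#'   data frame containing a logical/0-1 `ws_best` column and the five
#'   feature columns.
#' @return An object of class `rv_best_fit` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
best_method_regression <- function(summary) {
  feats <- c("n_causal_genes", "n_causal_snps", "n_total_snps",
             "avg_maf_causal_genes", "weighted_risk_score")
  if (inherits(summary, "rv_evaluation")) {
    if (is.null(summary$features)) {
      stop_rvpath("evaluation has no set features; rerun with `truth` and `gene_map`.",
                  "rvpath_validation_error")
    }
    ws <- summary$best[summary$best$method == "WS", ]
    if (nrow(ws) == 0L) {
      stop_rvpath("the evaluation does not include the WS method.",
                  "rvpath_validation_error")
    }
    df <- dplyr::inner_join(summary$features,
                            ws[, c("set_id", "is_best")], by = "set_id")
    df$ws_best <- df$is_best
  } else {
    df <- as.data.frame(summary)
    if (!"ws_best" %in% names(df)) {
      stop_rvpath("`summary` must contain a `ws_best` column.",
                  "rvpath_validation_error")
    }
  }
  missing_feats <- setdiff(feats, names(df))
  if (length(missing_feats)) {
    stop_rvpath(sprintf("missing feature column(s): %s.",
                        paste(missing_feats, collapse = ", ")),
                "rvpath_validation_error")
  }
  y <- as.integer(df$ws_best)
  if (length(unique(y)) < 2L) {
    stop_rvpath("the WS-best outcome is constant; nothing to model.",
                "rvpath_degenerate_error")
  }
  form <- stats::as.formula(paste("ws_best ~", paste(feats, collapse = " + ")))
  df$ws_best <- y
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = df, family = binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("did not converge", msg)) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged || any(abs(coef(fit)[-1]) > 50, na.rm = TRUE)) {
    separated <- TRUE
  }
  coefs <- summary(fit)$coefficients
  tidy_tbl <- tibble::tibble(term = rownames(coefs),
                             estimate = coefs[, 1],
                             std.error = coefs[, 2],
                             statistic = coefs[, 3],
                             p.value = coefs[, 4])
  penalized <- FALSE
  if (separated && requireNamespace("glmnet", quietly = TRUE)) {
    warn("separation detected; reporting ridge-penalized coefficients.")
    X <- as.matrix(df[, feats])
    gfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = 1e-3)
    cf <- as.numeric(coef(gfit))
    tidy_tbl <- tibble::tibble(term = c("(Intercept)", feats),
                               estimate = cf,
                               std.error = NA_real_,
                               statistic = NA_real_,
                               p.value = NA_real_)
    penalized <- TRUE
  }
  structure(list(fit = fit, tidy = tidy_tbl,
                 separated = separated, penalized = penalized,
                 n = nrow(df), n_ws_best = sum(y)),
            class = "rv_best_fit")
}

#' @export
print.rv_best_fit <- function(x, ...) {
  cat(sprintf("<rv_best_fit> n = %d sets (%d WS-best)%s\n", x$n, x$n_ws_best,
              if (x$separated) " [separation flagged]" else ""))
  print(x$tidy)
  invisible(x)
}

#' Coefficient table of a best-method regression
#' @param x An `rv_best_fit` from [best_method_regression()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.rv_best_fit <- function(x, ...) x$tidy

#' One-row fit summary of a best-method regression
#' @inheritParams tidy.rv_best_fit
#' @return A tibble with fit diagnostics and the separation flag.
#' @export
glance.rv_best_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_ws_best = x$n_ws_best,
                 deviance = stats::deviance(x$fit),
                 aic = stats::AIC(x$fit),
                 separated = x$separated, penalized = x$penalized)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
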