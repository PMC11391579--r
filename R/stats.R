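#' Validate a benchmark results table
#'
#' The benchmark table is a long-format data.frame with one row per
#' (protein, prediction method): columns `protein_id`, `expt_method`
#' (`"nmr"`/`"xray"`), `ss_class` (`"alpha"`, `"beta"`, `"alpha_beta"`),
#' `method`, and the correlation coefficients `r_p`, `r_s` in \[-1, 1\].
#' Extra columns (e.g. `n_residues`) are allowed and preserved.
#'
#' @param df A data.frame.
#' @return The validated data.frame with class `"benchmark_table"` prepended.
#' @export
benchmark_table <- function(df) {
  req <- c("protein_id", "expt_method", "ss_class", "method", "r_p", "r_s")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("benchmark_table: missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!all(df$expt_method %in% c("nmr", "xray")))
    stop("benchmark_table: expt_method must be 'nmr' or 'xray'")
  if (!all(df$ss_class %in% c("alpha", "beta", "alpha_beta")))
    stop("benchmark_table: ss_class must be alpha/beta/alpha_beta")
  ok <- stats::complete.cases(df[, c("r_p", "r_s")])
  if (any(abs(df$r_p[ok]) > 1 + 1e-9) || any(abs(df$r_s[ok]) > 1 + 1e-9))
    stop("benchmark_table: correlation coefficients must lie in [-1, 1]")
  if (anyDuplicated(df[, c("protein_id", "method")]))
    stop("benchmark_table: one row per (protein, method) required")
  class(df) <- unique(c("benchmark_table", class(df)))
  df
}

#' Two-way ANOVA of correlation coefficients
#'
#' Fixed-effects two-way analysis of variance of a correlation coefficient
#' on prediction method and secondary-structure class, with interaction,
#' carried out separately per structure-determination method. Type II sums
#' of squares are used so unbalanced class sizes are handled by the
#' standard main-effects convention.
#'
#' @param table A [benchmark_table()] (or coercible data.frame).
#' @param response `"r_p"` or `"r_s"`.
#' @param expt_method Optional filter: `"nmr"` or `"xray"`.
#' @param alpha Significance level used to flag effects.
#' @return A data.frame with one row per term (`method`, `ss_class`,
#'   `method:ss_class`, `Residuals`): `sum_sq`, `df`, `F`, `p`,
#'   `significant`.
#' @export
two_way_anova <- function(table, response = c("r_p", "r_s"),
                          expt_method = NULL, alpha = 0.05) {
  response <- match.arg(response)
  df <- as.data.frame(table)
  if (!is.null(expt_method)) df <- df[df$expt_method == expt_method, ]
  df <- df[stats::complete.cases(df[, c(response, "method", "ss_class")]), ]
  df$method <- factor(df$method)
  df$ss_class <- factor(df$ss_class)
  if (nlevels(df$method) < 2L || nlevels(df$ss_class) < 2L)
    stop("two_way_anova: each factor needs at least 2 non-empty levels")
  df$.resp <- df[[response]]
  fit <- stats::lm(.resp ~ method * ss_class, data = df)
  if (stats::df.residual(fit) < 1L)
    stop("two_way_anova: zero residual degrees of freedom")
  if (sum(stats::residuals(fit)^2) < 1e-24 &&
      stats::var(df$.resp) < 1e-24)
    stop("two_way_anova: degenerate design (all responses identical)")
  a2 <- car::Anova(fit, type = 2)
  out <- data.frame(term = rownames(a2),
                    sum_sq = a2[["Sum Sq"]],
                    df = a2[["Df"]],
                    F = a2[["F value"]],
                    p = a2[["Pr(>F)"]],
                    row.names = NULL)
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}

#' Pairwise Student's test between two prediction methods
#'
#' Compares the per-protein correlation coefficients of two methods over
#' the shared proteins. The default is a paired two-sided t-test on the
#' per-protein differences (the same proteins are scored under each
#' method); `paired = FALSE` gives an unpaired test.
#'
#' @param table A [benchmark_table()] (or coercible data.frame).
#' @param method_a,method_b Method names to compare (A minus B).
#' @param response `"r_p"` or `"r_s"`.
#' @param expt_method Optional filter: `"nmr"` or `"xray"`.
#' @param ss_class Optional filter on secondary-structure class.
#' @param paired Paired test (default) or unpaired.
#' @return A list: `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
pairwise_t <- function(table, method_a, method_b,
                       response = c("r_p", "r_s"), expt_method = NULL,
                       ss_class = NULL, paired = TRUE) {
  response <- match.arg(response)
  df <- as.data.frame(table)
  if (!is.null(expt_method)) df <- df[df$expt_method == expt_method, ]
  if (!is.null(ss_class)) df <- df[df$ss_class == ss_class, ]
  a <- df[df$method == method_a, c("protein_id", response)]
  b <- df[df$method == method_b, c("protein_id", response)]
  shared <- intersect(a$protein_id, b$protein_id)
  if (length(shared) < 3L)
    stop("pairwise_t: fewer than 3 shared proteins after filtering")
  xa <- a[[response]][match(shared, a$protein_id)]
  xb <- b[[response]][match(shared, b$protein_id)]
  keep <- is.finite(xa) & is.finite(xb)
  xa <- xa[keep]; xb <- xb[keep]
  if (length(xa) < 3L)
    stop("pairwise_t: fewer than 3 complete shared proteins")
  if (paired && stats::sd(xa - xb) == 0) {
    if (all(xa == xb))
      return(list(t = 0, df = length(xa) - 1L, p = 1,
                  mean_diff = 0, n = length(xa)))
    stop("pairwise_t: zero-variance differences; test degenerate")
  }
  tt <- if (paired) stats::t.test(xa, xb, paired = TRUE)
        else stats::t.test(xa, xb, paired = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(xa) - mean(xb), n = length(xa))
}

#' Signed significance matrix of method comparisons
#'
#' Builds the method-by-method grid of pairwise Student's tests: the upper
#' triangle classifies the Pearson coefficient (`r_p`), the lower triangle
#' the Spearman coefficient (`r_s`). Cell (A, B) is
#' `"positive_significant"` when method A (row) beats method B (column) at
#' level `alpha`, `"negative_significant"` when it is significantly worse,
#' and `"not_significant"` otherwise. No multiple-testing correction is
#' applied across cells.
#'
#' @param table A [benchmark_table()] (or coercible data.frame).
#' @param methods Method names to include (default: all in the table).
#' @param alpha Significance level.
#' @param expt_method,ss_class Optional filters.
#' @param paired Passed to [pairwise_t()].
#' @return A list of class `"significance_matrix"`: `classification`
#'   (character matrix), `p` and `t` (numeric matrices), `alpha`.
#' @export
significance_matrix <- function(table, methods = NULL, alpha = 0.05,
                                expt_method = NULL, ss_class = NULL,
                                paired = TRUE) {
  df <- as.data.frame(table)
  if (is.null(methods)) methods <- sort(unique(df$method))
  k <- length(methods)
  if (k < 2L) stop("significance_matrix: at least 2 methods required")
  cls <- matrix(NA_character_, k, k, dimnames = list(methods, methods))
  pm <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  tm <- pm
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    response <- if (i < j) "r_p" else "r_s"   # upper: Pearson, lower: Spearman
    res <- pairwise_t(df, methods[i], methods[j], response = response,
                      expt_method = expt_method, ss_class = ss_class,
                      paired = paired)
    pm[i, j] <- res$p
    tm[i, j] <- res$t
    cls[i, j] <- if (res$p >= alpha || !is.finite(res$p)) "not_significant"
                 else if (res$mean_diff > 0) "positive_significant"
                 else "negative_significant"
  }
  structure(list(classification = cls, p = pm, t = tm, alpha = alpha,
                 methods = methods),
            class = "significance_matrix")
}

#' @export
print.significance_matrix <- function(x, ...) {
  cat(sprintf("Significance matrix (alpha = %g; upper: r_p, lower: r_s)\n",
              x$alpha))
  abbrev <- matrix(".", nrow(x$classification), ncol(x$classification),
                   dimnames = dimnames(x$classification))
  abbrev[x$classification == "positive_significant"] <- "+"
  abbrev[x$classification == "negative_significant"] <- "-"
  print(abbrev, quote = FALSE)
  invisible(x)
}
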