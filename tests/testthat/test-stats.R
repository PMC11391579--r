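# Small benchmark-table builder: one row per (protein, method).
make_table <- function(r_by_method, expt = "nmr", classes = NULL) {
  methods <- names(r_by_method)
  n <- length(r_by_method[[1]])
  if (is.null(classes)) classes <- rep("alpha", n)
  do.call(rbind, lapply(methods, function(m)
    data.frame(protein_id = sprintf("P%02d", seq_len(n)),
               expt_method = expt, ss_class = classes, method = m,
               r_p = r_by_method[[m]], r_s = r_by_method[[m]])))
}

test_that("balanced 2x2 ANOVA matches the closed-form decomposition", {
  # 2 methods x 2 classes, 2 proteins per cell
  y <- c(0.70, 0.80, 0.50, 0.60,    # method A: alpha alpha beta beta
         0.40, 0.50, 0.45, 0.35)    # method B
  df <- data.frame(
    protein_id = sprintf("P%d", c(1:4, 1:4)),
    expt_method = "nmr",
    ss_class = rep(c("alpha", "alpha", "beta", "beta"), 2),
    method = rep(c("A", "B"), each = 4),
    r_p = y, r_s = y)
  res <- two_way_anova(df, response = "r_p")

  grand <- mean(y)
  cell <- tapply(y, list(df$method, df$ss_class), mean)
  m_a <- rowMeans(cell); m_b <- colMeans(cell)
  ss_method <- 4 * sum((m_a - grand)^2)
  ss_class <- 4 * sum((m_b - grand)^2)
  ss_int <- 2 * sum((cell - outer(m_a, rep(1, 2)) -
                       outer(rep(1, 2), m_b) + grand)^2)
  ss_err <- sum((y - cell[cbind(df$method, df$ss_class)])^2)

  got <- setNames(res$sum_sq, res$term)
  expect_equal(got[["method"]], ss_method, tolerance = 1e-10)
  expect_equal(got[["ss_class"]], ss_class, tolerance = 1e-10)
  expect_equal(got[["method:ss_class"]], ss_int, tolerance = 1e-10)
  expect_equal(got[["Residuals"]], ss_err, tolerance = 1e-10)
  f <- setNames(res$F, res$term)
  expect_equal(f[["method"]], (ss_method / 1) / (ss_err / 4),
               tolerance = 1e-10)
  expect_true(all(res$p[!is.na(res$p)] > 0 & res$p[!is.na(res$p)] <= 1))
  expect_true(all(res$F[!is.na(res$F)] >= 0))

  # on a balanced design Type II equals the classical sequential table
  df$.resp <- df$r_p
  seq_tab <- stats::anova(stats::lm(.resp ~ method * ss_class, data = df))
  expect_equal(got[["method"]], seq_tab["method", "Sum Sq"],
               tolerance = 1e-12)
  expect_equal(got[["ss_class"]], seq_tab["ss_class", "Sum Sq"],
               tolerance = 1e-12)
})

test_that("degenerate ANOVA designs are rejected", {
  df <- make_table(list(A = rep(0.5, 6), B = rep(0.5, 6)),
                   classes = rep(c("alpha", "beta"), 3))
  expect_error(two_way_anova(df, response = "r_p"), "degenerate")

  one_level <- make_table(list(A = runif(6, 0, 1)),
                          classes = rep(c("alpha", "beta"), 3))
  expect_error(two_way_anova(one_level, response = "r_p"), "2 non-empty")
})

test_that("paired Student's test matches hand computation and symmetry", {
  a <- c(0.5, 0.6, 0.7); b <- a - c(0.1, 0.2, 0.3)  # differences mean 0.2
  df <- make_table(list(A = a, B = b))
  res <- pairwise_t(df, "A", "B", response = "r_p")
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$mean_diff, 0.2, tolerance = 1e-12)

  swapped <- pairwise_t(df, "B", "A", response = "r_p")
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)

  same <- pairwise_t(make_table(list(A = a, B = a)), "A", "B", "r_p")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # a constant nonzero shift has zero-variance differences: degenerate
  expect_error(pairwise_t(make_table(list(A = a + 0.05, B = a)), "A", "B",
                          "r_p"), "zero-variance")
})

test_that("t statistic sign follows a constant offset with jitter", {
  set.seed(12)
  base <- runif(10, 0.2, 0.6)
  jit <- rnorm(10, sd = 0.02)
  df <- make_table(list(A = base + 0.1 + jit, B = base))
  expect_gt(pairwise_t(df, "A", "B", "r_p")$t, 0)
  df2 <- make_table(list(A = base - 0.1 + jit, B = base))
  expect_lt(pairwise_t(df2, "A", "B", "r_p")$t, 0)
})

test_that("significance matrix classifies separation and is antisymmetric", {
  set.seed(13)
  n <- 12
  truth <- runif(n, 0.6, 0.95)
  tab <- make_table(list(good = pmin(truth + rnorm(n, sd = 0.02), 1),
                         bad = -truth / 2 + rnorm(n, sd = 0.05),
                         mid = truth - 0.3 + rnorm(n, sd = 0.05)))
  sm <- significance_matrix(tab, expt_method = "nmr")
  expect_equal(sm$classification["bad", "good"], "negative_significant")
  expect_equal(sm$classification["good", "bad"], "positive_significant")
  # sign antisymmetry across the diagonal for every pair
  flip <- c(positive_significant = "negative_significant",
            negative_significant = "positive_significant",
            not_significant = "not_significant")
  for (i in rownames(sm$classification)) for (j in colnames(sm$classification))
    if (i != j)
      expect_equal(unname(flip[sm$classification[i, j]]),
                   sm$classification[j, i])

  same <- significance_matrix(make_table(list(A = truth, B = truth)))
  expect_true(all(same$classification[!is.na(same$classification)] ==
                    "not_significant"))
})
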