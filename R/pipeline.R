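#' Evaluate all prediction methods for one protein
#'
#' Runs the per-protein comparison protocol: the experimental fluctuation
#' profile is computed over the whole chain (ensemble RMSF for NMR,
#' B-factor conversion for X-ray); the terminal truncation range is derived
#' from that experimental profile only (iterated for NMR, single-pass for
#' X-ray); every predicted profile is computed on the complete structure,
#' replicate-averaged, and restricted to the kept range; finally both sides
#' are normalized to unit maximum and compared by Pearson and Spearman
#' correlation.
#'
#' @param protein_id Label used in the output rows.
#' @param experimental A [calpha_ensemble()] (NMR) or a [calpha()] with
#'   B-factors (X-ray).
#' @param expt_method `"nmr"` or `"xray"`.
#' @param predicted Named list: one entry per prediction method, each a
#'   list of replicate [calpha_ensemble()]s (a single ensemble or a single
#'   [fluct_profile()] is also accepted and treated as one replicate).
#' @param ss_class Secondary-structure class label carried into the output.
#' @param config A [flex_config()].
#' @param enm_predictor Also run the built-in elastic-network predictor
#'   (on the X-ray structure or NMR model 1) as method `"enm"`?
#' @return A data.frame with one row per method: `protein_id`,
#'   `expt_method`, `ss_class`, `method`, `n_residues`, `first_kept`,
#'   `last_kept`, `n_kept`, `r_p`, `r_s`.
#' @examples
#' ref <- make_trace(30, "helix", seed = 1)
#' sig <- terminal_sigma_profile(30, 0.25, 3, 4)
#' expt <- make_ensemble(ref, sig, 20, seed = 2)
#' pred <- list(self = list(make_ensemble(ref, sig, 20, seed = 3)))
#' evaluate_protein("toy", expt, "nmr", pred)
#' @export
evaluate_protein <- function(protein_id, experimental, expt_method,
                             predicted = list(), ss_class = NA_character_,
                             config = flex_config(), enm_predictor = FALSE) {
  expt_method <- match.arg(expt_method, c("nmr", "xray"))
  expt_profile <- if (expt_method == "nmr") {
    stopifnot(inherits(experimental, "calpha_ensemble"))
    ensemble_rmsf(experimental, source = "nmr")
  } else {
    if (inherits(experimental, "calpha_ensemble")) {
      if (length(experimental$models) != 1L)
        stop("evaluate_protein: an X-ray input must be a single model")
      experimental <- experimental$models[[1]]
    }
    xray_profile(experimental)
  }
  n_res <- length(expt_profile$values)
  trange <- truncate_termini(
    expt_profile,
    iterate = expt_method == "nmr" && config$truncate.iterate_nmr,
    threshold_sd = config$truncate.threshold_sd_multiples,
    sd_convention = config$truncate.sd_convention)

  if (enm_predictor) {
    ref <- if (expt_method == "xray") experimental
           else experimental$models[[1]]
    em <- enm_model(ref, cutoff = config$enm.cutoff_angstrom,
                    gamma = config$enm.gamma)
    predicted <- c(predicted, list(enm = list(enm_rmsf(em))))
  }
  if (length(predicted) == 0L)
    stop("evaluate_protein: no predicted sources given")
  if (is.null(names(predicted)) || any(names(predicted) == ""))
    stop("evaluate_protein: predicted methods must be named")

  expt_kept <- normalize_profile(
    restrict_profile(expt_profile, trange$first_kept, trange$last_kept))

  rows <- lapply(names(predicted), function(mname) {
    reps <- predicted[[mname]]
    if (!is.list(reps) || inherits(reps, c("calpha_ensemble",
                                           "fluct_profile")))
      reps <- list(reps)
    profs <- lapply(reps, function(r) {
      if (inherits(r, "calpha_ensemble")) ensemble_rmsf(r)
      else if (inherits(r, "fluct_profile")) r
      else stop("evaluate_protein: predicted replicates must be ensembles ",
                "or fluctuation profiles")
    })
    for (p in profs)
      if (!identical(p$residue_numbers, expt_profile$residue_numbers))
        stop(sprintf(paste0("evaluate_protein: residue numbering of method ",
                            "'%s' does not match the experimental input"),
                     mname))
    avg <- average_replicates(profs,
                              normalize_first = config$average.normalize_first)
    pred_kept <- normalize_profile(
      restrict_profile(avg, trange$first_kept, trange$last_kept))
    pair <- profile_pair(pred_kept, expt_kept)
    data.frame(protein_id = protein_id, expt_method = expt_method,
               ss_class = ss_class, method = mname, n_residues = n_res,
               first_kept = trange$first_kept, last_kept = trange$last_kept,
               n_kept = pair$n,
               r_p = profile_pearson(pair), r_s = profile_spearman(pair))
  })
  do.call(rbind, rows)
}

#' Evaluate a whole benchmark and emit the statistics tables
#'
#' Runs [evaluate_protein()] over every protein of a benchmark, assembles
#' the long results table, and computes the benchmark-level statistics:
#' group means and SDs by method, structure-determination method and
#' secondary-structure class; histograms (0.1 bins) and cumulative counts
#' of the correlation coefficients; skewness per method; two-way ANOVA
#' (method x class) per structure-determination method; pairwise t-tests
#' and the signed significance matrices; and the coefficient-vs-chain-length
#' summary. Proteins that fail (degenerate truncation, constant profiles,
#' mismatched residues) are excluded and reported, not fatal.
#'
#' @param benchmark A `"synthetic_benchmark"` from [make_benchmark()], or a
#'   manifest data.frame / path to a manifest CSV with columns
#'   `protein_id`, `expt_method`, `ss_class`, `experimental_path`, and one
#'   `<method>_rep<k>` path column per predicted replicate.
#' @param config A [flex_config()].
#' @param out_dir Optional directory: when given, all result tables are
#'   written there as CSV (numbers at 6 significant digits).
#' @param enm_predictor Include the built-in elastic-network predictor?
#' @return A list of class `"benchmark_results"`: `per_protein`
#'   ([benchmark_table()]), `group_means`, `histograms`, `cumulative`,
#'   `skewness`, `anova`, `pairs`, `matrices` (list of
#'   [significance_matrix()] per structure-determination method),
#'   `matrix_long`, `length_dependence`, `failures`.
#' @export
evaluate_benchmark <- function(benchmark, config = flex_config(),
                               out_dir = NULL, enm_predictor = FALSE) {
  inputs <- benchmark_inputs(benchmark)
  rows <- list()
  failures <- list()
  for (p in inputs) {
    res <- tryCatch(
      evaluate_protein(p$protein_id, p$experimental, p$expt_method,
                       predicted = p$predicted, ss_class = p$ss_class,
                       config = config, enm_predictor = enm_predictor),
      error = function(e) e)
    if (inherits(res, "error"))
      failures[[length(failures) + 1L]] <-
        data.frame(protein_id = p$protein_id, reason = conditionMessage(res))
    else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L)
    stop("evaluate_benchmark: every protein failed")
  per_protein <- benchmark_table(do.call(rbind, rows))
  failures <- if (length(failures)) do.call(rbind, failures)
              else data.frame(protein_id = character(0),
                              reason = character(0))

  group_means <- aggregate_coeffs(per_protein,
                                  c("method", "expt_method", "ss_class"))
  group_means <- rbind(group_means,
                       cbind(aggregate_coeffs(per_protein,
                                              c("method", "expt_method")),
                             ss_class = "all")[, names(group_means)])

  combos <- unique(per_protein[, c("method", "expt_method")])
  histograms <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- merge(per_protein, combos[i, ])
    do.call(rbind, lapply(c("r_p", "r_s"), function(resp) {
      h <- histogram_counts(sub[[resp]])
      data.frame(method = combos$method[i],
                 expt_method = combos$expt_method[i], response = resp, h)
    }))
  }))
  cumulative <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- merge(per_protein, combos[i, ])
    do.call(rbind, lapply(c("r_p", "r_s"), function(resp) {
      cc <- cumulative_counts(sub[[resp]])
      if (nrow(cc$table) == 0L) return(NULL)
      data.frame(method = combos$method[i],
                 expt_method = combos$expt_method[i], response = resp,
                 cc$table)
    }))
  }))
  skewness <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- merge(per_protein, combos[i, ])
    do.call(rbind, lapply(c("r_p", "r_s"), function(resp) {
      g1 <- tryCatch(coef_skewness(sub[[resp]],
                                   convention = config$skewness.convention),
                     error = function(e) NA_real_)
      data.frame(method = combos$method[i],
                 expt_method = combos$expt_method[i], response = resp,
                 n = nrow(sub), skewness = g1)
    }))
  }))

  expts <- unique(per_protein$expt_method)
  anova_tab <- do.call(rbind, lapply(expts, function(ex) {
    do.call(rbind, lapply(c("r_p", "r_s"), function(resp) {
      a <- tryCatch(two_way_anova(per_protein, response = resp,
                                  expt_method = ex, alpha = config$alpha),
                    error = function(e) NULL)
      if (is.null(a)) return(NULL)
      cbind(expt_method = ex, response = resp, a)
    }))
  }))

  methods <- sort(unique(per_protein$method))
  pairs_tab <- NULL
  matrices <- list()
  matrix_long <- NULL
  if (length(methods) >= 2L) {
    for (ex in expts) {
      sm <- tryCatch(
        significance_matrix(per_protein, methods = methods,
                            alpha = config$alpha, expt_method = ex,
                            paired = config$ttest.paired),
        error = function(e) NULL)
      if (is.null(sm)) next
      matrices[[ex]] <- sm
      for (i in seq_along(methods)) for (j in seq_along(methods)) {
        if (i == j) next
        matrix_long <- rbind(matrix_long, data.frame(
          expt_method = ex, method_row = methods[i], method_col = methods[j],
          response = if (i < j) "r_p" else "r_s",
          t = sm$t[i, j], p = sm$p[i, j],
          classification = sm$classification[i, j]))
      }
    }
    pairs_tab <- do.call(rbind, lapply(expts, function(ex) {
      out <- NULL
      for (i in seq_along(methods)) for (j in seq_along(methods)) {
        if (j <= i) next
        for (resp in c("r_p", "r_s")) {
          res <- tryCatch(
            pairwise_t(per_protein, methods[i], methods[j], response = resp,
                       expt_method = ex, paired = config$ttest.paired),
            error = function(e) NULL)
          if (is.null(res)) next
          out <- rbind(out, data.frame(
            expt_method = ex, method_a = methods[i], method_b = methods[j],
            response = resp, n = res$n, t = res$t, df = res$df, p = res$p,
            mean_diff = res$mean_diff))
        }
      }
      out
    }))
  }

  length_dependence <- do.call(rbind,
    lapply(seq_len(nrow(combos)), function(i) {
      sub <- merge(per_protein, combos[i, ])
      data.frame(method = combos$method[i],
                 expt_method = combos$expt_method[i], n = nrow(sub),
                 mean_length = mean(sub$n_residues),
                 cor_length_rp = if (nrow(sub) >= 3 &&
                                     stats::sd(sub$n_residues) > 0 &&
                                     stats::sd(sub$r_p) > 0)
                   stats::cor(sub$n_residues, sub$r_p) else NA_real_,
                 cor_length_rs = if (nrow(sub) >= 3 &&
                                     stats::sd(sub$n_residues) > 0 &&
                                     stats::sd(sub$r_s) > 0)
                   stats::cor(sub$n_residues, sub$r_s) else NA_real_)
    }))

  results <- structure(list(per_protein = per_protein,
                            group_means = group_means,
                            histograms = histograms,
                            cumulative = cumulative,
                            skewness = skewness,
                            anova = anova_tab,
                            pairs = pairs_tab,
                            matrices = matrices,
                            matrix_long = matrix_long,
                            length_dependence = length_dependence,
                            failures = failures,
                            config = config),
                       class = "benchmark_results")
  if (!is.null(out_dir)) write_benchmark_results(results, out_dir)
  results
}

#' @export
print.benchmark_results <- function(x, ...) {
  cat(sprintf("Benchmark results: %d proteins x %d methods (%d failed)\n",
              length(unique(x$per_protein$protein_id)),
              length(unique(x$per_protein$method)), nrow(x$failures)))
  means <- x$group_means[x$group_means$ss_class == "all", ]
  print(means[, c("method", "expt_method", "n", "mean_r_p", "mean_r_s")],
        row.names = FALSE)
  invisible(x)
}

# Normalize the two accepted benchmark input forms into a per-protein list.
benchmark_inputs <- function(benchmark) {
  if (inherits(benchmark, "synthetic_benchmark"))
    return(lapply(benchmark$proteins, function(p)
      list(protein_id = p$protein_id, expt_method = p$expt_method,
           ss_class = p$ss_class, experimental = p$experimental,
           predicted = p$predicted)))
  if (is.character(benchmark) && length(benchmark) == 1L)
    benchmark <- utils::read.csv(benchmark, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(benchmark))
  rep_cols <- grep("_rep[0-9]+$", names(benchmark), value = TRUE)
  method_names <- unique(sub("_rep[0-9]+$", "", rep_cols))
  lapply(seq_len(nrow(benchmark)), function(i) {
    row <- benchmark[i, ]
    expt <- read_calpha_ensemble(row$experimental_path,
                                 protein_id = row$protein_id)
    if (row$expt_method == "xray") expt <- expt$models[[1]]
    predicted <- lapply(method_names, function(m) {
      cols <- rep_cols[startsWith(rep_cols, paste0(m, "_rep"))]
      paths <- unlist(row[cols])
      paths <- paths[!is.na(paths) & nzchar(paths)]
      lapply(paths, read_calpha_ensemble, protein_id = row$protein_id)
    })
    names(predicted) <- method_names
    predicted <- predicted[vapply(predicted, length, integer(1)) > 0]
    list(protein_id = row$protein_id, expt_method = row$expt_method,
         ss_class = row$ss_class, experimental = expt, predicted = predicted)
  })
}

#' Write benchmark result tables as CSV
#'
#' Emits `per_protein.csv`, `group_means.csv`, `histograms.csv`,
#' `cumulative.csv`, `skewness.csv`, `anova.csv`, `pairs.csv`,
#' `matrix.csv`, `length_dependence.csv` and `failures.csv` into `dir`,
#' with all numeric columns rounded to 6 significant digits so repeated
#' runs are byte-identical.
#'
#' @param results A `"benchmark_results"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark_results <- function(results, dir) {
  stopifnot(inherits(results, "benchmark_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  emit(results$per_protein, "per_protein.csv")
  emit(results$group_means, "group_means.csv")
  emit(results$histograms, "histograms.csv")
  emit(results$cumulative, "cumulative.csv")
  emit(results$skewness, "skewness.csv")
  emit(results$anova, "anova.csv")
  emit(results$pairs, "pairs.csv")
  emit(results$matrix_long, "matrix.csv")
  emit(results$length_dependence, "length_dependence.csv")
  emit(results$failures, "failures.csv")
  invisible(dir)
}

# Mean/SD aggregation of both coefficients over grouping columns.
aggregate_coeffs <- function(df, by) {
  groups <- unique(df[, by, drop = FALSE])
  rownames(groups) <- NULL
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sub <- merge(df, groups[i, , drop = FALSE])
    data.frame(groups[i, , drop = FALSE], n = nrow(sub),
               mean_r_p = mean(sub$r_p), sd_r_p = stats::sd(sub$r_p),
               mean_r_s = mean(sub$r_s), sd_r_s = stats::sd(sub$r_s))
  }))
  rownames(out) <- NULL
  out
}
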