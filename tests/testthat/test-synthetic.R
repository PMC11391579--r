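test_that("generated traces have realistic virtual bond geometry", {
  for (fold in c("helix", "strand", "mixed", "random_walk")) {
    tr <- make_trace(20, fold, seed = 1)
    d <- sqrt(rowSums(diff(tr$coords)^2))
    expect_true(all(d > 3.2 & d < 3.9), label = paste(fold, "bond lengths"))
  }
  h <- make_trace(20, "helix", seed = 1)
  dh <- sqrt(rowSums(diff(h$coords)^2))
  expect_true(all(dh >= 3.7 & dh <= 3.9))

  # bit-reproducible given the seed
  expect_identical(make_trace(40, "random_walk", seed = 9)$coords,
                   make_trace(40, "random_walk", seed = 9)$coords)
  expect_false(identical(make_trace(40, "random_walk", seed = 9)$coords,
                         make_trace(40, "random_walk", seed = 10)$coords))
})

test_that("helices are more compact than random walks (i,i+4 contacts)", {
  contacts_i4 <- function(tr) {
    n <- nrow(tr$coords)
    sum(sqrt(rowSums((tr$coords[1:(n - 4), ] -
                        tr$coords[5:n, ])^2)) < 8)
  }
  helix_counts <- contacts_i4(make_trace(18, "helix", seed = 1))
  walk_counts <- mean(vapply(1:20, function(s)
    contacts_i4(make_trace(18, "random_walk", seed = s)), numeric(1)))
  expect_gt(helix_counts, walk_counts)
})

test_that("zero-noise ensembles are rigid motions of the reference", {
  ref <- make_trace(15, "helix", seed = 2)
  e <- make_ensemble(ref, rep(0, 15), n_models = 5, seed = 3)
  for (m in e$models) {
    k <- kabsch_superpose(m$coords, ref$coords)
    expect_lt(k$rmsd, 1e-9)
  }
  expect_lt(max(ensemble_rmsf(e)$values), 1e-6)
})

test_that("ensembles recover flat and terminal-boosted sigma profiles", {
  n <- 100
  ref <- make_trace(n, "mixed", seed = 4)
  flat <- make_ensemble(ref, rep(0.4, n), n_models = 1000, seed = 5)
  prof <- ensemble_rmsf(flat)
  expect_lt(diff(range(prof$values)) / mean(prof$values), 0.1)
  expect_lt(max(abs(prof$values - sqrt(3) * 0.4)) / (sqrt(3) * 0.4), 0.05)

  sig <- terminal_sigma_profile(n, 0.25, terminal_boost = 4,
                                terminal_length = 10)
  expect_equal(sig[1] / sig[n / 2], 4)
  expect_equal(sig[n], sig[1])
  boosted <- make_ensemble(ref, sig, n_models = 1000, seed = 6)
  bp <- ensemble_rmsf(boosted)
  core <- mean(bp$values[31:70])
  expect_lt(abs(bp$values[1] / core - 4) / 4, 0.10)
  expect_lt(abs(bp$values[n] / core - 4) / 4, 0.10)
})

test_that("X-ray structures encode a prescribed profile via B-factors", {
  ref <- make_trace(12, "strand", seed = 7)
  expect_equal(make_xray_structure(ref, rep(1, 12))$bfactors,
               rep(8 * pi^2 / 3, 12))
  expect_equal(make_xray_structure(ref, rep(0, 12))$bfactors, rep(0, 12))

  set.seed(8)
  rmsf <- runif(12, 0.2, 1.8)
  s <- make_xray_structure(ref, rmsf)
  expect_equal(xray_profile(s)$values, rmsf, tolerance = 1e-12)
  # through PDB text the 2-decimal B-factor rounding dominates
  rt <- read_calpha_ensemble(write_ensemble_pdb(s))$models[[1]]
  expect_lt(max(abs(xray_profile(rt)$values - rmsf)), 0.01)
  expect_error(make_xray_structure(ref, c(rep(1, 11), -0.2)), "non-negative")
})

test_that("benchmark generation respects mixes and is reproducible", {
  b <- make_benchmark(10, class_mix = c(alpha = 0.5, beta = 0.3,
                                        alpha_beta = 0.2),
                      expt_mix = c(nmr = 0.6, xray = 0.4), seed = 11)
  expect_equal(as.integer(table(b$manifest$ss_class)[c("alpha", "beta",
                                                       "alpha_beta")]),
               c(5L, 3L, 2L))
  expect_equal(sum(b$manifest$expt_method == "nmr"), 6)
  expect_equal(nrow(b$manifest), 10)

  b2 <- make_benchmark(10, class_mix = c(alpha = 0.5, beta = 0.3,
                                         alpha_beta = 0.2),
                       expt_mix = c(nmr = 0.6, xray = 0.4), seed = 11)
  expect_identical(b$proteins[[3]]$reference$coords,
                   b2$proteins[[3]]$reference$coords)
  expect_identical(b$proteins[[7]]$predicted[[1]][[2]]$models[[4]]$coords,
                   b2$proteins[[7]]$predicted[[1]][[2]]$models[[4]]$coords)
})

test_that("generated PDB files are accepted cleanly by the reader", {
  dir <- withr::local_tempdir()
  b <- make_benchmark(4, seed = 12, dir = dir,
                      expt_mix = c(nmr = 0.5, xray = 0.5))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  for (i in seq_len(nrow(b$manifest))) {
    expect_no_warning(e <- read_calpha_ensemble(b$manifest$experimental_path[i]))
    nm <- if (b$manifest$expt_method[i] == "nmr") 25L else 1L
    expect_length(e$models, nm)
  }
})

test_that("a perfect-fidelity method scores near 1 through the pipeline", {
  # ensembles large enough that sampling noise is subdominant to the
  # core fluctuation contrast left after terminal truncation
  ref <- make_trace(60, "mixed", seed = 21)
  sig <- terminal_sigma_profile(60, 0.25, 4, 6) * (1 + abs(sin(1:60 / 4)))
  expt <- make_ensemble(ref, sig, n_models = 300, seed = 22)
  pred <- lapply(1:3, function(r)
    make_ensemble(ref, sig, n_models = 300, seed = 22 + r))
  row <- evaluate_protein("perfect", expt, "nmr",
                          predicted = list(perfect = pred))
  expect_gte(row$r_p, 0.95)
})

test_that("a zero-fidelity method is uncorrelated on average", {
  bench <- make_benchmark(30, methods = c(noise = 0),
                          expt_mix = c(nmr = 0, xray = 1), seed = 23)
  res <- evaluate_benchmark(bench)
  expect_lt(abs(mean(res$per_protein$r_p)), 0.25)
})
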