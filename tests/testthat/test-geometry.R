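test_that("kabsch superposition recovers exact rigid motions", {
  set.seed(11)
  ref <- matrix(rnorm(30), ncol = 3)
  k0 <- kabsch_superpose(ref, ref)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-9)
  expect_lt(sqrt(sum(k0$translation^2)), 1e-9)
  expect_lt(k0$rmsd, 1e-12)

  # 90 degree rotation about z then a shift: the inverse is recovered
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  mobile <- sweep(ref %*% t(Rz), 2, c(1, 2, 3), "+")
  k <- kabsch_superpose(mobile, ref)
  expect_lt(k$rmsd, 1e-9)
  expect_equal(k$rotation, t(Rz), tolerance = 1e-9)
  fitted <- apply_transform(k, mobile)
  expect_lt(max(abs(fitted - ref)), 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(k$rotation), diag(3), tolerance = 1e-9)

  expect_error(kabsch_superpose(ref[1:5, ], ref), "equal-size")
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -1:3 * 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("kabsch rmsd matches a brute-force rotation-grid search", {
  set.seed(21)
  mobile <- matrix(rnorm(12), ncol = 3)
  reference <- mobile + matrix(rnorm(12, sd = 0.3), ncol = 3)
  k <- kabsch_superpose(mobile, reference)

  # exhaustive search over ZYZ Euler angles at 6-degree resolution,
  # translations handled exactly by centroid matching
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  step <- 6 * pi / 180
  a_grid <- seq(0, 2 * pi - step, by = step)
  b_grid <- seq(0, pi, by = step)
  best <- Inf
  for (a in a_grid) for (b in b_grid) for (g in a_grid) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(g); sg <- sin(g)
    R <- rbind(
      c(ca * cb * cg - sa * sg, -ca * cb * sg - sa * cg, ca * sb),
      c(sa * cb * cg + ca * sg, -sa * cb * sg + ca * cg, sa * sb),
      c(-sb * cg, sb * sg, cb))
    r <- sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
    if (r < best) best <- r
  }
  expect_lte(k$rmsd, best + 1e-12)      # closed form is never worse
  expect_lt(best - k$rmsd, 0.05)        # and the grid comes close to it
})

test_that("kabsch agrees with an independent implementation (bio3d)", {
  skip_if_not_installed("bio3d")
  set.seed(31)
  for (i in 1:5) {
    a <- matrix(rnorm(30), ncol = 3)
    b <- a + matrix(rnorm(30, sd = 0.4), ncol = 3)
    k <- kabsch_superpose(b, a)
    fitted <- suppressWarnings(
      matrix(bio3d::fit.xyz(as.vector(t(a)), as.vector(t(b))),
             ncol = 3, byrow = TRUE))
    expect_equal(k$rmsd, sqrt(mean(rowSums((fitted - a)^2))),
                 tolerance = 1e-9)
  }
})

test_that("mean structure reproduces fixed points and averages noise", {
  tr <- random_trace(15, seed = 7)
  e1 <- calpha_ensemble(list(tr))
  expect_equal(mean_structure(e1)$coords, tr$coords, tolerance = 0)

  # two exact rigid motions of one shape: mean congruent to that shape
  Q <- test_rotation(5)
  m2 <- calpha(tr$protein_id, "A", tr$residue_numbers,
               sweep(tr$coords %*% t(Q), 2, c(5, -3, 2), "+"))
  ms <- mean_structure(calpha_ensemble(list(tr, m2)))
  k <- kabsch_superpose(ms$coords, tr$coords)
  expect_lt(k$rmsd, 1e-6)

  # 100 noisy copies: the mean approaches the reference (law of large numbers)
  set.seed(99)
  sigma <- 0.1
  mods <- lapply(1:100, function(j)
    calpha("t", "A", tr$residue_numbers,
           tr$coords + matrix(rnorm(45, sd = sigma), ncol = 3)))
  mavg <- mean_structure(calpha_ensemble(mods))
  fit <- apply_transform(kabsch_superpose(mavg$coords, tr$coords),
                         mavg$coords)
  expect_lt(max(abs(fit - tr$coords)), 4 * sigma / sqrt(100))
})

test_that("ensemble RMSF matches forced and sampled fluctuation magnitudes", {
  tr <- random_trace(12, seed = 13)
  same <- calpha_ensemble(list(tr, tr, tr))
  expect_lt(max(ensemble_rmsf(same)$values), 1e-9)
  expect_error(ensemble_rmsf(calpha_ensemble(list(tr))), "two models")

  # symmetric radial displacement of an antipodal residue pair: the
  # displacement field has zero net translation and torque, so the optimal
  # superposition is the identity and RMSF is exactly d on those residues
  base <- rbind(c(6, 0, 0), c(-6, 0, 0), c(0, 5, 0), c(0, -5, 0),
                c(0, 0, 4), c(1, 1, 4))
  d <- 0.7
  u <- matrix(0, 6, 3); u[1, ] <- c(d, 0, 0); u[2, ] <- c(-d, 0, 0)
  e2 <- calpha_ensemble(list(calpha("s", "A", 1:6, base + u),
                             calpha("s", "A", 1:6, base - u)))
  prof <- ensemble_rmsf(e2)
  expect_equal(prof$values[1:2], c(d, d), tolerance = 1e-9)
  expect_lt(max(prof$values[3:6]), 1e-9)
})

test_that("RMSF recovers sqrt(3) sigma and is rigid-motion invariant", {
  # protein-scale chain: at small n the superposition step visibly absorbs
  # the rigid-subspace component of the noise at high-leverage residues
  n <- 100
  tr <- random_trace(n, seed = 17)
  sigma <- seq(0.2, 0.4, length.out = n)
  e <- make_ensemble(tr, sigma, n_models = 1000, seed = 23)
  prof <- ensemble_rmsf(e)
  expect_lt(max(abs(prof$values - sqrt(3) * sigma) / (sqrt(3) * sigma)),
            0.05)

  # one global rigid motion applied to every model changes nothing
  Q <- test_rotation(8)
  sub <- calpha_ensemble(e$models[1:50])
  moved <- calpha_ensemble(lapply(sub$models, function(m) {
    m$coords <- sweep(m$coords %*% t(Q), 2, c(3, 1, -9), "+")
    m
  }))
  expect_equal(ensemble_rmsf(moved)$values, ensemble_rmsf(sub)$values,
               tolerance = 1e-9)

  # model order is irrelevant
  perm <- calpha_ensemble(sub$models[sample(seq_along(sub$models))])
  expect_equal(ensemble_rmsf(perm)$values, ensemble_rmsf(sub)$values,
               tolerance = 1e-9)
})
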