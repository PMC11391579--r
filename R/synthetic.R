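#' Generate an idealized C-alpha trace
#'
#' Builds a synthetic C-alpha backbone with realistic consecutive spacing
#' (3.7-3.9 Å) for use as a reference structure. Available folds:
#' `"helix"` (canonical alpha-helical C-alpha parameters: 1.5 Å rise per
#' residue, 100 degrees per turn, 2.3 Å helix radius), `"strand"` (a pleated
#' extended zigzag), `"mixed"` (a helix and a strand packed side by side,
#' joined by a short turn) and `"random_walk"` (a self-avoiding walk with
#' 3.8 Å steps).
#'
#' @param n_residues Number of residues (>= 5).
#' @param fold One of `"helix"`, `"strand"`, `"mixed"`, `"random_walk"`.
#' @param seed Integer seed; the trace is deterministic given `seed` (only
#'   `random_walk` and `mixed` consume randomness).
#' @param protein_id,chain_id Labels for the resulting model.
#' @return A [calpha()] model without B-factors.
#' @examples
#' tr <- make_trace(20, "helix", seed = 1)
#' range(sqrt(rowSums(diff(tr$coords)^2)))
#' @export
make_trace <- function(n_residues, fold = c("helix", "strand", "mixed",
                                            "random_walk"),
                       seed = 1, protein_id = "synthetic", chain_id = "A") {
  fold <- match.arg(fold)
  n <- as.integer(n_residues)
  if (n < 5L) stop("make_trace: at least 5 residues required")
  xyz <- with_seed(seed, switch(fold,
    helix = helix_coords(n),
    strand = strand_coords(n),
    mixed = mixed_coords(n),
    random_walk = walk_coords(n)))
  calpha(protein_id, chain_id, seq_len(n), xyz)
}

# Canonical C-alpha helix: rise 1.5 A, 100 deg/residue, radius 2.3 A.
helix_coords <- function(n, phase = 0) {
  t <- (seq_len(n) - 1) * 100 * pi / 180 + phase
  cbind(2.3 * cos(t), 2.3 * sin(t), (seq_len(n) - 1) * 1.5)
}

# Twisted extended strand: ~2 residues per turn with the natural beta twist
# (-170 deg/residue, 3.3 A rise, 0.95 A radius). The twist keeps the trace
# non-planar, which a central-force elastic network requires.
strand_coords <- function(n) {
  t <- (seq_len(n) - 1) * (-170) * pi / 180
  cbind(0.95 * cos(t), 0.95 * sin(t), (seq_len(n) - 1) * 3.3)
}

# Helix packed against a strand, with a bridging loop residue when needed.
mixed_coords <- function(n) {
  n1 <- max(5L, n %/% 2L)
  h <- helix_coords(n1)
  n2 <- n - n1
  if (n2 == 0L) return(h)
  s <- strand_coords(max(n2, 2L))[seq_len(n2), , drop = FALSE]
  # run the strand antiparallel alongside the helix, ~6 A away, and anchor
  # its first residue 3.8 A from the helix C-terminus
  s <- cbind(s[, 3], s[, 2], -s[, 1])          # point strand along -z
  last <- h[n1, ]
  dir <- c(6, 0, -1); dir <- dir / sqrt(sum(dir^2))
  s <- sweep(s, 2, s[1, ]) # start at origin
  s <- sweep(s, 2, last + 3.8 * dir, "+")
  rbind(h, s)
}

# Self-avoiding random walk: 3.8 A steps, non-adjacent residues kept > 3.9 A
# apart, with a mild forward persistence to avoid trapping.
walk_coords <- function(n, step = 3.8, clash = 3.9, max_try = 200L) {
  xyz <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    placed <- FALSE
    for (k in seq_len(max_try)) {
      prop <- dir + stats::rnorm(3, sd = 0.8)
      prop <- prop / sqrt(sum(prop^2))
      cand <- xyz[i - 1, ] + step * prop
      prev <- xyz[seq_len(max(i - 2, 1)), , drop = FALSE]
      if (i == 2 ||
          min(sqrt(rowSums(sweep(prev, 2, cand)^2))) > clash) {
        xyz[i, ] <- cand
        dir <- prop
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("make_trace: self-avoiding walk trapped; try another seed")
  }
  xyz
}

#' Ramped per-residue fluctuation magnitudes with inflated termini
#'
#' Produces the sigma profile (Å) used by [make_ensemble()]: a constant
#' core value with a linear multiplicative ramp over the first and last
#' `terminal_length` residues rising to `terminal_boost` times the core at
#' the chain ends — emulating the markedly higher mobility of N- and
#' C-terminal segments of single-chain proteins.
#'
#' @param n_residues Chain length.
#' @param sigma_core Core per-coordinate standard deviation (Å).
#' @param terminal_boost Multiplier at the outermost residue (>= 1).
#' @param terminal_length Number of residues in each ramp
#'   (< `n_residues` / 2).
#' @return Numeric vector of length `n_residues`.
#' @examples
#' terminal_sigma_profile(12, 0.3, terminal_boost = 4, terminal_length = 3)
#' @export
terminal_sigma_profile <- function(n_residues, sigma_core,
                                   terminal_boost = 1, terminal_length = 0) {
  n <- as.integer(n_residues)
  stopifnot(sigma_core > 0, terminal_boost >= 1, terminal_length >= 0)
  if (terminal_length >= n / 2)
    stop("terminal_sigma_profile: terminal_length must be < n_residues/2")
  ramp <- rep(1, n)
  if (terminal_length > 0) {
    k <- seq_len(terminal_length)
    factor_k <- 1 + (terminal_boost - 1) * (terminal_length - k + 1) /
      terminal_length
    ramp[k] <- factor_k
    ramp[n - k + 1] <- factor_k
  }
  sigma_core * ramp
}

#' Generate a Gaussian conformational ensemble around a reference
#'
#' Each model is the reference plus independent isotropic Gaussian
#' displacements with per-residue standard deviation `sigma_profile`
#' (applied per coordinate), followed by a random global rigid motion so
#' that downstream superposition is exercised. Deterministic given `seed`.
#'
#' @param reference A [calpha()] model.
#' @param sigma_profile Per-residue sigma in Å (length matching the
#'   reference), e.g. from [terminal_sigma_profile()].
#' @param n_models Number of models.
#' @param seed Integer seed.
#' @return A [calpha_ensemble()] whose per-residue RMSF approaches
#'   `sqrt(3) * sigma_profile` for large `n_models`.
#' @examples
#' ref <- make_trace(20, "helix", seed = 1)
#' e <- make_ensemble(ref, rep(0.3, 20), n_models = 10, seed = 2)
#' length(e$models)
#' @export
make_ensemble <- function(reference, sigma_profile, n_models, seed = 1) {
  stopifnot(inherits(reference, "calpha"))
  n <- length(reference$residue_numbers)
  sigma_profile <- as.numeric(sigma_profile)
  if (length(sigma_profile) != n)
    stop("make_ensemble: sigma_profile length must match the reference")
  if (any(sigma_profile < 0))
    stop("make_ensemble: sigma values must be non-negative")
  n_models <- as.integer(n_models)
  stopifnot(n_models >= 1L)
  models <- with_seed(seed, lapply(seq_len(n_models), function(j) {
    noise <- matrix(stats::rnorm(3 * n), ncol = 3) * sigma_profile
    xyz <- reference$coords + noise
    R <- random_rotation()
    xyz <- sweep(xyz %*% t(R), 2, stats::runif(3, -10, 10), "+")
    calpha(reference$protein_id, reference$chain_id,
           reference$residue_numbers, xyz)
  }))
  calpha_ensemble(models, protein_id = reference$protein_id)
}

# Uniform random proper rotation via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate an X-ray-style structure encoding a fluctuation profile
#'
#' Writes the prescribed RMSF profile into the B-factor column of a copy of
#' the reference via the Debye-Waller relation B = (8 pi^2 / 3) RMSF^2, so
#' that [xray_profile()] recovers the input (up to PDB 2-decimal rounding
#' when round-tripped through text).
#'
#' @param reference A [calpha()] model.
#' @param rmsf_profile Non-negative per-residue RMSF in Å.
#' @return A [calpha()] with B-factors set.
#' @examples
#' s <- make_xray_structure(make_trace(10, "helix"), rep(1, 10))
#' s$bfactors[1]   # 8*pi^2/3
#' @export
make_xray_structure <- function(reference, rmsf_profile) {
  stopifnot(inherits(reference, "calpha"))
  rmsf_profile <- as.numeric(rmsf_profile)
  if (length(rmsf_profile) != length(reference$residue_numbers))
    stop("make_xray_structure: profile length must match the reference")
  reference$bfactors <- rmsf_to_bfactor(rmsf_profile)
  reference
}

#' Generate a complete synthetic benchmark with known ground truth
#'
#' Creates a desk-scale benchmark: for each protein, a reference trace, an
#' "experimental" input (a multi-model NMR-style ensemble or an X-ray-style
#' B-factor structure) generated from a true per-residue fluctuation
#' profile with inflated termini, and replicate "predicted" ensembles for
#' each simulated method. A method of fidelity f samples from a profile
#' mixing the true profile with an independent rough noise profile in
#' proportion f : (1 - f), so fidelity 1 reproduces the truth and fidelity
#' 0 is uninformative.
#'
#' @param n_proteins Number of proteins (>= 4).
#' @param class_mix Named numeric proportions or counts over
#'   `c("alpha", "beta", "alpha_beta")`.
#' @param expt_mix Named proportions or counts over `c("nmr", "xray")`.
#' @param methods Named numeric vector of method fidelities in \[0, 1\].
#' @param seed Integer seed; everything is reproducible from it.
#' @param dir Optional directory: when given, experimental and predicted
#'   PDB files plus `manifest.csv` and `truth.csv` are written there.
#' @param n_models Models per generated ensemble.
#' @param n_replicates Replicate predicted ensembles per method.
#' @param residue_range Range the chain length is drawn from.
#' @return A list of class `"synthetic_benchmark"`: `proteins` (per-protein
#'   list with reference, experimental input, predicted ensembles and the
#'   true sigma profile), `manifest` (data.frame), `truth` (data.frame),
#'   and `dir` (or `NULL`).
#' @examples
#' \donttest{
#' bench <- make_benchmark(4, seed = 1)
#' bench$manifest[, c("protein_id", "expt_method", "ss_class")]
#' }
#' @export
make_benchmark <- function(n_proteins,
                           class_mix = c(alpha = 0.30, beta = 0.21,
                                         alpha_beta = 0.49),
                           expt_mix = c(nmr = 0.5, xray = 0.5),
                           methods = c(high = 0.9, low = 0.3),
                           seed = 1, dir = NULL, n_models = 25L,
                           n_replicates = 3L,
                           residue_range = c(40L, 70L)) {
  n_proteins <- as.integer(n_proteins)
  if (n_proteins < 4L) stop("make_benchmark: at least 4 proteins required")
  if (is.null(names(methods)) || any(methods < 0) || any(methods > 1))
    stop("make_benchmark: methods must be a named vector of fidelities in [0,1]")
  classes <- mix_counts(class_mix, c("alpha", "beta", "alpha_beta"),
                        n_proteins)
  expts <- mix_counts(expt_mix, c("nmr", "xray"), n_proteins)

  proteins <- with_seed(seed, lapply(seq_len(n_proteins), function(i) {
    pid <- sprintf("SYN%03d", i)
    n_res <- sample(residue_range[1]:residue_range[2], 1)
    fold <- switch(classes[i], alpha = "helix", beta = "strand",
                   alpha_beta = "mixed")
    ref <- make_trace(n_res, fold, seed = sample.int(2^20, 1),
                      protein_id = pid)
    # true fluctuation profile: boosted termini + smooth core variation
    base <- terminal_sigma_profile(n_res, sigma_core = 0.25,
                                   terminal_boost = 4, terminal_length = 5L)
    wiggle <- 1 + 0.5 * abs(sin(seq_len(n_res) / 4 + stats::runif(1, 0, pi)))
    sigma_true <- base * wiggle
    rmsf_true <- sqrt(3) * sigma_true
    expt <- expts[i]
    experimental <- if (expt == "nmr") {
      make_ensemble(ref, sigma_true, n_models = n_models,
                    seed = sample.int(2^20, 1))
    } else {
      make_xray_structure(ref, rmsf_true)
    }
    predicted <- lapply(names(methods), function(mname) {
      f <- methods[[mname]]
      lapply(seq_len(n_replicates), function(r) {
        noise <- 1 + 2 * abs(sin(seq_len(n_res) / 3 +
                                   stats::runif(1, 0, 2 * pi))) +
          abs(stats::rnorm(n_res, sd = 0.5))
        sigma_m <- f * sigma_true + (1 - f) * 0.25 * noise
        make_ensemble(ref, sigma_m, n_models = n_models,
                      seed = sample.int(2^20, 1))
      })
    })
    names(predicted) <- names(methods)
    list(protein_id = pid, ss_class = classes[i], expt_method = expt,
         n_residues = n_res, reference = ref, experimental = experimental,
         predicted = predicted, sigma_true = sigma_true,
         rmsf_true = rmsf_true)
  }))

  manifest <- do.call(rbind, lapply(proteins, function(p) {
    data.frame(protein_id = p$protein_id, expt_method = p$expt_method,
               ss_class = p$ss_class, n_residues = p$n_residues,
               experimental_path = NA_character_)
  }))
  for (mname in names(methods))
    for (r in seq_len(n_replicates))
      manifest[[sprintf("%s_rep%d", mname, r)]] <- NA_character_
  truth <- do.call(rbind, lapply(proteins, function(p) {
    data.frame(protein_id = p$protein_id, ss_class = p$ss_class,
               expt_method = p$expt_method, n_residues = p$n_residues,
               residue = seq_len(p$n_residues), sigma_true = p$sigma_true)
  }))
  fidelity <- data.frame(method = names(methods),
                         fidelity = as.numeric(methods))

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(proteins)) {
      p <- proteins[[k]]
      epath <- file.path(dir, sprintf("%s_expt.pdb", p$protein_id))
      write_ensemble_pdb(if (p$expt_method == "nmr") p$experimental
                         else calpha_ensemble(list(p$experimental)), epath)
      manifest$experimental_path[k] <- epath
      for (mname in names(p$predicted))
        for (r in seq_along(p$predicted[[mname]])) {
          ppath <- file.path(dir, sprintf("%s_%s_rep%d.pdb",
                                          p$protein_id, mname, r))
          write_ensemble_pdb(p$predicted[[mname]][[r]], ppath)
          col <- sprintf("%s_rep%d", mname, r)
          manifest[[col]][k] <- ppath
        }
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(fidelity, file.path(dir, "fidelity.csv"),
                     row.names = FALSE)
  }

  structure(list(proteins = proteins, manifest = manifest, truth = truth,
                 fidelity = fidelity, dir = dir, seed = seed),
            class = "synthetic_benchmark")
}

# Turn proportions/counts into an assignment vector of length n.
mix_counts <- function(mix, levels, n) {
  if (is.null(names(mix))) names(mix) <- levels[seq_along(mix)]
  mix <- mix[levels[levels %in% names(mix)]]
  counts <- round(mix / sum(mix) * n)
  while (sum(counts) > n) counts[which.max(counts)] <-
    counts[which.max(counts)] - 1L
  while (sum(counts) < n) counts[which.min(counts)] <-
    counts[which.min(counts)] + 1L
  rep(names(counts), times = counts)
}
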