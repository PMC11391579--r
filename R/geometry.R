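#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference`, via singular value decomposition of the
#' cross-covariance matrix with the reflection branch excluded.
#'
#' @param mobile,reference Numeric n x 3 coordinate matrices, n >= 3.
#' @return A list of class `"rigid_transform"` with elements `rotation`
#'   (3 x 3 proper orthogonal), `translation` (length-3), and `rmsd` (Å),
#'   such that `sweep(mobile %*% t(rotation), 2, translation, "+")`
#'   best fits `reference`.
#' @examples
#' ref <- matrix(rnorm(30), ncol = 3)
#' th <- pi / 5
#' R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' kabsch_superpose(ref %*% t(R), ref)$rmsd
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("kabsch_superpose: coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("kabsch_superpose: at least 3 points required")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  dP <- svd(P)$d; dQ <- svd(Q)$d
  if (dP[2] <= 1e-10 * max(dP[1], 1) || dQ[2] <= 1e-10 * max(dQ[1], 1))
    stop("kabsch_superpose: degenerate (collinear) point set")
  s <- svd(crossprod(P, Q))          # t(P) %*% Q = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # x' = R x for column vectors
  translation <- as.numeric(cr - R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2, translation, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates or a model
#'
#' @param transform A `"rigid_transform"` from [kabsch_superpose()].
#' @param x An n x 3 coordinate matrix, a [calpha()] model, or a
#'   [calpha_ensemble()] (applied to every model).
#' @return The transformed object, same type as `x`.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "calpha_ensemble")) {
    x$models <- lapply(x$models, function(m) apply_transform(transform, m))
    return(x)
  }
  if (inherits(x, "calpha")) {
    x$coords <- apply_transform(transform, x$coords)
    return(x)
  }
  sweep(as.matrix(x) %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Iterative mean structure of an ensemble
#'
#' All models are superposed on the first model and averaged; models are
#' then re-superposed on the running mean and re-averaged until successive
#' means differ by less than `tol` RMSD (or `max_iter` passes). In practice
#' the second mean is already essentially converged.
#'
#' @param ensemble A [calpha_ensemble()].
#' @param tol Convergence threshold on the RMSD between successive means (Å).
#' @param max_iter Maximum refinement passes.
#' @return A [calpha()] holding the mean coordinates (no B-factors).
#' @examples
#' xyz <- cbind(0:9 * 3.8, sin(0:9), 0)
#' e <- calpha_ensemble(list(calpha("t", "A", 1:10, xyz),
#'                           calpha("t", "A", 1:10, xyz + 0.05)))
#' mean_structure(e)
#' @export
mean_structure <- function(ensemble, tol = 1e-6, max_iter = 10L) {
  stopifnot(inherits(ensemble, "calpha_ensemble"))
  models <- ensemble$models
  if (length(models) == 1L) {
    out <- models[[1]]
    out$bfactors <- NULL
    return(out)
  }
  ref <- models[[1]]$coords
  superpose_all <- function(target) {
    lapply(models, function(m)
      apply_transform(kabsch_superpose(m$coords, target), m$coords))
  }
  fitted <- superpose_all(ref)
  mean_xyz <- Reduce(`+`, fitted) / length(fitted)
  for (it in seq_len(max_iter)) {
    fitted <- superpose_all(mean_xyz)
    new_mean <- Reduce(`+`, fitted) / length(fitted)
    delta <- sqrt(mean(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (delta < tol) break
  }
  calpha(ensemble$protein_id, models[[1]]$chain_id,
         models[[1]]$residue_numbers, mean_xyz)
}

#' Per-residue RMSF of an ensemble
#'
#' Computes the root mean square fluctuation of each C-alpha about the
#' iterative mean structure: every model is superposed on the converged
#' mean, and
#' \deqn{RMSF_i = \sqrt{\frac{1}{M}\sum_{j=1}^{M} |x_i(j) - \langle x_i\rangle|^2}}
#' with M the number of models (a population average over snapshots, so the
#' denominator is M, not M-1).
#'
#' @param ensemble A [calpha_ensemble()] with at least two models.
#' @param source Provenance tag for the resulting profile: `"nmr"` for
#'   experimental ensembles, `"predicted"` (default) otherwise.
#' @return An unnormalized [fluct_profile()] in Å.
#' @examples
#' set.seed(1)
#' ref <- cbind(0:19 * 3.8, 0, 0)
#' mods <- lapply(1:50, function(i)
#'   calpha("t", "A", 1:20, ref + matrix(rnorm(60, sd = 0.3), ncol = 3)))
#' ensemble_rmsf(calpha_ensemble(mods))
#' @export
ensemble_rmsf <- function(ensemble, source = c("predicted", "nmr")) {
  stopifnot(inherits(ensemble, "calpha_ensemble"))
  source <- match.arg(source)
  if (length(ensemble$models) < 2L)
    stop("ensemble_rmsf: at least two models required")
  mean_ca <- mean_structure(ensemble)
  mean_xyz <- mean_ca$coords
  sq <- matrix(0, nrow = length(ensemble$models), ncol = nrow(mean_xyz))
  for (j in seq_along(ensemble$models)) {
    fit <- apply_transform(
      kabsch_superpose(ensemble$models[[j]]$coords, mean_xyz),
      ensemble$models[[j]]$coords)
    sq[j, ] <- rowSums((fit - mean_xyz)^2)
  }
  fluct_profile(ensemble$protein_id, mean_ca$residue_numbers,
                sqrt(colMeans(sq)), source)
}
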