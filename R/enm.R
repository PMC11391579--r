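#' Anisotropic elastic-network model on a C-alpha trace
#'
#' Defines the harmonic anisotropic elastic network (AEN): every residue
#' pair whose reference C-alpha distance is below `cutoff` is connected by
#' a spring of force constant `gamma` anchored at that reference distance,
#' \deqn{E = \frac{\gamma}{2} \sum_{d^0_{ij} < cutoff} (d_{ij} - d^0_{ij})^2.}
#' Normal modes are obtained by diagonalizing the Hessian of this potential
#' at the reference structure.
#'
#' @param coords Reference C-alpha coordinates: an n x 3 matrix or a
#'   [calpha()] model.
#' @param cutoff Interaction distance threshold in Å (default 12, a standard
#'   value for C-alpha anisotropic networks).
#' @param gamma Spring force constant (default 1; the absolute scale cancels
#'   once profiles are normalized).
#' @return An object of class `"enm_model"`.
#' @examples
#' m <- enm_model(cbind(0:9 * 3.8, sin(0:9), cos(0:9)))
#' m$cutoff
#' @export
enm_model <- function(coords, cutoff = 12, gamma = 1) {
  resno <- NULL
  pid <- "enm"
  if (inherits(coords, "calpha")) {
    resno <- coords$residue_numbers
    pid <- coords$protein_id
    coords <- coords$coords
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) < 2L)
    stop("enm_model: coords must be an n x 3 matrix with n >= 2")
  if (cutoff <= 0 || gamma <= 0)
    stop("enm_model: cutoff and gamma must be positive")
  if (is.null(resno)) resno <- seq_len(nrow(coords))
  structure(list(coords = unname(coords), cutoff = cutoff, gamma = gamma,
                 residue_numbers = as.integer(resno), protein_id = pid),
            class = "enm_model")
}

#' Hessian matrix of the elastic-network potential
#'
#' Builds the 3N x 3N second-derivative matrix of the AEN potential at the
#' reference structure. For each contact pair (i, j) within the cutoff the
#' off-diagonal 3x3 block is \eqn{-\gamma\, r_{ij} r_{ij}^T / |r_{ij}|^2}
#' with \eqn{r_{ij}} the reference inter-residue vector; diagonal blocks are
#' minus the sum of the row's off-diagonal blocks, so each row of blocks
#' sums to zero (translational invariance).
#'
#' @param model An [enm_model()].
#' @return A symmetric 3N x 3N numeric matrix.
#' @examples
#' h <- build_hessian(enm_model(rbind(c(0, 0, 0), c(3.8, 0, 0)), cutoff = 8))
#' eigen(h, symmetric = TRUE)$values
#' @export
build_hessian <- function(model) {
  stopifnot(inherits(model, "enm_model"))
  xyz <- model$coords
  n <- nrow(xyz)
  dmat <- as.matrix(stats::dist(xyz))
  if (any(dmat[upper.tri(dmat)] < 1e-6))
    stop("build_hessian: coincident residues in reference structure")
  H <- matrix(0, 3 * n, 3 * n)
  idx <- function(i) (3 * (i - 1) + 1):(3 * i)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- dmat[i, j]
      if (d >= model$cutoff) next
      r <- xyz[j, ] - xyz[i, ]
      blk <- -model$gamma * tcrossprod(r) / d^2
      H[idx(i), idx(j)] <- blk
      H[idx(j), idx(i)] <- blk
      H[idx(i), idx(i)] <- H[idx(i), idx(i)] - blk
      H[idx(j), idx(j)] <- H[idx(j), idx(j)] - blk
    }
  }
  H
}

#' Normal modes of an elastic network
#'
#' Full symmetric eigendecomposition of the Hessian. Modes whose eigenvalue
#' is below `tol_zero` times the largest eigenvalue are flagged as zero
#' (rigid-body) modes. A connected, non-collinear three-dimensional network
#' has exactly six: three translations and three rotations.
#'
#' @param hessian Symmetric 3N x 3N matrix from [build_hessian()], or an
#'   [enm_model()] (whose Hessian is built first).
#' @param tol_zero Relative eigenvalue threshold for zero-mode detection.
#'   Rigid-body eigenvalues sit at the numerical noise floor (below about
#'   1e-12 of the largest eigenvalue in double precision), while loosely
#'   packed chains can have genuine internal modes as soft as a few 1e-9;
#'   the default 1e-10 separates the two with margin on both sides.
#' @param expected_zero Number of zero modes required (default 6). More
#'   flagged modes raise a disconnected-network error, fewer a
#'   numerical-tolerance error; set `strict = FALSE` to accept any count
#'   (needed e.g. for two-body or collinear systems, which have five).
#' @param strict Enforce `expected_zero`?
#' @return An object of class `"enm_modes"`: `eigenvalues` (ascending),
#'   `eigenvectors` (orthonormal columns, matching order), `n_zero`.
#' @examples
#' set.seed(7)
#' m <- enm_model(cbind(0:9 * 3.8, rnorm(10), rnorm(10)))
#' compute_modes(m)$n_zero
#' @export
compute_modes <- function(hessian, tol_zero = 1e-10, expected_zero = 6L,
                          strict = TRUE) {
  if (inherits(hessian, "enm_model")) hessian <- build_hessian(hessian)
  hessian <- as.matrix(hessian)
  if (max(abs(hessian - t(hessian))) > 1e-9)
    stop("compute_modes: matrix is not symmetric")
  e <- eigen(hessian, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  lam_max <- max(abs(values))
  n_zero <- if (lam_max == 0) length(values)
            else sum(abs(values) < tol_zero * lam_max)
  if (strict) {
    if (n_zero > expected_zero)
      stop(sprintf(paste0("compute_modes: %d zero modes (expected %d); the ",
                          "network is disconnected"), n_zero, expected_zero))
    if (n_zero < expected_zero)
      stop(sprintf(paste0("compute_modes: only %d zero modes (expected %d); ",
                          "check tol_zero"), n_zero, expected_zero))
  }
  structure(list(eigenvalues = values, eigenvectors = vectors,
                 n_zero = n_zero, tol_zero = tol_zero),
            class = "enm_modes")
}

#' @export
print.enm_modes <- function(x, ...) {
  cat(sprintf("ENM modes: %d total, %d zero; lowest internal eigenvalue %.4g\n",
              length(x$eigenvalues), x$n_zero,
              if (x$n_zero < length(x$eigenvalues))
                x$eigenvalues[x$n_zero + 1] else NA))
  invisible(x)
}

#' Mode-derived per-residue fluctuation profile
#'
#' In the harmonic approximation the mean-square fluctuation of residue i is
#' proportional to the diagonal of the Hessian pseudo-inverse:
#' \deqn{\langle \Delta r_i^2 \rangle = c \sum_{k > n_{zero}}
#'   \frac{1}{\lambda_k} (v_{k,ix}^2 + v_{k,iy}^2 + v_{k,iz}^2),}
#' summing over the internal (non-rigid-body) modes. The profile is the
#' square root of these values; the overall scale `c` is arbitrary (it
#' cancels under normalization) and defaults to 1.
#'
#' @param modes An [enm_modes()] object (with zero modes flagged), or an
#'   [enm_model()] / coordinate matrix, in which case modes are computed
#'   first.
#' @param scale Multiplicative constant `c` applied to the mean-square
#'   fluctuations.
#' @param residue_numbers,protein_id Optional labelling when `modes` carries
#'   none.
#' @return A [fluct_profile()] with `source = "predicted"`.
#' @examples
#' set.seed(7)
#' m <- enm_model(cbind(0:9 * 3.8, rnorm(10), rnorm(10)))
#' enm_rmsf(m)
#' @export
enm_rmsf <- function(modes, scale = 1, residue_numbers = NULL,
                     protein_id = "enm") {
  if (inherits(modes, "calpha") || is.matrix(modes))
    modes <- enm_model(modes)
  if (inherits(modes, "enm_model")) {
    if (is.null(residue_numbers)) residue_numbers <- modes$residue_numbers
    protein_id <- modes$protein_id
    modes <- compute_modes(modes)
  }
  stopifnot(inherits(modes, "enm_modes"))
  nk <- length(modes$eigenvalues)
  n <- nk / 3L
  if (modes$n_zero >= nk) stop("enm_rmsf: no internal modes")
  internal <- (modes$n_zero + 1):nk
  msf <- numeric(n)
  for (k in internal) {
    v2 <- matrix(modes$eigenvectors[, k]^2, nrow = 3)
    msf <- msf + colSums(v2) / modes$eigenvalues[k]
  }
  if (is.null(residue_numbers)) residue_numbers <- seq_len(n)
  fluct_profile(protein_id, residue_numbers, sqrt(scale * msf),
                source = "predicted")
}
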