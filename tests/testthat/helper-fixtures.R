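# Shared fixtures and independent oracles used across test files.

# Fixed-column PDB ATOM line (same layout the package writes, but assembled
# independently so reader tests do not depend on the writer).
pdb_atom_line <- function(serial, resno, x, y, z, chain = "A", occ = 1,
                          b = 0, altloc = " ", name = " CA ",
                          record = "ATOM  ", icode = " ") {
  sprintf("%s%5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name, altloc, "ALA", chain, resno, icode,
          x, y, z, occ, b)
}

# Two-model, five-residue NMR-style fixture.
two_model_fixture <- function() {
  lines <- c("MODEL        1")
  for (i in 1:5)
    lines <- c(lines, pdb_atom_line(i, i, i * 3.8, 0, 0, b = i))
  lines <- c(lines, "TER", "ENDMDL", "MODEL        2")
  for (i in 1:5)
    lines <- c(lines, pdb_atom_line(i, i, i * 3.8, 0.5, 0, b = i + 1))
  lines <- c(lines, "TER", "ENDMDL", "END")
  paste(lines, collapse = "\n")
}

# Random non-degenerate calpha model (self-avoiding walk trace).
random_trace <- function(n, seed) make_trace(n, "random_walk", seed = seed)

# Compact random point cloud with protein-like density and excluded volume:
# a connected, well-conditioned elastic network under a 12 A cutoff (chain
# walks can carry nearly-straight dangling ends, i.e. genuine soft modes).
random_cluster <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- 0
  radius <- 3 * n^(1 / 3)
  k <- 1
  while (k < n) {
    cand <- stats::runif(3, -radius, radius)
    if (sqrt(sum(cand^2)) > radius) next
    if (min(sqrt(colSums((t(pts[1:k, , drop = FALSE]) - cand)^2))) > 3.8) {
      k <- k + 1
      pts[k, ] <- cand
    }
  }
  pts
}

# Independent per-residue mean-square-fluctuation oracle: 3x3 block traces
# of the Moore-Penrose pseudo-inverse of the Hessian.
pinv_msf <- function(hessian) {
  g <- diag(MASS::ginv(hessian, tol = 1e-10))
  colSums(matrix(g, nrow = 3))
}

# Brute-force rank-based Spearman: average ranks + explicit product-moment
# formula, written without stats::cor.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Explicit product-moment Pearson, without stats::cor.
brute_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Random proper rotation matrix for invariance tests.
test_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
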