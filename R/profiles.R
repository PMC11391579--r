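#' B-factor / RMSF conversion (Debye-Waller relation)
#'
#' The crystallographic B-factor is related to the isotropic mean-square
#' displacement by \eqn{B = \frac{8\pi^2}{3}\, RMSF^2}, so
#' \eqn{RMSF = \sqrt{3B / (8\pi^2)}}. The two functions are exact inverses.
#'
#' @param b B-factor(s) in Å², non-negative.
#' @param rmsf Fluctuation value(s) in Å, non-negative.
#' @return `bfactor_to_rmsf`: RMSF in Å; `rmsf_to_bfactor`: B in Å².
#' @examples
#' bfactor_to_rmsf(8 * pi^2 / 3)   # exactly 1
#' rmsf_to_bfactor(1)
#' @export
bfactor_to_rmsf <- function(b) {
  b <- as.numeric(b)
  if (any(!is.finite(b)) || any(b < 0))
    stop("bfactor_to_rmsf: B-factors must be finite and non-negative")
  sqrt(3 * b / (8 * pi^2))
}

#' @rdname bfactor_to_rmsf
#' @export
rmsf_to_bfactor <- function(rmsf) {
  rmsf <- as.numeric(rmsf)
  if (any(!is.finite(rmsf)) || any(rmsf < 0))
    stop("rmsf_to_bfactor: RMSF values must be finite and non-negative")
  (8 * pi^2 / 3) * rmsf^2
}

#' Experimental fluctuation profile from X-ray B-factors
#'
#' Converts the per-residue C-alpha B-factor column of a crystal structure
#' into an RMSF profile via the Debye-Waller relation, over the whole chain.
#'
#' @param structure A [calpha()] with B-factors present.
#' @return A [fluct_profile()] with `source = "xray"`, in Å.
#' @examples
#' s <- calpha("x", "A", 1:3, cbind(0:2 * 3.8, 0, 0),
#'             bfactors = c(26.32, 0, 26.32))
#' xray_profile(s)$values
#' @export
xray_profile <- function(structure) {
  stopifnot(inherits(structure, "calpha"))
  if (is.null(structure$bfactors))
    stop("xray_profile: structure has no B-factors")
  fluct_profile(structure$protein_id, structure$residue_numbers,
                bfactor_to_rmsf(structure$bfactors), source = "xray")
}

#' Terminal-segment truncation of a fluctuation profile
#'
#' Chain termini usually fluctuate far more than the core, which can
#' dominate profile comparisons; this trims them. The mean m and standard
#' deviation s of the whole profile are computed, then residues are removed
#' from the N-terminus inward while their value strictly exceeds
#' m + `threshold_sd` * s, and likewise from the C-terminus. Interior
#' residues are never removed. With `iterate = TRUE` (the NMR convention)
#' m and s are recomputed on the kept segment and the procedure repeats
#' until nothing more is removed or at most `min_keep` residues remain;
#' X-ray profiles use a single pass.
#'
#' @param profile A [fluct_profile()] with at least 3 residues.
#' @param iterate Repeat on the truncated chain (NMR convention)?
#' @param threshold_sd Multiples of the standard deviation above the mean.
#' @param sd_convention `"sample"` (n-1) or `"population"` (n).
#' @param min_keep Iteration stops once the kept segment is this short.
#' @return A list of class `"truncation_range"`: `first_kept`, `last_kept`
#'   (residue numbers), `lnt`, `lct` (counts removed at N- and C-termini).
#' @examples
#' p <- fluct_profile("t", 1:8, c(10, 1, 1, 1, 1, 1, 1, 10), "nmr")
#' truncate_termini(p, iterate = TRUE)
#' @export
truncate_termini <- function(profile, iterate = FALSE, threshold_sd = 1,
                             sd_convention = c("sample", "population"),
                             min_keep = 3L) {
  stopifnot(inherits(profile, "fluct_profile"))
  sd_convention <- match.arg(sd_convention)
  v <- profile$values
  n0 <- length(v)
  if (n0 < 3L) stop("truncate_termini: at least 3 residues required")
  sdev <- function(x) {
    s <- stats::sd(x)                       # sample (n-1)
    if (sd_convention == "population")
      s <- s * sqrt((length(x) - 1) / length(x))
    if (is.finite(s)) s else 0
  }
  lo <- 1L; hi <- n0
  repeat {
    kept <- v[lo:hi]
    thr <- mean(kept) + threshold_sd * sdev(kept)
    removed <- 0L
    while (lo < hi && v[lo] > thr) { lo <- lo + 1L; removed <- removed + 1L }
    while (hi > lo && v[hi] > thr) { hi <- hi - 1L; removed <- removed + 1L }
    if (hi - lo + 1L < min_keep)
      stop("truncate_termini: truncation would remove (almost) everything")
    if (!iterate || removed == 0L || hi - lo + 1L <= min_keep) break
  }
  structure(list(first_kept = profile$residue_numbers[lo],
                 last_kept = profile$residue_numbers[hi],
                 lnt = lo - 1L, lct = n0 - hi),
            class = "truncation_range")
}

#' @export
print.truncation_range <- function(x, ...) {
  cat(sprintf("Truncation: keep residues %d-%d (removed %d N-terminal, %d C-terminal)\n",
              x$first_kept, x$last_kept, x$lnt, x$lct))
  invisible(x)
}

#' Normalize a fluctuation profile to unit maximum
#'
#' Divides every value by the profile maximum so that different fluctuation
#' amplitudes become comparable; the result has maximum exactly 1. Pearson
#' and Spearman correlations are invariant to this positive rescaling.
#'
#' @param profile A [fluct_profile()] with at least one positive value.
#' @return The normalized [fluct_profile()] (`normalized = TRUE`).
#' @examples
#' normalize_profile(fluct_profile("t", 1:3, c(2, 4, 8), "nmr"))$values
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "fluct_profile"))
  mx <- max(profile$values)
  if (mx <= 0)
    stop("normalize_profile: all-zero profile cannot be normalized")
  fluct_profile(profile$protein_id, profile$residue_numbers,
                profile$values / mx, profile$source, normalized = TRUE)
}

#' Replicate-averaged fluctuation profile
#'
#' Combines replicate profiles of the same protein (e.g. independent
#' trajectories) into one: each profile is first normalized to unit maximum,
#' the normalized profiles are averaged element-wise, and the mean is
#' re-normalized. Set `normalize_first = FALSE` to average raw values
#' instead (the result is still re-normalized).
#'
#' @param profiles List of [fluct_profile()] objects with identical residue
#'   numbering.
#' @param normalize_first Normalize each replicate before averaging?
#' @return A normalized [fluct_profile()]; the source tag is taken from the
#'   first replicate.
#' @examples
#' p1 <- fluct_profile("t", 1:3, c(1, 2, 4), "predicted")
#' p2 <- fluct_profile("t", 1:3, c(2, 4, 8), "predicted")
#' average_replicates(list(p1, p2))$values
#' @export
average_replicates <- function(profiles, normalize_first = TRUE) {
  if (!is.list(profiles) || length(profiles) < 1L)
    stop("average_replicates: at least one profile required")
  stopifnot(all(vapply(profiles, inherits, logical(1), "fluct_profile")))
  rn <- profiles[[1]]$residue_numbers
  for (p in profiles)
    if (!identical(p$residue_numbers, rn))
      stop("average_replicates: residue numbering differs between replicates")
  vals <- vapply(profiles, function(p) {
    if (normalize_first) normalize_profile(p)$values else p$values
  }, numeric(length(rn)))
  avg <- rowMeans(as.matrix(vals))
  normalize_profile(fluct_profile(profiles[[1]]$protein_id, rn, avg,
                                  profiles[[1]]$source))
}
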