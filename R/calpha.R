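#' C-alpha trace of a single structural model
#'
#' A `calpha` object holds the ordered C-alpha trace of one model of a
#' protein chain: residue sequence numbers, Cartesian coordinates (Å) and,
#' when available, per-residue B-factors (Å², taken from the C-alpha atom).
#'
#' @param protein_id Text label for the protein.
#' @param chain_id One-character chain identifier.
#' @param residue_numbers Strictly increasing integer vector of PDB residue
#'   sequence numbers.
#' @param coords Numeric n x 3 matrix of coordinates in Å.
#' @param bfactors Optional numeric vector of B-factors in Å² (one per
#'   residue), or `NULL` when the model carries none.
#'
#' @return An object of class `"calpha"`.
#' @examples
#' xyz <- cbind(seq(0, 19) * 3.8, 0, 0)
#' s <- calpha("toy", "A", 1:20, xyz)
#' length(s$residue_numbers)
#' @export
calpha <- function(protein_id, chain_id, residue_numbers, coords,
                   bfactors = NULL) {
  residue_numbers <- as.integer(residue_numbers)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(residue_numbers)
  if (n < 1L) stop("calpha: at least one residue required")
  if (any(diff(residue_numbers) <= 0L))
    stop("calpha: residue numbers must be strictly increasing")
  if (!is.matrix(coords) || ncol(coords) != 3L || nrow(coords) != n)
    stop("calpha: coords must be an n x 3 matrix matching residue_numbers")
  if (!all(is.finite(coords)))
    stop("calpha: all coordinates must be finite")
  if (!is.null(bfactors)) {
    bfactors <- as.numeric(bfactors)
    if (length(bfactors) != n)
      stop("calpha: bfactors length must match residue_numbers")
  }
  structure(list(protein_id = as.character(protein_id)[1],
                 chain_id = as.character(chain_id)[1],
                 residue_numbers = residue_numbers,
                 coords = unname(coords),
                 bfactors = bfactors),
            class = "calpha")
}

#' @export
print.calpha <- function(x, ...) {
  cat(sprintf("C-alpha trace '%s' chain %s: %d residues (%d-%d)%s\n",
              x$protein_id, x$chain_id, length(x$residue_numbers),
              min(x$residue_numbers), max(x$residue_numbers),
              if (is.null(x$bfactors)) "" else ", with B-factors"))
  invisible(x)
}

#' @export
length.calpha <- function(x) length(x$residue_numbers)

#' Ensemble of C-alpha models with shared residue indexing
#'
#' Wraps an ordered list of [calpha()] models (an NMR ensemble, simulation
#' snapshots or a replicate set). All models must agree on chain identifier
#' and residue numbering.
#'
#' @param models List of `calpha` objects.
#' @param protein_id Text label; defaults to the first model's label.
#'
#' @return An object of class `"calpha_ensemble"`.
#' @examples
#' xyz <- cbind(seq(0, 9) * 3.8, 0, 0)
#' m <- calpha("toy", "A", 1:10, xyz)
#' e <- calpha_ensemble(list(m, m))
#' length(e$models)
#' @export
calpha_ensemble <- function(models, protein_id = NULL) {
  if (!is.list(models) || length(models) < 1L)
    stop("calpha_ensemble: at least one model required")
  if (!all(vapply(models, inherits, logical(1), "calpha")))
    stop("calpha_ensemble: all models must be 'calpha' objects")
  ref <- models[[1]]
  for (k in seq_along(models)) {
    m <- models[[k]]
    if (!identical(m$residue_numbers, ref$residue_numbers) ||
        !identical(m$chain_id, ref$chain_id))
      stop(sprintf(paste0("calpha_ensemble: model %d has a different residue",
                          " set or chain than model 1"), k))
  }
  structure(list(models = models,
                 protein_id = if (is.null(protein_id)) ref$protein_id
                              else as.character(protein_id)[1]),
            class = "calpha_ensemble")
}

#' @export
print.calpha_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble '%s': %d models x %d residues\n", x$protein_id,
              length(x$models), length(x$models[[1]]$residue_numbers)))
  invisible(x)
}

# Stack ensemble coordinates into an M x N x 3 array.
ensemble_coord_array <- function(ensemble) {
  n <- length(ensemble$models[[1]]$residue_numbers)
  m <- length(ensemble$models)
  arr <- array(NA_real_, dim = c(m, n, 3))
  for (j in seq_len(m)) arr[j, , ] <- ensemble$models[[j]]$coords
  arr
}

#' Per-residue fluctuation profile
#'
#' Stores a per-residue fluctuation magnitude (RMSF in Å, or unitless once
#' normalized so the maximum equals one) together with its provenance:
#' `"nmr"` (ensemble spread), `"xray"` (converted B-factors) or
#' `"predicted"`.
#'
#' @param protein_id Text label.
#' @param residue_numbers Strictly increasing integer vector.
#' @param values Non-negative numeric vector, same length.
#' @param source One of `"nmr"`, `"xray"`, `"predicted"`.
#' @param normalized Logical; `TRUE` when values have been divided by their
#'   maximum.
#'
#' @return An object of class `"fluct_profile"`.
#' @examples
#' p <- fluct_profile("toy", 1:4, c(0.5, 1, 2, 4), "predicted")
#' max(normalize_profile(p)$values)
#' @export
fluct_profile <- function(protein_id, residue_numbers, values,
                          source = c("predicted", "nmr", "xray"),
                          normalized = FALSE) {
  source <- match.arg(source)
  residue_numbers <- as.integer(residue_numbers)
  values <- as.numeric(values)
  if (length(values) != length(residue_numbers))
    stop("fluct_profile: values and residue_numbers must have equal length")
  if (any(diff(residue_numbers) <= 0L))
    stop("fluct_profile: residue numbers must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("fluct_profile: values must be finite and non-negative")
  if (isTRUE(normalized) && abs(max(values) - 1) > 1e-12)
    stop("fluct_profile: normalized profile must have maximum 1")
  structure(list(protein_id = as.character(protein_id)[1],
                 residue_numbers = residue_numbers,
                 values = values,
                 source = source,
                 normalized = isTRUE(normalized)),
            class = "fluct_profile")
}

#' @export
print.fluct_profile <- function(x, ...) {
  cat(sprintf("Fluctuation profile '%s' (%s%s): %d residues, range %.3g-%.3g\n",
              x$protein_id, x$source,
              if (x$normalized) ", normalized" else ", Å",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Restrict a profile to a residue-number window
#'
#' @param profile A [fluct_profile()].
#' @param first_kept,last_kept Residue numbers bounding the kept segment
#'   (inclusive), e.g. from [truncate_termini()].
#' @return The restricted `fluct_profile`.
#' @examples
#' p <- fluct_profile("toy", 1:5, c(9, 1, 1, 1, 9), "nmr")
#' restrict_profile(p, 2, 4)$values
#' @export
restrict_profile <- function(profile, first_kept, last_kept) {
  stopifnot(inherits(profile, "fluct_profile"))
  keep <- profile$residue_numbers >= first_kept &
          profile$residue_numbers <= last_kept
  if (!any(keep)) stop("restrict_profile: empty residue window")
  fluct_profile(profile$protein_id, profile$residue_numbers[keep],
                profile$values[keep], profile$source,
                normalized = FALSE)
}
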