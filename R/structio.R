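#' Read a C-alpha ensemble from PDB-format text
#'
#' Parses the fixed-column ATOM records of a PDB file into a
#' [calpha_ensemble()]. Each `MODEL`/`ENDMDL` block becomes one model; a file
#' without `MODEL` records yields a single-model ensemble. Only C-alpha
#' (`CA`) ATOM records on the selected chain are retained; `HETATM` records
#' and other atoms are ignored. Alternate locations are resolved to the
#' highest-occupancy record (first wins on a tie). The B-factor column
#' (61-66) is parsed into per-model B-factor vectors.
#'
#' @param pdb Either a path to a PDB file, or PDB-format text (a single
#'   string containing newlines, or a character vector of lines).
#' @param chain Chain identifier to extract; `NULL` (default) selects the
#'   first chain encountered among C-alpha records.
#' @param protein_id Label for the ensemble; defaults to the file base name
#'   or `"pdb"` for literal text.
#'
#' @return A [calpha_ensemble()].
#' @details Residue identity is (chain, residue sequence number); records
#'   carrying an insertion code are rejected with an error rather than
#'   silently misaligned. Models whose residue sets differ raise an
#'   ensemble-consistency error.
#' @examples
#' txt <- write_ensemble_pdb(calpha_ensemble(list(
#'   calpha("toy", "A", 1:3, cbind(0:2 * 3.8, 0, 0)))))
#' e <- read_calpha_ensemble(txt)
#' length(e$models)
#' @export
read_calpha_ensemble <- function(pdb, chain = NULL, protein_id = NULL) {
  if (length(pdb) == 1L && !grepl("\n", pdb, fixed = TRUE) &&
      file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(protein_id))
      protein_id <- sub("\\.pdb$", "", basename(pdb), ignore.case = TRUE)
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
    if (is.null(protein_id)) protein_id <- "pdb"
  }
  lines <- sub("[ \t\r]+$", "", lines)

  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  "
  is_model <- rec == "MODEL "
  is_endmdl <- rec == "ENDMDL"

  # Assign a model index to every line: 1 before any MODEL record, then the
  # running count of MODEL records seen.
  model_no <- cumsum(is_model)
  model_no[model_no == 0L] <- 1L
  if (!any(is_model)) model_no <- rep(1L, length(lines))

  atom_idx <- which(is_atom)
  if (length(atom_idx) == 0L) stop("read_calpha_ensemble: no ATOM records")
  al <- lines[atom_idx]
  atom_name <- trimws(substr(al, 13, 16))
  ca <- atom_name == "CA"
  if (!any(ca)) stop("read_calpha_ensemble: no CA atoms found")
  al <- al[ca]
  amodel <- model_no[atom_idx][ca]

  chain_col <- substr(al, 22, 22)
  if (is.null(chain)) chain <- chain_col[1]
  on_chain <- chain_col == chain
  if (!any(on_chain))
    stop(sprintf("read_calpha_ensemble: no CA atoms on chain '%s'", chain))
  al <- al[on_chain]
  amodel <- amodel[on_chain]

  icode <- substr(al, 27, 27)
  if (any(icode != " " & icode != ""))
    stop("read_calpha_ensemble: insertion codes are not supported")

  resno <- as.integer(substr(al, 23, 26))
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  occ_txt <- trimws(substr(al, 55, 60))
  occ <- suppressWarnings(as.numeric(occ_txt))
  occ[is.na(occ)] <- 1
  b_txt <- trimws(substr(al, 61, 66))
  bfac <- suppressWarnings(as.numeric(b_txt))
  if (any(is.na(resno)) || any(is.na(x)) || any(is.na(y)) || any(is.na(z)))
    stop("read_calpha_ensemble: malformed ATOM record")

  models <- lapply(sort(unique(amodel)), function(mi) {
    sel <- amodel == mi
    rn <- resno[sel]
    # Altloc / duplicate CA resolution: highest occupancy, first on tie.
    ord <- order(rn, -occ[sel], seq_len(sum(sel)))
    keep <- ord[!duplicated(rn[ord])]
    keep <- keep[order(rn[keep])]
    b <- bfac[sel][keep]
    if (all(is.na(b)) || all(b_txt[sel][keep] == "")) b <- NULL
    else b[is.na(b)] <- 0
    calpha(protein_id, chain, rn[keep],
           cbind(x[sel][keep], y[sel][keep], z[sel][keep]), b)
  })

  ref <- models[[1]]$residue_numbers
  for (k in seq_along(models))
    if (!identical(models[[k]]$residue_numbers, ref))
      stop(sprintf(paste0("read_calpha_ensemble: model %d residue set ",
                          "differs from model 1 (ensemble inconsistency)"), k))
  calpha_ensemble(models, protein_id = protein_id)
}

#' Write a C-alpha ensemble as PDB-format text
#'
#' Emits fixed-column ATOM records (coordinates to 3 decimals, occupancy and
#' B-factors to 2, per PDB convention). Multi-model ensembles are wrapped in
#' `MODEL`/`ENDMDL` blocks; single-model ensembles are written as bare ATOM
#' records. `read_calpha_ensemble()` round-trips the output up to
#' fixed-width rounding.
#'
#' @param ensemble A [calpha_ensemble()] (or a single [calpha()] model,
#'   which is wrapped).
#' @param file Optional path; when given the text is also written there.
#' @return The PDB text as a single string (invisibly when `file` is given).
#' @examples
#' e <- calpha_ensemble(list(calpha("toy", "A", 1:3, cbind(0:2 * 3.8, 0, 0))))
#' cat(substr(write_ensemble_pdb(e), 1, 66), "\n")
#' @export
write_ensemble_pdb <- function(ensemble, file = NULL) {
  if (inherits(ensemble, "calpha"))
    ensemble <- calpha_ensemble(list(ensemble))
  stopifnot(inherits(ensemble, "calpha_ensemble"))
  multi <- length(ensemble$models) > 1L
  out <- character(0)
  for (j in seq_along(ensemble$models)) {
    m <- ensemble$models[[j]]
    b <- if (is.null(m$bfactors)) rep(0, length(m$residue_numbers))
         else m$bfactors
    atom_lines <- sprintf(
      "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_along(m$residue_numbers), m$chain_id, m$residue_numbers,
      m$coords[, 1], m$coords[, 2], m$coords[, 3], 1, b)
    if (multi)
      out <- c(out, sprintf("MODEL     %4d", j), atom_lines, "ENDMDL")
    else
      out <- c(out, atom_lines)
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(txt))
  }
  txt
}
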