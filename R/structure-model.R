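#' Construct a structure model
#'
#' A `structure_model` holds the atomic coordinates of one conformational
#' state as a flat atom table (one row per atom), the representation used by
#' every other module.  Rows are ordered by chain, then author residue
#' number and insertion code, preserving file order within a residue.
#'
#' @param atom data frame with columns `type`, `eleno`, `elety`, `alt`,
#'   `resid`, `base`, `chain`, `resno`, `insert`, `refno`, `unmapped`,
#'   `x`, `y`, `z`, `o`, `b`, `elesy`.  Missing bookkeeping columns are
#'   filled with defaults; coordinate columns are mandatory.
#' @param source_id identifier of the originating file or generator.
#' @param metadata free-form named list.
#'
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atom, source_id = "model", metadata = list()) {
  stopifnot(is.data.frame(atom), all(c("x", "y", "z") %in% names(atom)))
  defaults <- list(type = "ATOM", eleno = NA_integer_, elety = "P",
                   alt = "", resid = "N", chain = "A", resno = NA_integer_,
                   insert = "", o = 1, b = 0, elesy = "")
  for (nm in names(defaults)) {
    if (is.null(atom[[nm]])) atom[[nm]] <- defaults[[nm]]
  }
  if (is.null(atom$base)) atom$base <- parent_base(atom$resid)
  if (is.null(atom$refno)) atom$refno <- NA_integer_
  if (is.null(atom$unmapped)) atom$unmapped <- NA
  atom$alt[is.na(atom$alt)] <- ""
  atom$insert[is.na(atom$insert)] <- ""
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z))) {
    stop("non-finite coordinates in atom table", call. = FALSE)
  }
  bad_occ <- !is.na(atom$o) & (atom$o < 0 | atom$o > 1)
  if (any(bad_occ)) stop("occupancy outside [0, 1]", call. = FALSE)
  ord <- order(atom$chain, atom$resno, atom$insert)
  atom <- atom[ord, , drop = FALSE]
  rownames(atom) <- NULL
  if (is.na(atom$eleno[1])) atom$eleno <- seq_len(nrow(atom))
  structure(list(source_id = source_id, atom = atom, metadata = metadata),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  rt <- residue_table(x)
  cat("structure_model '", x$source_id, "': ",
      nrow(x$atom), " atoms, ", nrow(rt), " residues, ",
      length(unique(x$atom$chain)), " chain(s) [",
      paste(unique(x$atom$chain), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Map residue names to their parent base
#'
#' Standard ribonucleotides map to themselves, common modified nucleotides
#' map through a built-in table, anything else to `"N"`.
#'
#' @param resid character vector of residue names.
#' @return character vector of `A`, `C`, `G`, `U` or `N`.
#' @export
parent_base <- function(resid) {
  resid <- toupper(trimws(resid))
  out <- ifelse(resid %in% RIBONUCLEOTIDES, resid,
                unname(MODIFIED_BASE_TABLE[resid]))
  # DNA-style names occasionally appear in author fields
  dna <- c(DA = "A", DC = "C", DG = "G", DT = "U", DU = "U")
  out[is.na(out) & resid %in% names(dna)] <- dna[resid[is.na(out) & resid %in% names(dna)]]
  out[is.na(out)] <- "N"
  out
}

# Unique residue key (chain | author number | insertion code).
residue_key <- function(atom) {
  paste(atom$chain, atom$resno, atom$insert, sep = "|")
}

#' Residue-level summary of a structure model
#'
#' @param model a `structure_model`.
#' @return data frame with one row per residue: `chain`, `resno`, `insert`,
#'   `resid`, `base`, `refno`, `unmapped`, `n_atoms` and the atom-table row
#'   range (`first`, `last`).
#' @export
residue_table <- function(model) {
  atom <- model$atom
  key <- residue_key(atom)
  first <- which(!duplicated(key))
  last <- c(first[-1] - 1L, nrow(atom))
  data.frame(chain = atom$chain[first], resno = atom$resno[first],
             insert = atom$insert[first], resid = atom$resid[first],
             base = atom$base[first], refno = atom$refno[first],
             unmapped = atom$unmapped[first],
             n_atoms = last - first + 1L, first = first, last = last,
             stringsAsFactors = FALSE)
}

#' Coordinate matrix of a structure model
#'
#' @param model a `structure_model`.
#' @param rows optional row index into the atom table.
#' @return numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @export
coords <- function(model, rows = NULL) {
  atom <- model$atom
  if (!is.null(rows)) atom <- atom[rows, , drop = FALSE]
  cbind(x = atom$x, y = atom$y, z = atom$z)
}

# Row indices of atoms belonging to the given residues.  `resno` is matched
# against the reference numbering where available (non-NA refno), falling
# back to author numbering, so stem catalogs keyed to E. coli numbering
# resolve after apply_numbering().
atom_rows_for_residues <- function(model, chain, resno) {
  atom <- model$atom
  eff <- ifelse(is.na(atom$refno), atom$resno, atom$refno)
  which(atom$chain == chain & eff %in% resno)
}

# Effective residue number (reference numbering where assigned).
effective_resno <- function(atom) {
  ifelse(is.na(atom$refno), atom$resno, atom$refno)
}

#' Subset a structure model by atom-table rows
#'
#' @param model a `structure_model`.
#' @param rows row index into the atom table.
#' @return a `structure_model` with only the selected atoms.
#' @export
subset_model <- function(model, rows) {
  atom <- model$atom[rows, , drop = FALSE]
  if (nrow(atom) == 0) stop("empty selection", call. = FALSE)
  rownames(atom) <- NULL
  structure(list(source_id = model$source_id, atom = atom,
                 metadata = model$metadata), class = "structure_model")
}
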