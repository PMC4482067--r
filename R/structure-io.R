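#' Read an atomic-coordinate file
#'
#' Loads a PDB or mmCIF (PDBx) coordinate file into a [structure_model()].
#' Parsing is delegated to \pkg{bio3d}; this wrapper then resolves
#' alternate locations (highest occupancy wins; ties go to the
#' lexicographically first identifier), drops waters, ions and
#' zero-occupancy atoms, and derives the parent base of each residue.
#'
#' @param path path to the coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return a `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    } else {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0) {
    stop("empty model: no atom records in ", path, call. = FALSE)
  }
  atom$elety <- gsub("\"", "", atom$elety)
  atom$alt[is.na(atom$alt)] <- ""
  atom$insert[is.na(atom$insert)] <- ""
  atom$o[is.na(atom$o)] <- 1
  atom$b[is.na(atom$b)] <- 0
  if (is.null(atom$elesy)) atom$elesy <- NA_character_
  atom$elesy[is.na(atom$elesy)] <- substr(gsub("[^A-Za-z]", "", atom$elety), 1, 1)

  # waters / common monoatomic ions are never part of the analysis
  solvent <- c("HOH", "DOD", "WAT", "MG", "K", "NA", "CL", "ZN", "MN",
               "CA", "SR", "CD", "NI", "OS", "IR", "IRI")
  atom <- atom[!(toupper(atom$resid) %in% solvent), , drop = FALSE]
  atom <- atom[atom$o > 0, , drop = FALSE]
  if (nrow(atom) == 0) stop("empty model after solvent/occupancy filtering",
                            call. = FALSE)
  atom <- resolve_altloc(atom)
  atom$base <- parent_base(atom$resid)
  atom <- atom[, c("type", "eleno", "elety", "alt", "resid", "base",
                   "chain", "resno", "insert", "x", "y", "z", "o", "b",
                   "elesy")]
  structure_model(atom, source_id = sub("\\.(pdb|cif)(\\.gz)?$", "",
                                        basename(path), ignore.case = TRUE),
                  metadata = list(path = path, format = format))
}

# Keep, per (residue, atom name), the alternate location with the highest
# occupancy; ties resolved by lexicographic alt id.
resolve_altloc <- function(atom) {
  has_alt <- atom$alt != ""
  if (!any(has_alt)) return(atom)
  key <- paste(residue_key(atom), atom$elety, sep = "|")
  ord <- order(key, -atom$o, atom$alt)
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(key[ord]), , drop = FALSE]
  atom[order(as.integer(atom$eleno)), , drop = FALSE]
}

#' Select rRNA chains from a structure model
#'
#' @param model a `structure_model`.
#' @param selector `"auto"` or a character vector of chain identifiers.
#'   Auto mode keeps chains whose residues are at least `min_frac`
#'   ribonucleotides (parent base `A`/`C`/`G`/`U`) and whose length exceeds
#'   `min_len` residues.
#' @param min_len minimum chain length (residues) for auto selection.
#' @param min_frac minimum ribonucleotide fraction for auto selection.
#' @return a `structure_model` containing only the selected chains.
#' @export
select_rrna <- function(model, selector = "auto", min_len = 100,
                        min_frac = 0.9) {
  rt <- residue_table(model)
  if (identical(selector, "auto")) {
    per_chain <- split(rt, rt$chain)
    keep <- names(per_chain)[vapply(per_chain, function(ch) {
      nrow(ch) > min_len &&
        mean(ch$base %in% RIBONUCLEOTIDES) >= min_frac
    }, logical(1))]
  } else {
    keep <- intersect(selector, unique(rt$chain))
  }
  if (length(keep) == 0) {
    stop("empty selection: no chain matches selector", call. = FALSE)
  }
  subset_model(model, which(model$atom$chain %in% keep))
}

#' Read a residue-numbering map
#'
#' The map is a tab-separated file with header
#' `chain  author_number  reference_number` giving, per chain, the
#' reference (E. coli) number of each author-numbered residue.
#'
#' @param path TSV file path.
#' @param reference_label label of the reference numbering scheme.
#' @return a `numbering_map` (data frame with attribute `reference_label`).
#' @export
read_numbering_map <- function(path, reference_label = "E. coli") {
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  names(map) <- c("chain", "author_number", "reference_number")[seq_along(names(map))]
  numbering_map(map, reference_label)
}

#' Construct a numbering map
#'
#' @param map data frame with columns `chain`, `author_number`,
#'   `reference_number`.
#' @param reference_label label of the reference numbering scheme.
#' @return a `numbering_map`.
#' @export
numbering_map <- function(map, reference_label = "E. coli") {
  stopifnot(all(c("chain", "author_number", "reference_number") %in% names(map)))
  for (ch in unique(map$chain)) {
    sub <- map[map$chain == ch, ]
    if (anyDuplicated(sub$author_number) || anyDuplicated(sub$reference_number)) {
      stop("numbering map not injective for chain ", ch, call. = FALSE)
    }
  }
  attr(map, "reference_label") <- reference_label
  class(map) <- c("numbering_map", class(map))
  map
}

#' Apply a reference numbering to a structure model
#'
#' Residues covered by the map carry both the author number (`resno`) and
#' the reference number (`refno`); uncovered residues are flagged
#' (`unmapped = TRUE`) but never dropped.  Coordinates and atom counts are
#' untouched.
#'
#' @param model a `structure_model`.
#' @param map a `numbering_map`.
#' @return the renumbered `structure_model`.
#' @export
apply_numbering <- function(model, map) {
  missing_chain <- setdiff(unique(map$chain), unique(model$atom$chain))
  if (length(missing_chain) > 0) {
    stop("numbering map refers to absent chain(s): ",
         paste(missing_chain, collapse = ", "), call. = FALSE)
  }
  atom <- model$atom
  key <- paste(atom$chain, atom$resno)
  mkey <- paste(map$chain, map$author_number)
  idx <- match(key, mkey)
  covered_chain <- atom$chain %in% unique(map$chain)
  atom$refno <- ifelse(is.na(idx), NA_integer_,
                       as.integer(map$reference_number[idx]))
  atom$unmapped <- covered_chain & is.na(idx)
  if (!any(!is.na(atom$refno))) {
    stop("numbering map covers no residue of the model", call. = FALSE)
  }
  model$atom <- atom
  model$metadata$reference_label <- attr(map, "reference_label")
  model
}

#' Write a structure model to disk
#'
#' PDB output goes through \pkg{bio3d}; mmCIF output is written as a
#' minimal PDBx `atom_site` loop.  `read_structure(write_structure(m))`
#' reproduces `m` within the coordinate precision of the format
#' (3 decimals for PDB, 4 for mmCIF).
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  atom <- model$atom
  if (nrow(atom) == 0) stop("refusing to write empty model", call. = FALSE)
  if (format == "pdb") {
    ok <- tryCatch({
      bio3d::write.pdb(file = path,
                       xyz = as.vector(t(coords(model))),
                       type = atom$type, resno = atom$resno,
                       resid = atom$resid, eleno = seq_len(nrow(atom)),
                       elety = atom$elety, chain = atom$chain,
                       insert = ifelse(atom$insert == "", NA, atom$insert),
                       o = atom$o, b = atom$b, elesy = atom$elesy)
      TRUE
    }, error = function(e) {
      stop("cannot write PDB to '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  } else {
    write_mmcif(model, path)
  }
  invisible(path)
}

# Minimal PDBx/mmCIF atom_site writer (coordinates to 4 decimals).
write_mmcif <- function(model, path) {
  atom <- model$atom
  quote_name <- function(x) ifelse(grepl("'", x), paste0('"', x, '"'), x)
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", model$source_id)),
    "#", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                            "label_atom_id", "label_alt_id",
                            "label_comp_id", "label_asym_id",
                            "label_entity_id", "label_seq_id",
                            "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                            "Cartn_z", "occupancy", "B_iso_or_equiv",
                            "auth_seq_id", "auth_comp_id", "auth_asym_id",
                            "auth_atom_id", "pdbx_PDB_model_num")),
    sprintf("%s %d %s %s %s %s %s 1 %d %s %.4f %.4f %.4f %.2f %.2f %d %s %s %s 1",
            atom$type, seq_len(nrow(atom)),
            ifelse(atom$elesy == "", "?", atom$elesy),
            quote_name(atom$elety),
            ifelse(atom$alt == "", ".", atom$alt),
            atom$resid, atom$chain, atom$resno,
            ifelse(atom$insert == "", "?", atom$insert),
            atom$x, atom$y, atom$z, atom$o, atom$b,
            atom$resno, atom$resid, atom$chain, quote_name(atom$elety)),
    "#")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write mmCIF to '", path,
                                           "'", call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
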