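#' Pair residues between two conformational states
#'
#' Establishes the residue-to-residue correspondence prior to any
#' superposition.  `by_number` pairs residues with identical
#' `(chain, author_number, insertion_code)`; `by_alignment` runs a global
#' sequence alignment on the parent-base letters of each shared chain
#' (match +1, mismatch -1, gap -2) and pairs aligned non-gap columns.
#'
#' @param a,b `structure_model` objects for the two states.
#' @param method `"by_number"` or `"by_alignment"`.
#' @return a `residue_pairing`: data frame with the residue identity of both
#'   partners (`chain_a`, `resno_a`, `insert_a`, `chain_b`, `resno_b`,
#'   `insert_b`, `base_a`, `base_b`) ordered by state-A position, with
#'   attribute `method`.
#' @export
pair_residues <- function(a, b, method = c("by_number", "by_alignment")) {
  method <- match.arg(method)
  ra <- residue_table(a)
  rb <- residue_table(b)
  if (nrow(ra) == 0 || nrow(rb) == 0) {
    stop("cannot pair residues of an empty model", call. = FALSE)
  }
  if (method == "by_number") {
    ka <- paste(ra$chain, ra$resno, ra$insert, sep = "|")
    kb <- paste(rb$chain, rb$resno, rb$insert, sep = "|")
    idx <- match(ka, kb)
    sel <- which(!is.na(idx))
    pairs <- data.frame(
      chain_a = ra$chain[sel], resno_a = ra$resno[sel],
      insert_a = ra$insert[sel], base_a = ra$base[sel],
      chain_b = rb$chain[idx[sel]], resno_b = rb$resno[idx[sel]],
      insert_b = rb$insert[idx[sel]], base_b = rb$base[idx[sel]],
      row_a = sel, row_b = idx[sel], stringsAsFactors = FALSE)
  } else {
    shared <- intersect(unique(ra$chain), unique(rb$chain))
    pieces <- lapply(shared, function(ch) {
      ia <- which(ra$chain == ch)
      ib <- which(rb$chain == ch)
      al <- align_base_sequences(ra$base[ia], rb$base[ib])
      if (nrow(al) == 0) return(NULL)
      data.frame(
        chain_a = ch, resno_a = ra$resno[ia[al$i]],
        insert_a = ra$insert[ia[al$i]], base_a = ra$base[ia[al$i]],
        chain_b = ch, resno_b = rb$resno[ib[al$j]],
        insert_b = rb$insert[ib[al$j]], base_b = rb$base[ib[al$j]],
        row_a = ia[al$i], row_b = ib[al$j], stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pieces)
  }
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop("correspondence error: zero paired residues", call. = FALSE)
  }
  pairs <- pairs[order(pairs$row_a), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "method") <- method
  class(pairs) <- c("residue_pairing", class(pairs))
  pairs
}

# Global alignment of two base-letter vectors via Biostrings
# (match +1, mismatch -1, linear gap -2); returns aligned index pairs.
align_base_sequences <- function(ba, bb) {
  sub <- matrix(-1, 5, 5, dimnames = list(c(RIBONUCLEOTIDES, "N"),
                                          c(RIBONUCLEOTIDES, "N")))
  diag(sub) <- 1
  pa <- Biostrings::pairwiseAlignment(
    paste(ba, collapse = ""), paste(bb, collapse = ""),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 2)
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  i <- cumsum(sa != "-")
  j <- cumsum(sb != "-")
  keep <- sa != "-" & sb != "-"
  data.frame(i = i[keep], j = j[keep])
}

#' Pair atoms across a residue pairing
#'
#' For each residue pair, atoms present in both residues and belonging to
#' the requested subset are paired by name.  Residues missing a requested
#' atom contribute their remaining atoms.  Fewer than `min_atoms` total
#' pairs is an error: a single complete Watson-Crick pair already yields
#' the default minimum of 30 heavy atoms, the sufficiency bound used for
#' stem superposition.
#'
#' @param rp a `residue_pairing` from [pair_residues()].
#' @param a,b the `structure_model` objects the pairing refers to.
#' @param atom_subset `"all_heavy"`, `"backbone"` (the 12 standard backbone
#'   names), or a character vector of atom names.
#' @param min_atoms minimum number of atom pairs required (default 30).
#' @return an `atom_pairing`: data frame with atom-table row indices
#'   `row_a`, `row_b` plus `elety`, `chain`, `resno_a`, `resno_b`.
#' @export
pair_atoms <- function(rp, a, b, atom_subset = "all_heavy", min_atoms = 30) {
  if (is.null(rp) || nrow(rp) == 0) {
    stop("insufficient atoms: empty residue pairing", call. = FALSE)
  }
  rta <- residue_table(a)
  rtb <- residue_table(b)
  out <- vector("list", nrow(rp))
  for (k in seq_len(nrow(rp))) {
    ia <- rta$first[rp$row_a[k]]:rta$last[rp$row_a[k]]
    ib <- rtb$first[rp$row_b[k]]:rtb$last[rp$row_b[k]]
    na_ <- a$atom$elety[ia]
    nb_ <- b$atom$elety[ib]
    keepn <- intersect(na_, nb_)
    if (identical(atom_subset, "all_heavy")) {
      keepn <- keepn[!grepl("^H|^\\dH", keepn)]
    } else if (identical(atom_subset, "backbone")) {
      keepn <- intersect(keepn, BACKBONE_ATOMS)
    } else if (is.character(atom_subset)) {
      keepn <- intersect(keepn, atom_subset)
    }
    if (length(keepn) == 0) next
    ma <- ia[match(keepn, na_)]
    mb <- ib[match(keepn, nb_)]
    out[[k]] <- data.frame(row_a = ma, row_b = mb, elety = keepn,
                           chain = rp$chain_a[k],
                           resno_a = rp$resno_a[k], resno_b = rp$resno_b[k],
                           stringsAsFactors = FALSE)
  }
  ap <- do.call(rbind, out)
  n <- if (is.null(ap)) 0 else nrow(ap)
  if (n < min_atoms) {
    stop("insufficient atoms: ", n, " atom pairs < minimum ", min_atoms,
         call. = FALSE)
  }
  rownames(ap) <- NULL
  attr(ap, "atom_subset") <- atom_subset
  class(ap) <- c("atom_pairing", class(ap))
  ap
}
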