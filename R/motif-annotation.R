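#' Geometric base-pair annotation
#'
#' Detects base pairs from geometry alone: candidate residue pairs with a
#' C1'-C1' distance in `c1c1_range`, at least `min_contacts` base
#' nitrogen/oxygen contacts below `contact_max`, and near-coplanar bases
#' (inter-base-plane angle below `plane_max_deg`).  Pairs are classed
#' `watson_crick` for A-U / G-C with canonical edge contacts,
#' `GU_wobble` for G-U showing the characteristic wobble contacts
#' (O6...N3 and/or N1...O2), and `other_noncanonical` otherwise.
#'
#' @param model a `structure_model`.
#' @param c1c1_range C1'-C1' distance window in Angstrom.
#' @param contact_max donor-acceptor contact cutoff in Angstrom.
#' @param plane_max_deg maximum inter-base-plane angle in degrees.
#' @param min_contacts minimum number of N/O contacts.
#' @return a `base_pair_records` data frame: `chain_i`, `resno_i`,
#'   `base_i`, `chain_j`, `resno_j`, `base_j`, `pair_class`, `c1c1_dist`,
#'   `n_contacts`, `min_contact`, with `i` preceding `j` in chain order.
#' @export
annotate_pairs <- function(model, c1c1_range = c(8.5, 11.5),
                           contact_max = 3.5, plane_max_deg = 30,
                           min_contacts = 2) {
  rt <- residue_table(model)
  atom <- model$atom
  n <- nrow(rt)
  c1 <- matrix(NA_real_, n, 3)
  base_rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- rt$first[i]:rt$last[i]
    nm <- atom$elety[rows]
    k <- match("C1'", nm)
    if (!is.na(k)) c1[i, ] <- as.numeric(atom[rows[k], c("x", "y", "z")])
    br <- rows[!(nm %in% BACKBONE_ATOMS) & !grepl("^H|^\\dH", nm)]
    base_rows[[i]] <- br
  }
  usable <- which(!is.na(c1[, 1]) & vapply(base_rows, length, 0L) >= 3)
  skipped <- setdiff(which(!is.na(rt$resno)), usable)
  if (length(skipped) > 0) {
    warning(length(skipped),
            " residue(s) lacking base atoms skipped in pair annotation")
  }
  recs <- list()
  if (length(usable) >= 2) {
    cu <- c1[usable, , drop = FALSE]
    dmat <- as.matrix(stats::dist(cu))
    cand <- which(upper.tri(dmat) & dmat >= c1c1_range[1] &
                    dmat <= c1c1_range[2], arr.ind = TRUE)
    for (r in seq_len(nrow(cand))) {
      i <- usable[cand[r, 1]]
      j <- usable[cand[r, 2]]
      rec <- evaluate_pair(model, rt, base_rows, i, j,
                           dmat[cand[r, 1], cand[r, 2]],
                           contact_max, plane_max_deg, min_contacts)
      if (!is.null(rec)) recs[[length(recs) + 1]] <- rec
    }
  }
  out <- if (length(recs) == 0) {
    data.frame(chain_i = character(0), resno_i = integer(0),
               base_i = character(0), chain_j = character(0),
               resno_j = integer(0), base_j = character(0),
               pair_class = character(0), c1c1_dist = numeric(0),
               n_contacts = integer(0), min_contact = numeric(0))
  } else do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("base_pair_records", class(out))
  out
}

base_plane_normal <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  sv$v[, 3]
}

evaluate_pair <- function(model, rt, base_rows, i, j, c1c1, contact_max,
                          plane_max_deg, min_contacts) {
  atom <- model$atom
  bi <- base_rows[[i]]
  bj <- base_rows[[j]]
  # donor/acceptor candidates: base nitrogens and oxygens
  ni <- bi[grepl("^[NO]", atom$elety[bi])]
  nj <- bj[grepl("^[NO]", atom$elety[bj])]
  if (length(ni) == 0 || length(nj) == 0) return(NULL)
  xi <- coords(model, ni)
  xj <- coords(model, nj)
  dd <- sqrt(outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj))
  contacts <- which(dd < contact_max, arr.ind = TRUE)
  if (nrow(contacts) < min_contacts) return(NULL)
  ang <- acos(min(1, abs(sum(base_plane_normal(coords(model, bi)) *
                               base_plane_normal(coords(model, bj)))))) *
    180 / pi
  if (ang > plane_max_deg) return(NULL)
  bases <- sort(c(rt$base[i], rt$base[j]))
  contact_names <- apply(contacts, 1, function(k) {
    paste(sort(c(atom$elety[ni[k[1]]], atom$elety[nj[k[2]]])),
          collapse = "~")
  })
  pair_class <- if (identical(bases, c("G", "U")) &&
                    any(contact_names %in% c("N3~O6", "N1~O2"))) {
    "GU_wobble"
  } else if (identical(bases, c("C", "G")) || identical(bases, c("A", "U"))) {
    "watson_crick"
  } else {
    "other_noncanonical"
  }
  # order so that i precedes j along the chain
  swap <- rt$chain[i] > rt$chain[j] ||
    (rt$chain[i] == rt$chain[j] && rt$resno[i] > rt$resno[j])
  if (swap) { tmp <- i; i <- j; j <- tmp }
  data.frame(chain_i = rt$chain[i], resno_i = rt$resno[i],
             base_i = rt$base[i], chain_j = rt$chain[j],
             resno_j = rt$resno[j], base_j = rt$base[j],
             pair_class = pair_class, c1c1_dist = c1c1,
             n_contacts = nrow(contacts), min_contact = min(dd),
             stringsAsFactors = FALSE)
}

# Secondary-structure bookkeeping for one chain: positional index of each
# residue, its partner's positional index (NA if unpaired), and the pair
# class backing that partner choice.  If a residue occurs in several
# records, Watson-Crick/wobble pairs win over noncanonical ones.
chain_pairing_map <- function(pairs, model, chain) {
  rt <- residue_table(model)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  pos <- seq_len(nrow(rt))
  partner <- rep(NA_integer_, nrow(rt))
  pclass <- rep(NA_character_, nrow(rt))
  sub <- pairs[pairs$chain_i == chain & pairs$chain_j == chain, ,
               drop = FALSE]
  rank <- c(watson_crick = 1, GU_wobble = 1, other_noncanonical = 2)
  sub <- sub[order(rank[sub$pair_class]), , drop = FALSE]
  for (k in seq_len(nrow(sub))) {
    pi <- match(sub$resno_i[k], rt$resno)
    pj <- match(sub$resno_j[k], rt$resno)
    if (is.na(pi) || is.na(pj)) next
    if (is.na(partner[pi]) && is.na(partner[pj])) {
      partner[pi] <- pj
      partner[pj] <- pi
      pclass[pi] <- pclass[pj] <- sub$pair_class[k]
    }
  }
  list(resno = rt$resno, pos = pos, partner = partner, pair_class = pclass)
}

# Positions (chain index) lying in multibranch-junction loops where >= 3
# helices meet, derived from the nested pairing structure.  A pair with
# two or more directly nested pairs closes a multiloop (its own helix plus
# each child helix meet there); pseudoknotted pairs are skipped.
junction_positions <- function(pm) {
  n <- length(pm$pos)
  closes <- pm$partner
  if (all(is.na(closes))) return(integer(0))
  open_of <- integer(0)
  close_of <- integer(0)
  children <- list()
  stack <- integer(0) # pair ids
  pid <- 0
  for (p in seq_len(n)) {
    if (is.na(closes[p])) next
    if (closes[p] > p) {
      pid <- pid + 1
      open_of[pid] <- p
      close_of[pid] <- closes[p]
      children[[pid]] <- integer(0)
      if (length(stack) > 0) {
        par <- stack[length(stack)]
        children[[par]] <- c(children[[par]], pid)
      }
      stack <- c(stack, pid)
    } else {
      if (length(stack) > 0 && open_of[stack[length(stack)]] == closes[p]) {
        stack <- stack[-length(stack)]
      }
    }
  }
  out <- integer(0)
  for (q in seq_len(pid)) {
    ch <- children[[q]]
    if (length(ch) < 2) next
    inner <- if (close_of[q] - open_of[q] >= 2) {
      seq(open_of[q] + 1, close_of[q] - 1)
    } else integer(0)
    for (cq in ch) inner <- setdiff(inner, seq(open_of[cq], close_of[cq]))
    bounds <- c(open_of[q], close_of[q], open_of[ch], close_of[ch])
    out <- c(out, inner, bounds)
  }
  sort(unique(out))
}

#' Classify the structural motif at a pivot site
#'
#' Applies the precedence G-U wobble > non-canonical pair > bulge >
#' three-way junction > unassigned.  A bulge is an unpaired run of 1-4
#' residues flanked by paired residues belonging to the same helix (their
#' partners within 2 positions of each other on the partner strand); a
#' junction call requires the site within 3 residues of a loop where at
#' least 3 helices meet in the pairing graph.  Watson-Crick-paired sites
#' away from any junction come back `unassigned`.
#'
#' @param pairs a [annotate_pairs()] result covering the site's
#'   neighborhood.
#' @param model the `structure_model` the pairs refer to (chain topology).
#' @param chain chain identifier of the site.
#' @param site residue number of the pivot site.
#' @return list with `motif_class`, `partner` (residue number or NA) and
#'   `evidence` (character).
#' @export
classify_site <- function(pairs, model, chain, site) {
  pm <- chain_pairing_map(pairs, model, chain)
  p <- match(site, pm$resno)
  if (is.na(p)) {
    return(list(motif_class = "unassigned", partner = NA_integer_,
                evidence = "site not in chain"))
  }
  partner_resno <- if (!is.na(pm$partner[p])) pm$resno[pm$partner[p]] else NA_integer_
  if (!is.na(pm$pair_class[p]) && pm$pair_class[p] == "GU_wobble") {
    return(list(motif_class = "GU_wobble", partner = partner_resno,
                evidence = paste0("wobble pair with ", partner_resno)))
  }
  if (!is.na(pm$pair_class[p]) && pm$pair_class[p] == "other_noncanonical") {
    return(list(motif_class = "noncanonical_pair", partner = partner_resno,
                evidence = paste0("non-canonical pair with ", partner_resno)))
  }
  if (is.na(pm$partner[p])) {
    run <- unpaired_run(pm, p)
    if (length(run) >= 1 && length(run) <= 4) {
      lo <- run[1] - 1
      hi <- run[length(run)] + 1
      if (lo >= 1 && hi <= length(pm$pos) &&
          !is.na(pm$partner[lo]) && !is.na(pm$partner[hi]) &&
          abs(pm$partner[lo] - pm$partner[hi]) <= 2) {
        return(list(motif_class = "bulge", partner = NA_integer_,
                    evidence = paste0(length(run), "-nt unpaired run")))
      }
    }
  }
  jpos <- junction_positions(pm)
  if (length(jpos) > 0 && min(abs(jpos - p)) <= 3) {
    return(list(motif_class = "three_way_junction", partner = partner_resno,
                evidence = "within 3 residues of a multihelix junction"))
  }
  list(motif_class = "unassigned", partner = partner_resno,
       evidence = if (is.na(partner_resno)) "unpaired" else
         "canonically paired")
}

unpaired_run <- function(pm, p) {
  lo <- p
  while (lo > 1 && is.na(pm$partner[lo - 1])) lo <- lo - 1
  hi <- p
  while (hi < length(pm$pos) && is.na(pm$partner[hi + 1])) hi <- hi + 1
  lo:hi
}
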