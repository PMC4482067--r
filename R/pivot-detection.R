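#' Default configuration for pivot detection
#'
#' @return named list of detection parameters: `min_atoms` (stem atom-pair
#'   floor, 30), `max_cycles` and `reject_sigma` for the refinement,
#'   `atom_subset` for stem superposition (`all_heavy`), `metric`
#'   (`per_residue_backbone_mean`), `threshold` (`NULL` = per-helix
#'   `max(1, 2 * stem_residual)`), `persistence` (2), `reporting_floor`
#'   (0; supply the comparison's global control RMSD to flag sub-threshold
#'   motion), `annotate` (classify pivot motifs), `contact_cutoff`,
#'   `amplification_factor`, `mobility_threshold` (`NULL` = derived from
#'   the global fit).
#' @export
pivot_config <- function() {
  list(min_atoms = 30, max_cycles = 5, reject_sigma = 2.0,
       atom_subset = "all_heavy", metric = "per_residue_backbone_mean",
       threshold = NULL, persistence = 2, reporting_floor = 0,
       annotate = TRUE, contact_cutoff = 5.0, amplification_factor = 1.5,
       mobility_threshold = NULL, screen_cycles = 20)
}

merge_config <- function(config) {
  base <- pivot_config()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  base
}

# Residue pairing restricted to the given chain/residue numbers (matched on
# the effective -- reference where available -- numbering in both models).
pair_for_residues <- function(a, b, chain, resnos) {
  rta <- residue_table(a)
  rtb <- residue_table(b)
  ea <- ifelse(is.na(rta$refno), rta$resno, rta$refno)
  eb <- ifelse(is.na(rtb$refno), rtb$resno, rtb$refno)
  ia <- match(paste(chain, resnos), paste(rta$chain, ea))
  ib <- match(paste(chain, resnos), paste(rtb$chain, eb))
  present <- !is.na(ia) & !is.na(ib)
  rp <- data.frame(chain_a = chain, resno_a = resnos[present],
                   insert_a = "", base_a = rta$base[ia[present]],
                   chain_b = chain, resno_b = resnos[present],
                   insert_b = "", base_b = rtb$base[ib[present]],
                   row_a = ia[present], row_b = ib[present],
                   stringsAsFactors = FALSE)
  attr(rp, "missing") <- resnos[!present]
  class(rp) <- c("residue_pairing", class(rp))
  rp
}

#' Superimpose two states on the rigid stem of one helix
#'
#' Aligns state B onto state A using only the stem residues of the given
#' helix, the step that decouples the helix's local hinge motion from
#' whatever global rearrangement (intersubunit rotation, head swivel) the
#' two states differ by.
#'
#' @param a,b `structure_model` objects (state A is the reference frame).
#' @param stem a [stem_definition()].
#' @param config named list overriding [pivot_config()] entries.
#' @return list with `fit` (the stem `superposition_result`; its
#'   `rmsd_kept` is the stem residual) and `b_aligned` (all of B mapped
#'   into A's frame).
#' @export
align_stem <- function(a, b, stem, config = list()) {
  cfg <- merge_config(config)
  rp <- pair_for_residues(a, b, stem$chain, stem$stem)
  miss <- attr(rp, "missing")
  if (length(miss) > 0) {
    stop("stem incomplete for ", stem$helix_id, ": missing residue(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ap <- pair_atoms(rp, a, b, atom_subset = cfg$atom_subset,
                   min_atoms = cfg$min_atoms)
  fit <- refine_superposition(ap, a, b, max_cycles = cfg$max_cycles,
                              reject_sigma = cfg$reject_sigma)
  list(fit = fit, b_aligned = transform_model(b, fit))
}

metric_atom_names <- function(metric) {
  switch(metric,
         per_residue_backbone_mean = METRIC_BACKBONE_ATOMS,
         per_residue_all_atom_mean = NULL,
         atom_max = NULL,
         stop("unknown deviation metric: ", metric, call. = FALSE))
}

# Deviation of a single residue between two (already superimposed) models:
# mean or max displacement over the shared metric atoms; NA if the residue
# is absent from either state.
residue_deviation <- function(a, b_aligned, chain, resno, metric) {
  names_keep <- metric_atom_names(metric)
  ia <- atom_rows_for_residues(a, chain, resno)
  ib <- atom_rows_for_residues(b_aligned, chain, resno)
  if (length(ia) == 0 || length(ib) == 0) return(c(dev = NA_real_, n = 0))
  na_ <- a$atom$elety[ia]
  nb_ <- b_aligned$atom$elety[ib]
  shared <- intersect(na_, nb_)
  if (!is.null(names_keep)) shared <- intersect(shared, names_keep)
  shared <- shared[!grepl("^H|^\\dH", shared)]
  if (length(shared) == 0) return(c(dev = NA_real_, n = 0))
  da <- coords(a, ia[match(shared, na_)])
  db <- coords(b_aligned, ib[match(shared, nb_)])
  d <- sqrt(rowSums((da - db)^2))
  dev <- if (metric == "atom_max") max(d) else mean(d)
  c(dev = dev, n = length(shared))
}

#' Per-residue deviation profile along a helix path
#'
#' After [align_stem()], computes for every helix-path residue the mean
#' (or maximum) displacement of its metric atoms between the two states,
#' in stem-to-loop order.  Residues missing from either state are flagged
#' absent and the profile continues.
#'
#' @param a reference-state `structure_model`.
#' @param b_aligned state B already mapped into A's frame.
#' @param stem a [stem_definition()].
#' @param metric `"per_residue_backbone_mean"` (default; mean over
#'   P/O5'/C5'/C4'/C3'/O3'), `"per_residue_all_atom_mean"` or `"atom_max"`.
#' @return a `deviation_profile`: data frame `resno`, `deviation`,
#'   `n_atoms`, `present` ordered along the helix path, with attributes
#'   `metric` and `helix_id`.
#' @export
deviation_profile <- function(a, b_aligned, stem,
                              metric = "per_residue_backbone_mean") {
  res <- t(vapply(stem$helix_path, function(r) {
    residue_deviation(a, b_aligned, stem$chain, r, metric)
  }, c(dev = 0, n = 0)))
  out <- data.frame(resno = stem$helix_path, deviation = res[, "dev"],
                    n_atoms = as.integer(res[, "n"]),
                    present = !is.na(res[, "dev"]))
  attr(out, "metric") <- metric
  attr(out, "helix_id") <- stem$helix_id
  class(out) <- c("deviation_profile", class(out))
  out
}

#' Locate the pivot position in a deviation profile
#'
#' Returns the first residue, in stem-to-loop order, whose deviation
#' exceeds `threshold` and such that the next `persistence - 1` present
#' residues also exceed it ("exceeds the noise floor and keeps
#' deviating").  `NA` (no-pivot) is a valid outcome.
#'
#' @param profile a [deviation_profile()].
#' @param threshold deviation threshold in Angstrom.
#' @param persistence number of consecutive present residues required
#'   above threshold (default 2).
#' @return residue number of the pivot, or `NA` if none qualifies.
#' @export
locate_pivot <- function(profile, threshold, persistence = 2) {
  stopifnot(nrow(profile) > 0)
  pres <- which(profile$present)
  dev <- profile$deviation[pres]
  above <- dev > threshold
  if (persistence < 1) persistence <- 1
  for (k in seq_along(pres)) {
    if (!above[k]) next
    run <- k:min(k + persistence - 1, length(pres))
    if (length(run) < persistence) return(NA_integer_)
    if (all(above[run])) return(profile$resno[pres[k]])
  }
  NA_integer_
}

#' Displacement of the helix tip (final-loop) residue
#'
#' @inheritParams deviation_profile
#' @return displacement in Angstrom of the tip residue's metric atom set
#'   between the stem-aligned states.
#' @export
tip_displacement <- function(a, b_aligned, stem,
                             metric = "per_residue_backbone_mean") {
  d <- residue_deviation(a, b_aligned, stem$chain, stem$tip_residue, metric)
  if (is.na(d["dev"])) {
    stop("tip residue ", stem$tip_residue, " absent from one state",
         call. = FALSE)
  }
  unname(d["dev"])
}

#' Detect pivots for a catalog of helices
#'
#' Runs the full two-step procedure per helix: rigid-stem superposition,
#' deviation profiling, pivot localization, tip-displacement measurement
#' and (optionally) motif classification of the pivot site.  Calls whose
#' displacement falls below `reporting_floor` are flagged
#' `sub_threshold`, not dropped, because motion smaller than the
#' coordinate uncertainty of the comparison cannot be distinguished from
#' noise.  Per-helix failures are recorded in `flags` without aborting the
#' run.
#'
#' @param a,b prepared `structure_model` objects (rRNA-selected,
#'   renumbered).
#' @param stems named list of [stem_definition()] objects.
#' @param config named list overriding [pivot_config()] entries.
#' @param comparison_id label recorded with every call.
#' @return a `pivot_calls` data frame: `helix_id`, `pivot_location`,
#'   `pivot_partner`, `motif_class`, `tip_residue`, `displacement`,
#'   `stem_residual`, `n_rejected`, `comparison_id`, `flags`.  The
#'   per-helix profiles are attached as attribute `profiles`.
#' @export
detect_pivots <- function(a, b, stems, config = list(),
                          comparison_id = "comparison") {
  cfg <- merge_config(config)
  pairs_a <- if (isTRUE(cfg$annotate)) annotate_pairs(a) else NULL
  rows <- vector("list", length(stems))
  profiles <- vector("list", length(stems))
  names(profiles) <- names(stems)
  for (i in seq_along(stems)) {
    s <- stems[[i]]
    row <- data.frame(helix_id = s$helix_id, pivot_location = NA_integer_,
                      pivot_partner = NA_integer_,
                      motif_class = "unassigned",
                      tip_residue = s$tip_residue,
                      displacement = NA_real_, stem_residual = NA_real_,
                      n_rejected = NA_integer_,
                      comparison_id = comparison_id, flags = "",
                      stringsAsFactors = FALSE)
    flags <- character(0)
    res <- tryCatch({
      al <- align_stem(a, b, s, cfg)
      if (isTRUE(al$fit$warning_flag)) flags <- c(flags, "fit_warning")
      prof <- deviation_profile(a, al$b_aligned, s, metric = cfg$metric)
      profiles[[i]] <- prof
      thr <- cfg$threshold %||% max(1.0, 2 * al$fit$rmsd_kept)
      piv <- locate_pivot(prof, threshold = thr,
                          persistence = cfg$persistence)
      disp <- tip_displacement(a, al$b_aligned, s, metric = cfg$metric)
      row$pivot_location <- piv
      row$displacement <- disp
      row$stem_residual <- al$fit$rmsd_kept
      row$n_rejected <- al$fit$n_rejected
      if (is.na(piv)) flags <- c(flags, "no_pivot")
      if (disp < cfg$reporting_floor) flags <- c(flags, "sub_threshold")
      if (!is.na(piv) && !is.null(pairs_a)) {
        mc <- classify_site(pairs_a, a, s$chain, piv)
        row$motif_class <- mc$motif_class
        row$pivot_partner <- mc$partner
      }
      row
    }, error = function(e) {
      flags <<- c(flags, paste0("error:", conditionMessage(e)))
      row
    })
    res$flags <- paste(flags, collapse = ";")
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "profiles") <- profiles
  attr(out, "config") <- cfg
  class(out) <- c("pivot_calls", class(out))
  out
}

#' Screen for particularly mobile helices
#'
#' Performs a global superposition over all paired atoms, computes
#' per-residue deviations, and ranks contiguous residue runs exceeding a
#' mobility threshold as candidate regions for stem-catalog construction
#' (the first step of the two-step identification procedure).
#'
#' @param a,b prepared `structure_model` objects.
#' @param config named list overriding [pivot_config()] entries;
#'   `mobility_threshold` defaults to `max(2, 2 * global rmsd_kept)`.
#' @return data frame of candidate runs (`chain`, `start`, `end`,
#'   `n_residues`, `peak_deviation`, `mean_deviation`) ranked by peak
#'   deviation, with the global fit attached as attribute `global_fit`.
#' @export
screen_mobile_helices <- function(a, b, config = list()) {
  cfg <- merge_config(config)
  rp <- pair_residues(a, b, method = "by_number")
  ap <- pair_atoms(rp, a, b, atom_subset = cfg$atom_subset,
                   min_atoms = max(3, cfg$min_atoms))
  # screening faces a large outlier fraction (whole moving helices), so it
  # runs many more rejection cycles than a stem fit needs
  fit <- refine_superposition(ap, a, b, max_cycles = cfg$screen_cycles,
                              reject_sigma = cfg$reject_sigma)
  b_al <- transform_model(b, fit)
  thr <- cfg$mobility_threshold %||% max(2.0, 2 * fit$rmsd_kept)
  dev <- t(mapply(function(ch, rn) {
    residue_deviation(a, b_al, ch, rn, cfg$metric)
  }, rp$chain_a, rp$resno_a))
  keep <- !is.na(dev[, "dev"]) & dev[, "dev"] > thr
  runs <- list()
  if (any(keep)) {
    idx <- which(keep)
    grp <- cumsum(c(1, diff(idx) != 1 |
                      rp$chain_a[idx[-1]] != rp$chain_a[idx[-length(idx)]]))
    for (g in split(idx, grp)) {
      runs[[length(runs) + 1]] <- data.frame(
        chain = rp$chain_a[g[1]], start = rp$resno_a[g[1]],
        end = rp$resno_a[g[length(g)]], n_residues = length(g),
        peak_deviation = max(dev[g, "dev"]),
        mean_deviation = mean(dev[g, "dev"]), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(runs) == 0) {
    data.frame(chain = character(0), start = integer(0), end = integer(0),
               n_residues = integer(0), peak_deviation = numeric(0),
               mean_deviation = numeric(0))
  } else do.call(rbind, runs)
  out <- out[order(-out$peak_deviation), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "global_fit") <- fit
  attr(out, "mobility_threshold") <- thr
  out
}

#' Rotation angle of a superposition, in degrees
#'
#' @param rotation 3 x 3 rotation matrix.
#' @return rotation angle in degrees (in `[0, 180]`).
#' @export
rotation_angle <- function(rotation) {
  ct <- (sum(diag(rotation)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Re-estimate a hinge angle from two stem-aligned states
#'
#' After rigid-stem superposition, the residual rotation that maps the
#' distal arm of state B onto the arm of state A is the hinge rotation
#' itself; its angle is returned in degrees.  On noise-free synthetic
#' hinges this recovers the generator's angle to numerical precision.
#'
#' @param a,b `structure_model` objects.
#' @param stem a [stem_definition()] whose path (beyond the stem) is the
#'   moving arm.
#' @param config named list overriding [pivot_config()] entries.
#' @return hinge angle estimate in degrees.
#' @export
estimate_hinge_angle <- function(a, b, stem, config = list()) {
  cfg <- merge_config(config)
  al <- align_stem(a, b, stem, cfg)
  arm <- setdiff(stem$helix_path, stem$stem)
  rp <- pair_for_residues(a, al$b_aligned, stem$chain, arm)
  ap <- pair_atoms(rp, a, al$b_aligned, atom_subset = cfg$atom_subset,
                   min_atoms = 3)
  fit <- kabsch(coords(a, ap$row_a), coords(al$b_aligned, ap$row_b))
  rotation_angle(fit$rotation)
}
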