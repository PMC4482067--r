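# ---- Idealized A-form geometry -------------------------------------------
#
# The generator emulates A-form duplex geometry with fixed helical
# parameters (rise 2.81 A, twist 32.7 deg/bp).  Atom positions come from a
# cylindrical backbone template plus in-plane base templates engineered so
# that Watson-Crick partners show the canonical edge contacts (~2.9 A) and
# a G-U wobble built with a 2.2 A shear shows the characteristic
# O6...N3 / N1...O2 contacts.  Only self-consistency of the geometry
# matters for the pipeline's math, not chemical exactness.

AFORM_RISE <- 2.81
AFORM_TWIST <- 32.7
AFORM_C1_RADIUS <- 9.4
AFORM_C1_HALFANGLE <- 33.5 # deg; C1'-C1' across a pair ~ 10.4 A
WOBBLE_SHEAR <- 2.2

# backbone atom placement relative to a residue's C1' phase/height
# (radius A, phase offset deg, height offset A); strand 2 uses mirrored
# offsets so the chain runs antiparallel.
aform_backbone_template <- function() {
  data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
             "O3'", "C2'", "O2'", "C1'"),
    radius = c(9.40, 10.60, 8.65, 9.00, 9.35, 9.25, 8.90, 9.05, 9.20,
               9.55, 10.40, 9.40),
    dphi = c(-13.0, -15.5, -17.0, -9.5, -5.0, 0.5, -3.0, 3.0, 7.5,
             3.5, 7.0, 0.0),
    dz = c(-1.90, -2.60, -1.20, -2.60, -3.10, -2.40, -1.20, -1.80,
           -1.50, -0.55, -0.30, 0.00),
    stringsAsFactors = FALSE)
}

# base atom placement in the pair plane: du = along the C1'->partner-C1'
# direction, dv = perpendicular (in-plane).  Watson-Crick edge atoms sit
# at du 3.75 so that partner edges are separated by ~2.9 A.
aform_base_template <- function(base) {
  pur <- data.frame(
    name = c("N9", "C8", "N7", "C5", "C4", "C6", "C2", "N1"),
    du = c(1.48, 1.05, 1.95, 2.50, 2.45, 3.30, 3.30, 3.75),
    dv = c(0.00, 1.25, 1.95, 0.80, -0.80, 0.90, -0.90, 0.00),
    stringsAsFactors = FALSE)
  pyr <- data.frame(
    name = c("N1", "C6", "C5", "C2", "C4", "N3"),
    du = c(1.48, 2.05, 2.05, 2.95, 2.95, 3.75),
    dv = c(0.00, 0.90, -0.90, 0.90, -0.90, 0.00),
    stringsAsFactors = FALSE)
  add <- function(df, name, du, dv) {
    rbind(df, data.frame(name = name, du = du, dv = dv,
                         stringsAsFactors = FALSE))
  }
  switch(base,
         G = add(add(pur, "O6", 3.75, 1.80), "N2", 3.75, -1.80),
         A = add(pur, "N6", 3.75, 1.80),
         C = add(add(pyr, "O2", 3.75, 1.80), "N4", 3.75, -1.80),
         U = add(add(pyr, "O2", 3.75, 1.80), "O4", 3.75, -1.80),
         pyr)
}

COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

cyl <- function(radius, phi_deg, z) {
  phi <- phi_deg * pi / 180
  c(radius * cos(phi), radius * sin(phi), z)
}

# atoms of one residue: backbone from the cylindrical template anchored at
# (c1_phase, c1_z), base in the plane z = c1_z along the unit vector `u`
# (toward the pairing partner).  `mirror` flips the template for the
# antiparallel strand; `radial_shift` pushes the whole backbone outward
# (bulged-out residues); `base_shift` translates base atoms (wobble shear).
residue_atoms <- function(base, c1_phase, c1_z, mirror = FALSE,
                          u = NULL, radial_shift = 0,
                          base_shift = c(0, 0, 0)) {
  bt <- aform_backbone_template()
  sgn <- if (mirror) -1 else 1
  xyz_bb <- t(vapply(seq_len(nrow(bt)), function(m) {
    cyl(bt$radius[m] + radial_shift, c1_phase + sgn * bt$dphi[m],
        c1_z + sgn * bt$dz[m])
  }, numeric(3)))
  c1 <- cyl(AFORM_C1_RADIUS + radial_shift, c1_phase, c1_z)
  if (is.null(u)) {
    u <- -c1 / sqrt(sum(c1^2))
    u[3] <- 0
    u <- u / sqrt(sum(u^2))
  }
  v <- c(-u[2], u[1], 0) # z_hat x u
  bs <- aform_base_template(base)
  xyz_base <- t(vapply(seq_len(nrow(bs)), function(m) {
    c1 + bs$du[m] * u + bs$dv[m] * v + base_shift
  }, numeric(3)))
  data.frame(elety = c(bt$name, bs$name),
             x = c(xyz_bb[, 1], xyz_base[, 1]),
             y = c(xyz_bb[, 2], xyz_base[, 2]),
             z = c(xyz_bb[, 3], xyz_base[, 3]),
             stringsAsFactors = FALSE)
}

random_sequence <- function(n) {
  sample(RIBONUCLEOTIDES, n, replace = TRUE)
}

# ---- duplex / hairpin builder --------------------------------------------

# Builds a capped hairpin: strand 1 runs bp 1..n_bp (5'->3', ascending),
# optional single-strand insertions, a terminal loop, then strand 2
# descends bp n_bp..1.  Returns the atom table plus per-residue roles.
build_hairpin <- function(n_bp, seq1, chain = "A", loop_len = 4,
                          loop_seq = NULL, wobble_at = integer(0),
                          bulge_after = NA, bulge_len = 0,
                          bulge_seq = NULL) {
  stopifnot(n_bp >= 2, length(seq1) == n_bp)
  seq2 <- unname(COMPLEMENT[seq1])
  seq2[wobble_at] <- "U"
  seq1[wobble_at] <- "G"
  if (is.null(loop_seq)) loop_seq <- random_sequence(loop_len)
  residues <- list()
  info <- list()
  add_res <- function(atoms, base, role, bp, strand) {
    residues[[length(residues) + 1]] <<- cbind(atoms, base = base)
    info[[length(info) + 1]] <<- data.frame(
      base = base, role = role, bp = bp, strand = strand,
      stringsAsFactors = FALSE)
  }
  phase1 <- function(k) (k - 1) * AFORM_TWIST - AFORM_C1_HALFANGLE
  phase2 <- function(k) (k - 1) * AFORM_TWIST + AFORM_C1_HALFANGLE
  height <- function(k) (k - 1) * AFORM_RISE
  pair_u <- function(k, from = 1) {
    a <- cyl(AFORM_C1_RADIUS, phase1(k), height(k))
    b <- cyl(AFORM_C1_RADIUS, phase2(k), height(k))
    d <- if (from == 1) b - a else a - b
    d / sqrt(sum(d^2))
  }
  # strand 1 ascending, with optional bulge insertion
  for (k in seq_len(n_bp)) {
    add_res(residue_atoms(seq1[k], phase1(k), height(k), mirror = FALSE,
                          u = pair_u(k, 1)),
            seq1[k], "paired", k, 1L)
    if (!is.na(bulge_after) && k == bulge_after && bulge_len > 0) {
      bseq <- bulge_seq %||% random_sequence(bulge_len)
      for (i in seq_len(bulge_len)) {
        t <- i / (bulge_len + 1)
        add_res(residue_atoms(bseq[i], phase1(k) + t * AFORM_TWIST,
                              height(k) + t * AFORM_RISE,
                              radial_shift = 3.0),
                bseq[i], "bulge", NA_integer_, 1L)
      }
    }
  }
  # terminal loop over the top; bases point outward so the cap does not
  # contact the closing pair
  for (i in seq_len(loop_len)) {
    t <- i / (loop_len + 1)
    ph <- phase1(n_bp) + t * (2 * AFORM_C1_HALFANGLE)
    u_out <- c(cos(ph * pi / 180), sin(ph * pi / 180), 0)
    add_res(residue_atoms(loop_seq[i], ph,
                          height(n_bp) + 3.5 * sin(pi * t), u = u_out),
            loop_seq[i], "loop", NA_integer_, 1L)
  }
  # strand 2 descending
  for (k in rev(seq_len(n_bp))) {
    shift <- if (k %in% wobble_at) {
      u1 <- pair_u(k, 1)
      WOBBLE_SHEAR * c(-u1[2], u1[1], 0)
    } else c(0, 0, 0)
    add_res(residue_atoms(seq2[k], phase2(k), height(k), mirror = TRUE,
                          u = pair_u(k, 2), base_shift = shift),
            seq2[k], "paired", k, 2L)
  }
  info <- do.call(rbind, info)
  info$resno <- seq_len(nrow(info))
  atom <- do.call(rbind, lapply(seq_along(residues), function(i) {
    r <- residues[[i]]
    data.frame(type = "ATOM", eleno = NA_integer_, elety = r$elety,
               alt = "", resid = info$base[i], base = info$base[i],
               chain = chain, resno = info$resno[i], insert = "",
               x = r$x, y = r$y, z = r$z, o = 1, b = 0,
               elesy = substr(r$elety, 1, 1), stringsAsFactors = FALSE)
  }))
  list(atom = atom, info = info)
}

#' Generate an idealized A-form hairpin duplex
#'
#' Builds a capped A-form duplex (rise 2.81 A, twist 32.7 deg/bp) with the
#' full backbone atom set and base ring/edge atoms per residue.  Strand 1
#' runs up, a terminal loop caps the helix, strand 2 runs back down;
#' residue numbering is sequential along the chain, so base pair k joins
#' residues `k` and `total - k + 1`.
#'
#' @param n_bp number of base pairs (>= 2).
#' @param sequence optional strand-1 base vector (length `n_bp`);
#'   random otherwise.
#' @param seed RNG seed; identical seeds give bitwise-identical
#'   coordinates.
#' @param chain chain identifier.
#' @param loop_len terminal-loop length in residues.
#' @param wobble_at base-pair indices converted to sheared G-U wobbles.
#' @param bulge_after base-pair index after which `bulge_len` unpaired
#'   strand-1 residues are inserted (bulged outward).
#' @param bulge_len bulge length in residues.
#' @return a `structure_model` with attribute `residue_info` (per-residue
#'   `role`, `bp`, `strand`).
#' @export
make_aform_duplex <- function(n_bp, sequence = NULL, seed = 1,
                              chain = "A", loop_len = 4,
                              wobble_at = integer(0), bulge_after = NA,
                              bulge_len = 0) {
  set.seed(seed)
  if (is.null(sequence)) sequence <- random_sequence(n_bp)
  hp <- build_hairpin(n_bp, sequence, chain = chain, loop_len = loop_len,
                      wobble_at = wobble_at, bulge_after = bulge_after,
                      bulge_len = bulge_len)
  m <- structure_model(hp$atom, source_id = sprintf("aform_%dbp", n_bp))
  attr(m, "residue_info") <- hp$info
  m
}

# ---- hinge machinery ------------------------------------------------------

#' Specify a synthetic hinge
#'
#' @param n_stem rigid-stem length in base pairs.
#' @param n_arm moving-arm length in base pairs.
#' @param pivot_index base-pair index of the hinge (defaults to `n_stem`);
#'   everything distal rotates.
#' @param hinge_angle hinge rotation in degrees, in `[0, 180)`.
#' @param hinge_axis `"auto"` (radial direction at the pivot, perpendicular
#'   to the helix axis) or a unit 3-vector.
#' @param noise_sigma Gaussian coordinate noise, expressed as the r.m.s.
#'   three-dimensional displacement per atom (A), added independently to
#'   every atom of both states.
#' @param motif_at_pivot `"none"`, `"GU_wobble"`, `"bulge"` or
#'   `"three_way_junction"`: structural motif placed at the first moving
#'   position.
#' @param motif_len bulge length when `motif_at_pivot = "bulge"`.
#' @param seed RNG seed.
#' @return a `hinge_spec` list.
#' @export
hinge_spec <- function(n_stem = 6, n_arm = 12, pivot_index = n_stem,
                       hinge_angle = 10, hinge_axis = "auto",
                       noise_sigma = 0, motif_at_pivot = "none",
                       motif_len = 2, seed = 1) {
  stopifnot(pivot_index > 0, pivot_index < n_stem + n_arm,
            hinge_angle >= 0, hinge_angle < 180, noise_sigma >= 0)
  structure(list(n_stem = n_stem, n_arm = n_arm,
                 pivot_index = pivot_index, hinge_angle = hinge_angle,
                 hinge_axis = hinge_axis, noise_sigma = noise_sigma,
                 motif_at_pivot = motif_at_pivot, motif_len = motif_len,
                 seed = seed), class = "hinge_spec")
}

# Rotate the selected coordinate rows about the axis (point, dir) by theta
# degrees.
rotate_about_axis <- function(xyz, point, dir, theta_deg) {
  th <- theta_deg * pi / 180
  k <- dir / sqrt(sum(dir^2))
  p <- sweep(xyz, 2, point)
  # Rodrigues rotation
  kx <- p %*% t(t(k)) # N x 1: p . k
  cross <- cbind(k[2] * p[, 3] - k[3] * p[, 2],
                 k[3] * p[, 1] - k[1] * p[, 3],
                 k[1] * p[, 2] - k[2] * p[, 1])
  rot <- p * cos(th) + cross * sin(th) +
    outer(as.numeric(kx), k) * (1 - cos(th))
  sweep(rot, 2, point, "+")
}

point_axis_distance <- function(xyz, point, dir) {
  k <- dir / sqrt(sum(dir^2))
  p <- sweep(xyz, 2, point)
  along <- as.numeric(p %*% k)
  sqrt(pmax(0, rowSums(p^2) - along^2))
}

# mean axis distance of a residue's metric backbone atoms
residue_axis_distance <- function(model, chain, resno, point, dir) {
  rows <- atom_rows_for_residues(model, chain, resno)
  rows <- rows[model$atom$elety[rows] %in% METRIC_BACKBONE_ATOMS]
  if (length(rows) == 0) return(NA_real_)
  mean(point_axis_distance(coords(model, rows), point, dir))
}

chord_length <- function(theta_deg, r) 2 * sin(theta_deg * pi / 360) * r

#' Generate a synthetic hinge pair with ground truth
#'
#' State A is an idealized capped A-form hairpin; state B equals A with
#' every residue distal to the pivot base pair rotated by the hinge angle
#' about an axis perpendicular to the helix axis through the pivot pair's
#' backbone centroid, after which independent Gaussian coordinate noise is
#' added to both states.  The truth record carries the analytic
#' expectations: a residue at mean axis distance `r` moves by the chord
#' `2 sin(theta/2) r`.
#'
#' If a motif is requested it is placed at the first moving position: a
#' sheared G-U wobble pair, a bulge of `motif_len` unpaired residues, or a
#' side hairpin creating a three-way junction.
#'
#' @param spec a [hinge_spec()].
#' @return list with `a`, `b` (`structure_model`s) and `truth`, a
#'   `hinge_truth` list: `pivot_residue` (first moving strand-1 residue),
#'   `theta`, `axis_point`, `axis_dir`, `r_path` (per helix-path residue
#'   mean axis distance), `r_tip`, `expected_tip_chord`, `stem`
#'   (auto-generated [stem_definition()]) and `residue_info`.
#' @export
make_hinge_pair <- function(spec) {
  stopifnot(inherits(spec, "hinge_spec"))
  set.seed(spec$seed)
  n_bp <- spec$n_stem + spec$n_arm
  p <- spec$pivot_index
  seq1 <- random_sequence(n_bp)
  wobble_at <- integer(0)
  bulge_after <- NA
  bulge_len <- 0
  if (spec$motif_at_pivot == "GU_wobble") {
    wobble_at <- p + 1
  } else if (spec$motif_at_pivot == "bulge") {
    bulge_after <- p
    bulge_len <- spec$motif_len
  }
  hp <- build_hairpin(n_bp, seq1, loop_len = 4, wobble_at = wobble_at,
                      bulge_after = bulge_after, bulge_len = bulge_len)
  atom <- hp$atom
  info <- hp$info
  if (spec$motif_at_pivot == "three_way_junction") {
    side <- build_side_hairpin(p, max(info$resno))
    atom <- renumber_insertion(atom, info, side, after_bp = p)
    info <- attr(atom, "info")
  }
  a <- structure_model(atom, source_id = "hinge_state_a")
  info <- info[match(sort(info$resno), info$resno), , drop = FALSE]

  # hinge axis: anchored at the backbone centroid of the 5'-strand pivot
  # residue (the helix hinges at that nucleotide's backbone, as real
  # pivots do), directed radially -- perpendicular to the helix axis,
  # pointing from the helix axis through the pivot backbone
  pivot_res <- info$resno[!is.na(info$bp) & info$bp == p &
                            info$strand == 1L]
  rows_piv <- which(a$atom$resno %in% pivot_res &
                      a$atom$elety %in% BACKBONE_ATOMS)
  axis_point <- unname(colMeans(coords(a, rows_piv)))
  axis_dir <- if (identical(spec$hinge_axis, "auto")) {
    radial <- c(axis_point[1], axis_point[2], 0)
    radial / sqrt(sum(radial^2))
  } else {
    spec$hinge_axis / sqrt(sum(spec$hinge_axis^2))
  }

  # residues distal to the pivot pair (both strands, insertions, loop)
  distal <- info$resno[(!is.na(info$bp) & info$bp > p) |
                         info$role %in% c("loop", "bulge", "side")]
  b <- a
  b$source_id <- "hinge_state_b"
  rows_d <- which(b$atom$resno %in% distal)
  if (length(rows_d) > 0 && spec$hinge_angle > 0) {
    xyz <- rotate_about_axis(coords(b, rows_d), axis_point, axis_dir,
                             spec$hinge_angle)
    b$atom$x[rows_d] <- xyz[, 1]
    b$atom$y[rows_d] <- xyz[, 2]
    b$atom$z[rows_d] <- xyz[, 3]
  }

  # catalog entries before noise: stem = pairs 1..n_stem on both strands;
  # path = strand-1 residues beyond the stem plus the loop
  total <- max(info$resno)
  strand1_beyond <- info$resno[info$strand == 1L &
                                 ((!is.na(info$bp) & info$bp > spec$n_stem) |
                                    info$role %in% c("bulge", "side", "loop"))]
  stem_res <- c(info$resno[info$strand == 1L & !is.na(info$bp) &
                             info$bp <= spec$n_stem],
                info$resno[info$strand == 2L & !is.na(info$bp) &
                             info$bp <= spec$n_stem])
  loop_res <- info$resno[info$role == "loop"]
  tip <- loop_res[min(2, length(loop_res))]
  stem <- stem_definition("H1", "A", sort(stem_res), sort(strand1_beyond),
                          tip_residue = tip)

  path <- stem$helix_path
  r_path <- vapply(path, function(r) {
    residue_axis_distance(a, "A", r, axis_point, axis_dir)
  }, numeric(1))
  r_tip <- residue_axis_distance(a, "A", tip, axis_point, axis_dir)
  first_moving <- min(info$resno[info$resno %in% distal & info$strand != 2L])

  if (spec$noise_sigma > 0) {
    # noise_sigma is the r.m.s. 3-D displacement per atom, so each
    # coordinate gets sd sigma/sqrt(3)
    s <- spec$noise_sigma / sqrt(3)
    na_ <- nrow(a$atom)
    a$atom[, c("x", "y", "z")] <- a$atom[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * na_, 0, s), na_, 3)
    b$atom[, c("x", "y", "z")] <- b$atom[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * na_, 0, s), na_, 3)
  }

  truth <- structure(list(
    pivot_residue = first_moving, theta = spec$hinge_angle,
    axis_point = axis_point, axis_dir = axis_dir,
    r_path = stats::setNames(r_path, path), r_tip = r_tip,
    expected_tip_chord = chord_length(spec$hinge_angle, r_tip),
    stem = stem, residue_info = info, spec = spec), class = "hinge_truth")
  list(a = a, b = b, truth = truth)
}

# side hairpin (4 bp + 4 loop) pointing radially outward at the insertion
# point between trunk pairs p and p+1 on strand 1
build_side_hairpin <- function(p, total_before) {
  side <- build_hairpin(4, c("G", "C", "G", "C"), loop_len = 4)
  xyz <- as.matrix(side$atom[, c("x", "y", "z")])
  phi_ins <- ((p - 0.5) * AFORM_TWIST - AFORM_C1_HALFANGLE) * pi / 180
  u_r <- c(cos(phi_ins), sin(phi_ins), 0)
  # rotate helix axis (z) onto u_r, then translate outward
  rot <- rotation_between(c(0, 0, 1), u_r)
  xyz <- xyz %*% t(rot)
  xyz <- sweep(xyz, 2, u_r * 13 + c(0, 0, (p - 0.5) * AFORM_RISE), "+")
  side$atom$x <- xyz[, 1]
  side$atom$y <- xyz[, 2]
  side$atom$z <- xyz[, 3]
  side$info$role <- "side"
  side
}

rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# splice the side hairpin's residues into the trunk numbering after trunk
# base pair `after_bp` on strand 1
renumber_insertion <- function(atom, info, side, after_bp) {
  ins_at <- info$resno[info$strand == 1L & !is.na(info$bp) &
                         info$bp == after_bp]
  n_side <- max(side$info$resno)
  shift <- atom$resno > ins_at
  atom$resno[shift] <- atom$resno[shift] + n_side
  info$resno[info$resno > ins_at] <- info$resno[info$resno > ins_at] + n_side
  side$atom$resno <- side$atom$resno + ins_at
  side$info$resno <- side$info$resno + ins_at
  out <- rbind(atom, side$atom)
  attr(out, "info") <- rbind(info, side$info)
  out
}

#' Generate a two-hinge construct for cascade analysis
#'
#' A trunk hairpin with an upstream hinge (chain A) carries a branch
#' hairpin (chain B) rigidly attached near the trunk's distal arm.  The
#' branch has its own local hinge.  In state B the branch first pivots
#' about its local hinge, then the whole distal assembly (trunk arm plus
#' branch) pivots about the upstream hinge, so branch-tip motion seen
#' after upstream-stem alignment combines both rotations while
#' branch-stem alignment isolates the local one.
#'
#' @param spec_upstream [hinge_spec()] for the trunk hinge; its
#'   `noise_sigma` and `seed` govern the whole construct.
#' @param spec_local [hinge_spec()] for the branch hinge.
#' @return list with `a`, `b`, `truth_upstream`, `truth_local`,
#'   `upstream_stem`, `local_stem` and `expected_upstream_tip_chord`
#'   (branch-tip chord induced by the upstream hinge alone).
#' @export
make_two_hinge_construct <- function(spec_upstream, spec_local) {
  set.seed(spec_upstream$seed)
  su <- spec_upstream
  sl <- spec_local
  su$noise_sigma <- 0
  sl$noise_sigma <- 0
  trunk <- make_hinge_pair(su)
  branch <- make_hinge_pair(sl)
  # place the branch alongside the trunk's distal arm
  n_trunk <- su$n_stem + su$n_arm
  top_z <- (n_trunk - 1) * AFORM_RISE
  rot <- rotation_between(c(0, 0, 1), c(sin(pi / 4), 0, cos(pi / 4)))
  shiftv <- c(14, 0, top_z * 0.7)
  place <- function(model) {
    xyz <- coords(model) %*% t(rot)
    xyz <- sweep(xyz, 2, shiftv, "+")
    model$atom$x <- xyz[, 1]
    model$atom$y <- xyz[, 2]
    model$atom$z <- xyz[, 3]
    model$atom$chain <- "B"
    model
  }
  ba <- place(branch$a)
  bb <- place(branch$b)
  # transform the branch truth into placed coordinates
  tl <- branch$truth
  tl$axis_point <- as.numeric(rot %*% tl$axis_point + shiftv)
  tl$axis_dir <- as.numeric(rot %*% tl$axis_dir)
  tl$stem$chain <- "B"
  tl$stem$helix_id <- "branch"
  # upstream hinge carries the branch: rotate placed branch state B by the
  # trunk hinge
  tu <- trunk$truth
  tu$stem$helix_id <- "trunk"
  carry <- function(model) {
    xyz <- rotate_about_axis(coords(model), tu$axis_point, tu$axis_dir,
                             su$hinge_angle)
    model$atom$x <- xyz[, 1]
    model$atom$y <- xyz[, 2]
    model$atom$z <- xyz[, 3]
    model
  }
  bb <- carry(bb)
  a <- combine_models(trunk$a, ba, source_id = "two_hinge_a")
  b <- combine_models(trunk$b, bb, source_id = "two_hinge_b")
  sigma <- spec_upstream$noise_sigma
  if (sigma > 0) {
    s <- sigma / sqrt(3)
    for (nm in c("a", "b")) {
      m <- get(nm)
      n <- nrow(m$atom)
      m$atom[, c("x", "y", "z")] <- m$atom[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * n, 0, s), n, 3)
      assign(nm, m)
    }
  }
  # branch tip distance to the upstream axis, in state-A placed coords
  r_branch_tip <- residue_axis_distance(a, "B", tl$stem$tip_residue,
                                        tu$axis_point, tu$axis_dir)
  list(a = a, b = b, truth_upstream = tu, truth_local = tl,
       upstream_stem = tu$stem, local_stem = tl$stem,
       r_branch_tip = r_branch_tip,
       expected_upstream_tip_chord = chord_length(su$hinge_angle,
                                                  r_branch_tip))
}

#' Combine structure models into one
#'
#' @param ... `structure_model` objects with distinct chain ids.
#' @param source_id identifier for the combined model.
#' @return a `structure_model`.
#' @export
combine_models <- function(..., source_id = "combined") {
  models <- list(...)
  atom <- do.call(rbind, lapply(models, function(m) m$atom))
  structure_model(atom, source_id = source_id)
}

#' Generate a three-way junction fixture
#'
#' One chain folding into three A-form arms that meet at a junction: a
#' closing duplex (arm 1) and two hairpin arms, connected by 2-nt
#' single-stranded linkers.  The junction's pairing topology is recorded
#' so motif classification can be checked against construction.
#'
#' @param arm_bp base pairs per arm (length-3 vector or scalar).
#' @param seed RNG seed.
#' @return a `structure_model` with attribute `junction_residues` (residue
#'   numbers of the linkers at the junction).
#' @export
make_junction <- function(arm_bp = c(5, 5, 5), seed = 1) {
  set.seed(seed)
  arm_bp <- rep(arm_bp, length.out = 3)
  a1 <- arm_bp[1]
  # arm 1: plain duplex (no loop) split across the chain ends
  hp1 <- build_hairpin(a1, random_sequence(a1), loop_len = 0)
  hp2 <- build_hairpin(arm_bp[2], random_sequence(arm_bp[2]), loop_len = 4)
  hp3 <- build_hairpin(arm_bp[3], random_sequence(arm_bp[3]), loop_len = 4)
  orient <- function(hp, axis, offset) {
    rot <- rotation_between(c(0, 0, 1), axis)
    xyz <- as.matrix(hp$atom[, c("x", "y", "z")]) %*% t(rot)
    xyz <- sweep(xyz, 2, axis * offset, "+")
    hp$atom$x <- xyz[, 1]
    hp$atom$y <- xyz[, 2]
    hp$atom$z <- xyz[, 3]
    hp
  }
  # arm 1 points down: its junction-side pair is bp a1, so drop the helix
  # so that bp a1 sits just below the origin and bp 1 is the outer end
  hp1$atom$z <- hp1$atom$z - (a1 - 1) * AFORM_RISE - 6
  deg <- pi / 180
  hp2 <- orient(hp2, c(sin(55 * deg), 0, cos(55 * deg)), 7)
  hp3 <- orient(hp3, c(-sin(55 * deg), 0, cos(55 * deg)), 7)
  # chain traversal: arm1 strand 1 (outer -> junction), linker, arm2
  # hairpin, linker, arm3 hairpin, linker, arm1 strand 2 (junction ->
  # outer).  arm1 strand 1 ascends toward the junction after mirroring.
  linker <- function(from_xyz, to_xyz, n = 2) {
    lapply(seq_len(n), function(i) {
      t <- i / (n + 1)
      pos <- from_xyz + t * (to_xyz - from_xyz)
      at <- residue_atoms("A", 0, 0)
      sh <- pos - colMeans(as.matrix(at[, c("x", "y", "z")]))
      at$x <- at$x + sh[1]
      at$y <- at$y + sh[2]
      at$z <- at$z + sh[3]
      cbind(at, base = "A")
    })
  }
  res_of <- function(hp, resnos) {
    hp$atom[hp$atom$resno %in% resnos, , drop = FALSE]
  }
  end_xyz <- function(df) {
    colMeans(as.matrix(df[df$elety == "C1'", c("x", "y", "z")]))
  }
  s1_1 <- hp1$info$resno[hp1$info$strand == 1L]
  s2_1 <- hp1$info$resno[hp1$info$strand == 2L]
  a1s1 <- res_of(hp1, s1_1)
  a1s2 <- res_of(hp1, s2_1)
  l1 <- linker(end_xyz(res_of(hp1, max(s1_1))),
               end_xyz(res_of(hp2, 1)))
  l2 <- linker(end_xyz(res_of(hp2, max(hp2$atom$resno))),
               end_xyz(res_of(hp3, 1)))
  l3 <- linker(end_xyz(res_of(hp3, max(hp3$atom$resno))),
               end_xyz(res_of(hp1, min(s2_1))))
  pieces <- c(list(a1s1), l1, list(hp2$atom), l2, list(hp3$atom), l3,
              list(a1s2))
  resno_counter <- 0
  out <- lapply(seq_along(pieces), function(i) {
    df <- pieces[[i]]
    if (!"resno" %in% names(df)) df$resno <- 1L
    old <- unique(df$resno)
    new <- resno_counter + seq_along(old)
    df$resno <- new[match(df$resno, old)]
    resno_counter <<- resno_counter + length(old)
    df[, c("elety", "x", "y", "z", "base", "resno")]
  })
  # linker pieces are single residues; record them as junction residues
  sizes <- vapply(pieces, function(df) {
    if ("resno" %in% names(df)) length(unique(df$resno)) else 1L
  }, 0L)
  is_linker <- vapply(pieces, function(df) nrow(df) <= 30, logical(1))
  starts <- cumsum(c(0, head(sizes, -1)))
  junction_res <- unlist(lapply(which(is_linker), function(i) {
    starts[i] + seq_len(sizes[i])
  }))
  atom <- do.call(rbind, out)
  keep <- c("type", "eleno", "elety", "alt", "resid", "base", "chain",
            "resno", "insert", "x", "y", "z", "o", "b", "elesy")
  atom$type <- "ATOM"
  atom$eleno <- NA_integer_
  atom$alt <- ""
  atom$resid <- atom$base
  atom$chain <- "A"
  atom$insert <- ""
  atom$o <- 1
  atom$b <- 0
  atom$elesy <- substr(atom$elety, 1, 1)
  m <- structure_model(atom[, keep], source_id = "three_way_junction")
  attr(m, "junction_residues") <- junction_res
  m
}
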