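# Small builders shared across the test files.

# one-atom-per-residue chain model (enough for pairing / numbering tests)
chain_model <- function(bases, chain = "A", resno = seq_along(bases),
                        x = seq_along(bases) * 6, y = 0, z = 0) {
  structure_model(data.frame(elety = "C1'", resid = bases, chain = chain,
                             resno = resno, x = x, y = y, z = z))
}

# model whose "residue" is a bag of uniquely named atoms at the given
# coordinates (for superposition tests)
point_model <- function(xyz) {
  structure_model(data.frame(elety = paste0("C", seq_len(nrow(xyz))),
                             resid = "G", chain = "A", resno = 1,
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# uniformly random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid_xyz <- function(xyz, rot, trans) {
  sweep(xyz %*% t(rot), 2, trans, "+")
}

# atom pairing covering all shared residues of two models
full_atom_pairing <- function(a, b, ...) {
  pair_atoms(pair_residues(a, b, "by_number"), a, b, ...)
}

altloc_fixture_path <- function() {
  system.file("extdata", "altloc_synthetic.cif", package = "rnapivot")
}
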