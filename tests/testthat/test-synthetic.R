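test_that("generation is bitwise reproducible from the seed", {
  m1 <- make_aform_duplex(8, seed = 5)
  m2 <- make_aform_duplex(8, seed = 5)
  expect_identical(m1$atom, m2$atom)
  m3 <- make_aform_duplex(8, seed = 6)
  expect_false(identical(m1$atom$resid, m3$atom$resid) &&
                 identical(coords(m1), coords(m3)))
  hp1 <- make_hinge_pair(hinge_spec(hinge_angle = 10, noise_sigma = 0.3,
                                    seed = 9))
  hp2 <- make_hinge_pair(hinge_spec(hinge_angle = 10, noise_sigma = 0.3,
                                    seed = 9))
  expect_identical(coords(hp1$a), coords(hp2$a))
  expect_identical(coords(hp1$b), coords(hp2$b))
})

test_that("helical parameters give the expected phosphate spacing", {
  m <- make_aform_duplex(10, seed = 3)
  at <- m$atom
  for (strand_res in list(1:10, 15:24)) {
    p <- at[at$elety == "P" & at$resno %in% strand_res, ]
    p <- p[order(p$resno), ]
    d <- sqrt(rowSums(diff(as.matrix(p[, c("x", "y", "z")]))^2))
    expect_true(all(abs(d - 5.9) < 0.5))
  }
})

test_that("every duplex residue carries the full backbone atom set", {
  m <- make_aform_duplex(6, seed = 2)
  rt <- residue_table(m)
  for (i in seq_len(nrow(rt))) {
    nm <- m$atom$elety[rt$first[i]:rt$last[i]]
    expect_true(all(c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "C2'",
                      "C1'", "O4'", "O2'") %in% nm))
    expect_false(anyDuplicated(nm) > 0)
  }
})

test_that("zero angle and zero noise reproduce state A exactly", {
  hp <- make_hinge_pair(hinge_spec(hinge_angle = 0, noise_sigma = 0,
                                   seed = 7))
  expect_identical(coords(hp$a), coords(hp$b))
  expect_equal(hp$truth$expected_tip_chord, 0)
})

test_that("the truth record is internally consistent", {
  hp <- make_hinge_pair(hinge_spec(n_stem = 6, n_arm = 12,
                                   hinge_angle = 10, noise_sigma = 0,
                                   seed = 2))
  tr <- hp$truth
  # the chord expectation follows from theta and the tip radius
  expect_equal(tr$expected_tip_chord,
               2 * sin(tr$theta * pi / 360) * tr$r_tip)
  # frozen closed form: theta = 10 deg at r = 30 A gives 5.2293 A
  expect_equal(2 * sin(10 * pi / 360) * 30, 5.229342, tolerance = 1e-6)
  # the pivot residue is the first that moves between the states
  moved <- vapply(sort(unique(hp$a$atom$resno)), function(r) {
    ra <- coords(hp$a, which(hp$a$atom$resno == r))
    rb <- coords(hp$b, which(hp$b$atom$resno == r))
    max(abs(ra - rb)) > 1e-9
  }, logical(1))
  first_moving <- sort(unique(hp$a$atom$resno))[which(moved)[1]]
  expect_equal(tr$pivot_residue, first_moving)
  # the axis is a unit vector perpendicular to the helix axis
  expect_equal(sum(tr$axis_dir^2), 1)
  expect_equal(tr$axis_dir[3], 0)
  # stem residues do not move
  expect_false(any(moved[seq_len(hp$truth$spec$n_stem)]))
})

test_that("noise magnitude matches the declared r.m.s. displacement", {
  clean <- make_hinge_pair(hinge_spec(hinge_angle = 8, noise_sigma = 0,
                                      seed = 21))
  noisy <- make_hinge_pair(hinge_spec(hinge_angle = 8, noise_sigma = 0.3,
                                      seed = 21))
  expect_identical(clean$a$atom$resid, noisy$a$atom$resid)
  disp <- rmsd_coords(coords(clean$a), coords(noisy$a))
  expect_equal(disp, 0.3, tolerance = 0.1)
})

test_that("invalid hinge specifications are refused", {
  expect_error(hinge_spec(pivot_index = 0))
  expect_error(hinge_spec(n_stem = 4, n_arm = 4, pivot_index = 8))
  expect_error(hinge_spec(hinge_angle = 190))
  expect_error(hinge_spec(noise_sigma = -1))
})

test_that("generator output survives a structure_io round trip", {
  hp <- make_hinge_pair(hinge_spec(hinge_angle = 12, noise_sigma = 0.2,
                                   seed = 13))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(hp$b, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atom), nrow(hp$b$atom))
  expect_lt(max(abs(coords(back) - coords(hp$b))), 1e-3)
})

test_that("the hinge angle round-trips through the full pipeline", {
  for (theta in c(2, 20, 45)) {
    hp <- make_hinge_pair(hinge_spec(hinge_angle = theta, noise_sigma = 0,
                                     seed = 17))
    expect_equal(estimate_hinge_angle(hp$a, hp$b, hp$truth$stem), theta,
                 tolerance = 0.1)
  }
})

test_that("the junction fixture has three arms meeting at its linkers", {
  j <- make_junction(arm_bp = c(5, 6, 4), seed = 2)
  pairs <- annotate_pairs(j)
  # three separate helices: 5 + 6 + 4 pairs
  expect_equal(nrow(pairs), 15)
  expect_gte(length(attr(j, "junction_residues")), 4)
})
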