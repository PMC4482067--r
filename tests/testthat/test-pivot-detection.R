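test_that("stem superposition decouples the rigid stem", {
  # noise-free hinge: the stem is an exact rigid match
  hp <- make_hinge_pair(hinge_spec(hinge_angle = 10, noise_sigma = 0,
                                   seed = 4))
  al <- align_stem(hp$a, hp$b, hp$truth$stem)
  expect_lt(al$fit$rmsd_kept, 1e-6)
  # zero hinge with noise: residual on the scale of the noise sigma
  hp0 <- make_hinge_pair(hinge_spec(hinge_angle = 0, noise_sigma = 0.3,
                                    seed = 4))
  al0 <- align_stem(hp0$a, hp0$b, hp0$truth$stem)
  expect_gt(al0$fit$rmsd_kept, 0.15)
  expect_lt(al0$fit$rmsd_kept, 0.6)
  # stem deviations stay within twice the noise sigma
  prof0 <- deviation_profile(hp0$a, al0$b_aligned,
                             stem_definition("stem", "A",
                                             hp0$truth$stem$stem,
                                             c(hp0$truth$stem$stem,
                                               hp0$truth$stem$helix_path)))
  stem_devs <- prof0$deviation[prof0$resno %in% hp0$truth$stem$stem]
  expect_lt(stats::quantile(stem_devs, 0.95), 2 * 0.3)
})

test_that("a stem accidentally crossing the hinge is flagged by its residual", {
  hp <- make_hinge_pair(hinge_spec(n_stem = 6, n_arm = 12,
                                   hinge_angle = 15, noise_sigma = 0,
                                   seed = 6))
  good <- align_stem(hp$a, hp$b, hp$truth$stem)
  total <- max(hp$a$atom$resno)
  bad_stem <- stem_definition("bad", "A",
                              c(4:9, (total - 8):(total - 3)),
                              hp$truth$stem$helix_path,
                              hp$truth$stem$tip_residue)
  bad <- align_stem(hp$a, hp$b, bad_stem)
  expect_lt(good$fit$rmsd_kept, 1e-6)
  expect_gt(bad$fit$rmsd_all, 10 * good$fit$rmsd_all + 0.5)
})

test_that("missing stem residues raise a stem-incomplete error naming them", {
  hp <- make_hinge_pair(hinge_spec(hinge_angle = 5, seed = 2))
  b_trunc <- subset_model(hp$b, which(hp$b$atom$resno != 2))
  expect_error(align_stem(hp$a, b_trunc, hp$truth$stem),
               "stem incomplete.*2")
})

test_that("deviation profiles read out constructed motions exactly", {
  hp <- make_hinge_pair(hinge_spec(hinge_angle = 0, noise_sigma = 0,
                                   seed = 9))
  al <- align_stem(hp$a, hp$b, hp$truth$stem)
  prof <- deviation_profile(hp$a, al$b_aligned, hp$truth$stem)
  expect_true(all(prof$deviation < 1e-9))
  # rigid 5 A translation of everything distal to residue k
  k <- 12
  b <- hp$a
  rows <- which(b$atom$resno > k & b$atom$resno <= max(b$atom$resno) / 2)
  b$atom$x[rows] <- b$atom$x[rows] + 5
  prof2 <- deviation_profile(hp$a, b, hp$truth$stem)
  before <- prof2$deviation[prof2$resno <= k]
  after <- prof2$deviation[prof2$resno > k &
                             prof2$resno <= max(b$atom$resno) / 2]
  expect_true(all(before < 1e-9))
  expect_true(all(abs(after - 5) < 1e-9))
  # absent residues are flagged, not fatal
  b_missing <- subset_model(hp$a, which(hp$a$atom$resno != k + 1))
  prof3 <- deviation_profile(hp$a, b_missing, hp$truth$stem)
  expect_false(prof3$present[prof3$resno == k + 1])
  expect_true(all(prof3$present[prof3$resno != k + 1]))
})

test_that("noise-free deviations equal the analytic chord at every residue", {
  for (theta in c(5, 10, 30)) {
    hp <- make_hinge_pair(hinge_spec(hinge_angle = theta, noise_sigma = 0,
                                     seed = 3))
    al <- align_stem(hp$a, hp$b, hp$truth$stem)
    prof <- deviation_profile(hp$a, al$b_aligned, hp$truth$stem)
    expected <- 2 * sin(theta * pi / 360) * hp$truth$r_path
    expect_lt(max(abs(prof$deviation - expected)), 1e-6)
  }
})

test_that("locate_pivot applies threshold and persistence in path order", {
  prof <- structure(data.frame(resno = 1:6,
                               deviation = c(0, 0, 0, 3, 4, 5),
                               n_atoms = 6L, present = TRUE),
                    class = c("deviation_profile", "data.frame"))
  expect_equal(locate_pivot(prof, threshold = 1, persistence = 2), 4)
  expect_equal(locate_pivot(prof, threshold = 1, persistence = 1), 4)
  # all-zero profile: no pivot
  prof0 <- prof
  prof0$deviation <- 0
  expect_true(is.na(locate_pivot(prof0, threshold = 1)))
  # an isolated spike fails the persistence requirement
  prof1 <- prof
  prof1$deviation <- c(0, 5, 0, 0, 0, 0)
  expect_true(is.na(locate_pivot(prof1, threshold = 1, persistence = 2)))
  # absent residues are skipped when counting persistence
  prof2 <- prof
  prof2$present <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  expect_equal(locate_pivot(prof2, threshold = 1, persistence = 2), 4)
})

test_that("tip displacement matches construction and the chord formula", {
  hp <- make_hinge_pair(hinge_spec(hinge_angle = 0, noise_sigma = 0,
                                   seed = 5))
  expect_lt(tip_displacement(hp$a, hp$b, hp$truth$stem), 1e-9)
  # pure translation of the distal arm
  b <- hp$a
  rows <- which(b$atom$resno > 10)
  b$atom$y[rows] <- b$atom$y[rows] + 5
  expect_equal(tip_displacement(hp$a, b, hp$truth$stem), 5,
               tolerance = 1e-9)
  # hinge: chord length at the tip radius
  hp2 <- make_hinge_pair(hinge_spec(hinge_angle = 25, noise_sigma = 0,
                                    seed = 5))
  al <- align_stem(hp2$a, hp2$b, hp2$truth$stem)
  expect_equal(tip_displacement(hp2$a, al$b_aligned, hp2$truth$stem),
               hp2$truth$expected_tip_chord, tolerance = 1e-6)
})

test_that("tip displacement grows strictly with the hinge angle", {
  angles <- c(0, 5, 10, 20, 30, 45, 60)
  disp <- vapply(angles, function(th) {
    hp <- make_hinge_pair(hinge_spec(hinge_angle = th, noise_sigma = 0,
                                     seed = 12))
    al <- align_stem(hp$a, hp$b, hp$truth$stem)
    tip_displacement(hp$a, al$b_aligned, hp$truth$stem)
  }, numeric(1))
  expect_true(all(diff(disp) > 0))
})

test_that("the hinge angle is recovered from stem-aligned arm frames", {
  for (theta in c(5, 10, 30)) {
    hp <- make_hinge_pair(hinge_spec(hinge_angle = theta, noise_sigma = 0,
                                     seed = 8))
    expect_equal(estimate_hinge_angle(hp$a, hp$b, hp$truth$stem), theta,
                 tolerance = 0.1)
  }
})

test_that("pivot recovery holds under noise and stays quiet without motion", {
  n_seeds <- 60
  hits <- 0
  for (s in seq_len(n_seeds)) {
    hp <- make_hinge_pair(hinge_spec(n_stem = 6, n_arm = 12,
                                     hinge_angle = 10, noise_sigma = 0.3,
                                     seed = s))
    al <- align_stem(hp$a, hp$b, hp$truth$stem)
    prof <- deviation_profile(hp$a, al$b_aligned, hp$truth$stem)
    piv <- locate_pivot(prof, max(1, 2 * al$fit$rmsd_kept))
    if (!is.na(piv) && abs(piv - hp$truth$pivot_residue) <= 1) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_seeds, 0.9)
  # false-positive control at zero angle
  fp <- 0
  for (s in seq_len(n_seeds)) {
    hp <- make_hinge_pair(hinge_spec(n_stem = 6, n_arm = 12,
                                     hinge_angle = 0, noise_sigma = 0.3,
                                     seed = s))
    al <- align_stem(hp$a, hp$b, hp$truth$stem)
    prof <- deviation_profile(hp$a, al$b_aligned, hp$truth$stem)
    if (!is.na(locate_pivot(prof, max(1, 2 * al$fit$rmsd_kept)))) {
      fp <- fp + 1
    }
  }
  expect_lte(fp / n_seeds, 0.02)
})

test_that("detect_pivots reports every catalog helix and self-comparisons are null", {
  hp <- make_hinge_pair(hinge_spec(hinge_angle = 12, noise_sigma = 0,
                                   seed = 10, motif_at_pivot = "GU_wobble"))
  calls <- detect_pivots(hp$a, hp$b, list(H1 = hp$truth$stem))
  expect_equal(nrow(calls), 1)
  expect_lte(abs(calls$pivot_location - hp$truth$pivot_residue), 1)
  expect_equal(calls$displacement, hp$truth$expected_tip_chord,
               tolerance = 1e-6)
  expect_equal(calls$motif_class, "GU_wobble")
  # self-comparison: zero displacement, flagged no-pivot, never dropped
  null_calls <- detect_pivots(hp$a, hp$a, list(H1 = hp$truth$stem),
                              config = list(annotate = FALSE))
  expect_equal(nrow(null_calls), 1)
  expect_lt(null_calls$displacement, 1e-9)
  expect_match(null_calls$flags, "no_pivot")
  # sub-threshold motion is flagged when a reporting floor is supplied
  tiny <- detect_pivots(hp$a, hp$a, list(H1 = hp$truth$stem),
                        config = list(annotate = FALSE,
                                      reporting_floor = 0.4))
  expect_match(tiny$flags, "sub_threshold")
  # per-helix failures don't abort the run
  bad <- stem_definition("H9", "A", 900:905, 906:920)
  both <- detect_pivots(hp$a, hp$b, list(H1 = hp$truth$stem, H9 = bad),
                        config = list(annotate = FALSE))
  expect_equal(nrow(both), 2)
  expect_match(both$flags[both$helix_id == "H9"], "error")
})

test_that("mobile-helix screening finds the hinged helix only", {
  th <- make_two_hinge_construct(
    hinge_spec(n_stem = 6, n_arm = 10, hinge_angle = 0, seed = 3),
    hinge_spec(n_stem = 4, n_arm = 8, hinge_angle = 15, noise_sigma = 0,
               seed = 4))
  sc <- screen_mobile_helices(th$a, th$b)
  expect_true(all(sc$chain == "B"))
  expect_gte(nrow(sc), 1)
  # the top run starts within 2 residues of the true pivot
  expect_lte(abs(sc$start[1] - th$truth_local$pivot_residue), 2)
  # identical models produce no candidates
  expect_equal(nrow(screen_mobile_helices(th$a, th$a)), 0)
})
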