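test_that("rmsd has its closed forms and symmetry", {
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd_coords(x, x), 0)
  # two points each displaced by d -> rmsd d
  a <- rbind(c(0, 0, 0), c(10, 0, 0))
  b <- rbind(c(3, 0, 0), c(13, 0, 0))
  expect_equal(rmsd_coords(a, b), 3)
  # three points at distances 1, 2, 2 -> sqrt((1+4+4)/3) = sqrt(3)
  a3 <- diag(0, 3)
  b3 <- rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 2))
  expect_equal(rmsd_coords(a3, b3), sqrt(3))
  y <- x + rnorm(30)
  expect_equal(rmsd_coords(x, y), rmsd_coords(y, x))
})

test_that("kabsch recovers exact rigid motions to numerical precision", {
  set.seed(1)
  x <- matrix(rnorm(90), 30, 3)
  expect_equal(kabsch(x, x)$rmsd_all, 0, tolerance = 1e-12)
  th <- pi / 2
  rot90 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                  3, 3, byrow = TRUE)
  y <- apply_rigid_xyz(x, rot90, c(1, 2, 3))
  fit <- kabsch(x, y)
  expect_lt(fit$rmsd_all, 1e-10)
  # proper orthonormal rotation
  expect_lt(max(abs(t(fit$rotation) %*% fit$rotation - diag(3))), 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_error(kabsch(x[1:2, ], y[1:2, ]), "degenerate")
})

test_that("kabsch beats random rigid transforms (optimality)", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(90), 30, 3)
    y <- x + matrix(rnorm(90, 0, 0.5), 30, 3)
    best <- kabsch(x, y)$rmsd_all
    worst <- min(replicate(200, {
      rmsd_coords(x, apply_rigid_xyz(y, random_rotation(), rnorm(3)))
    }))
    expect_lte(best, worst + 1e-12)
  }
})

test_that("kabsch RMSD is invariant to pre-transforming either input", {
  set.seed(7)
  x <- matrix(rnorm(60), 20, 3)
  y <- x + matrix(rnorm(60, 0, 0.3), 20, 3)
  base <- kabsch(x, y)$rmsd_all
  for (i in 1:5) {
    xr <- apply_rigid_xyz(x, random_rotation(), rnorm(3, 0, 10))
    yr <- apply_rigid_xyz(y, random_rotation(), rnorm(3, 0, 10))
    expect_equal(kabsch(xr, y)$rmsd_all, base, tolerance = 1e-6)
    expect_equal(kabsch(x, yr)$rmsd_all, base, tolerance = 1e-6)
  }
})

test_that("kabsch agrees with the bio3d least-squares fit", {
  set.seed(3)
  x <- matrix(rnorm(120), 40, 3)
  y <- apply_rigid_xyz(x + matrix(rnorm(120, 0, 0.4), 40, 3),
                       random_rotation(), c(5, -2, 1))
  ours <- kabsch(x, y)$rmsd_all
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(x)),
                                            as.vector(t(y))))
  ref <- bio3d::rmsd(as.vector(t(x)), fitted)
  # bio3d::rmsd rounds to 3 decimals, so compare absolutely
  expect_lt(abs(ours - ref), 1e-3)
})

test_that("weighted fits honor the weights", {
  set.seed(9)
  x <- matrix(rnorm(60), 20, 3)
  y <- x
  y[1, ] <- y[1, ] + 30
  w <- rep(1, 20)
  w[1] <- 0
  expect_lt(kabsch(x, y, weights = w)$rmsd_kept, 31)
  fit <- kabsch(x[-1, ], y[-1, ])
  expect_lt(fit$rmsd_all, 1e-10)
})

test_that("iterative rejection removes gross outliers only", {
  set.seed(5)
  xyz <- matrix(rnorm(150, sd = 4), 50, 3)
  a <- point_model(xyz)
  moved <- xyz
  moved[7, ] <- moved[7, ] + 20
  b <- point_model(apply_rigid_xyz(moved, random_rotation(), c(1, 1, 1)))
  ap <- full_atom_pairing(a, b, min_atoms = 3)
  fit <- refine_superposition(ap, a, b)
  expect_equal(which(!fit$kept), 7)
  expect_equal(fit$n_rejected, 1L)
  expect_lt(fit$rmsd_kept, 1e-6)
  expect_gt(fit$rmsd_all, 1)          # reported over the original pairing
  expect_lte(fit$rmsd_kept, fit$rmsd_all)
  # noiseless rigid copy: nothing to reject
  b0 <- point_model(apply_rigid_xyz(xyz, random_rotation(), c(3, 2, 1)))
  fit0 <- refine_superposition(full_atom_pairing(a, b0, min_atoms = 3),
                               a, b0)
  expect_equal(fit0$n_rejected, 0L)
  # max_cycles = 0 reduces to plain kabsch on the full pairing
  fitk <- refine_superposition(ap, a, b, max_cycles = 0)
  ref <- kabsch(coords(a, ap$row_a), coords(b, ap$row_b))
  expect_equal(fitk$rmsd_all, ref$rmsd_all)
  expect_equal(fitk$n_rejected, 0L)
})

test_that("transform_model applies the fit to every atom", {
  m <- make_aform_duplex(5, seed = 8)
  rot <- random_rotation()
  tr <- c(4, 5, 6)
  moved <- m
  xyz <- apply_rigid_xyz(coords(m), rot, tr)
  moved$atom$x <- xyz[, 1]; moved$atom$y <- xyz[, 2]; moved$atom$z <- xyz[, 3]
  ap <- full_atom_pairing(m, moved)
  fit <- refine_superposition(ap, m, moved)
  back <- transform_model(moved, fit)
  expect_lt(max(abs(coords(back) - coords(m))), 1e-8)
  expect_identical(back$atom$elety, moved$atom$elety)
})
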