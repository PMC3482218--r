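test_that("interior cubic-lattice cells are exactly spacing^3", {
  lat <- make_lattice(3, 2.0)
  v <- suppressMessages(voronoi_volumes(lat))
  xyz <- as.matrix(lat$atoms[, c("x", "y", "z")])
  ctr <- which.min(rowSums(sweep(xyz, 2, colMeans(xyz))^2))
  expect_equal(v$volume[ctr], 8.0, tolerance = 1e-6)
  expect_true(v$bounded[ctr])
  # packing density of the interior is 1 by construction (vstd = spacing^3)
  expect_equal(v$vstd[ctr] / v$volume[ctr], 1.0, tolerance = 1e-6)
})

test_that("an n=2 lattice has every cell capped by solvent, none interior", {
  lat <- make_lattice(2, 2.0)
  v <- suppressMessages(voronoi_volumes(lat))
  # all 8 atoms sit on the hull; solvent capping must close their cells
  expect_true(all(v$bounded))
  expect_true(all(v$volume > 8))  # larger than the interior cell they'd have
})

test_that("tessellation conserves the volume of a closed box", {
  set.seed(11)
  pts <- matrix(runif(90, 0, 10), 30, 3)
  wts <- runif(30, 1.2, 2.0)
  for (mode in c("radical", "bisector")) {
    cv <- cell_volumes(pts, wts, mode = mode, box = c(0, 0, 0, 10, 10, 10))
    expect_equal(sum(cv$volume), 1000, tolerance = 0.005)
  }
})

test_that("bisector and radical partitions agree exactly for equal radii", {
  set.seed(12)
  pts <- matrix(rnorm(60, sd = 4), 20, 3)
  a <- cell_volumes(pts, rep(1.6, 20), mode = "radical", box_hw = 10)
  b <- cell_volumes(pts, rep(1.6, 20), mode = "bisector", box_hw = 10)
  expect_equal(a$volume, b$volume, tolerance = 1e-9)
})

test_that("deleting a site never shrinks the remaining cells", {
  set.seed(13)
  pts <- matrix(runif(45, 0, 8), 15, 3)
  wts <- runif(15, 1.3, 1.9)
  before <- cell_volumes(pts, wts, box = c(-2, -2, -2, 10, 10, 10))
  after <- cell_volumes(pts[-8, ], wts[-8], box = c(-2, -2, -2, 10, 10, 10))
  expect_true(all(after$volume - before$volume[-8] > -1e-9))
})

test_that("exact cells agree with the Monte-Carlo oracle", {
  # lattice central cell with a box enclosing it: 8.0 within sampling error
  lat <- make_lattice(3, 2.0)
  xyz <- as.matrix(lat$atoms[, c("x", "y", "z")])
  ctr <- which.min(rowSums(sweep(xyz, 2, c(2, 2, 2))^2))
  box <- c(xyz[ctr, ] - 1.6, xyz[ctr, ] + 1.6)
  mc <- mc_volume_oracle(xyz, lat$atoms$radius, box, n_samples = 2e6,
                         seed = 101)
  expect_equal(mc$volume[ctr], 8.0, tolerance = 0.01)

  # helix atoms: exact cells clipped to a common box vs nearest-power-site
  # sampling in the same box (box-clipping makes the comparison exact in
  # expectation, whatever the cell shapes)
  h <- make_helix("AKLLEAWKST")
  g <- h$geom
  shell <- lipscan:::solvent_sites(g, h$atoms$radius)
  sites <- rbind(g, shell)
  wts <- c(h$atoms$radius, rep(1.4, nrow(shell)))
  asa <- compute_asa(h, n_points = 240)$asa
  pick <- order(asa)[1:3]
  for (i in pick) {
    box <- c(g[i, ] - 4.5, g[i, ] + 4.5)
    near <- which(abs(sites[, 1] - g[i, 1]) < 16 &
                    abs(sites[, 2] - g[i, 2]) < 16 &
                    abs(sites[, 3] - g[i, 3]) < 16)
    near <- union(i, near)
    ii <- match(i, near)
    ex <- cell_volumes(sites[near, ], wts[near], n_cells = length(near),
                       box = box)
    mc <- mc_volume_oracle(sites[near, ], wts[near], box, n_samples = 6e6,
                           seed = 200 + i)
    expect_equal(mc$volume[ii], ex$volume[ii], tolerance = 0.01)
  }
})

test_that("volumes sum over all sites in a box reproduces the box volume", {
  set.seed(14)
  pts <- matrix(runif(60, 1, 7), 20, 3)
  mc <- mc_volume_oracle(pts, rep(1.5, 20), box = c(0, 0, 0, 8, 8, 8),
                         n_samples = 5e5, seed = 3)
  expect_equal(sum(mc$volume), 512, tolerance = 512 * 0.001)
})

test_that("packing density arithmetic and exclusion rules", {
  b <- structure(list(interface = c(1L, 2L), window = 1),
                 class = "lip_burial")
  v <- tibble::tibble(serial = 1:2, vstd = c(10, 20),
                      volume = c(12.5, 25), bounded = TRUE)
  expect_equal(packing_density(b, v)$rho, 0.8)
  # identity when every real volume equals its standard volume
  v2 <- tibble::tibble(serial = 1:2, vstd = c(10, 20), volume = c(10, 20),
                       bounded = TRUE)
  expect_equal(packing_density(b, v2)$rho, 1.0)
  # unbounded cells drop out of both sums
  v3 <- tibble::tibble(serial = 1:2, vstd = c(10, 20), volume = c(12.5, 1e5),
                       bounded = c(TRUE, FALSE))
  r3 <- packing_density(b, v3)
  expect_equal(r3$rho, 10 / 12.5)
  expect_equal(r3$n_excluded, 1L)
  # all unbounded: missing with a warning
  v4 <- tibble::tibble(serial = 1:2, vstd = c(10, 20), volume = c(1, 1),
                       bounded = FALSE)
  expect_warning(r4 <- packing_density(b, v4), "unbounded")
  expect_true(is.na(r4$rho))
})

test_that("rho track is invariant under rigid-body transforms", {
  h <- helix_mixed()
  p1 <- scan_profiles(h, n_points = 240, protein_id = "fixture")
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  xyz <- as.matrix(h$atoms[, c("x", "y", "z")]) %*% t(R)
  a2 <- h$atoms
  a2$x <- xyz[, 1] - 7.2; a2$y <- xyz[, 2] + 3.9; a2$z <- xyz[, 3] + 0.4
  p2 <- scan_profiles(new_lip_structure(a2, source = "moved"),
                      n_points = 240, protein_id = "fixture")
  expect_equal(p2$rho, p1$rho, tolerance = 1e-9)
  expect_equal(p2$PR, p1$PR, tolerance = 1e-9)
  # written profiles are byte-identical
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_profile_tsv(p1, f1); write_profile_tsv(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
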