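test_that("exact one-sided rank-sum p-values on small samples", {
  m <- mann_whitney_one_sided(c(4, 5, 6), c(1, 2, 3), "a_greater")
  expect_equal(m$p, 1 / 20)
  expect_equal(m$method, "exact")
  expect_equal(m$U, 9)
  # identical samples carry no signal
  m2 <- mann_whitney_one_sided(c(1, 2, 3), c(1, 2, 3), "a_greater")
  expect_gte(m2$p, 0.5)
  # direction flip
  m3 <- mann_whitney_one_sided(c(1, 2, 3), c(4, 5, 6), "b_greater")
  expect_equal(m3$p, 1 / 20)
  expect_error(mann_whitney_one_sided(numeric(0), 1:3), "non-empty")
})

test_that("exact method matches brute-force enumeration exhaustively", {
  set.seed(31)
  for (rep in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(seq_len(100), n1 + n2)    # tie-free by construction
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    got <- mann_whitney_one_sided(a, b, "a_greater")
    expect_equal(got$method, "exact")
    expect_equal(got$p, brute_force_mwu(a, b), info = paste("rep", rep))
  }
})

test_that("exact and approximate p-values agree for moderate samples", {
  set.seed(32)
  for (rep in 1:20) {
    a <- rnorm(10); b <- rnorm(10, 0.3)
    ex <- mann_whitney_one_sided(a, b, "a_greater")
    ap <- mann_whitney_one_sided(a, b, "a_greater", exact_max = 0L)
    expect_equal(ex$method, "exact")
    expect_equal(ap$method, "normal_approx")
    expect_lt(abs(ex$p - ap$p), 0.02)
  }
})

test_that("exact route matches wilcox.test and refuses ties gracefully", {
  set.seed(33)
  a <- rnorm(8); b <- rnorm(7)
  got <- mann_whitney_one_sided(a, b, "a_greater")
  ref <- stats::wilcox.test(a, b, alternative = "greater", exact = TRUE)
  expect_equal(got$p, unname(ref$p.value))
  expect_equal(got$U, unname(ref$statistic))
  # ties force the tie-corrected approximation
  expect_message(
    tied <- mann_whitney_one_sided(c(1, 2, 2, 3), c(2, 2, 4), "a_greater"),
    "ties")
  expect_equal(tied$method, "normal_approx")
  ref2 <- suppressWarnings(
    stats::wilcox.test(c(1, 2, 2, 3), c(2, 2, 4), alternative = "greater",
                       exact = FALSE, correct = TRUE))
  expect_equal(tied$p, unname(ref2$p.value), tolerance = 1e-9)
})

test_that("p-values are invariant under monotone transforms of the data", {
  set.seed(34)
  a <- runif(9); b <- runif(6)
  p0 <- mann_whitney_one_sided(a, b, "a_greater")$p
  expect_equal(mann_whitney_one_sided(exp(5 * a), exp(5 * b), "a_greater")$p,
               p0)
  expect_equal(mann_whitney_one_sided(log(a), log(b), "a_greater")$p, p0)
})

test_that("region contrast detects a planted polarity separation", {
  set.seed(35)
  n <- 40
  pr <- runif(n, 0.3, 0.5)
  pr[11:20] <- runif(10, 0.9, 1.1)
  p <- planted_profile(PR = pr, rho = runif(n, 0.7, 0.9))
  ann <- tibble::tibble(start = c(11, 25), end = c(20, 34),
                        label = c("unstable", "stable"))
  r <- region_polarity_test(p, ann)
  expect_lt(r$p, 0.05)
  # no signal when all PR are drawn from the same band
  p2 <- planted_profile(PR = runif(n, 0.4, 0.5), rho = runif(n, 0.7, 0.9))
  r2 <- region_polarity_test(p2, ann)
  expect_gt(r2$p, 0.05)
  # flat profile: p >= 0.5 up to the normal-approximation correction
  p3 <- planted_profile(PR = rep(0.5, n), rho = runif(n, 0.7, 0.9))
  r3 <- suppressMessages(region_polarity_test(p3, ann))
  expect_gte(r3$p, 0.5)
  expect_error(
    region_polarity_test(p, tibble::tibble(start = 900, end = 950,
                                           label = "unstable")),
    "outside")
})

test_that("LIP-vs-rest contrast uses the complement when nonLIP is implicit", {
  set.seed(36)
  pr <- runif(30, 0.3, 0.5); pr[5:10] <- runif(6, 0.9, 1.2)
  p <- planted_profile(PR = pr, rho = runif(30, 0.7, 0.9))
  ann <- tibble::tibble(start = 5, end = 10, label = "LIP")
  r <- region_polarity_test(p, ann, contrast = "LIP_vs_nonLIP")
  expect_lt(r$p, 0.05)
})

test_that("anti-correlation is computed over finite pairs only", {
  p <- planted_profile(PR = c(0.2, 0.5, 0.9, 0.4),
                       rho = 1 - c(0.2, 0.5, 0.9, 0.4))
  expect_equal(profile_anticorrelation(p), -1)
  p2 <- planted_profile(PR = c(0.2, 0.5, 0.9, Inf),
                        rho = c(0.9, 0.8, 0.7, 0.1))
  expect_equal(profile_anticorrelation(p2),
               cor(c(0.2, 0.5, 0.9), c(0.9, 0.8, 0.7)))
  expect_error(profile_anticorrelation(
    planted_profile(PR = c(0.2, 0.5, 0.9), rho = rep(0.8, 3))), "degenerate")
  expect_error(profile_anticorrelation(
    planted_profile(PR = c(0.2, NA), rho = c(0.8, 0.9))), "3 paired")
})

test_that("an extended peptide buries almost nothing in the folded state", {
  ext <- make_helix("AKLVEQST", phi = -120, psi = 120)
  b <- reference_polarity(list(ext), n_points = 480)
  a <- ext$atoms
  asa_folded <- compute_asa(ext, n_points = 480)$asa
  ref <- lipscan:::reference_asa(ext, n_points = 480)
  buried <- pmax(0, ref - asa_folded)
  # buried area is a tiny fraction of the reference surface
  expect_lt(sum(buried) / sum(ref), 0.05)
  # surface ratio equals the folded-state polar/apolar exposure by definition
  pol <- a$polarity == "polar"
  expect_equal(b$per_protein$surface_ratio,
               sum(asa_folded[pol]) / sum(asa_folded[!pol]))
})

test_that("baselines are invariant to input order and rigid motion", {
  h1 <- make_helix("AKLVEQSTWD")
  h2 <- make_helix("LLLVATKKRE")
  b12 <- reference_polarity(list(h1, h2), n_points = 480)
  b21 <- reference_polarity(list(h2, h1), n_points = 480)
  expect_equal(b12$core_mean, b21$core_mean)
  expect_equal(b12$surface_sd, b21$surface_sd)

  th <- 0.4
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3,
              byrow = TRUE)
  xyz <- as.matrix(h1$atoms[, c("x", "y", "z")]) %*% t(R)
  a <- h1$atoms; a$x <- xyz[, 1] + 3; a$y <- xyz[, 2]; a$z <- xyz[, 3] - 5
  h1r <- new_lip_structure(a, source = "moved")
  br <- reference_polarity(list(h1r), n_points = 480)
  b1 <- reference_polarity(list(h1), n_points = 480)
  expect_equal(br$per_protein$core_ratio, b1$per_protein$core_ratio,
               tolerance = 1e-9)
})

test_that("region annotations load from TSV and BED", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tstart\tend\tlabel",
               "prot\t87\t108\tunstable", "prot\t1\t60\tstable"), tsv)
  ann <- read_region_annotation(tsv)
  expect_equal(ann$start, c(87, 1))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("prot\t86\t108\tunstable", "prot\t0\t60\tstable"), bed)
  ann2 <- read_region_annotation(bed)
  expect_equal(ann2$start, c(87, 1))
  expect_equal(ann2$end, c(108, 60))
  expect_equal(ann2$label, c("unstable", "stable"))
})
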