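test_that("packing cutoff uses the population SD", {
  p <- planted_profile(PR = rep(0.4, 4), rho = rep(0.8, 4))
  cut <- packing_cutoff(p, 2)
  expect_equal(cut$mu, 0.8)
  expect_equal(cut$sigma, 0)
  expect_equal(cut$cutoff, 0.8)

  p2 <- planted_profile(PR = c(0.4, 0.4), rho = c(0.9, 0.7))
  cut2 <- packing_cutoff(p2, 2)
  expect_equal(cut2$mu, 0.8)
  expect_equal(cut2$sigma, 0.1)
  expect_equal(cut2$cutoff, 0.6)
  expect_error(packing_cutoff(planted_profile(0.4, NA_real_), 2),
               "non-missing")
})

test_that("a flat sub-baseline profile yields no candidates", {
  p <- planted_profile(PR = rep(0.45, 20), rho = runif(20, 0.7, 0.9))
  expect_equal(nrow(find_polar_peaks(p)), 0)
  expect_equal(nrow(call_lips(p)), 0)
})

test_that("seeds extend to the baseline and report their peaks", {
  pr <- rep(0.4, 30)
  pr[12:18] <- c(0.6, 0.7, 0.9, 0.95, 0.9, 0.7, 0.6)
  p <- planted_profile(PR = pr, rho = rep(0.8, 30))
  cand <- find_polar_peaks(p)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 12)
  expect_equal(cand$end, 18)
  expect_equal(cand$peaks[[1]], c(14, 15, 16))
  expect_equal(cand$max_PR, 0.95)
})

test_that("overlapping extensions merge into one candidate", {
  pr <- rep(0.3, 40)
  pr[10:25] <- 0.6          # shared above-baseline plateau
  pr[c(13, 21)] <- 0.9      # two seeds within it
  p <- planted_profile(PR = pr, rho = rep(0.8, 40))
  cand <- find_polar_peaks(p)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end), c(10, 25))
  expect_equal(cand$peaks[[1]], c(13, 21))
  # a sub-baseline gap keeps candidates apart unless max_gap bridges it
  pr[17] <- 0.4
  p2 <- planted_profile(PR = pr, rho = rep(0.8, 40))
  expect_equal(nrow(find_polar_peaks(p2)), 2)
  merged <- find_polar_peaks(p2, lip_params(max_gap = 1))
  expect_equal(nrow(merged), 1)
})

test_that("missing positions terminate extension", {
  pr <- c(0.7, 0.9, NA, 0.7, 0.6, 0.2)
  p <- planted_profile(PR = pr, rho = rep(0.8, 6))
  cand <- find_polar_peaks(p)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end), c(1, 2))
})

test_that("infinite PR counts as a peak seed", {
  pr <- c(0.3, 0.6, Inf, 0.6, rep(0.3, 6))
  rho <- c(0.9, 0.8, 0.5, 0.8, 0.9, 0.88, 0.92, 0.9, 0.89, 0.91)
  p <- planted_profile(PR = pr, rho = rho)
  calls <- call_lips(p, lip_params(packing_mode = "strict"))
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$start, calls$end), c(2, 4))
  expect_identical(calls$max_PR, Inf)
})

test_that("candidates over well-packed regions are rejected", {
  # two identical PR humps; only the second sits in a deep packing minimum
  pr <- rep(0.4, 40)
  pr[8:12] <- c(0.6, 0.9, 1.0, 0.9, 0.6)
  pr[28:32] <- c(0.6, 0.9, 1.0, 0.9, 0.6)
  rho <- rep(0.85, 40)
  rho[26:34] <- c(0.82, 0.78, 0.72, 0.66, 0.60, 0.66, 0.72, 0.78, 0.82)
  p <- planted_profile(PR = pr, rho = rho)
  for (mode in c("strict", "wall")) {
    calls <- call_lips(p, lip_params(packing_mode = mode))
    expect_equal(nrow(calls), 1)
    expect_equal(c(calls$start, calls$end), c(28, 32))
  }
  cand <- attr(call_lips(p), "candidates")
  expect_equal(nrow(cand), 2)
  expect_false(cand$packing_pass[1])
})

test_that("wall mode admits a candidate on the flank of a deep minimum", {
  pr <- rep(0.4, 40)
  pr[12:16] <- c(0.6, 0.85, 0.9, 0.85, 0.6)   # candidate on the basin wall
  # deep minimum centred at 20; its below-cutoff core sits at 19-21 only
  rho <- 0.9 - 0.25 * exp(-((1:40) - 20)^2 / 18)
  p <- planted_profile(PR = pr, rho = rho)
  strict <- call_lips(p, lip_params(packing_mode = "strict"))
  wall <- call_lips(p, lip_params(packing_mode = "wall"))
  expect_equal(nrow(strict), 0)
  expect_equal(nrow(wall), 1)
  expect_equal(c(wall$start, wall$end), c(12, 16))
})

test_that("caller equals brute-force interval enumeration on random tracks", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(15:50, 1)
    pr <- round(runif(n, 0, 1.3), 2)
    pr[runif(n) < 0.08] <- NA
    rho <- round(runif(n, 0.55, 1.0), 2)
    rho[runif(n) < 0.05] <- NA
    params <- lip_params(packing_mode = sample(c("strict", "wall"), 1),
                         min_len = sample(1:2, 1))
    p <- planted_profile(PR = pr, rho = rho)
    got <- call_lips(p, params)
    want <- brute_force_lips(p, params)
    expect_equal(nrow(got), nrow(want), info = paste("rep", rep))
    if (nrow(want)) {
      expect_equal(got$start_resid, unname(want[, 1]), info = paste("rep", rep))
      expect_equal(got$end_resid, unname(want[, 2]), info = paste("rep", rep))
    }
  }
})

test_that("every returned LIP satisfies the definition invariants", {
  set.seed(5)
  pr <- abs(0.5 + cumsum(rnorm(60, 0, 0.18)))
  rho <- 0.8 + 0.06 * sin((1:60) / 4) + rnorm(60, 0, 0.02)
  p <- planted_profile(PR = pr, rho = rho)
  params <- lip_params()
  calls <- call_lips(p, params)
  for (k in seq_len(nrow(calls))) {
    i <- calls$start_resid[k]:calls$end_resid[k]
    expect_true(all(p$PR[i] > params$theta_base))
    expect_true(any(p$PR[i] >= params$theta_peak))
    expect_true(calls$packing_pass[k])
  }
  # idempotence
  expect_identical(tidy(calls), tidy(call_lips(p, params)))
})

test_that("raising thresholds never increases the number of calls", {
  set.seed(6)
  for (rep in 1:10) {
    pr <- abs(0.5 + cumsum(rnorm(40, 0, 0.2)))
    rho <- runif(40, 0.6, 0.95)
    p <- planted_profile(PR = pr, rho = rho)
    n_08 <- nrow(call_lips(p, lip_params(theta_peak = 0.8)))
    n_10 <- nrow(call_lips(p, lip_params(theta_peak = 1.0)))
    expect_lte(n_10, n_08)
    s_2 <- nrow(call_lips(p, lip_params(packing_mode = "strict", k_sd = 2)))
    s_25 <- nrow(call_lips(p, lip_params(packing_mode = "strict", k_sd = 2.5)))
    expect_lte(s_25, s_2)
  }
})

test_that("LIP outputs are written as BED (0-based) and TSV (inclusive)", {
  pr <- rep(0.4, 20); pr[8:12] <- c(0.6, 0.9, 1.0, 0.9, 0.6)
  rho <- rep(0.85, 20); rho[9:11] <- 0.5
  p <- planted_profile(PR = pr, rho = rho, start_resno = 101L)
  calls <- call_lips(p)
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_lips(calls, bed = bed, tsv = tsv)
  b <- read.delim(bed, header = FALSE)
  expect_equal(b$V2, 107)   # 0-based start of author residue 108
  expect_equal(b$V3, 112)   # half-open end covering residue 112
  expect_equal(b$V5, 100)   # round(100 * max_PR), max_PR = 1.0
  t <- read.delim(tsv)
  expect_equal(c(t$start, t$end), c(108, 112))
})
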