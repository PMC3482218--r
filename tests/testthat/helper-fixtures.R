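# Shared fixtures, lazily built and cached for the whole run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, build(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

helix_mixed <- function() cached("helix_mixed", function()
  make_helix("AKLLEAWKSTDQLLKA"))

lysozyme_path <- function()
  system.file("examples", "1hel.pdb", package = "bio3d")

lysozyme <- function() cached("lysozyme", function()
  load_structure(lysozyme_path(), chain = "A"))

lysozyme_profile <- function() cached("lysozyme_profile", function()
  scan_profiles(lysozyme()))

lysozyme2 <- function() cached("lysozyme2", function()
  suppressWarnings(load_structure(
    system.file("examples", "1dpx.pdb", package = "bio3d"), chain = "A")))

# independent brute-force LIP enumeration: all maximal intervals with every
# PR above the baseline, at least one PR at/above the peak threshold, and the
# packing association, evaluated directly from the definition
brute_force_lips <- function(p, params) {
  n <- nrow(p)
  pr <- p$PR
  rho <- p$rho
  above <- !is.na(pr) & pr > params$theta_base
  seed <- !is.na(pr) & pr >= params$theta_peak
  sat <- list()
  for (a in seq_len(n)) for (b in a:n) {
    i <- a:b
    if (all(above[i]) && any(seed[i]) &&
        (a == 1 || !above[a - 1]) && (b == n || !above[b + 1]) &&
        length(i) >= params$min_len)
      sat[[length(sat) + 1]] <- c(a, b)
  }
  if (!length(sat)) return(matrix(integer(), ncol = 2))
  cut <- packing_cutoff(p, params$k_sd)
  below_cut <- !is.na(rho) & rho < cut$cutoff
  below_mu <- !is.na(rho) & rho < cut$mu
  keep <- vapply(sat, function(iv) {
    i <- iv[1]:iv[2]
    if (params$packing_mode == "strict") return(any(below_cut[i]))
    for (j in which(below_cut)) {
      lo <- j; while (lo > 1 && below_mu[lo - 1]) lo <- lo - 1
      hi <- j; while (hi < n && below_mu[hi + 1]) hi <- hi + 1
      if (lo <= iv[2] && hi >= iv[1]) return(TRUE)
    }
    FALSE
  }, logical(1))
  out <- do.call(rbind, sat[keep])
  if (is.null(out)) return(matrix(integer(), ncol = 2))
  out[order(out[, 1]), , drop = FALSE]
}

# brute-force one-sided MWU p-value: U from direct pair counting (not rank
# sums), null distribution from complete enumeration of group labelings
brute_force_mwu <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(u_all >= u_obs - 1e-12)
}
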