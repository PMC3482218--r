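#' One-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Exact enumeration of the U distribution when the pooled sample has at most
#' `exact_max` observations and no ties; otherwise (or with ties) a
#' tie-corrected normal approximation with continuity correction.  The
#' alternative is one-sided: values of the named sample tend to be larger.
#'
#' @param a,b numeric samples.
#' @param alternative `"a_greater"` or `"b_greater"`.
#' @param exact_max largest pooled size for exact enumeration (default 20).
#' @return a `lip_mwu` list: `U` (for the sample named by the alternative),
#'   `p`, `n1`, `n2`, `alternative`, `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' mann_whitney_one_sided(c(4, 5, 6), c(1, 2, 3), "a_greater")$p  # 1/20
#' @export
mann_whitney_one_sided <- function(a, b,
                                   alternative = c("a_greater", "b_greater"),
                                   exact_max = 20L) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  if (alternative == "b_greater") {
    tmp <- a; a <- b; b <- tmp
  }
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0

  if (!ties && n1 + n2 <= exact_max) {
    # exact: enumerate all C(n1+n2, n1) assignments of ranks to sample a
    combs <- utils::combn(n1 + n2, n1)
    ranks <- seq_len(n1 + n2)
    u_all <- colSums(matrix(ranks[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(u_all >= U)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - corr)
    if (sigma2 <= 0) {
      # fully tied pooled sample: every labeling gives U = mu
      p <- as.numeric(U <= mu)
    } else {
      z <- (U - mu - 0.5) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal_approx"
    if (ties && n1 + n2 <= exact_max)
      inform("ties present; exact method unavailable, using normal approximation")
  }
  structure(list(U = U, p = p, n1 = n1, n2 = n2,
                 alternative = alternative, method = method),
            class = "lip_mwu")
}

#' @export
print.lip_mwu <- function(x, ...) {
  cat("One-sided Mann-Whitney-Wilcoxon (", x$alternative, ", ", x$method,
      ")\n  U = ", x$U, ", n = (", x$n1, ", ", x$n2, "), p = ",
      format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.lip_mwu <- function(x, ...) {
  tibble(U = x$U, p.value = x$p, n1 = x$n1, n2 = x$n2,
         alternative = x$alternative, method = x$method)
}

#' Compare interface polarity between annotated regions
#'
#' Pools the PR values at assigned positions inside each group's intervals
#' and tests, one-sided, whether the first group (unstable, or LIP) has
#' higher interface polarity than the second (stable, or non-LIP).  Infinite
#' PR sentinels are excluded with a warning.  For the `LIP_vs_nonLIP`
#' contrast, `annotation` intervals labelled `LIP` define the first group and
#' every other assigned position forms the second.
#'
#' @param p a `lip_profile`.
#' @param annotation tibble with `start`, `end` (author numbering, inclusive)
#'   and `label` in `unstable`, `stable`, `LIP`, `nonLIP`.
#' @param contrast `"unstable_vs_stable"` or `"LIP_vs_nonLIP"`.
#' @return a `lip_mwu` result.
#' @export
region_polarity_test <- function(p, annotation,
                                 contrast = c("unstable_vs_stable",
                                              "LIP_vs_nonLIP")) {
  contrast <- match.arg(contrast)
  labs <- if (contrast == "unstable_vs_stable") c("unstable", "stable")
          else c("LIP", "nonLIP")
  ann <- annotation[annotation$label %in% labs, , drop = FALSE]
  if (any(ann$start > ann$end)) abort("annotation has start > end")
  rng <- range(p$resno)
  if (any(ann$end < rng[1] | ann$start > rng[2]))
    abort("annotation interval outside profile range")

  in_label <- function(lab) {
    iv <- ann[ann$label == lab, , drop = FALSE]
    sel <- rep(FALSE, nrow(p))
    for (k in seq_len(nrow(iv)))
      sel <- sel | (p$resno >= iv$start[k] & p$resno <= iv$end[k])
    sel
  }
  g1 <- in_label(labs[1])
  g2 <- if (contrast == "LIP_vs_nonLIP" && !any(ann$label == "nonLIP"))
    !g1 else in_label(labs[2])

  x1 <- p$PR[g1]; x2 <- p$PR[g2]
  if (any(is.infinite(c(x1, x2)))) {
    warn("infinite PR sentinel(s) excluded from the rank-sum test")
    x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
  }
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  if (!length(x1) || !length(x2))
    abort("both groups need at least one finite profile position")
  mann_whitney_one_sided(x1, x2, "a_greater")
}

#' PR-rho anti-correlation of a profile
#'
#' Pearson correlation over positions where both tracks are finite.  High
#' polarity pairing with loose packing yields a negative value.
#'
#' @param p a `lip_profile`.
#' @return Pearson r.
#' @export
profile_anticorrelation <- function(p) {
  ok <- is.finite(p$PR) & is.finite(p$rho)
  if (sum(ok) < 3) abort("need at least 3 paired finite positions")
  if (stats::sd(p$PR[ok]) == 0 || stats::sd(p$rho[ok]) == 0)
    abort("degenerate track (zero variance); correlation undefined")
  stats::cor(p$PR[ok], p$rho[ok])
}

#' Core and surface polarity baselines over a protein set
#'
#' For each structure, every atom's reference ASA is computed in a
#' Gly-flanked tripeptide context extracted from the structure itself (the
#' atom's own residue in its actual conformation plus the backbone atoms of
#' the two sequence-adjacent residues).  The buried area of an atom is
#' `max(0, ASA_ref - ASA_folded)`.  The core polarity ratio of a protein is
#' total buried polar area over total buried apolar area; the surface ratio
#' is total exposed polar ASA over total exposed apolar ASA in the folded
#' state.  Set-level means use the population SD.
#'
#' @param structures list of `lip_structure` objects.
#' @param probe probe radius, Angstrom.
#' @param n_points SASA sphere sample count.
#' @return a `lip_baselines` list: `per_protein` tibble (`protein_id`,
#'   `core_ratio`, `surface_ratio`), `core_mean`, `core_sd`, `surface_mean`,
#'   `surface_sd`.
#' @export
reference_polarity <- function(structures, probe = 1.4, n_points = 960L) {
  if (inherits(structures, "lip_structure")) structures <- list(structures)
  if (!length(structures)) abort("need at least one structure")

  per <- purrr::map_dfr(structures, function(s) {
    a <- s$atoms
    asa_folded <- compute_asa(s, probe = probe, n_points = n_points)$asa
    asa_ref <- reference_asa(s, probe = probe, n_points = n_points)
    buried <- pmax(0, asa_ref - asa_folded)
    pol <- a$polarity == "polar"
    core <- ratio_or_inf(sum(buried[pol]), sum(buried[!pol]))
    surf <- ratio_or_inf(sum(asa_folded[pol]), sum(asa_folded[!pol]))
    tibble(protein_id = sub("\\.(pdb|ent|cif)$", "", basename(s$source)),
           core_ratio = core, surface_ratio = surf)
  })
  pop_sd <- function(x) {
    x <- x[is.finite(x)]
    sqrt(mean((x - mean(x))^2))
  }
  fin <- function(x) x[is.finite(x)]
  structure(list(per_protein = per,
                 core_mean = mean(fin(per$core_ratio)),
                 core_sd = pop_sd(per$core_ratio),
                 surface_mean = mean(fin(per$surface_ratio)),
                 surface_sd = pop_sd(per$surface_ratio)),
            class = "lip_baselines")
}

ratio_or_inf <- function(num, den) {
  if (den == 0) {
    if (num == 0) return(NA_real_)
    warn("degenerate composition: apolar total is zero; ratio is +Inf")
    return(Inf)
  }
  num / den
}

# per-atom ASA in the Gly-X-Gly-style reference context
reference_asa <- function(s, probe = 1.4, n_points = 960L) {
  a <- s$atoms
  xyz <- geom_xyz(s)
  out <- numeric(nrow(a))
  bb <- c("N", "CA", "C", "O")
  for (r in s$residues$resid) {
    own <- which(!is.na(a$resid) & a$resid == r)
    flank <- which(!is.na(a$resid) & a$resid %in% c(r - 1, r + 1) &
                     a$atom %in% bb)
    ctx <- c(own, flank)
    asa <- cpp_sasa(xyz[ctx, , drop = FALSE], a$radius[ctx],
                    probe, as.integer(n_points), seq_along(own))
    out[own] <- asa
  }
  env <- which(a$is_env)
  if (length(env)) {
    # environment atoms: isolated-group reference (their own het group)
    out[env] <- cpp_sasa(xyz[env, , drop = FALSE],
                         a$radius[env], probe, as.integer(n_points),
                         seq_along(env))
  }
  out
}

#' @export
print.lip_baselines <- function(x, ...) {
  cat("<lip_baselines> over", nrow(x$per_protein), "protein(s)\n")
  cat(sprintf("  core polarity:    %.3f +/- %.3f\n", x$core_mean, x$core_sd))
  cat(sprintf("  surface polarity: %.3f +/- %.3f\n",
              x$surface_mean, x$surface_sd))
  invisible(x)
}

#' @export
tidy.lip_baselines <- function(x, ...) x$per_protein

#' @export
glance.lip_baselines <- function(x, ...) {
  tibble(n_proteins = nrow(x$per_protein), core_mean = x$core_mean,
         core_sd = x$core_sd, surface_mean = x$surface_mean,
         surface_sd = x$surface_sd)
}

#' Read a region annotation table
#'
#' Accepts a TSV with columns `protein_id`, `start`, `end`, `label`
#' (author-numbered inclusive intervals) or a BED file (0-based half-open)
#' whose name field carries the label.
#'
#' @param path annotation file.
#' @return tibble with `protein_id`, `start`, `end`, `label`.
#' @export
read_region_annotation <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("protein_id", first)) {
    tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  } else {
    bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    tibble(protein_id = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
           label = bed[[4]])
  }
}
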