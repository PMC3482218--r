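#' Per-atom solvent-accessible surface area
#'
#' Deterministic Shrake-Rupley-type surface sampling: a fixed golden-section
#' spiral of `n_points` test points on each atom's expanded sphere
#' (radius + probe), with neighbour occlusion.  No randomness is involved, so
#' repeated calls are byte-identical.
#'
#' @param s a `lip_structure`, or a tibble with `x`, `y`, `z`, `radius`
#'   columns.
#' @param probe probe radius in Angstrom (default 1.40, a water molecule).
#' @param n_points sphere sample count (>= 60; default 960).
#' @param targets optional integer indices of the atoms to evaluate (their
#'   occluders are always the full atom set given); default all.
#' @return tibble with `serial` (when available), `asa` in square Angstrom,
#'   and the atom annotation columns of the input.
#' @examples
#' one <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.87)
#' compute_asa(one)$asa               # isolated sphere: 4*pi*(1.87+1.4)^2
#' @export
compute_asa <- function(s, probe = 1.4, n_points = 960L, targets = NULL) {
  if (inherits(s, "lip_structure")) {
    atoms <- s$atoms
    xyz <- geom_xyz(s)
  } else {
    atoms <- tibble::as_tibble(s)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
  }
  targets <- targets %||% seq_len(nrow(atoms))
  asa <- cpp_sasa(xyz, atoms$radius,
                  probe, as.integer(n_points), as.integer(targets))
  out <- atoms[targets, , drop = FALSE]
  out$asa <- asa
  out
}

# indices of atoms whose ASA can change when `moved` atoms are removed from
# or added to the context: anything within contact distance of a moved atom
contact_affected <- function(xyz, radii, moved, probe) {
  r <- radii + probe
  keep <- rep(FALSE, nrow(xyz))
  mx <- xyz[moved, , drop = FALSE]
  mr <- r[moved]
  for (k in seq_along(moved)) {
    d2 <- (xyz[, 1] - mx[k, 1])^2 + (xyz[, 2] - mx[k, 2])^2 +
      (xyz[, 3] - mx[k, 3])^2
    keep <- keep | d2 < (r + mr[k])^2
  }
  which(keep)
}

#' Areas buried at a window fragment / remainder interface
#'
#' For every atom, the buried area is its ASA computed in its own part alone
#' (fragment or remainder) minus its ASA in the full structure, clipped at
#' zero.  Atoms with buried area above `eps` form the interface; their buried
#' areas are totalled by polarity class into `A_pol` and `A_apol`.
#' Environment-only heteroatoms (when admitted by `het_policy`) belong to the
#' remainder and contribute to the totals.
#'
#' Only atoms within contact range of the fragment are re-evaluated; all
#' others have zero burial by construction.
#'
#' @param s a `lip_structure`.
#' @param w a `lip_window` from [split_window()].
#' @param probe probe radius, Angstrom.
#' @param eps interface membership threshold on buried area, square Angstrom.
#' @param n_points sphere sample count.
#' @param asa_full optional cached result of `compute_asa(s, ...)` at the same
#'   parameters, to avoid recomputation across windows.
#' @return a `lip_burial`: list with per-atom tibble `atoms` (buried areas for
#'   contact-affected atoms), `interface` (serials), `A_pol`, `A_apol`,
#'   window metadata.
#' @export
interface_burial <- function(s, w, probe = 1.4, eps = 0.1, n_points = 960L,
                             asa_full = NULL) {
  if (!inherits(w, "lip_window")) abort("`w` must be a lip_window")
  if (!w$valid) abort("window spans a chain break; burial undefined")
  atoms <- s$atoms
  xyz <- geom_xyz(s)
  frag <- w$fragment_atoms
  rest <- w$remainder_atoms

  if (is.null(asa_full)) asa_full <- compute_asa(s, probe, n_points)$asa

  # remainder atoms in contact range of the fragment + all fragment atoms
  aff <- contact_affected(xyz, atoms$radius, frag, probe)
  aff_rest <- setdiff(intersect(aff, rest), frag)

  asa_frag <- cpp_sasa(xyz[frag, , drop = FALSE],
                       atoms$radius[frag], probe, as.integer(n_points),
                       seq_along(frag))
  asa_rest <- if (length(aff_rest)) {
    cpp_sasa(xyz[rest, , drop = FALSE], atoms$radius[rest],
             probe, as.integer(n_points),
             as.integer(match(aff_rest, rest)))
  } else numeric(0)

  idx <- c(frag, aff_rest)
  part_asa <- c(asa_frag, asa_rest)
  buried <- pmax(0, part_asa - asa_full[idx])
  tab <- atoms[idx, c("serial", "atom", "resname", "resno", "resid",
                      "polarity", "is_env")]
  tab$side <- rep(c("fragment", "remainder"),
                  c(length(frag), length(aff_rest)))
  tab$asa_part <- part_asa
  tab$asa_full <- asa_full[idx]
  tab$buried <- buried

  iface <- tab$buried > eps
  structure(list(
    atoms = tab,
    interface = tab$serial[iface],
    A_pol = sum(tab$buried[iface & tab$polarity == "polar"]),
    A_apol = sum(tab$buried[iface & tab$polarity == "apolar"]),
    window = w$i, assigned = w$assigned, probe = probe, eps = eps
  ), class = "lip_burial")
}

#' Polarity ratio of a buried interface
#'
#' PR = buried polar area / buried apolar area.  A zero apolar total with a
#' positive polar total yields `Inf` with a warning (kept as a sentinel: such
#' interfaces count as above any peak threshold); an empty interface yields
#' `NA`.
#'
#' @param b a `lip_burial`, or a list with `A_pol` and `A_apol`.
#' @return dimensionless ratio.
#' @export
polarity_ratio <- function(b) {
  if (b$A_apol == 0) {
    if (b$A_pol == 0) return(NA_real_)
    warn("interface has no buried apolar area; polarity ratio is +Inf")
    return(Inf)
  }
  b$A_pol / b$A_apol
}
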