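#' Low-level cell volumes of a weighted point set
#'
#' Computes the volume of each site's Voronoi cell (`mode = "bisector"`) or
#' power-diagram cell weighted by the site radii (`mode = "radical"`), by
#' exact half-space clipping.  Cells are clipped either to a site-centered
#' cube of halfwidth `box_hw` (the default; cells still showing a cube face
#' afterwards are flagged unbounded) or, when `box` is given, to that common
#' axis-aligned box, in which case cell volumes partition the box exactly.
#'
#' @param sites numeric matrix (n x 3) of site coordinates.
#' @param weights site radii (used in radical mode; ignored by bisector).
#' @param mode `"radical"` or `"bisector"`.
#' @param n_cells number of leading sites to report volumes for (default all).
#' @param box_hw halfwidth of the site-centered bounding cube, Angstrom.
#' @param box optional common box `c(xlo, ylo, zlo, xhi, yhi, zhi)`.
#' @return tibble with `volume` (cubic Angstrom) and `bounded` per cell.
#' @export
cell_volumes <- function(sites, weights = rep(1, nrow(sites)),
                         mode = c("radical", "bisector"),
                         n_cells = nrow(sites), box_hw = 8, box = NULL) {
  mode <- match.arg(mode)
  sites <- as.matrix(sites)
  if (nrow(sites) < 5) abort("need at least 5 sites")
  res <- cpp_cell_volumes(sites, as.numeric(weights), as.integer(n_cells),
                          mode == "radical", box_hw,
                          if (is.null(box)) numeric(0) else as.numeric(box))
  tibble(volume = res$volume, bounded = res$bounded)
}

# solvent pseudo-sites on the accessible surface, pushed to radius + offset,
# deduplicated on a grid
solvent_sites <- function(xyz, radii, probe = 1.4, offset = 2.8,
                          dot_points = 80L, grid = 1.2) {
  dots <- cpp_surface_dots(xyz, radii,
                           probe, as.integer(dot_points), offset)
  if (!nrow(dots)) return(dots)
  key <- paste(round(dots[, 1] / grid), round(dots[, 2] / grid),
               round(dots[, 3] / grid))
  dots[!duplicated(key), , drop = FALSE]
}

#' Voronoi atomic volumes of a structure with solvent capping
#'
#' Tessellates space over the protein atoms plus solvent pseudo-sites
#' generated on the accessible surface (surface dots pushed to
#' atom center + radius + 2.8 Angstrom, the first hydration shell), so that
#' cells of surface atoms are closed by solvent rather than extending to
#' infinity.  Volumes are returned for protein atoms only.  The default
#' partition is the radical-plane (power) tessellation weighted by the van der
#' Waals radii; `mode = "bisector"` gives classical unweighted Voronoi cells.
#' Atoms whose cells remain open (still touching the bounding cube) are
#' flagged `bounded = FALSE` and should be excluded from packing sums.
#'
#' @param s a `lip_structure`.
#' @param mode `"radical"` (default) or `"bisector"`.
#' @param probe probe radius used to build the capping shell.
#' @param shell_offset distance above the atom radius for pseudo-sites,
#'   Angstrom (default 2.8, one water diameter).
#' @param solvent_radius weight given to pseudo-sites in radical mode.
#' @param dot_points surface dots per atom before deduplication.
#' @return tibble with one row per atom: `serial`, `volume`, `bounded`,
#'   `vstd` (standard volume) plus identity columns; attribute
#'   `n_solvent_sites` records the capping shell size.
#' @export
voronoi_volumes <- function(s, mode = c("radical", "bisector"), probe = 1.4,
                            shell_offset = 2.8, solvent_radius = 1.4,
                            dot_points = 80L) {
  mode <- match.arg(mode)
  atoms <- s$atoms
  if (nrow(atoms) < 5) abort("need at least 5 atoms")
  xyz <- geom_xyz(s)
  shell <- solvent_sites(xyz, atoms$radius, probe = probe,
                         offset = shell_offset, dot_points = dot_points)
  sites <- rbind(xyz, shell)
  wts <- c(atoms$radius, rep(solvent_radius, nrow(shell)))
  cv <- cell_volumes(sites, wts, mode = mode, n_cells = nrow(atoms))
  out <- atoms[, c("serial", "atom", "resname", "resno", "resid", "is_env",
                   "polarity", "vstd")]
  out$volume <- cv$volume
  out$bounded <- cv$bounded
  if (any(!out$bounded))
    inform(paste0(sum(!out$bounded),
                  " atom cell(s) open to the bounding cube; flagged unbounded"))
  attr(out, "n_solvent_sites") <- nrow(shell)
  attr(out, "mode") <- mode
  out
}

#' Interface packing density
#'
#' rho = sum of standard atomic volumes / sum of actual Voronoi volumes over
#' the interface atoms of a window.  Values near 1 indicate crystal-like
#' tight packing.  Atoms with unbounded (open) cells are excluded from both
#' sums, so numerator and denominator stay consistent.
#'
#' @param b a `lip_burial` from [interface_burial()].
#' @param v a volume table from [voronoi_volumes()] for the same structure.
#' @return list with `rho`, `n_interface`, `n_excluded`, `window`.
#' @export
packing_density <- function(b, v) {
  if (!inherits(b, "lip_burial")) abort("`b` must be a lip_burial")
  if (!length(b$interface)) abort("interface is empty; packing undefined")
  sel <- v[match(b$interface, v$serial), , drop = FALSE]
  ok <- !is.na(sel$volume) & sel$bounded & sel$volume > 0
  n_exc <- sum(!ok)
  if (!any(ok)) {
    warn("all interface atoms have unbounded cells; packing density missing")
    return(list(rho = NA_real_, n_interface = length(b$interface),
                n_excluded = n_exc, window = b$window))
  }
  list(rho = sum(sel$vstd[ok]) / sum(sel$volume[ok]),
       n_interface = length(b$interface), n_excluded = n_exc,
       window = b$window)
}

#' Monte-Carlo cell-volume oracle
#'
#' Independent validation path for [cell_volumes()]: uniform samples in `box`
#' are assigned to the site with smallest (power) distance; each cell volume
#' is the box volume times its hit fraction.  Slower than the exact
#' tessellation but free of any polyhedral geometry.
#'
#' @param sites numeric matrix (n x 3).
#' @param weights site radii (radical mode).
#' @param box common box `c(xlo, ylo, zlo, xhi, yhi, zhi)`.
#' @param n_samples number of samples (>= 1e5).
#' @param seed RNG seed (restored on exit).
#' @param mode `"radical"` or `"bisector"`.
#' @return tibble with `volume` and standard error `se` per site.
#' @export
mc_volume_oracle <- function(sites, weights = rep(1, nrow(sites)), box,
                             n_samples = 1e6, seed = 1L,
                             mode = c("radical", "bisector")) {
  mode <- match.arg(mode)
  if (n_samples < 1e5) abort("n_samples must be >= 1e5")
  sites <- as.matrix(sites)
  n <- nrow(sites)
  lo <- box[1:3]; hi <- box[4:6]
  vol_box <- prod(hi - lo)
  w2 <- if (mode == "radical") as.numeric(weights)^2 else rep(0, n)

  counts <- integer(n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  chunk <- 50000L
  done <- 0
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    px <- runif(m, lo[1], hi[1]); py <- runif(m, lo[2], hi[2])
    pz <- runif(m, lo[3], hi[3])
    best <- rep.int(1L, m)
    bestd <- (px - sites[1, 1])^2 + (py - sites[1, 2])^2 +
      (pz - sites[1, 3])^2 - w2[1]
    for (j in 2:n) {
      d <- (px - sites[j, 1])^2 + (py - sites[j, 2])^2 +
        (pz - sites[j, 3])^2 - w2[j]
      upd <- d < bestd
      best[upd] <- j
      bestd[upd] <- d[upd]
    }
    counts <- counts + tabulate(best, n)
    done <- done + m
  }
  p <- counts / n_samples
  tibble(volume = vol_box * p,
         se = vol_box * sqrt(p * (1 - p) / n_samples))
}
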