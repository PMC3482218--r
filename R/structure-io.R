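#' Load a single-chain protein structure from a PDB file
#'
#' Reads a PDB file (first model only), selects one chain, removes waters and
#' hydrogens, resolves alternate locations to the highest-occupancy conformer
#' (ties broken towards altloc "A"), and annotates every retained heavy atom
#' with its van der Waals radius, polarity class and standard Voronoi volume
#' (see [annotate_atoms()]).  Heteroatoms are excluded by default;
#' `het_policy = "environment"` admits non-water heteroatoms (cofactors, ions)
#' to the burial and tessellation environment, but they never join window
#' fragments nor receive profile positions.
#'
#' Atoms are put into canonical order (author residue number, insertion code,
#' serial), so files with scrambled record order yield identical results.
#'
#' @param path PDB file.
#' @param chain chain identifier; may be omitted for single-chain files.
#' @param het_policy `"exclude"` (default) or `"environment"`.
#' @param polar_sulfur classify sulfur atoms as polar (default `FALSE`).
#' @param params optional replacement atom-parameter table.
#' @return a `lip_structure`: list with `atoms` (tibble), `residues` (tibble),
#'   `chain`, `source`, `resolution`, `polar_sulfur`.
#' @examples
#' pdb <- system.file("examples", "1hel.pdb", package = "bio3d")
#' s <- load_structure(pdb, chain = "A")
#' s
#' @export
load_structure <- function(path, chain = NULL,
                           het_policy = c("exclude", "environment"),
                           polar_sulfur = FALSE, params = NULL) {
  het_policy <- match.arg(het_policy)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- tibble::as_tibble(pdb$atom)

  # element symbols; fall back to bio3d's name-based mapping when absent
  el <- toupper(trimws(at$elesy %||% rep(NA_character_, nrow(at))))
  bad <- is.na(el) | el == ""
  if (any(bad)) {
    el[bad] <- toupper(suppressWarnings(
      bio3d::atom2ele(at$elety[bad], rescue = TRUE)))
  }
  at$element <- el

  at <- dplyr::filter(at,
    !.data$resid %in% c("HOH", "WAT", "DOD", "H2O"),
    !.data$element %in% c("H", "D"))
  if (het_policy == "exclude") at <- dplyr::filter(at, .data$type == "ATOM")

  std_chains <- unique(at$chain[at$type == "ATOM"])
  if (is.null(chain)) {
    if (length(std_chains) > 1)
      abort(paste0("file contains chains ", paste(std_chains, collapse = ", "),
                   "; supply `chain`"))
    chain <- std_chains[1]
  }
  at <- dplyr::filter(at, .data$chain == !!chain)
  if (!any(at$type == "ATOM"))
    abort(paste0("chain '", chain, "' has no standard residues (available: ",
                 paste(std_chains, collapse = ", "), ")"))

  # altloc resolution: highest occupancy, ties -> first altloc alphabetically
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$o <- ifelse(is.na(at$o), 1, at$o)
  at <- at %>%
    dplyr::group_by(.data$type, .data$resno, .data$insert, .data$elety) %>%
    dplyr::arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()

  atoms <- tibble(
    serial = as.integer(at$eleno),
    atom = trimws(at$elety),
    element = at$element,
    resname = trimws(at$resid),
    resno = as.integer(at$resno),
    insert = at$insert,
    is_env = at$type != "ATOM",
    x = at$x, y = at$y, z = at$z
  )
  atoms <- dplyr::arrange(atoms, .data$is_env, .data$resno, .data$insert,
                          .data$serial)
  atoms <- annotate_atoms(atoms, polar_sulfur = polar_sulfur, params = params)

  res <- resolution_from_pdb(path)
  new_lip_structure(atoms, chain = chain, source = path, resolution = res,
                    polar_sulfur = polar_sulfur)
}

resolution_from_pdb <- function(path) {
  lines <- tryCatch(readLines(path, n = 2000, warn = FALSE),
                    error = function(e) character())
  hit <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (!length(hit)) return(NA_real_)
  num <- regmatches(hit[1], regexpr("[0-9]+\\.[0-9]+", hit[1]))
  if (!length(num)) NA_real_ else as.numeric(num)
}

#' Construct a structure object from an atom table
#'
#' Internal-facing constructor used by [load_structure()] and the synthetic
#' fixture generators.  `atoms` must carry `atom`, `element`, `resname`,
#' `resno`, `x`, `y`, `z`; annotation columns are added when missing.
#'
#' @param atoms atom tibble.
#' @param chain,source,resolution metadata.
#' @param polar_sulfur polarity convention used for annotation.
#' @param params optional replacement atom-parameter table.
#' @return a `lip_structure`.
#' @export
new_lip_structure <- function(atoms, chain = "A", source = "synthetic",
                              resolution = NA_real_, polar_sulfur = FALSE,
                              params = NULL) {
  atoms <- tibble::as_tibble(atoms)
  has <- function(col) col %in% names(atoms)
  if (!has("serial")) atoms$serial <- seq_len(nrow(atoms))
  if (!has("insert")) atoms$insert <- ""
  if (!has("is_env")) atoms$is_env <- FALSE
  if (!all(c("radius", "vstd", "polarity") %in% names(atoms)))
    atoms <- annotate_atoms(atoms, polar_sulfur = polar_sulfur, params = params)
  if (any(atoms$radius <= 0) || any(atoms$vstd <= 0))
    abort("radii and standard volumes must be positive")

  key <- paste(atoms$resno, atoms$insert)
  poly_key <- unique(key[!atoms$is_env])
  resid_map <- stats::setNames(seq_along(poly_key), poly_key)
  atoms$resid <- ifelse(atoms$is_env, NA_integer_,
                        as.integer(resid_map[key]))
  residues <- atoms %>%
    dplyr::filter(!.data$is_env) %>%
    dplyr::group_by(.data$resid) %>%
    dplyr::summarise(resno = dplyr::first(.data$resno),
                     insert = dplyr::first(.data$insert),
                     resname = dplyr::first(.data$resname),
                     n_atoms = dplyr::n(), .groups = "drop")
  s <- structure(list(atoms = atoms, residues = residues, chain = chain,
                      source = source, resolution = resolution,
                      polar_sulfur = polar_sulfur),
                 class = "lip_structure")
  s$geom <- canonical_frame(as.matrix(atoms[, c("x", "y", "z")]))
  s
}

# Geometry is evaluated in a canonical molecular frame (centroid origin,
# principal axes, deterministic signs), so that rigidly transformed inputs
# give identical surface areas and volumes: the quadrature point set is fixed
# in space, not attached to the molecule.
canonical_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  x0 <- sweep(xyz, 2, ctr)
  if (nrow(xyz) < 3) return(x0)
  ev <- eigen(crossprod(x0) / nrow(x0), symmetric = TRUE)
  v <- ev$vectors
  # signs fixed by transform-invariant statistics of the projections:
  # correlation with position along the chain, falling back to skewness
  w <- seq_len(nrow(x0)) - (nrow(x0) + 1) / 2
  for (k in 1:2) {
    pr <- x0 %*% v[, k]
    d <- sum(w * pr)
    if (abs(d) < 1e-8) d <- sum(pr^3)
    if (d < 0) v[, k] <- -v[, k]
  }
  v[, 3] <- c(v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
              v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
              v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2])
  x0 %*% v
}

# canonical coordinates used by the geometry engines
geom_xyz <- function(s) s$geom

#' @export
print.lip_structure <- function(x, ...) {
  cat("<lip_structure> chain", x$chain, "-", nrow(x$residues), "residues,",
      nrow(x$atoms), "atoms")
  if (any(x$atoms$is_env)) cat(" (", sum(x$atoms$is_env), "environment-only)")
  if (!is.na(x$resolution)) cat(" - resolution", x$resolution, "A")
  cat("\n  source:", x$source, "\n")
  invisible(x)
}

#' @export
as_tibble.lip_structure <- function(x, ...) x$atoms

#' Number of resolved residues
#' @param s a `lip_structure`.
#' @return integer residue count (environment-only heteroatoms excluded).
#' @export
n_residues <- function(s) nrow(s$residues)

#' Write a structure back to a PDB file
#'
#' Coordinates are written at the standard three-decimal PDB precision;
#' environment-only atoms become HETATM records.
#'
#' @param s a `lip_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$is_env, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$atom, chain = rep(s$chain, nrow(a)),
                   insert = ifelse(a$insert == "", NA, a$insert),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' Split a chain into a window fragment and its remainder
#'
#' Extracts the probe fragment of `L` consecutive resolved residues starting
#' at sequential residue index `i`; every other residue (plus any
#' environment-only heteroatom) forms the remainder.  The window is invalid
#' when it spans a chain break, i.e. any adjacent residue pair inside the
#' window has a CA-CA distance above `break_threshold`.
#'
#' @param s a `lip_structure`.
#' @param i 1-based window start over resolved residues.
#' @param L window length in residues (default 8).
#' @param break_threshold chain-break CA-CA distance, Angstrom.
#' @return a `lip_window`: list with atom index vectors `fragment_atoms` and
#'   `remainder_atoms`, the `assigned` residue (sequential index, author
#'   number, insertion code) at position `ceiling(L/2)` of the fragment, and a
#'   `valid` flag.
#' @export
split_window <- function(s, i, L = 8L, break_threshold = 4.5) {
  N <- n_residues(s)
  if (L < 1 || N < L) abort("window length exceeds chain length")
  if (i < 1 || i > N - L + 1) abort("window start out of range")
  frag_resid <- seq.int(i, i + L - 1)
  a <- s$atoms
  in_frag <- !is.na(a$resid) & a$resid %in% frag_resid
  assigned_resid <- i + ceiling(L / 2) - 1L
  res <- s$residues

  # chain-break check on representative (CA, else first) atoms
  valid <- TRUE
  if (L > 1) {
    rep_xyz <- vapply(frag_resid, function(r) {
      sub <- a[!is.na(a$resid) & a$resid == r, , drop = FALSE]
      ca <- sub[sub$atom == "CA", , drop = FALSE]
      p <- if (nrow(ca)) ca[1, ] else sub[1, ]
      c(p$x, p$y, p$z)
    }, numeric(3))
    gaps <- sqrt(rowSums(diff(t(rep_xyz))^2))
    valid <- all(gaps <= break_threshold)
  }

  structure(list(
    i = i, L = L, valid = valid,
    fragment_resid = frag_resid,
    fragment_atoms = which(in_frag),
    remainder_atoms = which(!in_frag),
    assigned = list(resid = assigned_resid,
                    resno = res$resno[assigned_resid],
                    insert = res$insert[assigned_resid],
                    resname = res$resname[assigned_resid])
  ), class = "lip_window")
}

#' Enumerate all window splits of a chain
#'
#' @inheritParams split_window
#' @return tibble with one row per window: start index, assigned residue and
#'   validity flag.
#' @export
window_splits <- function(s, L = 8L, break_threshold = 4.5) {
  N <- n_residues(s)
  if (N < L) abort("chain shorter than window")
  purrr::map_dfr(seq_len(N - L + 1), function(i) {
    w <- split_window(s, i, L, break_threshold)
    tibble(window = i, assigned_resid = w$assigned$resid,
           resno = w$assigned$resno, insert = w$assigned$insert,
           resname = w$assigned$resname, valid = w$valid)
  })
}
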