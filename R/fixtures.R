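# Synthetic structures and independent oracles.  These are first-class,
# tested code: every computational stage of the package can be exercised
# without downloading a single structure.

#' Cubic-lattice pseudo-protein
#'
#' One pseudo-atom per residue on a simple cubic grid, chained in
#' boustrophedon (snake) order so consecutive residues are always one grid
#' spacing apart.  Interior Voronoi cells are analytically `spacing^3`.
#' Atoms are named CA (element C, apolar) so window splitting works; their
#' standard volume is set to `spacing^3`, making the interior packing density
#' exactly 1.
#'
#' @param n_per_side grid points per edge (>= 2).
#' @param spacing grid spacing, Angstrom.
#' @param radius pseudo-atom van der Waals radius, Angstrom.
#' @return a `lip_structure` with `n_per_side^3` single-atom residues.
#' @export
make_lattice <- function(n_per_side, spacing = 2.0, radius = 1.87) {
  if (n_per_side < 2) abort("n_per_side must be >= 2")
  if (spacing <= 0) abort("spacing must be positive")
  n <- n_per_side
  idx <- list()
  row <- 0
  for (k in 0:(n - 1)) {
    js <- if (k %% 2 == 0) 0:(n - 1) else (n - 1):0
    for (j in js) {
      ii <- if (row %% 2 == 0) 0:(n - 1) else (n - 1):0
      for (i in ii) idx[[length(idx) + 1]] <- c(i, j, k)
      row <- row + 1
    }
  }
  g <- do.call(rbind, idx) * spacing
  m <- nrow(g)
  atoms <- tibble(atom = "CA", element = "C", resname = "LAT",
                  resno = seq_len(m), x = g[, 1], y = g[, 2], z = g[, 3])
  params <- tibble(residue_name = "LAT", atom_name = "CA", element = "C",
                   radius = radius, volume = spacing^3, group = "pseudo")
  new_lip_structure(atoms, source = "synthetic_lattice", params = params)
}

# internal coordinate placement: position d with |c-d| = bond,
# angle(b,c,d) = ang (degrees) and dihedral(a,b,c,d) = dih (degrees)
place_atom <- function(a, b, c, bond, ang, dih) {
  ang <- ang * pi / 180; dih <- dih * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  if (sum(n^2) < 1e-12) n <- pracma_cross(c(1, 0, 0), bc)
  if (sum(n^2) < 1e-12) n <- pracma_cross(c(0, 1, 0), bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# side-chain centroid parameters: distance from CA, effective radius,
# element carrying the polarity class, and approximate side-chain volume
sc_params <- function() {
  tibble::tribble(
    ~res, ~dist, ~radius, ~element, ~volume,
    "ALA", 1.53, 1.90, "C", 26,
    "ARG", 4.10, 2.30, "N", 110,
    "ASN", 2.50, 2.00, "N", 56,
    "ASP", 2.50, 2.00, "O", 50,
    "CYS", 2.10, 2.00, "S", 38,
    "GLN", 3.10, 2.10, "N", 75,
    "GLU", 3.10, 2.10, "O", 68,
    "HIS", 3.20, 2.20, "N", 79,
    "ILE", 2.40, 2.30, "C", 84,
    "LEU", 2.60, 2.30, "C", 84,
    "LYS", 3.50, 2.20, "N", 92,
    "MET", 2.90, 2.30, "C", 87,
    "PHE", 3.40, 2.40, "C", 97,
    "PRO", 1.90, 2.10, "C", 62,
    "SER", 1.90, 1.70, "O", 30,
    "THR", 1.90, 1.90, "O", 50,
    "TRP", 3.90, 2.60, "C", 127,
    "TYR", 3.80, 2.40, "O", 107,
    "VAL", 1.97, 2.20, "C", 64
  )
}

#' Ideal alpha-helix with centroid side chains
#'
#' Builds an ideal alpha-helical backbone (phi = -57, psi = -47, omega = 180
#' degrees; standard bond geometry) for the given one-letter sequence.  Side
#' chains are single centroid pseudo-atoms (atom name `SC`) carrying a
#' residue-appropriate distance from CA, radius, volume and polarity class —
#' deliberately non-physical, but sufficient to give polar and apolar
#' residues distinguishable buried interfaces.  Construction is fully
#' deterministic.
#'
#' @param sequence one-letter amino-acid string (length >= 2; standard
#'   residues only).
#' @param phi,psi backbone dihedrals in degrees; the defaults give an ideal
#'   alpha helix, `phi = -120, psi = 120` an extended strand.
#' @return a `lip_structure`.
#' @examples
#' make_helix("AKLLKA")
#' @export
make_helix <- function(sequence, phi = -57, psi = -47) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(seq1) < 2) abort("sequence too short")
  res3 <- suppressWarnings(bio3d::aa123(seq1))
  if (any(is.na(res3)) || any(res3 == "UNK"))
    abort(paste0("unknown residue letter(s): ",
                 paste(unique(seq1[is.na(res3) | res3 == "UNK"]),
                       collapse = ", ")))
  omega <- 180
  nres <- length(res3)

  rows <- list()
  # first residue backbone laid out in the xy plane
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
  C <- place_atom(c(-1, 1, 0), N, CA, 1.525, 111.2, 0)
  for (i in seq_len(nres)) {
    O <- place_atom(N, CA, C, 1.231, 120.8, psi + 180)
    rows[[length(rows) + 1]] <-
      tibble(atom = c("N", "CA", "C", "O"),
             element = c("N", "C", "C", "O"),
             resname = res3[i], resno = i,
             x = c(N[1], CA[1], C[1], O[1]),
             y = c(N[2], CA[2], C[2], O[2]),
             z = c(N[3], CA[3], C[3], O[3]))
    if (res3[i] != "GLY") {
      sp <- sc_params()
      sp <- sp[sp$res == res3[i], ]
      SC <- place_atom(N, C, CA, sp$dist, 109.5, 122.5)
      rows[[length(rows) + 1]] <-
        tibble(atom = "SC", element = sp$element, resname = res3[i],
               resno = i, x = SC[1], y = SC[2], z = SC[3])
    }
    if (i < nres) {
      Nn <- place_atom(N, CA, C, 1.329, 116.2, psi)
      CAn <- place_atom(CA, C, Nn, 1.458, 121.7, omega)
      Cn <- place_atom(C, Nn, CAn, 1.525, 111.2, phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  atoms <- dplyr::bind_rows(rows)
  atoms <- dplyr::arrange(atoms, .data$resno,
                          match(.data$atom, c("N", "CA", "C", "O", "SC")))
  sp <- sc_params()
  params <- dplyr::bind_rows(
    atom_param_table(),
    tibble(residue_name = sp$res, atom_name = "SC", element = sp$element,
           radius = sp$radius, volume = sp$volume, group = "centroid"))
  new_lip_structure(atoms, source = "synthetic_helix", params = params)
}

#' Two-body fixture
#'
#' Two single-atom residues a fixed distance apart; the minimal system for
#' checking buried areas against the analytic two-sphere cap formula.
#'
#' @param d center-center distance, Angstrom.
#' @param r1,r2 van der Waals radii.
#' @param elements element symbols (drive the polarity classes).
#' @return a `lip_structure` with two residues.
#' @export
make_two_body <- function(d, r1 = 1.87, r2 = 1.87, elements = c("C", "C")) {
  atoms <- tibble(atom = "CA", element = elements, resname = "LAT",
                  resno = 1:2, x = c(0, d), y = 0, z = 0)
  s <- new_lip_structure(atoms, source = "synthetic_two_body",
                         params = tibble(residue_name = "LAT",
                                         atom_name = "CA", element = "C",
                                         radius = 1.8, volume = 20,
                                         group = "pseudo"))
  # direct radius assignment; polarity already follows the element rule
  s$atoms$radius <- c(r1, r2)
  s
}

#' Planted profile
#'
#' Wraps explicit PR and rho tracks as a `lip_profile`, for exercising the
#' LIP caller and the statistics on exactly known inputs.
#'
#' @param PR,rho numeric tracks of equal length (`NA` = missing window,
#'   `Inf` PR allowed).
#' @param start_resno author number of the first position.
#' @param protein_id label.
#' @return a `lip_profile`.
#' @export
planted_profile <- function(PR, rho, start_resno = 1L,
                            protein_id = "planted") {
  stopifnot(length(PR) == length(rho))
  n <- length(PR)
  resno <- seq.int(start_resno, length.out = n)
  rows <- tibble(protein_id = protein_id, resid = seq_len(n), resno = resno,
                 insert = "", resname = "ALA", PR = PR, rho = rho,
                 A_pol = NA_real_, A_apol = NA_real_,
                 n_interface = NA_integer_,
                 valid = !(is.na(PR) & is.na(rho)))
  structure(rows, class = c("lip_profile", class(rows)),
            L = 8L, probe = 1.4, n_points = NA_integer_, eps = 0.1,
            mode = "radical", protein_id = protein_id,
            residues = tibble(resid = seq_len(n), resno = resno, insert = "",
                              resname = "ALA", n_atoms = 1L))
}

#' Dense-sampling ASA oracle
#'
#' Independent validation path for [compute_asa()]: equal-area
#' latitude-band sampling (a different deterministic point construction than
#' the engine's golden spiral) at high density, with brute-force occlusion.
#' Slow; intended for small fixtures.
#'
#' @param s a `lip_structure` or atom tibble with `x`, `y`, `z`, `radius`.
#' @param probe probe radius, Angstrom.
#' @param resolution target point spacing on the expanded sphere, Angstrom
#'   (default 0.1).
#' @return numeric vector of per-atom ASA, square Angstrom.
#' @export
sasa_oracle <- function(s, probe = 1.4, resolution = 0.1) {
  atoms <- if (inherits(s, "lip_structure")) s$atoms else tibble::as_tibble(s)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  er <- atoms$radius + probe
  n <- nrow(atoms)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- band_points(ceiling(4 * pi * er[i]^2 / resolution^2))
    p <- sweep(pts * er[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, nrow(p))
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- sum((xyz[j, ] - xyz[i, ])^2)
      if (d2 >= (er[i] + er[j])^2) next
      dd <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dd >= er[j]^2
    }
    out[i] <- 4 * pi * er[i]^2 * mean(free)
  }
  out
}

# Deserno-style equal-area points on the unit sphere (deterministic)
band_points <- function(n) {
  a <- 4 * pi / n
  d <- sqrt(a)
  m_theta <- round(pi / d)
  d_theta <- pi / m_theta
  d_phi <- a / d_theta
  pts <- list()
  for (m in 0:(m_theta - 1)) {
    theta <- pi * (m + 0.5) / m_theta
    m_phi <- round(2 * pi * sin(theta) / d_phi)
    if (m_phi < 1) m_phi <- 1
    phi <- 2 * pi * (0:(m_phi - 1)) / m_phi
    pts[[m + 1]] <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi),
                          rep(cos(theta), m_phi))
  }
  do.call(rbind, pts)
}
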