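# Packaged per-atom parameter tables: van der Waals radii (Chothia-type
# convention: O 1.40, N 1.65, S 1.85, trigonal C 1.76, tetrahedral C 1.87),
# standard Voronoi volumes of protein heavy-atom groups (small-molecule
# crystal reference set) and element-level fallbacks.

the <- new.env(parent = emptyenv())

atom_param_table <- function() {
  if (is.null(the$params)) {
    path <- system.file("extdata", "atom_params.tsv", package = "lipscan",
                        mustWork = TRUE)
    the$params <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  }
  the$params
}

element_fallback_table <- function() {
  if (is.null(the$fallback)) {
    path <- system.file("extdata", "element_fallback.tsv", package = "lipscan",
                        mustWork = TRUE)
    the$fallback <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  }
  the$fallback
}

#' Annotate atoms with radii, polarity classes and standard volumes
#'
#' Attaches to each heavy atom its van der Waals radius (Angstrom), its
#' polarity class and its standard Voronoi volume (cubic Angstrom).  Polarity
#' follows the element rule: N and O are polar, C is apolar, S is apolar by
#' default (set `polar_sulfur = TRUE` for the alternative convention).  Atoms
#' without a (residue, atom name) entry in the packaged table receive
#' element-level fallback values, a `param_fallback` flag and one warning.
#'
#' @param atoms tibble with at least `resname`, `atom` and `element` columns.
#' @param polar_sulfur logical; classify sulfur as polar.
#' @param params optional replacement parameter table (same columns as the
#'   packaged `atom_params.tsv`).
#' @return the input tibble with `radius`, `polarity`, `vstd` and
#'   `param_fallback` columns added.
#' @export
annotate_atoms <- function(atoms, polar_sulfur = FALSE, params = NULL) {
  params <- params %||% atom_param_table()
  fb <- element_fallback_table()
  atoms <- dplyr::left_join(
    atoms,
    dplyr::select(params, resname = "residue_name", atom = "atom_name",
                  radius_tab = "radius", vstd_tab = "volume"),
    by = c("resname", "atom")
  )
  el <- toupper(atoms$element)
  unknown <- !el %in% fb$element
  if (any(unknown)) {
    el[unknown] <- "X"
    abort(paste0("unknown element(s): ",
                 paste(unique(toupper(atoms$element)[unknown]), collapse = ", ")))
  }
  idx <- match(el, fb$element)
  miss <- is.na(atoms$radius_tab)
  if (any(miss)) {
    warn(paste0(sum(miss), " atom(s) lack a parameter-table entry; ",
                "element-level fallback radii/volumes assigned (e.g. ",
                paste(utils::head(unique(paste(atoms$resname[miss],
                                               atoms$atom[miss])), 3),
                      collapse = ", "), ")"))
  }
  atoms$radius <- ifelse(miss, fb$radius[idx], atoms$radius_tab)
  atoms$vstd <- ifelse(miss, fb$volume[idx], atoms$vstd_tab)
  atoms$param_fallback <- miss
  polar_set <- if (polar_sulfur) c("N", "O", "S") else c("N", "O")
  atoms$polarity <- ifelse(el %in% polar_set, "polar", "apolar")
  dplyr::select(atoms, -"radius_tab", -"vstd_tab")
}
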