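#' Polarity-ratio and packing-density profiles of a chain
#'
#' Slides an `L`-residue probe fragment along the chain; for every valid
#' window the polar/apolar buried-area ratio (PR) at the fragment/remainder
#' interface and the interface packing density (rho) are computed and
#' assigned to the residue at position `ceiling(L/2)` of the fragment (the
#' 4th residue for the default 8-residue probe).  Windows spanning chain
#' breaks yield missing values; nothing is interpolated.
#'
#' The full-structure ASA and the Voronoi volume set are computed once and
#' shared across windows, so a 200-residue chain scans in seconds.
#'
#' @param s a `lip_structure`.
#' @param L window length in residues (default 8).
#' @param probe probe radius, Angstrom (default 1.40).
#' @param n_points SASA sphere sample count.
#' @param eps interface membership threshold, square Angstrom.
#' @param mode Voronoi partition mode, `"radical"` or `"bisector"`.
#' @param protein_id label used in outputs; defaults to the source file name.
#' @param break_threshold chain-break CA-CA distance, Angstrom.
#' @return a `lip_profile` tibble with one row per assigned residue:
#'   `protein_id`, `resid`, `resno`, `insert`, `resname`, `PR`, `rho`,
#'   `A_pol`, `A_apol`, `n_interface`, `valid`.  Attributes carry the scan
#'   parameters and the full residue table (used by
#'   [project_onto_alignment()]).
#' @examples
#' h <- make_helix(strrep("A", 10))
#' scan_profiles(h, n_points = 240)
#' @export
scan_profiles <- function(s, L = 8L, probe = 1.4, n_points = 960L, eps = 0.1,
                          mode = c("radical", "bisector"), protein_id = NULL,
                          break_threshold = 4.5) {
  mode <- match.arg(mode)
  if (n_residues(s) < L) abort("chain shorter than window length")
  protein_id <- protein_id %||%
    sub("\\.(pdb|ent|cif)$", "", basename(s$source))

  asa_full <- compute_asa(s, probe = probe, n_points = n_points)$asa
  vols <- voronoi_volumes(s, mode = mode, probe = probe)

  N <- n_residues(s)
  rows <- purrr::map_dfr(seq_len(N - L + 1), function(i) {
    w <- split_window(s, i, L, break_threshold)
    base <- tibble(protein_id = protein_id, window = i,
                   resid = w$assigned$resid, resno = w$assigned$resno,
                   insert = w$assigned$insert, resname = w$assigned$resname,
                   valid = w$valid)
    if (!w$valid)
      return(dplyr::mutate(base, PR = NA_real_, rho = NA_real_,
                           A_pol = NA_real_, A_apol = NA_real_,
                           n_interface = NA_integer_))
    b <- interface_burial(s, w, probe = probe, eps = eps,
                          n_points = n_points, asa_full = asa_full)
    pr <- suppressWarnings(polarity_ratio(b))
    rho <- if (length(b$interface)) {
      suppressMessages(packing_density(b, vols)$rho)
    } else NA_real_
    dplyr::mutate(base, PR = pr, rho = rho, A_pol = b$A_pol,
                  A_apol = b$A_apol, n_interface = length(b$interface))
  })
  rows <- dplyr::select(rows, "protein_id", "resid", "resno", "insert",
                        "resname", "PR", "rho", "A_pol", "A_apol",
                        "n_interface", "valid")
  structure(rows,
            class = c("lip_profile", class(rows)),
            L = L, probe = probe, n_points = n_points, eps = eps, mode = mode,
            protein_id = protein_id, residues = s$residues)
}

#' Write a profile to TSV
#'
#' Plain tab-separated output (one row per assigned residue) with a stable
#' numeric format, so identical scans produce byte-identical files.
#'
#' @param p a `lip_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(p, path) {
  fmt <- function(x) ifelse(is.na(x), "NA",
                            ifelse(is.infinite(x), "Inf", sprintf("%.6f", x)))
  out <- data.frame(protein_id = p$protein_id, resno = p$resno,
                    insert = p$insert, resname = p$resname,
                    PR = fmt(p$PR), rho = fmt(p$rho),
                    flag = ifelse(!p$valid, "chain_break",
                                  ifelse(is.infinite(p$PR), "inf_PR", "")))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Project profiles onto a multiple sequence alignment
#'
#' Maps each protein's per-residue profile values to the columns of a
#' supplied alignment so that profiles of homologous structures can be
#' compared column-by-column.  Each profile's ungapped alignment sequence
#' must match the structure's residue sequence exactly; mismatching positions
#' raise an error listing them.  Gap columns propagate as missing values.
#'
#' @param profiles a `lip_profile` or list of them (distinct `protein_id`s).
#' @param msa named character vector of aligned sequences (one-letter code
#'   with `-` gaps), or a file path readable by [read_alignment()].
#' @return tibble with `column`, `protein_id`, `resid`, `resno`, `aa`, `PR`,
#'   `rho`; class `lip_aligned_profiles`.
#' @export
project_onto_alignment <- function(profiles, msa) {
  if (inherits(profiles, "lip_profile")) profiles <- list(profiles)
  if (is.character(msa) && length(msa) == 1 && file.exists(msa))
    msa <- read_alignment(msa)
  ids <- vapply(profiles, function(p) attr(p, "protein_id"), character(1))
  if (anyDuplicated(ids)) abort("duplicate protein ids in `profiles`")
  missing_ids <- setdiff(ids, names(msa))
  if (length(missing_ids))
    abort(paste0("protein(s) absent from alignment: ",
                 paste(missing_ids, collapse = ", ")))

  purrr::map_dfr(profiles, function(p) {
    id <- attr(p, "protein_id")
    aln <- toupper(msa[[id]])
    cols <- strsplit(aln, "")[[1]]
    ungapped <- which(!cols %in% c("-", "."))
    res <- attr(p, "residues")
    if (length(ungapped) != nrow(res))
      abort(paste0(id, ": alignment has ", length(ungapped),
                   " residues, structure has ", nrow(res)))
    seq3 <- res$resname
    seq1 <- suppressWarnings(bio3d::aa321(seq3))
    seq1[is.na(seq1)] <- "X"
    mism <- which(cols[ungapped] != seq1 & cols[ungapped] != "X" & seq1 != "X")
    if (length(mism))
      abort(paste0(id, ": sequence/structure mismatch at alignment position(s) ",
                   paste(utils::head(ungapped[mism], 10), collapse = ", ")))
    col_of_resid <- rep(NA_integer_, nrow(res))
    col_of_resid[seq_len(nrow(res))] <- ungapped
    out <- tibble(column = seq_along(cols), protein_id = id, aa = cols,
                  resid = NA_integer_, resno = NA_integer_,
                  PR = NA_real_, rho = NA_real_)
    out$resid[ungapped] <- seq_len(nrow(res))
    out$resno[ungapped] <- res$resno
    hit <- match(out$resid, p$resid)
    out$PR <- p$PR[hit]
    out$rho <- p$rho[hit]
    out
  }) -> long
  class(long) <- c("lip_aligned_profiles", class(long))
  long
}

#' Read a multiple sequence alignment
#'
#' @param path FASTA or CLUSTAL alignment file.
#' @param format `"auto"` (sniff the first line), `"fasta"` or `"clustal"`.
#' @return named character vector of aligned sequences.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal"
              else "fasta"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  toupper(as.character(aln))
}
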