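#' Run the full LIP scan on one structure file
#'
#' Convenience pipeline: load, scan, call, write.  Outputs are a profile TSV,
#' LIP intervals as BED (0-based half-open) and TSV (author-numbered
#' inclusive), and a JSON run summary with parameters, the packing cutoff and
#' per-candidate diagnostics.  All outputs are written atomically (temp file
#' then rename) and reruns on identical input are byte-identical.
#'
#' @param path PDB file.
#' @param out_dir output directory (created if needed).
#' @param chain chain identifier (optional for single-chain files).
#' @param L,probe,n_points,eps,mode scan parameters, see [scan_profiles()].
#' @param params LIP-calling parameters, see [lip_params()].
#' @param het_policy heteroatom policy, see [load_structure()].
#' @param protein_id output label; defaults to the file name.
#' @return invisible list with `profile`, `calls` and the output paths.
#' @export
run_scan <- function(path, out_dir = ".", chain = NULL, L = 8L, probe = 1.4,
                     n_points = 960L, eps = 0.1,
                     mode = c("radical", "bisector"), params = lip_params(),
                     het_policy = c("exclude", "environment"),
                     protein_id = NULL) {
  mode <- match.arg(mode)
  het_policy <- match.arg(het_policy)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- load_structure(path, chain = chain, het_policy = het_policy)
  p <- scan_profiles(s, L = L, probe = probe, n_points = n_points, eps = eps,
                     mode = mode, protein_id = protein_id)
  calls <- call_lips(p, params)
  id <- attr(p, "protein_id")

  atomically <- function(write_fn, final) {
    tmp <- paste0(final, ".tmp")
    write_fn(tmp)
    file.rename(tmp, final)
    final
  }
  paths <- list(
    profile = atomically(function(f) write_profile_tsv(p, f),
                         file.path(out_dir, paste0(id, "_profile.tsv"))),
    bed = atomically(function(f) write_lips(calls, bed = f),
                     file.path(out_dir, paste0(id, "_lips.bed"))),
    tsv = atomically(function(f) write_lips(calls, tsv = f),
                     file.path(out_dir, paste0(id, "_lips.tsv"))),
    json = atomically(function(f) write_scan_summary(p, calls, f),
                      file.path(out_dir, paste0(id, "_summary.json")))
  )
  invisible(list(structure = s, profile = p, calls = calls, paths = paths))
}

write_scan_summary <- function(p, calls, path) {
  cut <- attr(calls, "cutoff")
  prm <- attr(calls, "params")
  cand <- attr(calls, "candidates")
  fin <- is.finite(p$PR) & is.finite(p$rho)
  summary <- list(
    protein_id = attr(p, "protein_id"),
    parameters = list(L = attr(p, "L"), probe = attr(p, "probe"),
                      n_points = attr(p, "n_points"), eps = attr(p, "eps"),
                      mode = attr(p, "mode"), theta_peak = prm$theta_peak,
                      theta_base = prm$theta_base, k_sd = prm$k_sd,
                      packing_mode = prm$packing_mode),
    packing = list(mean = cut$mu, sd = cut$sigma, cutoff = cut$cutoff),
    n_positions = nrow(p), n_missing = sum(!p$valid),
    n_inf_PR = sum(is.infinite(p$PR)),
    PR_rho_cor = if (sum(fin) >= 3) stats::cor(p$PR[fin], p$rho[fin])
                 else NA_real_,
    candidates = lapply(seq_len(nrow(cand)), function(k) list(
      start = cand$start[k], end = cand$end[k],
      peaks = cand$peaks[[k]], max_PR = cand$max_PR[k],
      min_rho = cand$min_rho[k], packing_pass = cand$packing_pass[k])),
    lips = lapply(seq_len(nrow(calls)), function(k) list(
      start = calls$start[k], end = calls$end[k]))
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
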