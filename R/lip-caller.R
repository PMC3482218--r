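#' Parameters of the LIP caller
#'
#' Defaults are the published operating point: a candidate interface is
#' organised around at least one position with PR >= 0.8 (more polar than an
#' average protein surface), extends over flanking positions with PR above
#' the 0.5 core baseline, and must be associated with a packing-density
#' minimum below the protein-specific cutoff mean(rho) - 2 SD.
#'
#' @param theta_peak PR peak threshold (default 0.8).
#' @param theta_base PR extension baseline (default 0.5).
#' @param k_sd SD multiplier for the packing cutoff (default 2).
#' @param packing_mode `"wall"` (default): the candidate must overlap a
#'   packing basin, i.e. a maximal run of positions with rho below the
#'   profile mean that contains at least one position below the cutoff;
#'   `"strict"`: the candidate itself must contain a position below the
#'   cutoff.
#' @param min_len minimum candidate length in residues (default 1).
#' @param max_gap largest run of sub-baseline positions bridged when merging
#'   candidate extensions (default 0: only overlapping/adjacent extensions
#'   merge).
#' @return a `lip_params` list.
#' @export
lip_params <- function(theta_peak = 0.8, theta_base = 0.5, k_sd = 2,
                       packing_mode = c("wall", "strict"), min_len = 1L,
                       max_gap = 0L) {
  packing_mode <- match.arg(packing_mode)
  if (!(theta_peak > theta_base && theta_base > 0))
    abort("need theta_peak > theta_base > 0")
  if (k_sd <= 0) abort("k_sd must be positive")
  structure(list(theta_peak = theta_peak, theta_base = theta_base,
                 k_sd = k_sd, packing_mode = packing_mode,
                 min_len = as.integer(min_len), max_gap = as.integer(max_gap)),
            class = "lip_params")
}

#' Protein-specific packing cutoff
#'
#' Mean minus `k_sd` population standard deviations of the non-missing
#' packing-density track.
#'
#' @param p a `lip_profile` (or any tibble with a `rho` column).
#' @param k_sd SD multiplier (default 2).
#' @return list with `mu`, `sigma` (population SD) and `cutoff`.
#' @export
packing_cutoff <- function(p, k_sd = 2) {
  rho <- p$rho[is.finite(p$rho)]
  if (length(rho) < 2) abort("need at least 2 non-missing rho values")
  mu <- mean(rho)
  sigma <- sqrt(mean((rho - mu)^2))
  list(mu = mu, sigma = sigma, cutoff = mu - k_sd * sigma)
}

# maximal runs of TRUE in a logical vector (NA counts FALSE); returns
# two-column matrix of start/end indices
runs_of <- function(x) {
  x <- !is.na(x) & x
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Candidate high-polarity intervals of a profile
#'
#' Seeds are positions with PR at or above `theta_peak` (`Inf` sentinels
#' count); each seed is extended maximally left and right over positions with
#' PR above `theta_base`.  Missing positions terminate extension.
#' Overlapping or bookended extensions merge; `max_gap > 0` additionally
#' bridges short sub-baseline gaps between extensions.
#'
#' @param p a `lip_profile`.
#' @param params a [lip_params()] list.
#' @return tibble of candidates: `start`/`end` (author numbering, inclusive),
#'   `start_resid`/`end_resid`, `peaks` (list of author-numbered peak
#'   positions), `max_PR`, `n_pos`.
#' @export
find_polar_peaks <- function(p, params = lip_params()) {
  stopifnot(nrow(p) > 0)
  pr <- p$PR
  seed <- !is.na(pr) & pr >= params$theta_peak
  above <- !is.na(pr) & pr > params$theta_base
  if (!any(seed)) return(empty_candidates())

  ext <- runs_of(above)
  keep <- apply(ext, 1, function(r) any(seed[r[1]:r[2]]))
  ext <- ext[keep, , drop = FALSE]

  if (params$max_gap > 0 && nrow(ext) > 1) {
    merged <- list(ext[1, ])
    for (k in 2:nrow(ext)) {
      prev <- merged[[length(merged)]]
      if (ext[k, 1] - prev[2] - 1 <= params$max_gap)
        merged[[length(merged)]] <- c(prev[1], ext[k, 2])
      else merged[[length(merged) + 1]] <- ext[k, ]
    }
    ext <- do.call(rbind, merged)
    colnames(ext) <- c("start", "end")
  }

  out <- purrr::map_dfr(seq_len(nrow(ext)), function(k) {
    i <- ext[k, 1]:ext[k, 2]
    tibble(start = p$resno[ext[k, 1]], end = p$resno[ext[k, 2]],
           start_resid = p$resid[ext[k, 1]], end_resid = p$resid[ext[k, 2]],
           peaks = list(p$resno[i][seed[i]]),
           max_PR = max(pr[i][is.finite(pr[i])],
                        if (any(is.infinite(pr[i]))) Inf else -Inf),
           n_pos = length(i))
  })
  out[out$n_pos >= params$min_len, , drop = FALSE]
}

empty_candidates <- function() {
  tibble(start = integer(), end = integer(), start_resid = integer(),
         end_resid = integer(), peaks = list(), max_PR = numeric(),
         n_pos = integer())
}

#' Call LIPs on a profile
#'
#' Applies the full quantitative definition: candidate high-polarity
#' intervals from [find_polar_peaks()] are tested for association with a
#' packing-density minimum.  In `"strict"` mode the candidate itself must
#' contain a position with rho below the cutoff (profile mean minus
#' `k_sd` SD); in `"wall"` mode (default) it suffices that the candidate
#' overlaps a basin — a maximal run of below-mean rho containing at least one
#' below-cutoff position — which also admits interfaces sitting on the wall
#' of a deep minimum.  Candidates failing the packing test are retained in
#' the `candidates` attribute with `packing_pass = FALSE` but excluded from
#' the returned list.
#'
#' @param p a `lip_profile` with both PR and rho tracks.
#' @param params a [lip_params()] list.
#' @return a `lip_calls` tibble of LIPs sorted by start (author numbering,
#'   inclusive), with `peak_positions`, `max_PR`, `min_rho`, `packing_pass`
#'   columns; attributes `cutoff` (from [packing_cutoff()]), `params` and
#'   `candidates` (all candidates with pass flags).
#' @export
call_lips <- function(p, params = lip_params()) {
  cand <- find_polar_peaks(p, params)
  cut <- packing_cutoff(p, params$k_sd)
  rho <- p$rho

  if (nrow(cand)) {
    below_cut <- !is.na(rho) & rho < cut$cutoff
    below_mu <- !is.na(rho) & rho < cut$mu
    basins <- runs_of(below_mu)
    if (nrow(basins)) {
      deep <- apply(basins, 1, function(r) any(below_cut[r[1]:r[2]]))
      basins <- basins[deep, , drop = FALSE]
    }
    pass <- logical(nrow(cand))
    min_rho <- numeric(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- match(cand$start_resid[k], p$resid):match(cand$end_resid[k], p$resid)
      rr <- rho[i][is.finite(rho[i])]
      min_rho[k] <- if (length(rr)) min(rr) else NA_real_
      pass[k] <- if (params$packing_mode == "strict") {
        any(below_cut[i])
      } else {
        nrow(basins) > 0 &&
          any(basins[, 1] <= max(i) & basins[, 2] >= min(i))
      }
    }
    cand$min_rho <- min_rho
    cand$packing_pass <- pass
  } else {
    cand$min_rho <- numeric(0)
    cand$packing_pass <- logical(0)
  }

  out <- cand[cand$packing_pass, , drop = FALSE]
  out <- dplyr::arrange(out, .data$start)
  out <- dplyr::rename(out, peak_positions = "peaks")
  structure(out, class = c("lip_calls", class(out)),
            cutoff = cut, params = params, candidates = cand,
            protein_id = attr(p, "protein_id"))
}

#' Write LIP calls to BED and TSV
#'
#' The BED file uses 0-based half-open residue coordinates with
#' `score = round(100 * max_PR)` (capped at 1000 for infinite PR); the TSV
#' keeps author-numbered inclusive intervals plus diagnostics.
#'
#' @param calls a `lip_calls` tibble.
#' @param bed,tsv output paths (either may be `NULL` to skip).
#' @return invisible list of written paths.
#' @export
write_lips <- function(calls, bed = NULL, tsv = NULL) {
  id <- attr(calls, "protein_id") %||% "protein"
  if (!is.null(bed)) {
    score <- ifelse(is.finite(calls$max_PR),
                    pmin(1000, round(100 * calls$max_PR)), 1000)
    bed_df <- data.frame(chrom = rep(id, nrow(calls)),
                         start = calls$start - 1L,
                         end = calls$end, name = rep(id, nrow(calls)),
                         score = score,
                         strand = rep(".", nrow(calls)))
    write.table(bed_df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv)) {
    df <- data.frame(protein_id = rep(id, nrow(calls)),
                     start = calls$start, end = calls$end,
                     peaks = vapply(calls$peak_positions, paste,
                                    character(1), collapse = ","),
                     max_PR = sprintf("%.4f", calls$max_PR),
                     min_rho = sprintf("%.4f", calls$min_rho),
                     packing_mode = rep(attr(calls, "params")$packing_mode,
                                        nrow(calls)))
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(bed = bed, tsv = tsv))
}
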