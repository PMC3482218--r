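#' Plot a polarity/packing profile
#'
#' Two stacked tracks: the polarity ratio with the 0.8 peak threshold and
#' 0.5 baseline, and the packing density with its mean and mean - k_sd * SD
#' cutoff.  If `calls` is supplied, LIP intervals are shaded.
#'
#' @param object a `lip_profile`.
#' @param calls optional `lip_calls` for the same protein.
#' @param params a [lip_params()] list (thresholds drawn on the PR panel).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lip_profile <- function(object, calls = NULL, params = lip_params(),
                                 ...) {
  cut <- tryCatch(packing_cutoff(object, params$k_sd), error = function(e) NULL)
  long <- tidyr::pivot_longer(
    dplyr::mutate(object, PR = ifelse(is.infinite(.data$PR), NA, .data$PR)),
    c("PR", "rho"), names_to = "track", values_to = "value")
  long$track <- factor(long$track, c("PR", "rho"),
                       c("polarity ratio", "packing density"))
  hl <- tibble(track = factor(rep(c("polarity ratio", "packing density"),
                                  c(2, 2)),
                              levels = levels(long$track)),
               y = c(params$theta_peak, params$theta_base,
                     if (is.null(cut)) c(NA, NA) else c(cut$mu, cut$cutoff)))
  g <- ggplot2::ggplot(long, ggplot2::aes(x = .data$resno, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(data = hl, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey50", na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track), scales = "free_y") +
    ggplot2::labs(x = "residue (author numbering)", y = NULL,
                  title = attr(object, "protein_id")) +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    shade <- tibble(xmin = calls$start - 0.5, xmax = calls$end + 0.5)
    g <- g + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE)
  }
  g
}

#' Plot profiles projected on an alignment
#'
#' @param object a `lip_aligned_profiles` tibble.
#' @param track `"PR"` or `"rho"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lip_aligned_profiles <- function(object, track = c("PR", "rho"),
                                          ...) {
  track <- match.arg(track)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$column, y = .data[[track]],
                               colour = .data$protein_id)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "alignment column", y = track, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
tidy.lip_calls <- function(x, ...) {
  tibble(protein_id = attr(x, "protein_id") %||% NA_character_,
         start = x$start, end = x$end,
         n_pos = x$n_pos,
         peaks = vapply(x$peak_positions, paste, character(1), collapse = ","),
         max_PR = x$max_PR, min_rho = x$min_rho,
         packing_pass = x$packing_pass)
}

#' @export
glance.lip_calls <- function(x, ...) {
  cut <- attr(x, "cutoff")
  cand <- attr(x, "candidates")
  tibble(n_lips = nrow(x), n_candidates = nrow(cand),
         rho_mean = cut$mu, rho_sd = cut$sigma, rho_cutoff = cut$cutoff,
         packing_mode = attr(x, "params")$packing_mode)
}

#' @export
glance.lip_profile <- function(x, ...) {
  fin <- is.finite(x$PR) & is.finite(x$rho)
  cut <- tryCatch(packing_cutoff(x, 2), error = function(e)
    list(mu = NA_real_, sigma = NA_real_, cutoff = NA_real_))
  tibble(protein_id = attr(x, "protein_id"), n_positions = nrow(x),
         n_missing = sum(!x$valid), n_inf_PR = sum(is.infinite(x$PR)),
         PR_mean = mean(x$PR[is.finite(x$PR)]),
         rho_mean = cut$mu, rho_sd = cut$sigma, rho_cutoff = cut$cutoff,
         PR_rho_cor = if (sum(fin) >= 3 && stats::sd(x$PR[fin]) > 0 &&
                          stats::sd(x$rho[fin]) > 0)
           stats::cor(x$PR[fin], x$rho[fin]) else NA_real_)
}
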