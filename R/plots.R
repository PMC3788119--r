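# ggplot2 displays: Woods plots of per-peptide differences, kinetics time
# courses, and per-residue burial profiles.

#' Woods plot of differential protection
#'
#' Each peptide is a horizontal bar spanning its residue range at height
#' `delta` (reference minus test fraction of exchange; positive = more
#' protected in the test state), with `sigma_multiplier * sigma` error
#' bars; significant peptides are coloured. Values are shown as computed;
#' out-of-range fractions are never clipped for statistics, only here for
#' display when `clip` is set.
#'
#' @param calls Differential call tibble from [differential_calls()] or an
#'   `hdx_screen`.
#' @param time_s Time point to display (default: earliest).
#' @param sigma_multiplier Error-bar multiplier (default 2).
#' @param clip Optional `c(lo, hi)` y-limits for display only.
#' @return A ggplot object.
#' @export
plot_woods <- function(calls, time_s = NULL, sigma_multiplier = 2, clip = NULL) {
  if (inherits(calls, "hdx_screen")) calls <- calls$calls
  if (is.null(time_s)) time_s <- min(calls$time_s)
  dat <- filter(calls, .data$time_s == .env$time_s)
  p <- ggplot2::ggplot(dat, ggplot2::aes(y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   yend = .data$delta, colour = .data$significant),
      linewidth = 1.6
    ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(x = (.data$start + .data$end) / 2,
                   ymin = .data$delta - sigma_multiplier * .data$sigma,
                   ymax = .data$delta + sigma_multiplier * .data$sigma,
                   colour = .data$significant),
      width = 0, linewidth = 0.4
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "residue position", y = expression(Delta * f),
                  colour = "significant",
                  title = paste0("Differential protection at ", time_s, " s")) +
    ggplot2::theme_minimal()
  if (!is.null(clip)) p <- p + ggplot2::coord_cartesian(ylim = clip)
  p
}

#' @rdname plot_woods
#' @param object An `hdx_screen`.
#' @param ... Passed to [plot_woods()].
#' @method autoplot hdx_screen
#' @export
autoplot.hdx_screen <- function(object, ...) plot_woods(object, ...)

#' Exchange kinetics time courses
#'
#' Mean fraction of exchange versus time on a logarithmic timescale, one
#' facet per peptide, coloured by state, with SD error bars.
#'
#' @param fractions Fraction table from [exchange_fractions()].
#' @param peptides Optional peptide sequences to display.
#' @param charge Optional charge state selection.
#' @return A ggplot object.
#' @export
plot_kinetics <- function(fractions, peptides = NULL, charge = NULL) {
  dat <- fractions
  if (!is.null(peptides)) dat <- filter(dat, .data$peptide_sequence %in% .env$peptides)
  if (!is.null(charge)) dat <- filter(dat, .data$charge %in% .env$charge)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s, y = .data$f,
                                    colour = .data$state, group = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$f - .data$sd,
                                        ymax = .data$f + .data$sd), width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~ .data$peptide_sequence + .data$charge) +
    ggplot2::labs(x = "exchange time (s, log scale)", y = "fraction of exchange") +
    ggplot2::theme_minimal()
}

#' @rdname buried_surface
#' @param object A `burial_profile`.
#' @method autoplot burial_profile
#' @export
autoplot.burial_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$resno, y = .data$delta_sasa,
                               fill = .data$hydrophobic)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$chain, ncol = 1) +
    ggplot2::labs(x = "residue", y = expression(Delta * SASA ~ (ring(A)^2)),
                  fill = "hydrophobic") +
    ggplot2::theme_minimal()
}
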