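#' Plot a conformational landscape
#'
#' Scatter of the 2-D embedding, coloured by cluster (noise in grey) and
#' shaped by provenance source when available.
#'
#' @param object A `landscape_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot landscape_result
#' @export
autoplot.landscape_result <- function(object, ...) {
  pts <- object$points |>
    dplyr::mutate(cluster = factor(ifelse(.data$cluster < 0, "noise", .data$cluster)))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$cluster))
  if ("source" %in% names(pts)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$source), size = 1.5)
  } else {
    p <- p + ggplot2::geom_point(size = 1.5)
  }
  p + ggplot2::labs(x = "embedding 1", y = "embedding 2") +
    ggplot2::theme_minimal()
}

#' Plot a preferential-solvation profile
#'
#' Per-shell THF/water enhancement over the bulk composition as a step
#' profile; the dashed line marks no preference.
#'
#' @param profile Tibble from [solvation_profile()].
#' @return A ggplot object.
#' @export
plot_solvation_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(
    x = (.data$bin_left + .data$bin_right) / 2, y = .data$enhancement)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "distance from peptoid surface (Å)",
                  y = "THF/water enhancement") +
    ggplot2::theme_minimal()
}

#' Plot an assembly-energy profile
#'
#' Assembly energy per structure class, one line per solvent condition.
#'
#' @param profile Tibble from [assembly_profile()].
#' @return A ggplot object.
#' @export
plot_assembly_profile <- function(profile) {
  profile <- dplyr::mutate(profile, label = factor(.data$label, levels = unique(.data$label)))
  ggplot2::ggplot(profile, ggplot2::aes(
    x = .data$label, y = .data$assembly_energy,
    colour = .data$solvent_label, group = .data$solvent_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "structure class", y = "assembly energy (kJ/mol)") +
    ggplot2::theme_minimal()
}

#' Plot RMSD histograms per solvent
#'
#' @param hist Tibble from [rmsd_histogram()].
#' @return A ggplot object.
#' @export
plot_rmsd_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(
    x = (.data$bin_left + .data$bin_right) / 2, y = .data$density,
    fill = .data$solvent_label)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6,
                      width = hist$bin_right[1] - hist$bin_left[1]) +
    ggplot2::labs(x = "RMSD to reference (Å)", y = "density") +
    ggplot2::theme_minimal()
}
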