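# Standalone plot helpers for tabular results.

#' CSP-per-residue bar plot with threshold line
#'
#' @param profile CSP profile from [compute_csp()].
#' @param threshold Threshold (ppm) drawn as a dashed line and used to
#'   highlight mapped residues.
#' @return A ggplot object.
#' @export
plot_csp_profile <- function(profile, threshold = 0.3) {
  dat <- filter(profile, !.data$missing)
  ggplot2::ggplot(dat, ggplot2::aes(.data$residue, .data$csp,
                                    fill = .data$csp > threshold)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "magenta3")) +
    ggplot2::labs(x = "residue", y = "Δδ(H,N) [ppm]",
                  title = "Chemical shift perturbation per residue") +
    ggplot2::theme_minimal()
}

#' Per-model RMSD bar plot for an ensemble
#'
#' @param rmsd Result of [ensemble_rmsd()].
#' @return A ggplot object.
#' @export
plot_ensemble_rmsd <- function(rmsd) {
  per <- attr(rmsd, "per_model")
  ggplot2::ggplot(per, ggplot2::aes(factor(.data$model),
                                    .data$rmsd_to_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = rmsd$to_mean, linetype = "dashed") +
    ggplot2::labs(x = "model", y = "RMSD to mean [Å]",
                  title = sprintf("Ensemble spread: to-mean %.2f Å, pairwise %.2f Å",
                                  rmsd$to_mean, rmsd$pairwise)) +
    ggplot2::theme_minimal()
}
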