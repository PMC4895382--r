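# Helix axis fitting by principal component analysis.

#' Fit a helix axis to a residue range of one ensemble model
#'
#' The axis is the largest-variance principal direction of the selected atom
#' coordinates, sign-oriented from the centroid of the N-terminal half of
#' the range toward the centroid of the C-terminal half, so reversing atom
#' order cannot flip it. `rmsd_to_axis` is the root-mean-square distance of
#' the atoms to the fitted line, a quality measure of the helix idealisation.
#'
#' @param model_atoms Atom tibble of a single model.
#' @param resno Integer residue range of the helix (length >= 5 residues).
#' @param atoms Atom class used for the fit (default `"CA"`).
#' @param chain Optional chain restriction.
#' @return A `helix_segment` list: `axis` (unit 3-vector, N->C), `centroid`,
#'   `resno`, `rmsd_to_axis`.
#' @export
fit_helix_axis <- function(model_atoms, resno, atoms = "CA", chain = NULL) {
  if (length(unique(resno)) < 5) {
    stop_input("helix range must span at least 5 residues")
  }
  if (length(unique(model_atoms$model)) != 1) {
    stop_input("fit_helix_axis expects a single model")
  }
  sel <- select_atoms(model_atoms, residue_selection(resno, chain, atoms))
  co <- as.matrix(sel[, c("x", "y", "z")])
  centroid <- colMeans(co)
  cc <- sweep(co, 2, centroid)
  ax <- svd(cc, nu = 0, nv = 1)$v[, 1]
  # orient from N-terminal-half centroid toward C-terminal-half centroid
  ord <- order(sel$resno)
  half <- floor(length(ord) / 2)
  dir_nc <- colMeans(co[ord[(length(ord) - half + 1):length(ord)], , drop = FALSE]) -
    colMeans(co[ord[seq_len(half)], , drop = FALSE])
  if (sum(ax * dir_nc) < 0) ax <- -ax
  proj <- cc %*% ax
  # residual vector form avoids the cancellation of rowSums(cc^2) - proj^2
  perp2 <- rowSums((cc - proj %*% t(ax))^2)
  structure(list(axis = as.numeric(ax), centroid = as.numeric(centroid),
                 resno = range(resno),
                 rmsd_to_axis = sqrt(mean(pmax(perp2, 0)))),
            class = "helix_segment")
}

#' @export
print.helix_segment <- function(x, ...) {
  cat(sprintf("helix %d-%d: axis (%.3f, %.3f, %.3f), rmsd to axis %.2f A\n",
              x$resno[1], x$resno[2], x$axis[1], x$axis[2], x$axis[3],
              x$rmsd_to_axis))
  invisible(x)
}
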