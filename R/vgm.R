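# Vector-geometry interhelical angles (theta, phi) for EF hands.
#
# Each EF hand is reduced to its entering helix axis, exiting helix axis
# and the CA position of the first loop residue. A loop-anchored local
# frame replaces an external reference structure: z is the entering-helix
# axis (N->C) and x is the component of (loop anchor - entering centroid)
# orthogonal to z, so the frame is intrinsic to the hand and the angles are
# invariant under any global rigid transform. theta (polar angle of the
# exiting axis from z) measures the degree of opening; phi (azimuth in the
# x-y plane, counterclockwise from +x viewed from +z) measures the
# horizontal swing.

#' EF-hand geometry: two helix segments plus the loop anchor
#'
#' @param entering,exiting `helix_segment` objects ([fit_helix_axis()]);
#'   entering must precede exiting in sequence, ranges non-overlapping.
#' @param loop_anchor Numeric xyz of the first loop residue's CA.
#' @return An `ef_geometry` list.
#' @export
ef_geometry <- function(entering, exiting, loop_anchor) {
  stopifnot(inherits(entering, "helix_segment"),
            inherits(exiting, "helix_segment"))
  if (entering$resno[2] >= exiting$resno[1]) {
    stop_input("entering helix must precede the exiting helix; ranges must not overlap")
  }
  structure(list(entering = entering, exiting = exiting,
                 loop_anchor = as.numeric(loop_anchor)),
            class = "ef_geometry")
}

#' Loop-anchored orthonormal frame of an EF hand
#'
#' @param geometry An [ef_geometry()].
#' @return A 3x3 matrix with columns x, y, z; right-handed, orthonormal to
#'   1e-12.
#' @export
local_frame <- function(geometry) {
  z <- unit(geometry$entering$axis)
  v <- geometry$loop_anchor - geometry$entering$centroid
  x <- v - sum(v * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-8 * max(sqrt(sum(v^2)), 1e-8) || nx < 1e-10) {
    abort("loop anchor lies on the entering-helix axis: frame is degenerate",
          class = "efbind_degenerate_frame")
  }
  x <- x / nx
  y <- cross3(z, x)
  F <- cbind(x = x, y = y, z = z)
  if (max(abs(crossprod(F) - diag(3))) > 1e-12) {
    F[, "y"] <- unit(F[, "y"]) # guard against accumulated rounding
  }
  F
}

#' Interhelical angles of an EF hand
#'
#' @param geometry An [ef_geometry()].
#' @return One-row tibble: `theta` (degrees, in \[0, 180\]), `phi` (degrees,
#'   in (-180, 180\]; reported as 0 with `degenerate = TRUE` when the axes
#'   are (anti)parallel and the azimuth is undefined).
#' @export
vgm_angles <- function(geometry) {
  F <- local_frame(geometry)
  e <- unit(geometry$exiting$axis)
  ez <- sum(e * F[, "z"])
  theta <- acos(pmin(pmax(ez, -1), 1)) * DEG
  s2 <- sum((e - ez * F[, "z"])^2)
  if (s2 < 1e-24) {
    return(tibble(theta = theta, phi = 0, degenerate = TRUE))
  }
  phi <- atan2(sum(e * F[, "y"]), sum(e * F[, "x"])) * DEG
  tibble(theta = theta, phi = phi, degenerate = FALSE)
}

#' EF-hand helix definitions for ensemble angle analysis
#'
#' @param hand Hand label (e.g. `"EF1"`).
#' @param entering,exiting Integer residue ranges of the entering and
#'   exiting helices (author numbering).
#' @param anchor Residue number of the first loop residue (its CA is the
#'   frame anchor).
#' @param chain Optional chain.
#' @return A one-row tibble; rows from several calls can be bound into a
#'   definition table for [ensemble_vgm()].
#' @export
hand_definition <- function(hand, entering, exiting, anchor, chain = NULL) {
  tibble(hand = hand, entering = list(as.integer(entering)),
         exiting = list(as.integer(exiting)), anchor = as.integer(anchor),
         chain = chain %||% NA_character_)
}

#' Per-model interhelical angles of EF hands across an ensemble
#'
#' Fits helix axes in every model, builds the loop-anchored frame and
#' reports per-model (theta, phi) plus the arithmetic mean of theta and
#' circular mean / circular SD of phi per hand. Models in which the frame
#' is degenerate are excluded and counted.
#'
#' @param atoms Ensemble tibble.
#' @param hands Definition table (rows from [hand_definition()]).
#' @param atom_class Atom class for axis fitting (default `"CA"`).
#' @return A `vgm_result`: list with `angles` (hand, model, theta, phi) and
#'   `summary` (hand, mean_theta, sd_theta, mean_phi, circ_sd_phi,
#'   n_models, n_excluded). Supports [tidy()] and [autoplot()].
#' @export
ensemble_vgm <- function(atoms, hands, atom_class = "CA") {
  models <- sort(unique(atoms$model))
  angles <- pmap(hands, function(hand, entering, exiting, anchor, chain) {
    ch <- if (is.na(chain)) NULL else chain
    map(models, function(m) {
      ma <- filter(atoms, .data$model == m)
      res <- tryCatch({
        ent <- fit_helix_axis(ma, entering, atoms = atom_class, chain = ch)
        ext <- fit_helix_axis(ma, exiting, atoms = atom_class, chain = ch)
        anc <- filter(ma, .data$resno == anchor, .data$atom == "CA")
        if (!is.null(ch)) anc <- filter(anc, .data$chain %in% ch)
        if (nrow(anc) != 1) stop_input("anchor CA not found (or ambiguous)")
        g <- ef_geometry(ent, ext, as.numeric(anc[1, c("x", "y", "z")]))
        mutate(vgm_angles(g), hand = hand, model = m, excluded = FALSE)
      }, efbind_degenerate_frame = function(e) {
        tibble(theta = NA_real_, phi = NA_real_, degenerate = TRUE,
               hand = hand, model = m, excluded = TRUE)
      })
      res
    }) |> list_rbind()
  }) |> list_rbind()

  summary <- angles |>
    group_by(.data$hand) |>
    summarise(
      mean_theta = mean(.data$theta[!.data$excluded]),
      sd_theta = sd(.data$theta[!.data$excluded]),
      mean_phi = circ_mean(.data$phi[!.data$excluded]),
      circ_sd_phi = circ_sd(.data$phi[!.data$excluded]),
      n_models = sum(!.data$excluded),
      n_excluded = sum(.data$excluded)
    )
  structure(list(angles = select(angles, "hand", "model", "theta", "phi",
                                 "degenerate", "excluded"),
                 summary = summary),
            class = "vgm_result")
}

#' @export
print.vgm_result <- function(x, ...) {
  cat("Interhelical angle analysis (loop-anchored frame)\n")
  print(x$summary, ...)
  invisible(x)
}

#' @rdname ensemble_vgm
#' @param x,object A `vgm_result`.
#' @param ... Unused.
#' @export
tidy.vgm_result <- function(x, ...) x$angles

#' @rdname ensemble_vgm
#' @export
glance.vgm_result <- function(x, ...) x$summary

#' @rdname ensemble_vgm
#' @export
autoplot.vgm_result <- function(object, ...) {
  ggplot2::ggplot(object$angles,
                  ggplot2::aes(.data$phi, .data$theta, colour = .data$hand)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = expression(phi ~ "[deg]"), y = expression(theta ~ "[deg]"),
                  title = "Per-model interhelical angles") +
    ggplot2::theme_minimal()
}

#' Angle changes between two states (holo minus apo)
#'
#' @param apo,holo `vgm_result` objects computed with identical hand
#'   definitions.
#' @return A tibble per hand: `delta_theta = mean_theta_holo -
#'   mean_theta_apo` and `delta_phi`, the circular difference of mean phi
#'   wrapped to (-180, 180\].
#' @export
compare_states <- function(apo, holo) {
  if (!setequal(apo$summary$hand, holo$summary$hand)) {
    stop_input("apo and holo results cover different EF-hand sets")
  }
  inner_join(
    select(apo$summary, "hand", apo_theta = "mean_theta", apo_phi = "mean_phi"),
    select(holo$summary, "hand", holo_theta = "mean_theta", holo_phi = "mean_phi"),
    by = "hand"
  ) |>
    mutate(delta_theta = .data$holo_theta - .data$apo_theta,
           delta_phi = wrap_angle(.data$holo_phi - .data$apo_phi))
}
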