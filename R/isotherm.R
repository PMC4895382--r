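# Exact 1:1 binding isotherm.
#
# For P + L <-> PL with Kd = [P][L]/[PL], mass balance over total
# concentrations P0 and L0 gives the quadratic root
#   [PL] = ((P0 + L0 + Kd) - sqrt((P0 + L0 + Kd)^2 - 4 P0 L0)) / 2
# and the observed fast-exchange shift change is delta_max * [PL]/P0.

#' Bound-complex concentration for 1:1 binding
#'
#' @param P0,L0 Total protein and ligand concentrations (molar). Vectorised.
#' @param Kd Dissociation constant (molar).
#' @return `[PL]` at equilibrium (molar).
#' @export
bound_complex <- function(P0, L0, Kd) {
  if (any(P0 < 0) || any(L0 < 0)) stop_input("concentrations must be non-negative")
  if (any(Kd <= 0)) stop_input("Kd must be positive")
  s <- P0 + L0 + Kd
  disc <- pmax(s^2 - 4 * P0 * L0, 0)
  # conjugate form of the smaller quadratic root: algebraically equal to
  # (s - sqrt(disc))/2 but immune to cancellation when Kd dominates
  ifelse(s > 0, 2 * P0 * L0 / (s + sqrt(disc)), 0)
}

#' Observed shift change from the exact 1:1 isotherm
#'
#' Fast-exchange weighted-average model: the observed chemical shift
#' perturbation is the saturation value `delta_max` scaled by the bound
#' fraction `[PL]/P0`, with `[PL]` from the quadratic mass-balance root.
#'
#' @inheritParams bound_complex
#' @param delta_max Limiting shift change at saturation (ppm).
#' @return Predicted observed shift change (ppm); `0` at `L0 = 0`, strictly
#'   below `delta_max` for finite `L0`, tending to `delta_max` as
#'   `L0 -> Inf`.
#' @export
#' @examples
#' isotherm_1to1(P0 = 1, L0 = 1, Kd = 1, delta_max = 1) # (3 - sqrt(5))/2
isotherm_1to1 <- function(P0, L0, Kd, delta_max) {
  if (any(P0 <= 0)) stop_input("P0 must be positive")
  delta_max * bound_complex(P0, L0, Kd) / P0
}
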