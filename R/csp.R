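# Chemical shift perturbation (CSP) computation and binding-site mapping.

#' Combined amide chemical shift perturbation between two states
#'
#' For each residue present in both states the combined perturbation is
#' \deqn{\Delta\delta(H,N) = \sqrt{\Delta\delta_H^2 + (w\,\Delta\delta_N)^2}}
#' where `w` is the nitrogen scaling weight accounting for the wider 15N
#' shift range. Residues missing from either state (broadened peaks) are
#' flagged `missing`, never imputed as zero.
#'
#' @param reference,state Peak tables with columns `residue`, `dH_ppm`,
#'   `dN_ppm` and optionally `present` (logical; default `TRUE`).
#' @param nitrogen_weight Scaling weight `w` for the 15N dimension
#'   (default 0.2, the common amide scaling); recorded in the output.
#' @return A tibble with `residue`, `d_dH`, `d_dN`, `csp`, `missing`, plus a
#'   `nitrogen_weight` attribute. `csp` is `NA` for missing residues.
#' @export
#' @examples
#' ref <- tibble::tibble(residue = 1:2, dH_ppm = c(8.1, 7.9),
#'                       dN_ppm = c(120, 118))
#' bound <- tibble::tibble(residue = 1:2, dH_ppm = c(8.16, 7.9),
#'                         dN_ppm = c(120.4, 118))
#' compute_csp(ref, bound)
compute_csp <- function(reference, state, nitrogen_weight = 0.2) {
  if (nitrogen_weight <= 0) stop_input("nitrogen_weight must be positive")
  reference <- normalise_peaks(reference)
  state <- normalise_peaks(state)
  common <- intersect(reference$residue, state$residue)
  if (length(common) == 0) stop_input("no common residues between states")
  all_res <- sort(union(reference$residue, state$residue))
  out <- tibble(residue = all_res) |>
    left_join(rename(reference, rH = "dH_ppm", rN = "dN_ppm",
                     rpres = "present"), by = "residue") |>
    left_join(rename(state, sH = "dH_ppm", sN = "dN_ppm",
                     spres = "present"), by = "residue") |>
    mutate(
      missing = is.na(.data$rpres) | is.na(.data$spres) |
        !.data$rpres | !.data$spres,
      d_dH = ifelse(.data$missing, NA_real_, .data$sH - .data$rH),
      d_dN = ifelse(.data$missing, NA_real_, .data$sN - .data$rN),
      csp = sqrt(.data$d_dH^2 + (nitrogen_weight * .data$d_dN)^2)
    ) |>
    select("residue", "d_dH", "d_dN", "csp", "missing")
  attr(out, "nitrogen_weight") <- nitrogen_weight
  out
}

normalise_peaks <- function(peaks) {
  need <- c("residue", "dH_ppm", "dN_ppm")
  if (!all(need %in% names(peaks))) {
    stop_input("peak table needs columns residue, dH_ppm, dN_ppm")
  }
  peaks <- as_tibble(peaks)
  if (!"present" %in% names(peaks)) peaks$present <- TRUE
  if (any(peaks$present & (!is.finite(peaks$dH_ppm) | !is.finite(peaks$dN_ppm)))) {
    stop_input("non-finite shifts on peaks marked present")
  }
  select(peaks, "residue", "dH_ppm", "dN_ppm", "present")
}

#' Per-point CSP trajectory across a titration series
#'
#' Computes [compute_csp()] of every titration point against the ligand-free
#' first point, returning a long table suitable for fitting and plotting.
#'
#' @param series Long titration table (see [titration_series()]).
#' @inheritParams compute_csp
#' @return A long tibble: `point`, `ligand_total`, `protein_total`,
#'   `equivalents`, `residue`, `csp`, `missing`.
#' @export
csp_series <- function(series, nitrogen_weight = 0.2) {
  series <- validate_titration(series)
  ref <- filter(series, .data$point == min(series$point))
  pts <- distinct(series, .data$point, .data$ligand_total,
                  .data$protein_total, .data$equivalents)
  map(pts$point, function(p) {
    st <- filter(series, .data$point == p)
    prof <- compute_csp(select(ref, "residue", "dH_ppm", "dN_ppm", "present"),
                        select(st, "residue", "dH_ppm", "dN_ppm", "present"),
                        nitrogen_weight)
    mutate(prof, point = p, .before = 1)
  }) |>
    list_rbind() |>
    left_join(pts, by = "point") |>
    select("point", "ligand_total", "protein_total", "equivalents",
           "residue", "csp", "missing")
}

#' Map the binding site by CSP threshold
#'
#' Returns the residues whose combined perturbation at the (saturating)
#' end-point exceeds a threshold — the criterion used to colour perturbed
#' residues on the structure and to select residues for Kd fitting.
#'
#' @param profile CSP profile from [compute_csp()] at the end point.
#' @param threshold Threshold in ppm (default 0.3).
#' @return Sorted integer vector of residue numbers with `csp > threshold`.
#' @export
map_binding_site <- function(profile, threshold = 0.3) {
  sort(profile$residue[!is.na(profile$csp) & profile$csp > threshold])
}
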