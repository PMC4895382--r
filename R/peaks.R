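# Peak tracking across titration points for unassigned peak lists.
#
# Links peaks between consecutive titration points by greedy
# nearest-neighbour matching in weighted shift space (dH, w*dN). A track
# whose best candidate lies further than `max_step` is marked absent at that
# point; its predicted position keeps extrapolating so a peak broadened out
# at intermediate points can be re-linked when it reappears.

#' Resolve residue correspondence across a titration by peak tracking
#'
#' If every peak already carries a residue assignment the series is returned
#' unchanged. Otherwise the assigned reference point (first point) seeds one
#' track per residue; tracks are extended point-by-point by greedy
#' nearest-neighbour linking in `(dH, w*dN)` space, with linear extrapolation
#' of each track's position from its last two observations.
#'
#' @param series Long titration tibble; unassigned peaks have `residue = NA`.
#' @param max_step Maximum allowed weighted shift distance (ppm) between a
#'   track's predicted position and a candidate peak.
#' @param nitrogen_weight 15N weight of the distance metric.
#' @return The series with `residue` filled in where linking succeeded;
#'   unlinked peaks are dropped and broken tracks marked absent
#'   (`present = FALSE`) at the affected points.
#' @export
track_peaks <- function(series, max_step = 0.1, nitrogen_weight = 0.2) {
  if (max_step <= 0) stop_input("max_step must be positive")
  series <- validate_titration(series)
  if (!anyNA(series$residue)) return(series)

  pts <- sort(unique(series$point))
  ref <- filter(series, .data$point == pts[1])
  if (anyNA(ref$residue)) {
    stop_input("reference (first) point must be fully assigned to seed tracks")
  }
  w <- nitrogen_weight

  # track state: per residue, last two observed positions
  tracks <- ref |>
    mutate(uH = .data$dH_ppm, uN = .data$dN_ppm,   # last observed
           pH = .data$dH_ppm, pN = .data$dN_ppm) |> # one before last
    select("residue", "uH", "uN", "pH", "pN")

  out <- list(mutate(ref, present = TRUE))
  for (p in pts[-1]) {
    obs <- filter(series, .data$point == p, .data$present)
    pred <- mutate(tracks,
                   eH = .data$uH + (.data$uH - .data$pH),
                   eN = .data$uN + (.data$uN - .data$pN))
    dmat <- outer(seq_len(nrow(pred)), seq_len(nrow(obs)),
                  function(i, j) sqrt((pred$eH[i] - obs$dH_ppm[j])^2 +
                                      (w * (pred$eN[i] - obs$dN_ppm[j]))^2))
    assign_track <- rep(NA_integer_, nrow(pred)) # obs index per track
    free_obs <- rep(TRUE, nrow(obs))
    repeat {
      dmat_masked <- dmat
      dmat_masked[!is.na(assign_track), ] <- Inf
      dmat_masked[, !free_obs] <- Inf
      m <- which(dmat_masked == min(dmat_masked), arr.ind = TRUE)
      if (!length(m) || !is.finite(min(dmat_masked)) ||
          min(dmat_masked) > max_step) break
      i <- m[1, 1]; j <- m[1, 2]
      assign_track[i] <- j
      free_obs[j] <- FALSE
    }
    rows <- map(seq_len(nrow(pred)), function(i) {
      j <- assign_track[i]
      if (is.na(j)) {
        tibble(residue = tracks$residue[i], dH_ppm = NA_real_,
               dN_ppm = NA_real_, present = FALSE)
      } else {
        tibble(residue = tracks$residue[i], dH_ppm = obs$dH_ppm[j],
               dN_ppm = obs$dN_ppm[j], present = TRUE)
      }
    }) |> list_rbind()
    meta <- distinct(filter(series, .data$point == p),
                     .data$point, .data$ligand_total, .data$protein_total,
                     .data$equivalents)
    out[[length(out) + 1]] <- mutate(rows, point = meta$point,
                                     ligand_total = meta$ligand_total,
                                     protein_total = meta$protein_total,
                                     equivalents = meta$equivalents,
                                     .before = 1)
    # update track state for linked tracks only
    hit <- !is.na(assign_track)
    tracks$pH[hit] <- tracks$uH[hit]; tracks$pN[hit] <- tracks$uN[hit]
    tracks$uH[hit] <- obs$dH_ppm[assign_track[hit]]
    tracks$uN[hit] <- obs$dN_ppm[assign_track[hit]]
    # broken tracks: advance prediction so extrapolation continues
    tracks$pH[!hit] <- tracks$uH[!hit] - (pred$eH[!hit] - tracks$uH[!hit])
    tracks$pN[!hit] <- tracks$uN[!hit] - (pred$eN[!hit] - tracks$uN[!hit])
    tracks$uH[!hit] <- pred$eH[!hit]
    tracks$uN[!hit] <- pred$eN[!hit]
  }
  list_rbind(out)
}
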