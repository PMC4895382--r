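# Independent oracles used across tests.

# Equilibrium [PL] by root-finding on the mass-balance equation, independent
# of the closed-form quadratic used by the package.
solve_equilibrium <- function(P0, L0, Kd) {
  if (L0 == 0 || P0 == 0) return(0)
  f <- function(pl) (P0 - pl) * (L0 - pl) - Kd * pl
  stats::uniroot(f, c(0, min(P0, L0)), tol = 1e-15)$root
}

# Brute-force EF-loop scan: every 12-window, checked position-by-position
# with plain set membership (no shared code with the scanner internals).
brute_force_scan <- function(residues, rules) {
  n <- nchar(residues)
  out <- list()
  for (s in seq_len(max(n - 11, 0))) {
    win <- strsplit(substring(residues, s, s + 11), "")[[1]]
    ok_first <- {
      a <- rules$allowed[[match(1L, rules$position)]]
      all(is.na(a)) || win[1] %in% a
    }
    if (!ok_first) next
    fails <- character()
    for (i in seq_len(nrow(rules))) {
      a <- rules$allowed[[i]]
      if (all(is.na(a))) next
      if (!win[rules$position[i]] %in% a) fails <- c(fails, rules$label[i])
    }
    out[[length(out) + 1]] <- data.frame(
      loop_start = s, canonical = length(fails) == 0,
      failed = paste(fails, collapse = ","))
  }
  do.call(rbind, out)
}

# Random peak table helper
random_peaks <- function(residues, seed) {
  withr::with_seed(seed, tibble::tibble(
    residue = residues,
    dH_ppm = runif(length(residues), 6, 10),
    dN_ppm = runif(length(residues), 105, 135)
  ))
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    ax <- rnorm(3)
    efbind:::rotation_about(ax, runif(1, 0.1, 3))
  })
}

apply_rigid <- function(atoms, R, t) {
  co <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  dplyr::mutate(atoms, x = co[, 1] + t[1], y = co[, 2] + t[2],
                z = co[, 3] + t[3])
}
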