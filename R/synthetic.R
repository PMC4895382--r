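# Synthetic-data generators with machine-readable ground truth.
#
# Defaults reproduce the study conditions of the alpha-actinin-1 CaMD
# titration: 15 points between 0 and 20 molar equivalents of Ca2+ at a
# fixed protein concentration of 0.312 mM; binder saturation shifts between
# 0.3 and 1.24 ppm; Gaussian shift noise of 0.005 ppm; optional peak
# dropout over 0.25-1.0 equivalents emulating exchange broadening. All
# generators are deterministic given `seed` (withr::with_seed, single RNG
# stream) and attach their ground truth as a `truth` attribute.

EQ_SCHEDULE_DEFAULT <- c(0, 0.125, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8,
                         12, 16, 20)

#' Generate a synthetic CSP titration series
#'
#' Binding residues follow the exact 1:1 isotherm with residue-specific
#' saturation shifts drawn uniformly from `delta_max_range`, split between
#' the 1H and (weight-scaled) 15N dimensions at a random direction;
#' non-binding residues carry pure noise around their free-state peak.
#'
#' @param residues Number of residues (numbered from `first_residue`).
#' @param binding_subset Number of binding residues.
#' @param Kd True dissociation constant (molar); default 170 uM, the
#'   CSP-derived value for the CaMD study system.
#' @param delta_max_range Range (ppm) of per-residue saturation shifts.
#' @param P0 Protein concentration (molar).
#' @param equivalents Ligand equivalents schedule; first entry must be 0.
#' @param noise_sd Gaussian noise SD (ppm) added to each shift dimension.
#' @param dropout Optional list `list(residues =, window = c(lo, hi))`
#'   marking those residues absent at points inside the equivalents window
#'   (exchange-broadened peaks). Default `NULL` (off).
#' @param nitrogen_weight 15N weight used to apportion the combined shift.
#' @param first_residue Author number of the first residue.
#' @param seed Integer seed (required; generation is deterministic).
#' @return Long titration tibble with a `truth` attribute:
#'   `list(Kd, binders, delta_max, nitrogen_weight)`.
#' @export
gen_titration <- function(residues = 56, binding_subset = 6, Kd = 170e-6,
                          delta_max_range = c(0.3, 1.24), P0 = 0.312e-3,
                          equivalents = EQ_SCHEDULE_DEFAULT,
                          noise_sd = 0.005, dropout = NULL,
                          nitrogen_weight = 0.2, first_residue = 743L,
                          seed) {
  if (binding_subset > residues) {
    stop_input("binding_subset cannot exceed the residue count")
  }
  if (equivalents[1] != 0 || is.unsorted(equivalents)) {
    stop_input("equivalents schedule must start at 0 and be non-decreasing")
  }
  withr::with_seed(seed, {
    res_no <- seq.int(first_residue, length.out = residues)
    binders <- sort(sample(res_no, binding_subset))
    dmax <- runif(binding_subset, delta_max_range[1], delta_max_range[2])
    # free-state peak positions, HSQC-like
    baseH <- runif(residues, 6.5, 10.5)
    baseN <- runif(residues, 105, 135)
    # direction of travel in (dH, w*dN) space per binder
    psi <- runif(binding_subset, 0, 2 * pi)
    L0 <- equivalents * P0
    peaks <- map(seq_along(L0), function(i) {
      dH <- baseH
      dN <- baseN
      bidx <- match(binders, res_no)
      dd <- isotherm_1to1(P0, L0[i], Kd, dmax)
      dH[bidx] <- dH[bidx] + dd * cos(psi)
      dN[bidx] <- dN[bidx] + dd * sin(psi) / nitrogen_weight
      pk <- tibble(residue = res_no,
                   dH_ppm = dH + rnorm(residues, 0, noise_sd),
                   dN_ppm = dN + rnorm(residues, 0, noise_sd),
                   present = TRUE)
      if (!is.null(dropout)) {
        inside <- equivalents[i] >= dropout$window[1] &
          equivalents[i] <= dropout$window[2]
        if (inside) {
          drop_res <- dropout$residues
          pk$present[pk$residue %in% drop_res] <- FALSE
          pk$dH_ppm[pk$residue %in% drop_res] <- NA_real_
          pk$dN_ppm[pk$residue %in% drop_res] <- NA_real_
        }
      }
      pk
    })
    series <- titration_series(peaks, L0, P0)
    attr(series, "truth") <- list(Kd = Kd, binders = binders,
                                  delta_max = setNames(dmax, binders),
                                  nitrogen_weight = nitrogen_weight,
                                  noise_sd = noise_sd)
    series
  })
}

# Ideal alpha-helix CA trace: radius 2.3 A, rise 1.5 A/residue, 100 deg
# twist, built N->C along +z.
helix_template <- function(n_res, rise = 1.5, radius = 2.3, twist = 100) {
  k <- seq_len(n_res) - 1
  ang <- k * twist / DEG
  cbind(x = radius * cos(ang), y = radius * sin(ang), z = k * rise)
}

# Axis of a coordinate matrix by the same PCA used in fit_helix_axis,
# oriented first->last half. Used so generated helices can be posed exactly.
pca_axis <- function(co) {
  cc <- sweep(co, 2, colMeans(co))
  ax <- svd(cc, nu = 0, nv = 1)$v[, 1]
  half <- floor(nrow(co) / 2)
  dir_nc <- colMeans(co[(nrow(co) - half + 1):nrow(co), , drop = FALSE]) -
    colMeans(co[seq_len(half), , drop = FALSE])
  if (sum(ax * dir_nc) < 0) ax <- -ax
  as.numeric(ax)
}

#' Generate a synthetic helix-pair ensemble with prescribed (theta, phi)
#'
#' Builds idealised CA-trace helices (rise 1.5 A/residue, radius 2.3 A,
#' 100 deg twist) for an entering and an exiting helix joined by a short
#' loop, posed so the loop-anchored frame yields exactly the requested
#' angles at zero jitter: the entering helix is rotated so its fitted PCA
#' axis lies on +z, the loop anchor is placed with its perpendicular
#' component exactly on +x, and the exiting helix is rotated so its fitted
#' axis points along (sin t cos p, sin t sin p, cos t). Per-model angular
#' jitter perturbs (theta, phi) by Gaussian noise.
#'
#' @param theta,phi Target angles (degrees); `theta` in (0, 180).
#' @param models Number of models.
#' @param jitter_sd Angular jitter SD (degrees) applied independently to
#'   theta and phi per model.
#' @param helix_length Residues per helix (>= 5).
#' @param rise,radius Helix geometry (Angstrom).
#' @param seed Integer seed.
#' @return Ensemble tibble with attributes `truth` (target and per-model
#'   angles) and `hands` (a [hand_definition()] table describing the pair).
#' @export
gen_helix_pair_ensemble <- function(theta, phi, models = 20, jitter_sd = 0,
                                    helix_length = 12, rise = 1.5,
                                    radius = 2.3, seed = 1) {
  if (theta <= 0 || theta >= 180) stop_input("theta must lie in (0, 180)")
  if (models < 1) stop_input("need at least one model")
  withr::with_seed(seed, {
    L <- helix_length
    tmpl <- helix_template(L, rise, radius)
    a0 <- pca_axis(tmpl)
    c0 <- colMeans(tmpl)
    tmpl_c <- sweep(tmpl, 2, c0)

    # entering helix: fitted axis exactly +z, centroid at origin
    R_ent <- rotation_between(a0, c(0, 0, 1))
    ent <- tmpl_c %*% t(R_ent)

    z_top <- max(ent[, 3])
    anchor <- c(6, 0, z_top + 1.5) # perpendicular component on +x exactly

    th_m <- theta + rnorm(models, 0, jitter_sd)
    ph_m <- phi + rnorm(models, 0, jitter_sd)
    th_m <- pmin(pmax(th_m, 1e-3), 180 - 1e-3)

    atoms <- map(seq_len(models), function(m) {
      e <- c(sin(th_m[m] / DEG) * cos(ph_m[m] / DEG),
             sin(th_m[m] / DEG) * sin(ph_m[m] / DEG),
             cos(th_m[m] / DEG))
      R_ext <- rotation_between(a0, e)
      ext <- sweep(tmpl_c %*% t(R_ext), 2,
                   anchor + e * (2 + L * rise / 2), `+`)
      loop_mid <- (anchor + ext[1, ]) / 2
      co <- unname(rbind(ent, anchor, loop_mid, ext))
      tibble(model = m, chain = "A",
             resno = seq_len(nrow(co)),
             resname = "ALA", atom = "CA",
             x = co[, 1], y = co[, 2], z = co[, 3])
    }) |> list_rbind()

    attr(atoms, "truth") <- list(theta = theta, phi = phi,
                                 theta_models = th_m, phi_models = ph_m)
    attr(atoms, "hands") <- hand_definition(
      "EF", entering = 1:L, exiting = (L + 3):(2 * L + 2), anchor = L + 1,
      chain = "A")
    attr(atoms, "source_id") <- "synthetic-helix-pair"
    atoms
  })
}

#' Perturb a base model into a Gaussian-jitter ensemble
#'
#' @param base_atoms Single-model atom tibble.
#' @param models Number of models to emit.
#' @param coordinate_sd Isotropic per-coordinate Gaussian SD (Angstrom);
#'   `0` yields identical copies.
#' @param seed Integer seed.
#' @return Ensemble tibble.
#' @export
gen_ensemble_jitter <- function(base_atoms, models, coordinate_sd, seed) {
  if (coordinate_sd < 0) stop_input("coordinate_sd must be non-negative")
  withr::with_seed(seed, {
    base <- mutate(base_atoms, model = NULL)
    map(seq_len(models), function(m) {
      k <- nrow(base)
      mutate(base, model = m,
             x = .data$x + rnorm(k, 0, coordinate_sd),
             y = .data$y + rnorm(k, 0, coordinate_sd),
             z = .data$z + rnorm(k, 0, coordinate_sd),
             .before = 1)
    }) |> list_rbind()
  })
}

#' Generate EF-loop sequence fixtures with known classification
#'
#' Canonical loops satisfy every constrained rule position (unconstrained
#' positions are filled randomly); degenerate loops violate one or more
#' named positions. Loops are embedded in random flanks drawn from an
#' alphabet without Asp/Glu, which cannot create an accidental canonical
#' window (position 1 requires Asp and any window leaking into a flank
#' fails -Z); this is additionally verified by scanning each record.
#'
#' @param canonical,degenerate Number of loops of each kind.
#' @param rules Rule set ([ef_rules()]).
#' @param flank_length Flank length on both sides of each embedded loop.
#' @param break_positions For degenerate loops: list of label vectors (one
#'   per loop, recycled) naming constrained positions to violate; default
#'   one random constrained position each.
#' @param seed Integer seed.
#' @return A sequence record tibble (one record per loop) with a `truth`
#'   attribute: per-record canonical flag, loop start and broken positions.
#' @export
gen_ef_sequences <- function(canonical = 3, degenerate = 5,
                             rules = ef_rules(), flank_length = 20,
                             break_positions = NULL, seed = 1) {
  flank_alphabet <- setdiff(AA_STANDARD, c("D", "E"))
  constrained <- rules$label[!map_lgl(rules$allowed, function(a) all(is.na(a)))]
  withr::with_seed(seed, {
    build_loop <- function(break_labels = character()) {
      res <- sample(flank_alphabet, EF_LOOP_LENGTH, replace = TRUE)
      for (i in seq_len(nrow(rules))) {
        allowed <- rules$allowed[[i]]
        if (all(is.na(allowed))) next
        lab <- rules$label[i]
        pos <- rules$position[i]
        if (lab %in% break_labels) {
          res[pos] <- sample(setdiff(AA_STANDARD, allowed), 1)
        } else {
          res[pos] <- sample(allowed, 1)
        }
      }
      paste(res, collapse = "")
    }
    n_total <- canonical + degenerate
    if (n_total == 0) {
      return(structure(sequence_record(character(), character()),
                       truth = tibble()))
    }
    if (is.null(break_positions)) {
      break_positions <- map(seq_len(max(degenerate, 1)),
                             function(i) sample(constrained, 1))
    }
    break_positions <- rep_len(break_positions, max(degenerate, 1))
    specs <- tibble(
      kind = c(rep("canonical", canonical), rep("degenerate", degenerate)),
      broken = c(rep(list(character()), canonical),
                 if (degenerate > 0) break_positions[seq_len(degenerate)]
                 else list())
    )
    recs <- pmap(list(specs$kind, specs$broken, seq_len(n_total)),
                 function(kind, broken, i) {
      repeat {
        loop <- build_loop(broken)
        flank1 <- paste(sample(flank_alphabet, flank_length, replace = TRUE),
                        collapse = "")
        flank2 <- paste(sample(flank_alphabet, flank_length, replace = TRUE),
                        collapse = "")
        rec <- sequence_record(sprintf("%s_%02d", kind, i),
                               paste0(flank1, loop, flank2))
        hits <- scan_ef_hands(rec, rules, mode = "window")
        planted_start <- flank_length + 1L
        stray <- hits$canonical & hits$loop_start != planted_start
        planted_ok <- if (kind == "canonical") {
          any(hits$canonical & hits$loop_start == planted_start)
        } else {
          !any(hits$canonical)
        }
        if (!any(stray) && planted_ok) {
          return(list(rec = rec,
                      truth = tibble(id = rec$id, kind = kind,
                                     loop_start = planted_start,
                                     loop_sequence = loop,
                                     broken = paste(broken, collapse = ","))))
        }
      }
    })
    seqs <- list_rbind(map(recs, "rec"))
    attr(seqs, "truth") <- list_rbind(map(recs, "truth"))
    seqs
  })
}

#' Generate a noisy synthetic ITC experiment
#'
#' Simulates the single-site thermogram ([simulate_itc()]) and adds
#' Gaussian heat noise with SD `noise_fraction * max(|heat|)`.
#'
#' @param params [thermo_params()] row.
#' @param design [itc_experiment()] design (heats ignored).
#' @param noise_fraction Noise SD as a fraction of the largest heat.
#' @param seed Integer seed.
#' @return An `itc_experiment` with noisy heats and a `truth` attribute.
#' @export
gen_itc <- function(params, design, noise_fraction = 0, seed = 1) {
  withr::with_seed(seed, {
    sim <- simulate_itc(params, design)
    noise_sd <- noise_fraction * max(abs(sim$heats))
    sim$heats <- sim$heats + rnorm(length(sim$heats), 0, noise_sd)
    attr(sim, "truth") <- as.list(params)
    sim
  })
}

#' Synthetic CaMD-like demonstration construct
#'
#' A synthetic stand-in for a calmodulin-like domain with four EF hands,
#' built around the documented calcium-coordinating residues of
#' alpha-actinin-1 EF1 (Asp759 at X, Asp761 at Y, Ser763 at Z, Thr765 at -Y
#' via the backbone, Gly767 at the water-mediated -X, Glu770 at -Z) and an
#' EF2-like loop starting at Asp800 that lacks canonical residues at Z and
#' -Z. The EF3/EF4-like loops are degenerate at several positions. Flanking
#' segments contain no Asp/Glu, so window-mode scanning cannot produce
#' accidental canonical frames. This is not the natural protein sequence;
#' only the annotated coordination positions are meaningful.
#'
#' @return A list with `seqs` (a [sequence_record()] with
#'   `numbering_offset = 743`) and `annotations` (tibble of the four EF-loop
#'   starts: 759, 800, 836, 875).
#' @export
camd_demo_sequence <- function() {
  residues <- paste0(
    "MTSKGASLFGNKAYLT",              # 743-758
    "DPDYSGTLGKIE",                  # EF1-like loop 759-770 (canonical)
    "KAFRVMNQLGTSWVHKAPSGYLNCRTFIK", # 771-799
    "DKNGAGTLSKIA",                  # EF2-like loop 800-811 (fails Z, -Z)
    "VLSTGHKAMNPQRYWFCIKGTSLA",      # 812-835
    "AKNGSGTLSKIQ",                  # EF3-like loop 836-847 (fails X, -Z)
    "QWNHKAYLTVGSRMPFCIKGTSLANVH",   # 848-874
    "GKAGAGTLAKIA",                  # EF4-like loop 875-886 (fails X, Y, Z, -X, -Z)
    "GSTKLYAQWFNVHM"                 # 887-900
  )
  list(
    seqs = sequence_record("synthetic_CaMD", residues, numbering_offset = 743L),
    annotations = tibble(id = "synthetic_CaMD",
                         loop_start = c(759L, 800L, 836L, 875L))
  )
}
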