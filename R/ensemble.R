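# Multi-model structure ensembles as tidy atom tables.
#
# An ensemble is a tibble with one row per atom per model: model (integer),
# chain, resno (author numbering), resname, atom (name, e.g. "CA"), x, y, z
# in Angstrom; attribute "source_id" records provenance. PDB/mmCIF parsing
# is delegated to bio3d; multi-model files are split on MODEL/ENDMDL so each
# model is parsed independently and inventory mismatches can be reported
# per model and residue.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Read a (multi-model) PDB or mmCIF file into an ensemble table
#'
#' Heteroatoms are excluded; alternate location 'A' is kept; insertion codes
#' are rejected (not expected in NMR entries). All models must share the
#' same atom inventory; mismatches are reported naming the model and
#' residues involved.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param source_id Optional identifier stored on the result (defaults to
#'   the file name).
#' @return An ensemble tibble (see file header) with attribute `source_id`.
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "mmcif"),
                          source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input(paste0("cannot read '", path, "'"))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (format == "mmcif") {
    pdb <- bio3d::read.cif(path, multi = TRUE, verbose = FALSE)
    atoms <- bio3d_to_tibble(pdb)
  } else {
    lines <- readLines(path)
    model_starts <- grep("^MODEL", lines)
    if (length(model_starts) <= 1) {
      pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
      atoms <- bio3d_to_tibble(pdb)
    } else {
      model_ends <- grep("^ENDMDL", lines)
      if (length(model_ends) != length(model_starts)) {
        stop_input("unbalanced MODEL/ENDMDL records")
      }
      atoms <- map(seq_along(model_starts), function(m) {
        chunk <- lines[(model_starts[m] + 1):(model_ends[m] - 1)]
        tf <- tempfile(fileext = ".pdb")
        on.exit(unlink(tf), add = TRUE)
        writeLines(c(chunk, "END"), tf)
        pdb <- bio3d::read.pdb(tf, multi = FALSE, verbose = FALSE)
        mutate(bio3d_to_tibble(pdb), model = m)
      }) |> list_rbind()
    }
  }
  check_inventory(atoms)
  attr(atoms, "source_id") <- source_id %||% basename(path)
  atoms
}

bio3d_to_tibble <- function(pdb) {
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (any(nzchar(at$insert[keep]) & !is.na(at$insert[keep]))) {
    stop_input("insertion codes are not supported")
  }
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1) {
    models <- nrow(xyz)
    map(seq_len(models), function(m) {
      co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
      tibble(model = m, chain = at$chain, resno = at$resno,
             resname = at$resid, atom = at$elety,
             x = co[, 1], y = co[, 2], z = co[, 3])[keep, ]
    }) |> list_rbind()
  } else {
    tibble(model = 1L, chain = at$chain, resno = at$resno,
           resname = at$resid, atom = at$elety,
           x = at$x, y = at$y, z = at$z)[keep, ]
  }
}

check_inventory <- function(atoms) {
  inv <- atoms |>
    mutate(key = paste(.data$chain, .data$resno, .data$atom, sep = "|"))
  ref_keys <- inv$key[inv$model == min(inv$model)]
  for (m in unique(inv$model)) {
    keys <- inv$key[inv$model == m]
    extra <- setdiff(keys, ref_keys)
    miss <- setdiff(ref_keys, keys)
    if (length(extra) || length(miss)) {
      stop_input(paste0(
        "inconsistent atom inventory in model ", m,
        if (length(miss)) paste0("; missing: ",
                                 paste(utils::head(miss, 5), collapse = ", ")),
        if (length(extra)) paste0("; extra: ",
                                  paste(utils::head(extra, 5), collapse = ", "))))
    }
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop_input("non-finite coordinates")
  }
  invisible(atoms)
}

#' Write an ensemble table as a multi-MODEL PDB file
#'
#' @param atoms Ensemble tibble.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_ensemble_pdb <- function(atoms, path) {
  models <- sort(unique(atoms$model))
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    a <- filter(atoms, .data$model == m)
    tf <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(file = tf, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resno, chain = a$chain, resid = a$resname,
                     elety = a$atom)
    body <- readLines(tf)
    unlink(tf)
    body <- body[grepl("^ATOM|^TER", body)]
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(body, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Atom selection for superposition / RMSD
#'
#' @param chain Chain identifier or `NULL` for all chains.
#' @param resno Integer vector of author residue numbers (e.g. `743:820`).
#' @param atoms Atom class: `"backbone"` (N, CA, C, O), `"CA"` or `"all"`.
#' @return A `residue_selection` list.
#' @export
residue_selection <- function(resno, chain = NULL,
                              atoms = c("backbone", "CA", "all")) {
  atoms <- match.arg(atoms)
  if (length(resno) == 0) stop_input("empty residue selection")
  structure(list(chain = chain, resno = as.integer(resno), atoms = atoms),
            class = "residue_selection")
}

select_atoms <- function(ens, selection) {
  out <- filter(ens, .data$resno %in% selection$resno)
  if (!is.null(selection$chain)) {
    out <- filter(out, .data$chain %in% selection$chain)
  }
  if (selection$atoms == "backbone") {
    out <- filter(out, .data$atom %in% BACKBONE_ATOMS)
  } else if (selection$atoms == "CA") {
    out <- filter(out, .data$atom == "CA")
  }
  if (nrow(out) == 0) stop_input("selection matches no atoms")
  missing <- setdiff(selection$resno, unique(out$resno))
  if (length(missing)) {
    stop_input(paste0("selection residues absent from ensemble: ",
                      paste(missing, collapse = ", ")))
  }
  arrange(out, .data$model, .data$chain, .data$resno,
          match(.data$atom, c(BACKBONE_ATOMS,
                              sort(unique(out$atom)))))
}

coords_by_model <- function(sel) {
  models <- sort(unique(sel$model))
  map(models, function(m) {
    a <- filter(sel, .data$model == m)
    as.matrix(a[, c("x", "y", "z")])
  }) |> setNames(models)
}

#' Superpose ensemble models onto a reference over a selection
#'
#' Each model is rigidly transformed (proper rotation + translation, Kabsch)
#' to minimise the RMSD of the selected atoms to the reference: either a
#' model index, or `"mean"` for the iterated mean structure (superpose onto
#' model 1, take the coordinate mean, re-superpose; two iterations).
#'
#' @param atoms Ensemble tibble.
#' @param selection A [residue_selection()].
#' @param reference `"mean"` (default) or a model index.
#' @return The transformed ensemble; per-model transforms are stored in the
#'   `transforms` attribute as `list(R, t)`.
#' @export
superpose <- function(atoms, selection, reference = "mean") {
  sel <- select_atoms(atoms, selection)
  mats <- coords_by_model(sel)
  # degenerate-selection guard: need >= 2 significant spatial dimensions
  sv <- svd(scale(mats[[1]], scale = FALSE))$d
  if (length(sv) < 2 || sv[2] < 1e-8 * max(sv[1], 1)) {
    stop_input("degenerate (collinear) selection: superposition is ill-defined")
  }
  target <- if (identical(reference, "mean")) {
    ref <- mats[[1]]
    for (iter in 1:2) {
      aligned <- map(mats, function(P) {
        k <- kabsch(P, ref)
        sweep(P %*% k$R, 2, k$t, `+`)
      })
      ref <- Reduce(`+`, aligned) / length(aligned)
    }
    ref
  } else {
    ref_idx <- as.integer(reference)
    if (!as.character(ref_idx) %in% names(mats)) {
      stop_input("reference model index not in ensemble")
    }
    mats[[as.character(ref_idx)]]
  }
  transforms <- map(mats, function(P) kabsch(P, target))
  models <- as.integer(names(mats))
  out <- map(seq_along(models), function(i) {
    a <- filter(atoms, .data$model == models[i])
    co <- as.matrix(a[, c("x", "y", "z")])
    co <- sweep(co %*% transforms[[i]]$R, 2, transforms[[i]]$t, `+`)
    mutate(a, x = co[, 1], y = co[, 2], z = co[, 3])
  }) |> list_rbind()
  attr(out, "source_id") <- attr(atoms, "source_id")
  attr(out, "transforms") <- transforms
  out
}

#' Ensemble RMSD statistics over a selection
#'
#' Both reporting conventions are always computed on the (already
#' superposed) ensemble:
#' * `to_mean`: the ensemble standard deviation about the mean structure,
#'   `sqrt( sum_m msd_m / (n - 1) )` where `msd_m` is the mean squared
#'   deviation of model `m`'s selected atoms from the coordinate mean. The
#'   `n - 1` normalisation makes the estimate unbiased for isotropic jitter
#'   and gives the exact identity `pairwise = sqrt(2) * to_mean` for
#'   two-model ensembles.
#' * `pairwise`: the average over all unordered model pairs of the pairwise
#'   RMSD.
#'
#' @param atoms Superposed ensemble tibble (superpose on the same selection
#'   first; see [superpose()]).
#' @param selection A [residue_selection()].
#' @return A one-row tibble: `to_mean`, `pairwise` (Angstrom), `n_models`,
#'   `n_atoms`; per-model RMSDs to the mean structure are in the
#'   `per_model` attribute.
#' @export
ensemble_rmsd <- function(atoms, selection) {
  sel <- select_atoms(atoms, selection)
  mats <- coords_by_model(sel)
  n <- length(mats)
  mean_str <- Reduce(`+`, mats) / n
  msd <- map_dbl(mats, function(P) mean(rowSums((P - mean_str)^2)))
  to_mean <- if (n > 1) sqrt(sum(msd) / (n - 1)) else 0
  pw <- c()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        pw <- c(pw, sqrt(mean(rowSums((mats[[i]] - mats[[j]])^2))))
      }
    }
  }
  out <- tibble(to_mean = to_mean,
                pairwise = if (n > 1) mean(pw) else 0,
                n_models = n, n_atoms = nrow(mats[[1]]))
  attr(out, "per_model") <- tibble(model = as.integer(names(mats)),
                                   rmsd_to_mean = sqrt(msd))
  out
}
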