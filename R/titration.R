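# Titration series container and file I/O.
#
# A titration series is a long tibble with one row per (titration point,
# residue): point, ligand_total, protein_total, equivalents, residue,
# dH_ppm, dN_ppm, present. The first point is the ligand-free reference.

#' Assemble a titration series from per-point peak tables
#'
#' @param peaks A list of peak tibbles (`residue`, `dH_ppm`, `dN_ppm`,
#'   optional `present`), ordered by titration point.
#' @param ligand_total Total ligand concentration per point (molar);
#'   must start at 0 and be non-decreasing.
#' @param protein_total Total protein concentration per point (molar),
#'   recycled if scalar.
#' @return A long titration tibble (see file header) validated for the
#'   series invariants.
#' @export
titration_series <- function(peaks, ligand_total, protein_total) {
  if (length(peaks) != length(ligand_total)) {
    stop_input("one ligand_total per titration point is required")
  }
  protein_total <- rep_len(protein_total, length(peaks))
  series <- imap(peaks, function(pk, i) {
    l0 <- ligand_total[i]
    p0 <- protein_total[i]
    normalise_peaks(pk) |>
      mutate(point = i, ligand_total = l0, protein_total = p0,
             equivalents = l0 / p0, .before = 1)
  }) |> list_rbind()
  validate_titration(series)
}

validate_titration <- function(series) {
  need <- c("point", "ligand_total", "protein_total", "equivalents",
            "residue", "dH_ppm", "dN_ppm")
  if (!all(need %in% names(series))) {
    stop_input(paste("titration series needs columns:",
                     paste(need, collapse = ", ")))
  }
  if (!"present" %in% names(series)) series$present <- TRUE
  pts <- distinct(series, .data$point, .data$ligand_total,
                  .data$protein_total, .data$equivalents) |>
    arrange(.data$point)
  if (any(pts$ligand_total < 0) || any(pts$protein_total <= 0)) {
    stop_input("concentrations must be non-negative (protein positive)")
  }
  if (pts$ligand_total[1] != 0) {
    stop_input("first titration point must be the ligand-free reference (ligand_total = 0)")
  }
  if (is.unsorted(pts$ligand_total)) {
    stop_input("ligand_total must be non-decreasing across points")
  }
  if (any(abs(pts$equivalents - pts$ligand_total / pts$protein_total) > 1e-9)) {
    stop_input("equivalents inconsistent with ligand_total / protein_total")
  }
  as_tibble(series)
}

#' Read a titration series from a manifest of peak-list files
#'
#' The manifest is a CSV with columns `file` (per-point peak list CSV/TSV
#' with `residue`, `dH_ppm`, `dN_ppm`, optional `present`) and either
#' `ligand_total_M` or `equivalents`, plus `protein_total_M`. Paths are
#' resolved relative to the manifest.
#'
#' @param manifest Path to the manifest CSV.
#' @return A long titration tibble.
#' @export
read_titration <- function(manifest) {
  man <- readr::read_csv(manifest, show_col_types = FALSE)
  if (!"file" %in% names(man) || !"protein_total_M" %in% names(man)) {
    stop_input("manifest needs columns file, protein_total_M and ligand_total_M or equivalents")
  }
  L0 <- if ("ligand_total_M" %in% names(man)) {
    man$ligand_total_M
  } else if ("equivalents" %in% names(man)) {
    man$equivalents * man$protein_total_M
  } else {
    stop_input("manifest needs ligand_total_M or equivalents")
  }
  paths <- file.path(dirname(manifest), man$file)
  peaks <- map(paths, function(p) {
    readr::read_delim(p, show_col_types = FALSE,
                      delim = if (grepl("\\.tsv$", p)) "\t" else ",")
  })
  titration_series(peaks, L0, man$protein_total_M)
}

#' Write a titration series as per-point peak lists plus a manifest
#'
#' Inverse of [read_titration()]. If the series carries a `truth` attribute
#' (synthetic data), it is written alongside as `truth.json`.
#'
#' @param series Long titration tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path invisibly.
#' @export
write_titration <- function(series, dir) {
  series <- validate_titration(series)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pts <- distinct(series, .data$point, .data$ligand_total, .data$protein_total)
  files <- sprintf("point_%02d.csv", pts$point)
  for (i in seq_len(nrow(pts))) {
    series |>
      filter(.data$point == pts$point[i]) |>
      select("residue", "dH_ppm", "dN_ppm", "present") |>
      readr::write_csv(file.path(dir, files[i]))
  }
  man <- tibble(file = files, ligand_total_M = pts$ligand_total,
                protein_total_M = pts$protein_total)
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(man, manifest)
  truth <- attr(series, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}
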