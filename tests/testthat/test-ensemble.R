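# Ensemble reading, superposition and RMSD statistics.

make_small_ensemble <- function(models = 3, seed = 2, sd = 0.3) {
  base <- dplyr::filter(
    gen_helix_pair_ensemble(theta = 75, phi = 30, models = 1, seed = seed),
    model == 1)
  gen_ensemble_jitter(base, models, sd, seed = seed + 1)
}

test_that("multi-model PDB round-trips with consistent atom inventories", {
  ens <- make_small_ensemble(models = 20)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_ensemble(path)
  expect_equal(length(unique(back$model)), 20)
  expect_equal(nrow(back), nrow(ens))
  expect_equal(back$resno, ens$resno)
  expect_equal(back$x, ens$x, tolerance = 1e-3) # PDB stores 3 decimals
  expect_equal(attr(back, "source_id"), basename(path))
})

test_that("single-model files yield size-1 ensembles with zero RMSD", {
  ens <- dplyr::filter(make_small_ensemble(), model == 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_ensemble(path)
  expect_equal(unique(back$model), 1L)
  sel <- residue_selection(sort(unique(back$resno)), atoms = "CA")
  r <- ensemble_rmsd(back, sel)
  expect_equal(r$to_mean, 0)
  expect_equal(r$pairwise, 0)
})

test_that("a model with a missing atom is reported by model and residue", {
  ens <- make_small_ensemble(models = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  lines <- readLines(path)
  # delete one CA of residue 5 inside the second MODEL block
  m2 <- which(grepl("^MODEL", lines))[2]
  hit <- which(grepl("^ATOM", lines) & grepl(" CA ", lines) &
                 as.integer(substr(lines, 23, 26)) == 5 &
                 seq_along(lines) > m2)[1]
  writeLines(lines[-hit], path)
  expect_error(read_ensemble(path), "model 2.*5|inconsistent")
})

test_that("superposition removes translations and recovers known rotations", {
  m1 <- dplyr::filter(make_small_ensemble(), model == 1)
  sel <- residue_selection(sort(unique(m1$resno)), atoms = "CA")
  # pure translation
  shifted <- dplyr::mutate(m1, model = 2L, x = x + 4, y = y - 2, z = z + 9)
  both <- dplyr::bind_rows(m1, shifted)
  sup <- superpose(both, sel, reference = 1)
  d <- dplyr::filter(sup, model == 2)
  expect_equal(as.matrix(d[, c("x", "y", "z")]),
               as.matrix(m1[, c("x", "y", "z")]), tolerance = 1e-9)
  # known rotation: recovered transform equals its inverse mapping
  R <- random_rotation(33)
  rotated <- dplyr::mutate(apply_rigid(m1, R, c(1, 2, 3)), model = 2L)
  sup2 <- superpose(dplyr::bind_rows(m1, rotated), sel, reference = 1)
  tr <- attr(sup2, "transforms")[[2]]
  expect_equal(det(tr$R), 1, tolerance = 1e-9)
  expect_equal(tr$R %*% t(R), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # self-superposition is the identity
  tr1 <- attr(sup2, "transforms")[[1]]
  expect_equal(tr1$R, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tr1$t, c(0, 0, 0), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("superposition agrees with the bio3d reference implementation", {
  ens <- make_small_ensemble(models = 4)
  sel <- residue_selection(sort(unique(ens$resno)), atoms = "CA")
  sup <- superpose(ens, sel, reference = 1)
  # independent route: bio3d::fit.xyz onto model 1
  mats <- lapply(split(ens[, c("x", "y", "z")], ens$model),
                 \(d) as.numeric(t(as.matrix(d))))
  fixed <- mats[[1]]
  for (m in 2:4) {
    moved <- bio3d::fit.xyz(fixed, mats[[m]],
                            fixed.inds = seq_along(fixed),
                            mobile.inds = seq_along(fixed))
    ours <- dplyr::filter(sup, model == m)
    expect_equal(as.numeric(t(as.matrix(ours[, c("x", "y", "z")]))),
                 as.numeric(moved), tolerance = 1e-6)
  }
})

test_that("rmsd is invariant under global rigid motion applied before superposition", {
  ens <- make_small_ensemble(models = 5)
  sel <- residue_selection(sort(unique(ens$resno)), atoms = "CA")
  r0 <- ensemble_rmsd(superpose(ens, sel), sel)
  R <- random_rotation(44)
  moved <- apply_rigid(ens, R, c(-3, 7, 2))
  r1 <- ensemble_rmsd(superpose(moved, sel), sel)
  expect_equal(r1$to_mean, r0$to_mean, tolerance = 1e-9)
  expect_equal(r1$pairwise, r0$pairwise, tolerance = 1e-9)
})

test_that("two-model ensembles obey pairwise = sqrt(2) * to_mean exactly", {
  ens <- make_small_ensemble(models = 2)
  sel <- residue_selection(sort(unique(ens$resno)), atoms = "CA")
  r <- ensemble_rmsd(superpose(ens, sel), sel)
  expect_equal(r$pairwise, sqrt(2) * r$to_mean, tolerance = 1e-12)
})

test_that("a hand-computable 3-atom toy matches direct arithmetic", {
  # two models, one atom displaced by d: mean structure splits the
  # difference, so to_mean = d/sqrt(6) with the n-1 model normalisation and
  # pairwise = d/sqrt(3)
  d <- 0.8
  a <- tibble::tibble(model = 1L, chain = "A", resno = 1:3, resname = "GLY",
                      atom = "CA", x = c(0, 3, 6), y = 0, z = 0)
  b <- dplyr::mutate(a, model = 2L, x = x + c(d, 0, 0))
  r <- ensemble_rmsd(dplyr::bind_rows(a, b),
                     residue_selection(1:3, atoms = "CA"))
  expect_equal(r$to_mean, d / sqrt(6), tolerance = 1e-12)
  expect_equal(r$pairwise, d / sqrt(3), tolerance = 1e-12)
})

test_that("gaussian jitter ensembles match the sigma*sqrt(3) expectation", {
  base <- dplyr::filter(
    gen_helix_pair_ensemble(theta = 80, phi = 10, models = 1,
                            helix_length = 100, seed = 55),
    model == 1) # 202 atoms
  sigma <- 0.4
  ens <- gen_ensemble_jitter(base, models = 20, coordinate_sd = sigma,
                             seed = 56)
  sel <- residue_selection(sort(unique(ens$resno)), atoms = "CA")
  r <- ensemble_rmsd(superpose(ens, sel), sel)
  expect_equal(r$to_mean, sigma * sqrt(3), tolerance = 0.1)
  # sd = 0 gives identical models
  ens0 <- gen_ensemble_jitter(base, models = 3, coordinate_sd = 0, seed = 57)
  r0 <- ensemble_rmsd(ens0, sel)
  expect_equal(r0$to_mean, 0)
})

test_that("degenerate collinear selections are rejected", {
  line <- tibble::tibble(model = rep(1:2, each = 6), chain = "A",
                         resno = rep(1:6, 2), resname = "GLY", atom = "CA",
                         x = rep(seq(0, 5), 2), y = 0, z = 0)
  expect_error(superpose(line, residue_selection(1:6, atoms = "CA")),
               "collinear")
})
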