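# Helix axes, local frames and interhelical angles.

# geometry constructed directly from rotation matrices (no atom fitting)
make_geometry <- function(theta, phi, R = diag(3), t = c(0, 0, 0)) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  e <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  ent <- structure(list(axis = as.numeric(R %*% c(0, 0, 1)),
                        centroid = as.numeric(R %*% c(0, 0, 0) + t),
                        resno = c(1L, 12L), rmsd_to_axis = 0),
                   class = "helix_segment")
  ext <- structure(list(axis = as.numeric(R %*% e),
                        centroid = as.numeric(R %*% c(5, 0, 14) + t),
                        resno = c(15L, 26L), rmsd_to_axis = 0),
                   class = "helix_segment")
  ef_geometry(ent, ext, as.numeric(R %*% c(4, 0, 10) + t))
}

test_that("helix axis fitting recovers generator ground truth", {
  ens <- gen_helix_pair_ensemble(theta = 90, phi = 0, models = 1, seed = 3)
  hands <- attr(ens, "hands")
  m1 <- dplyr::filter(ens, model == 1)
  ent <- fit_helix_axis(m1, hands$entering[[1]])
  expect_equal(ent$axis, c(0, 0, 1), tolerance = 1e-9)
  ext <- fit_helix_axis(m1, hands$exiting[[1]])
  expect_equal(ext$axis, c(1, 0, 0), tolerance = 1e-9) # theta 90, phi 0
  # rotated model: axis rotates with it
  R <- random_rotation(8)
  ent_r <- fit_helix_axis(apply_rigid(m1, R, c(2, -1, 4)),
                          hands$entering[[1]])
  expect_equal(ent_r$axis, as.numeric(R %*% c(0, 0, 1)), tolerance = 1e-9)
})

test_that("axis orientation comes from termini, not eigenvector sign", {
  ens <- gen_helix_pair_ensemble(theta = 45, phi = 120, models = 1, seed = 4)
  m1 <- dplyr::filter(ens, model == 1)
  rng <- attr(ens, "hands")$entering[[1]]
  fwd <- fit_helix_axis(m1, rng)
  rev <- fit_helix_axis(m1[rev(seq_len(nrow(m1))), ], rng)
  expect_equal(fwd$axis, rev$axis, tolerance = 1e-12)
  expect_error(fit_helix_axis(m1, 1:4), "at least 5")
})

test_that("collinear atoms give an exact axis with zero residual", {
  line <- tibble::tibble(model = 1L, chain = "A", resno = 1:6,
                         resname = "GLY", atom = "CA",
                         x = 2 * (0:5), y = 2 * (0:5), z = 0)
  h <- fit_helix_axis(line, 1:6)
  expect_equal(h$axis, c(1, 1, 0) / sqrt(2), tolerance = 1e-12)
  expect_equal(h$rmsd_to_axis, 0, tolerance = 1e-9)
})

test_that("the loop-anchored frame is orthonormal, right-handed and equivariant", {
  g <- make_geometry(60, 45)
  F0 <- local_frame(g)
  expect_equal(crossprod(F0), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(det(F0), 1, tolerance = 1e-12)
  expect_equal(F0, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  R <- random_rotation(9)
  FR <- local_frame(make_geometry(60, 45, R, c(1, 2, 3)))
  expect_equal(FR, R %*% F0, tolerance = 1e-9, ignore_attr = TRUE)
  # anchor on the helix axis: degenerate
  ent <- structure(list(axis = c(0, 0, 1), centroid = c(0, 0, 0),
                        resno = c(1L, 12L), rmsd_to_axis = 0),
                   class = "helix_segment")
  ext <- structure(list(axis = c(1, 0, 0), centroid = c(0, 0, 14),
                        resno = c(15L, 26L), rmsd_to_axis = 0),
                   class = "helix_segment")
  bad <- ef_geometry(ent, ext, c(0, 0, 10))
  expect_error(local_frame(bad), class = "efbind_degenerate_frame")
})

test_that("angles follow the polar/azimuth conventions on canonical poses", {
  # parallel axes: theta 0, phi degenerate and reported 0
  ent <- structure(list(axis = c(0, 0, 1), centroid = c(0, 0, 0),
                        resno = c(1L, 12L), rmsd_to_axis = 0),
                   class = "helix_segment")
  ext_par <- structure(list(axis = c(0, 0, 1), centroid = c(3, 0, 14),
                            resno = c(15L, 26L), rmsd_to_axis = 0),
                       class = "helix_segment")
  g <- ef_geometry(ent, ext_par, c(4, 0, 10))
  a <- vgm_angles(g)
  expect_equal(a$theta, 0)
  expect_equal(a$phi, 0)
  expect_true(a$degenerate)
  # exiting axis along +x: theta 90, phi 0
  a2 <- vgm_angles(make_geometry(90, 0))
  expect_equal(a2$theta, 90, tolerance = 1e-12)
  expect_equal(a2$phi, 0, tolerance = 1e-12)
})

test_that("construct-then-measure round-trips and is rigid-motion invariant", {
  withr::with_seed(77, {
    thetas <- runif(200, 1, 179)
    phis <- runif(200, -180, 180)
  })
  for (i in seq_along(thetas)) {
    a <- vgm_angles(make_geometry(thetas[i], phis[i]))
    expect_equal(a$theta, thetas[i], tolerance = 1e-6)
    expect_equal(a$phi, phis[i], tolerance = 1e-6)
  }
  R <- random_rotation(10)
  for (i in 1:20) {
    a0 <- vgm_angles(make_geometry(thetas[i], phis[i]))
    a1 <- vgm_angles(make_geometry(thetas[i], phis[i], R, c(3, -2, 8)))
    expect_equal(a1$theta, a0$theta, tolerance = 1e-9)
    expect_equal(a1$phi, a0$phi, tolerance = 1e-9)
  }
})

test_that("ensemble summaries: constant ensembles and jittered means", {
  ens0 <- gen_helix_pair_ensemble(theta = 56.3, phi = -27.6, models = 20,
                                  jitter_sd = 0, seed = 11)
  r0 <- ensemble_vgm(ens0, attr(ens0, "hands"))
  expect_equal(r0$summary$sd_theta, 0, tolerance = 1e-9)
  expect_equal(r0$summary$mean_theta, 56.3, tolerance = 1e-6)
  expect_equal(r0$summary$mean_phi, -27.6, tolerance = 1e-6)
  ens3 <- gen_helix_pair_ensemble(theta = 56.3, phi = -27.6, models = 20,
                                  jitter_sd = 3, seed = 12)
  r3 <- ensemble_vgm(ens3, attr(ens3, "hands"))
  expect_equal(r3$summary$mean_theta, 56.3, tolerance = 1)
  expect_equal(r3$summary$n_models, 20)
  # per-model values match the generator's per-model ground truth
  truth <- attr(ens3, "truth")
  expect_equal(r3$angles$theta, truth$theta_models, tolerance = 1e-6)
  expect_equal(r3$angles$phi, truth$phi_models, tolerance = 1e-6)
})

test_that("models with a degenerate frame are excluded and counted", {
  ens <- gen_helix_pair_ensemble(theta = 70, phi = 20, models = 5, seed = 13)
  hands <- attr(ens, "hands")
  # move model 3's anchor CA onto the entering-helix axis
  anchor_res <- hands$anchor[1]
  idx <- ens$model == 3 & ens$resno == anchor_res
  ens$x[idx] <- 0; ens$y[idx] <- 0; ens$z[idx] <- 30
  r <- ensemble_vgm(ens, hands)
  expect_equal(r$summary$n_excluded, 1)
  expect_equal(r$summary$n_models, 4)
  # remaining per-model values are unchanged by the exclusion
  full <- ensemble_vgm(dplyr::filter(ens, model != 3), hands)
  expect_equal(dplyr::filter(r$angles, !excluded)$theta,
               full$angles$theta)
})

test_that("state comparison wraps the azimuthal difference correctly", {
  apo <- gen_helix_pair_ensemble(theta = 41.2, phi = 179, models = 3,
                                 seed = 14)
  same <- compare_states(ensemble_vgm(apo, attr(apo, "hands")),
                         ensemble_vgm(apo, attr(apo, "hands")))
  expect_equal(same$delta_theta, 0)
  expect_equal(same$delta_phi, 0)
  holo <- gen_helix_pair_ensemble(theta = 56.3, phi = -179, models = 3,
                                  seed = 15)
  d <- compare_states(ensemble_vgm(apo, attr(apo, "hands")),
                      ensemble_vgm(holo, attr(holo, "hands")))
  expect_equal(d$delta_theta, 15.1, tolerance = 1e-6)
  expect_equal(d$delta_phi, 2, tolerance = 1e-6) # +179 -> -179 is +2, not -358
  # mismatched hand sets are rejected
  other <- ensemble_vgm(holo, dplyr::mutate(attr(holo, "hands"),
                                            hand = "EF9"))
  expect_error(compare_states(ensemble_vgm(apo, attr(apo, "hands")), other),
               "different EF-hand sets")
})
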