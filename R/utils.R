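# Shared numerical helpers: angles, rotations, rigid-body superposition.

DEG <- 180 / pi

#' Wrap an angle in degrees to (-180, 180]
#'
#' Circular differences (e.g. between azimuthal angles of two states) must be
#' reported on a single branch; this maps any angle onto (-180, 180], so that
#' a change from +179 deg to -179 deg is reported as +2 deg.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector wrapped to (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(358, -358, 180, -180))
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360) # lands in [-180, 180)
  w[w == -180] <- 180
  w
}

# circular mean of angles in degrees
circ_mean <- function(x) {
  atan2(mean(sin(x / DEG)), mean(cos(x / DEG))) * DEG
}

# circular standard deviation in degrees: sqrt(-2 log Rbar)
circ_sd <- function(x) {
  rbar <- sqrt(mean(sin(x / DEG))^2 + mean(cos(x / DEG))^2)
  sqrt(pmax(-2 * log(pmax(rbar, .Machine$double.xmin)), 0)) * DEG
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) abort("cannot normalise a (near-)zero vector")
  v / nv
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix about unit axis `ax` by `ang` radians (Rodrigues).
rotation_about <- function(ax, ang) {
  ax <- unit(ax)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# Minimal proper rotation mapping unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- cross3(a, b)
  s <- sqrt(sum(v^2))
  c_ <- sum(a * b)
  if (s < 1e-14) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_about(cross3(a, ref), pi))
  }
  rotation_about(v / s, atan2(s, c_))
}

# Kabsch: optimal proper rotation R and translation t such that
# P %*% R + t approximates Q (rows are points). Returns list(R, t, rmsd).
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  R <- t(R) # so that points-as-rows transform as P %*% R
  t_ <- cq - as.numeric(cp %*% R)
  fitted <- sweep(P %*% R, 2, t_, `+`)
  list(R = R, t = t_, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

`%||%` <- rlang::`%||%`

stop_input <- function(msg, class = "efbind_input_error") {
  abort(msg, class = class)
}
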