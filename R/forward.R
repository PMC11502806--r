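#' Current dipole in a spherical conductor
#'
#' @param position 3-vector, meters, head frame with the sphere center at the
#'   origin (x left-to-right, y posterior-to-anterior, z inferior-to-superior).
#' @param moment 3-vector, A*m.
#' @return an object of class `dipole`.
#' @export
dipole <- function(position, moment) {
  stopifnot(length(position) == 3, length(moment) == 3)
  structure(list(position = as.numeric(position), moment = as.numeric(moment)),
            class = "dipole")
}

#' Magnetic field of a current dipole in a spherically symmetric conductor
#'
#' Closed-form external field (Sarvas solution). Conductivity layering does
#' not affect the external field under spherical symmetry, so a three-layer
#' spherical head model reduces exactly to this formula; radial dipoles are
#' magnetically silent.
#'
#' @param d a `dipole` (position strictly inside the measurement radius).
#' @param points numeric 3-vector or n x 3 matrix of field points (m), all
#'   strictly outside the dipole's radius.
#' @return n x 3 matrix of field vectors in tesla.
#' @export
dipole_field <- function(d, points) {
  stopifnot(inherits(d, "dipole"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  r0 <- d$position; q <- d$moment
  R <- sqrt(rowSums(points^2))
  if (any(R <= sqrt(sum(r0^2)) + 1e-12))
    stop("field point at or inside the dipole radius")
  a_vec <- sweep(points, 2, r0)               # a = r - r0
  A <- sqrt(rowSums(a_vec^2))
  if (any(A < 1e-12)) stop("field point coincides with the dipole")
  adotr <- rowSums(a_vec * points)
  r0dotr <- points %*% r0
  F <- A * (R * A + R^2 - as.numeric(r0dotr))
  cF1 <- A^2 / R + adotr / A + 2 * A + 2 * R
  cF2 <- A + 2 * R + adotr / A
  gradF <- points * cF1 - matrix(r0, nrow(points), 3, byrow = TRUE) * cF2
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  qxr0dotr <- points %*% qxr0
  B <- (matrix(qxr0, nrow(points), 3, byrow = TRUE) * F -
          gradF * as.numeric(qxr0dotr)) * (1e-7 / F^2)
  B
}

#' Default planar-gradiometer helmet array
#'
#' A Vector-view-like geometry: `n_sites` sensor sites quasi-uniformly
#' distributed (Fibonacci lattice) on a spherical cap of the helmet radius,
#' covering the upper head down to the temporal region. Each site carries two
#' orthogonal planar gradiometers (204 channels at the default 102 sites)
#' whose pick-up coils straddle the site along the gradient direction.
#'
#' @param n_sites number of sensor sites (default 102).
#' @param helmet_radius_m radius of the sensor shell (default 0.12).
#' @param sphere_radius_m conductor sphere radius (default 0.09).
#' @param baseline_m gradiometer coil separation (default 0.0168).
#' @param cap_deg angular radius of the helmet cap from the vertex (default 110).
#' @return a `sensor_array`: list with `channels` data.frame (positions,
#'   coil normals, gradient directions, baseline, hemisphere), `sphere_center`,
#'   `sphere_radius_m`, `n_sites`.
#' @export
default_sensor_array <- function(n_sites = 102, helmet_radius_m = 0.12,
                                 sphere_radius_m = 0.09, baseline_m = 0.0168,
                                 cap_deg = 110) {
  stopifnot(n_sites >= 2, helmet_radius_m > sphere_radius_m)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_sites) - 0.5
  cosmax <- cos(cap_deg * pi / 180)
  z <- 1 - (i / n_sites) * (1 - cosmax)       # uniform in cos(theta) over the cap
  phi <- golden * (seq_len(n_sites) - 1)
  st <- sqrt(pmax(1 - z^2, 0))
  u <- cbind(st * cos(phi), st * sin(phi), z)  # site unit directions
  pos <- u * helmet_radius_m
  # tangential frame at each site
  e1 <- cbind(-u[, 2], u[, 1], 0)
  deg <- which(sqrt(rowSums(e1^2)) < 1e-9)
  if (length(deg) > 0)
    e1[deg, ] <- matrix(c(1, 0, 0), length(deg), 3, byrow = TRUE)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
              u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
              u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
  e2 <- e2 / sqrt(rowSums(e2^2))

  idx <- rep(seq_len(n_sites), each = 2)
  gdir <- matrix(0, 2 * n_sites, 3)
  gdir[seq(1, 2 * n_sites, 2), ] <- e1
  gdir[seq(2, 2 * n_sites, 2), ] <- e2
  channels <- data.frame(
    channel = seq_len(2 * n_sites),
    site = idx,
    x = pos[idx, 1], y = pos[idx, 2], z = pos[idx, 3],
    nx = u[idx, 1], ny = u[idx, 2], nz = u[idx, 3],
    gx = gdir[, 1], gy = gdir[, 2], gz = gdir[, 3],
    baseline_m = baseline_m,
    hemisphere = ifelse(pos[idx, 1] < 0, "left", "right"),
    stringsAsFactors = FALSE)
  structure(list(channels = channels, sphere_center = c(0, 0, 0),
                 sphere_radius_m = sphere_radius_m, n_sites = n_sites),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d planar gradiometers at %d sites, sphere R = %g m\n",
              nrow(x$channels), x$n_sites, x$sphere_radius_m))
  invisible(x)
}

#' Planar-gradiometer response to a current dipole
#'
#' Each channel measures the difference of the field component along the coil
#' normal between two pick-up points straddling the site along the gradient
#' direction, divided by the baseline: a two-point realization of dB_n/dg.
#' Output is in fT/cm, the conventional planar-gradiometer unit.
#'
#' @param d a `dipole`; must lie inside the conductor sphere.
#' @param array a `sensor_array`.
#' @return numeric vector, one value per channel (fT/cm).
#' @export
gradiometer_response <- function(d, array) {
  stopifnot(inherits(d, "dipole"), inherits(array, "sensor_array"))
  if (sqrt(sum(d$position^2)) >= array$sphere_radius_m)
    stop("dipole lies outside the conductor sphere")
  ch <- array$channels
  p <- as.matrix(ch[, c("x", "y", "z")])
  g <- as.matrix(ch[, c("gx", "gy", "gz")])
  nrm <- as.matrix(ch[, c("nx", "ny", "nz")])
  b <- ch$baseline_m
  pts <- rbind(p + g * (b / 2), p - g * (b / 2))
  B <- dipole_field(d, pts)
  nch <- nrow(ch)
  bn <- rowSums(B * rbind(nrm, nrm))
  # fT/cm: delta(B.n) in fT over the baseline in cm
  (bn[seq_len(nch)] - bn[nch + seq_len(nch)]) * 1e15 / (b * 100)
}

# Lead field: n_channels x 3 matrix mapping a dipole moment at `position`
# to channel signals in fT/cm. Linear in the moment by construction.
leadfield <- function(position, array) {
  sapply(1:3, function(j) {
    m <- numeric(3); m[j] <- 1
    gradiometer_response(dipole(position, m), array)
  })
}
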