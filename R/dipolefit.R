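#' Fit an equivalent current dipole to an evoked window
#'
#' Iterative least-squares fit in the spherical conductor: the dipole
#' position is found by nonlinear minimization of the residual sum of
#' squares over the window, with the moment vector solved linearly (ordinary
#' least squares against the unit-moment forward fields) at every sample.
#' Position candidates are first screened on a 3 x 3 x 3 grid beneath the
#' hemisphere's strongest channel; Nelder-Mead simplex refinement starts
#' from the best grid points. The orientation is the first principal axis of
#' the moment timecourse; goodness of fit is the fraction of field variance
#' explained over the window.
#'
#' @param ev an `evoked`.
#' @param array the `sensor_array`.
#' @param window_ms length-2 fit window (ms), conventionally peak +/- 20.
#' @param hemisphere `"left"` or `"right"`: only that hemisphere's channels
#'   enter the fit.
#' @param n_starts number of grid candidates refined by simplex (default 2).
#' @return a `dipole_fit`: list with `position` (m), `orientation` (unit
#'   3-vector, first nonzero component positive), `moment_timecourse`
#'   (3 x n_samples, A*m), `gof`, `window_ms`, `hemisphere`, `converged`.
#' @export
fit_dipole <- function(ev, array, window_ms, hemisphere = c("left", "right"),
                       n_starts = 2) {
  stopifnot(inherits(ev, "evoked"), inherits(array, "sensor_array"))
  hemisphere <- match.arg(hemisphere)
  chans <- which(array$channels$hemisphere == hemisphere)
  sub <- subset_array(array, chans)
  sel <- which(ev$times_ms >= window_ms[1] & ev$times_ms <= window_ms[2])
  if (length(sel) < 2) stop("fit window outside the epoch")
  Y <- ev$data[chans, sel, drop = FALSE]
  ss_data <- sum(Y^2)
  if (ss_data < .Machine$double.eps) stop("degenerate (all-zero) fit window")

  R <- array$sphere_radius_m
  rss_at <- function(p) {
    if (sqrt(sum(p^2)) >= 0.95 * R) return(ss_data * (1 + sum(p^2)))  # barrier
    G <- leadfield(p, sub)
    sum((Y - G %*% ls_moment(G, Y))^2)
  }

  # grid screen beneath the strongest channel of the window
  ch_max <- chans[which.max(apply(abs(Y), 1, max))]
  u <- unlist(array$channels[array$channels$channel == ch_max, c("nx", "ny", "nz")])
  center <- u * 0.06
  offs <- c(-0.02, 0, 0.02)
  grid <- as.matrix(expand.grid(x = center[1] + offs, y = center[2] + offs,
                                z = center[3] + offs))
  grid_rss <- apply(grid, 1, rss_at)
  ord <- order(grid_rss)[seq_len(min(n_starts, nrow(grid)))]

  best <- NULL
  for (i in ord) {
    opt <- stats::optim(grid[i, ], rss_at, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  p <- best$par
  if (sqrt(sum(p^2)) >= 0.95 * R)
    stop("dipole fit did not converge to an interior position")
  G <- leadfield(p, sub)
  M <- ls_moment(G, Y)                       # 3 x n_samples moment timecourse
  rss <- sum((Y - G %*% M)^2)
  sv <- svd(M)
  ori <- sv$u[, 1]
  nz <- which(abs(ori) > 1e-12)[1]
  if (!is.na(nz) && ori[nz] < 0) ori <- -ori  # sign convention
  structure(list(position = unname(p), orientation = ori,
                 moment_timecourse = M, gof = 1 - rss / ss_data,
                 window_ms = window_ms, hemisphere = hemisphere,
                 converged = best$convergence == 0),
            class = "dipole_fit")
}

#' @export
print.dipole_fit <- function(x, ...) {
  cat(sprintf("<dipole_fit> %s: pos (%.1f, %.1f, %.1f) mm, gof %.4f, window %g..%g ms\n",
              x$hemisphere, 1000 * x$position[1], 1000 * x$position[2],
              1000 * x$position[3], x$gof, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

# least-squares moment solve via SVD pseudo-inverse: the lead field of a
# spherical conductor is rank 2 (the radial moment direction is silent), so
# an ordinary QR solve is rank-deficient by construction
ls_moment <- function(G, Y) {
  s <- svd(G)
  keep <- s$d > max(s$d) * 1e-10
  dinv <- ifelse(keep, 1 / s$d, 0)
  s$v %*% (dinv * (t(s$u) %*% Y))
}

# restrict a sensor_array to a channel subset
subset_array <- function(array, chans) {
  array$channels <- array$channels[chans, , drop = FALSE]
  array
}

#' Fit dipoles for all significant M100 components
#'
#' One fit per significant component, window = peak latency +/- 20 ms, on the
#' hemisphere the components were detected in. Non-significant components
#' are skipped; a failing fit is recorded (with its error message) without
#' aborting the batch.
#'
#' @param ev an `evoked`.
#' @param array the `sensor_array`.
#' @param components 4-row component data.frame from [count_m100()].
#' @param hemisphere hemisphere label for the fits.
#' @param halfwidth_ms fit window half-width (default 20).
#' @return data.frame, one row per fitted component: `component_index`,
#'   `hemisphere`, `x_mm`, `y_mm`, `z_mm`, `ox`, `oy`, `oz`, `gof`,
#'   `window_lo_ms`, `window_hi_ms`, `error`.
#' @export
fit_all_components <- function(ev, array, components,
                               hemisphere = c("left", "right"),
                               halfwidth_ms = 20) {
  hemisphere <- match.arg(hemisphere)
  sig <- components[which(components$significant), , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(sig))) {
    lat <- sig$peak_latency_ms[i]
    win <- c(lat - halfwidth_ms, lat + halfwidth_ms)
    row <- data.frame(component_index = sig$index[i], hemisphere = hemisphere,
                      x_mm = NA_real_, y_mm = NA_real_, z_mm = NA_real_,
                      ox = NA_real_, oy = NA_real_, oz = NA_real_,
                      gof = NA_real_, window_lo_ms = win[1], window_hi_ms = win[2],
                      error = NA_character_, stringsAsFactors = FALSE)
    fit <- tryCatch(fit_dipole(ev, array, win, hemisphere),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      row$error <- conditionMessage(fit)
    } else {
      row[c("x_mm", "y_mm", "z_mm")] <- as.list(1000 * fit$position)
      row[c("ox", "oy", "oz")] <- as.list(fit$orientation)
      row$gof <- fit$gof
    }
    out <- rbind(out, row)
  }
  if (is.null(out))
    out <- data.frame(component_index = integer(0), hemisphere = character(0),
                      x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      ox = numeric(0), oy = numeric(0), oz = numeric(0),
                      gof = numeric(0), window_lo_ms = numeric(0),
                      window_hi_ms = numeric(0), error = character(0),
                      stringsAsFactors = FALSE)
  out
}
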