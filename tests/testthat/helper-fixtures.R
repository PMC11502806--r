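# Shared fixtures and independent oracles. Everything here is generated in
# code at test time; no stored data.

tiny_array <- function(n_sites = 16) default_sensor_array(n_sites = n_sites)

# a quiet, fast simulator configuration for unit tests
quick_cfg <- function(...) {
  default_sim_config(n_epochs = 24, artifact_fraction = 0, ...)
}

# evoked container straight from a channels x times matrix
make_evoked <- function(data, times_ms = seq(-100, 900), rate_hz = 1000) {
  structure(list(data = data, times_ms = times_ms, rate_hz = rate_hz,
                 t0_ms = times_ms[1], n_epochs_averaged = 1L,
                 processing_log = "constructed"),
            class = "evoked")
}

# all permutations of a vector (for the Spearman enumeration oracle)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

# exact two-sided Spearman p by enumeration over all rank permutations
exact_spearman_p <- function(x, y) {
  rho_obs <- cor(rank(x), rank(y))
  rhos <- vapply(all_perms(seq_along(x)),
                 function(p) cor(seq_along(x), p), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# exact two-sided Wilcoxon signed-rank p by enumeration over sign patterns
exact_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  mu <- n * (n + 1) / 4
  w_obs <- sum(r[d > 0])
  wplus <- vapply(0:(2^n - 1), function(m)
    sum(r[as.logical(bitwAnd(m, 2^(0:(n - 1))))]), numeric(1))
  mean(abs(wplus - mu) >= abs(w_obs - mu) - 1e-9)
}

# Wilks' Lambda by the independent eigendecomposition route
eigen_wilks <- function(A, B) {
  Wm <- crossprod(scale(A, scale = FALSE)) + crossprod(scale(B, scale = FALSE))
  ma <- colMeans(A); mb <- colMeans(B); m <- colMeans(rbind(A, B))
  Bm <- nrow(A) * tcrossprod(ma - m) + nrow(B) * tcrossprod(mb - m)
  prod(1 / (1 + Re(eigen(solve(Wm) %*% Bm, only.values = TRUE)$values)))
}

# unit tangential moment (anterior direction projected onto the tangent plane)
tangential_unit <- function(pos) {
  u <- pos / sqrt(sum(pos^2))
  m <- c(0, 1, 0) - sum(c(0, 1, 0) * u) * u
  m / sqrt(sum(m^2))
}

# dominant spectral peak (Hz) of a snippet within a frequency band
spectral_peak <- function(x, rate_hz, band) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  m <- Mod(stats::fft(x * w))[1:(n %/% 2)]
  f <- (0:(n %/% 2 - 1)) * rate_hz / n
  sel <- f >= band[1] & f <= band[2]
  f[sel][which.max(m[sel])]
}
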