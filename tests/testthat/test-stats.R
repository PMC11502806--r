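test_that("Spearman rho matches monotone expectations and base R", {
  expect_equal(spearman(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman(1:4, c(40, 30, 20, 10))$rho, -1)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  expect_equal(spearman(x, y)$rho,
               unname(stats::cor.test(x, y, method = "spearman", exact = FALSE)$estimate))
  expect_error(spearman(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman(1:2, 1:2), "3")
})

test_that("Spearman agrees with the permutation enumeration oracle", {
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  r <- spearman(x, y)
  rhos <- vapply(all_perms(1:5), function(p) cor(1:5, p), numeric(1))
  expect_true(any(abs(rhos - r$rho) < 1e-12))       # rho attained by its ranks
  expect_equal(r$rho, 0.8)
  p_exact <- exact_spearman_p(x, y)
  expect_lt(abs(r$p_value - p_exact), 0.05)         # t approximation at n = 5
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(21)
  x <- stats::rnorm(12); y <- stats::rnorm(12)
  r0 <- spearman(x, y)$rho
  expect_equal(spearman(exp(x), y)$rho, r0)
  expect_equal(spearman(x, y^3 + 2 * y)$rho, r0)
  expect_equal(spearman(x, x)$rho, 1)
})

test_that("Wilcoxon matches its construction and the enumeration oracle", {
  w0 <- wilcoxon_signed_rank(1:6, (1:6) + 2)        # uniform shift
  expect_identical(w0$W, 0)
  sym <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3), rep(0, 6))
  expect_equal(sym$z, 0)
  expect_equal(sym$p_asymptotic, 1)
  for (s in c(3, 5, 8)) {
    set.seed(s)
    xa <- round(stats::rnorm(8), 2); xb <- round(xa + stats::rnorm(8, 0.6), 2)
    r <- wilcoxon_signed_rank(xa, xb)
    expect_lt(abs(r$p_asymptotic - exact_wilcoxon_p(xa, xb)), 0.02)
    # symmetry under swapping the pair order
    r2 <- wilcoxon_signed_rank(xb, xa)
    expect_equal(r$p_asymptotic, r2$p_asymptotic)
    expect_equal(r$W, r2$W)
  }
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
})

test_that("Wilks' Lambda matches the eigendecomposition oracle and MANOVA", {
  set.seed(9)
  A <- matrix(stats::rnorm(120), 20, 6)
  B <- matrix(stats::rnorm(120, 0.5), 20, 6)
  dw <- discriminant_wilks(A, B)
  expect_lt(abs(dw$wilks_lambda - eigen_wilks(A, B)), 1e-10)
  g <- factor(rep(1:2, each = 20))
  mv <- summary(stats::manova(rbind(A, B) ~ g), test = "Wilks")$stats[1, 2]
  expect_lt(abs(dw$wilks_lambda - unname(mv)), 1e-10)
  expect_true(dw$wilks_lambda > 0 && dw$wilks_lambda < 1)
})

test_that("Wilks' Lambda limits and invariances hold", {
  set.seed(10)
  A <- matrix(stats::rnorm(60), 10, 6)
  same <- discriminant_wilks(A, A)
  expect_equal(same$wilks_lambda, 1)
  expect_gt(same$p_value, 0.99)
  far <- discriminant_wilks(A, A + 100)
  expect_lt(far$wilks_lambda, 1e-3)
  # affine change of basis applied to both groups
  M <- matrix(stats::rnorm(36), 6, 6) + 3 * diag(6)
  b <- stats::rnorm(6)
  B <- matrix(stats::rnorm(60, 0.5), 10, 6)
  l1 <- discriminant_wilks(A, B)$wilks_lambda
  l2 <- discriminant_wilks(sweep(A %*% M, 2, b, "+"),
                           sweep(B %*% M, 2, b, "+"))$wilks_lambda
  expect_equal(l1, l2, tolerance = 1e-8)
  expect_error(discriminant_wilks(A[1:4, ], B), "observations")
})

test_that("orientation sign normalization removes antiparallel duplicates", {
  o <- rbind(c(0.6, 0.8, 0), c(-0.6, -0.8, 0), c(0, -1, 0))
  n <- normalize_orientation_sign(o)
  expect_equal(n[1, ], n[2, ])
  expect_equal(n[3, ], c(0, 1, 0))
})

test_that("the composite report has the full pairwise-comparison layout", {
  set.seed(33)
  durs <- seq(75, 600, by = 75)
  beh <- simulate_behavior(durs, 8, seed = 2)
  det <- beh
  names(det)[names(det) == "perceived_count"] <- "n_significant"
  det$n_significant <- pmin(4L, det$n_significant +
                              stats::rbinom(nrow(det), 1, 0.2))
  fits <- do.call(rbind, lapply(c("left", "right"), function(h)
    do.call(rbind, lapply(1:4, function(k)
      data.frame(participant_id = 1:8, component_index = k, hemisphere = h,
                 x_mm = stats::rnorm(8, ifelse(k == 1, 62, 57)),
                 y_mm = stats::rnorm(8, 6), z_mm = stats::rnorm(8, 27),
                 ox = stats::rnorm(8, 0.1), oy = stats::rnorm(8, 0.9),
                 oz = stats::rnorm(8, 0.3))))))
  rep <- analysis_report(beh, det, fits)
  expect_identical(nrow(rep$correlations), 3L)
  expect_true(all(rep$correlations$rho > 0))
  expect_lt(rep$correlations$p_value[1], 0.05)
  expect_identical(nrow(rep$discriminant), 12L)
  expect_identical(sort(unique(rep$discriminant$comparison)),
                   c("1 vs. 2", "1 vs. 3", "1 vs. 4",
                     "2 vs. 3", "2 vs. 4", "3 vs. 4"))
  expect_identical(sort(unique(rep$discriminant$hemisphere)), c("left", "right"))
  expect_identical(nrow(rep$wilcoxon), 14L)          # 7 conditions x 2 measures
  # single condition: correlations skipped with a warning
  b1 <- beh[beh$duration_ms == 600, ]
  d1 <- det[det$duration_ms == 600, ]
  expect_warning(r1 <- analysis_report(b1, d1), "single condition")
  expect_null(r1$correlations)
})
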