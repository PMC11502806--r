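#' Spearman rank correlation with a significance test
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties); the
#' p-value uses the t approximation with n - 2 degrees of freedom, adequate
#' at the pooled participant-by-condition sample sizes this pipeline
#' produces.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n_pairs`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant input vector")
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p_value = min(p, 1), n_pairs = n)
}

#' Wilcoxon signed-rank test (asymptotic)
#'
#' Paired test: zero differences are dropped, ties of |difference| get
#' mid-ranks, W is the smaller signed-rank sum, and z uses the normal
#' approximation with the tie correction and a 0.5 continuity correction
#' (which keeps the asymptotic p within 0.02 of the exact permutation p at
#' n = 8); the p-value is two-sided.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `W`, `z`, `p_asymptotic`, `n_effective`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) stop("degenerate variance (all differences tied at one rank)")
  z <- sign(w_pos - mu) * max(abs(w_pos - mu) - 0.5, 0) / sqrt(sig2)
  p <- min(2 * stats::pnorm(-abs(z)), 1)
  list(W = W, z = z, p_asymptotic = p, n_effective = n)
}

#' Two-group discriminant analysis via Wilks' Lambda
#'
#' Tests for a difference in multivariate group means: Lambda = det(W) /
#' det(W + B) with W and B the within- and between-group cross-product
#' matrices; the p-value uses Bartlett's chi-square approximation with
#' p (number of variables) degrees of freedom for two groups. Smaller Lambda
#' means more separation.
#'
#' @param group_a,group_b numeric matrices (rows = observations, columns =
#'   the variables, e.g. x, y, z position and the three orientation
#'   components); each group must have more rows than variables.
#' @return list with `wilks_lambda`, `p_value`, `group_sizes`, `n_variables`.
#' @export
discriminant_wilks <- function(group_a, group_b) {
  A <- as.matrix(group_a); B2 <- as.matrix(group_b)
  p <- ncol(A)
  if (ncol(B2) != p) stop("groups must share the same variables")
  na <- nrow(A); nb <- nrow(B2)
  if (na <= p || nb <= p)
    stop("each group needs more observations than variables; reduce variables")
  X <- rbind(A, B2)
  n <- na + nb
  ma <- colMeans(A); mb <- colMeans(B2); m <- colMeans(X)
  Wm <- crossprod(sweep(A, 2, ma)) + crossprod(sweep(B2, 2, mb))
  Bm <- na * tcrossprod(ma - m) + nb * tcrossprod(mb - m)
  dW <- det(Wm)
  dT <- det(Wm + Bm)
  if (!is.finite(dW) || dW <= 0 || dT <= 0)
    stop("singular within-group matrix; consider reducing the variable set")
  lambda <- dW / dT
  g <- 2
  chi2 <- -(n - 1 - (p + g) / 2) * log(lambda)
  p_value <- stats::pchisq(chi2, df = p * (g - 1), lower.tail = FALSE)
  list(wilks_lambda = lambda, p_value = p_value,
       group_sizes = c(na, nb), n_variables = p)
}

#' Normalize dipole orientation signs
#'
#' Makes the first nonzero component of each orientation row positive, so
#' antiparallel duplicates of the same axis do not inflate group separation
#' in the discriminant analysis.
#'
#' @param ori matrix with orientation columns (e.g. ox, oy, oz).
#' @return the sign-normalized matrix.
#' @export
normalize_orientation_sign <- function(ori) {
  ori <- as.matrix(ori)
  t(apply(ori, 1, function(v) {
    nz <- which(abs(v) > 1e-12)[1]
    if (!is.na(nz) && v[nz] < 0) -v else v
  }))
}

#' Compose the full statistical report
#'
#' Computes the three Spearman correlations (perceived count vs duration,
#' duration vs detected M100 count, perceived vs detected count) on aligned
#' participant-by-condition pairs and on condition means; the per-condition
#' Wilcoxon signed-rank tests of each stimulus against the longest-duration
#' condition; and the pairwise component-versus-component discriminant tests
#' on dipole position and orientation per hemisphere (six row labels
#' "1 vs. 2" .. "3 vs. 4").
#'
#' @param behavior data.frame from [simulate_behavior()] (columns
#'   `participant_id`, `duration_ms`, `perceived_count`).
#' @param detections data.frame with `participant_id`, `duration_ms`,
#'   `n_significant`.
#' @param fits data.frame of dipole fits with `participant_id`,
#'   `component_index`, `hemisphere`, `x_mm`, `y_mm`, `z_mm`, `ox`, `oy`,
#'   `oz` (may be NULL to skip the discriminant block).
#' @param reference_ms the reference condition for the Wilcoxon tests
#'   (default the maximum duration present).
#' @return list with `correlations`, `correlations_condition_means`,
#'   `wilcoxon`, `discriminant` data.frames.
#' @export
analysis_report <- function(behavior, detections, fits = NULL,
                            reference_ms = NULL) {
  merged <- merge(behavior, detections, by = c("participant_id", "duration_ms"))
  if (nrow(merged) == 0) stop("behavior and detection tables share no labels")
  if (is.null(reference_ms)) reference_ms <- max(merged$duration_ms)
  durs <- sort(unique(merged$duration_ms))

  cor_rows <- function(df) {
    pairs <- list(
      c("perceived_count", "duration_ms"),
      c("duration_ms", "n_significant"),
      c("perceived_count", "n_significant"))
    do.call(rbind, lapply(pairs, function(pr) {
      r <- tryCatch(spearman(df[[pr[1]]], df[[pr[2]]]),
                    error = function(e) list(rho = NA, p_value = NA,
                                             n_pairs = nrow(df)))
      data.frame(pair = paste(pr[1], "vs", pr[2]), rho = r$rho,
                 p_value = r$p_value, n_pairs = r$n_pairs,
                 stringsAsFactors = FALSE)
    }))
  }
  correlations <- if (length(durs) < 2) {
    warning("single condition only; correlation stage skipped")
    NULL
  } else cor_rows(merged)
  cond_means <- stats::aggregate(
    merged[c("perceived_count", "n_significant")],
    by = list(duration_ms = merged$duration_ms), FUN = mean)
  correlations_means <- if (length(durs) < 3) NULL else cor_rows(cond_means)

  wilcoxon <- NULL
  ref <- merged[merged$duration_ms == reference_ms, ]
  ref <- ref[order(ref$participant_id), ]
  for (d in setdiff(durs, reference_ms)) {
    cur <- merged[merged$duration_ms == d, ]
    cur <- cur[order(cur$participant_id), ]
    for (vbl in c("perceived_count", "n_significant")) {
      r <- tryCatch(wilcoxon_signed_rank(cur[[vbl]], ref[[vbl]]),
                    error = function(e) list(W = NA, z = NA, p_asymptotic = NA))
      wilcoxon <- rbind(wilcoxon, data.frame(
        duration_ms = d, reference_ms = reference_ms, measure = vbl,
        W = r$W, z = r$z, p_asymptotic = r$p_asymptotic,
        stringsAsFactors = FALSE))
    }
  }

  discriminant <- NULL
  if (!is.null(fits) && nrow(fits) > 0) {
    vars <- c("x_mm", "y_mm", "z_mm", "ox", "oy", "oz")
    fits <- fits[stats::complete.cases(fits[vars]), ]
    fits[c("ox", "oy", "oz")] <-
      normalize_orientation_sign(fits[c("ox", "oy", "oz")])
    for (h in c("left", "right")) {
      fh <- fits[fits$hemisphere == h, ]
      for (i in 1:3) for (j in (i + 1):4) {
        ga <- as.matrix(fh[fh$component_index == i, vars])
        gb <- as.matrix(fh[fh$component_index == j, vars])
        r <- tryCatch(discriminant_wilks(ga, gb),
                      error = function(e) list(wilks_lambda = NA, p_value = NA,
                                               group_sizes = c(nrow(ga), nrow(gb))))
        discriminant <- rbind(discriminant, data.frame(
          hemisphere = h, comparison = sprintf("%d vs. %d", i, j),
          wilks_lambda = r$wilks_lambda, p_value = r$p_value,
          n_a = r$group_sizes[1], n_b = r$group_sizes[2],
          stringsAsFactors = FALSE))
      }
    }
  }
  list(correlations = correlations,
       correlations_condition_means = correlations_means,
       wilcoxon = wilcoxon, discriminant = discriminant)
}
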