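#' @title Statistical kernels with exact small-sample behaviour
#' @description Paired Wilcoxon signed-rank and Mann-Whitney U tests with
#'   tie-aware full enumeration of the permutation null at small n (normal
#'   approximation with tie correction above), the Benjamini-Hochberg
#'   step-up FDR adjustment, and the D'Agostino-Pearson omnibus normality
#'   test. These are the tests of the study's analysis battery.
#' @name stat-kernels
NULL

.new_test_result <- function(name, statistic, p_raw, method,
                             n = NA_integer_, degenerate = FALSE,
                             family = NA_character_) {
  structure(list(name = name, statistic = statistic, p_raw = p_raw,
                 p_adjusted = NA_real_, significant = NA,
                 method = method, n = n, degenerate = degenerate,
                 family = family),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %.4g%s%s\n", x$method, x$statistic,
              x$p_raw,
              if (!is.na(x$p_adjusted))
                sprintf(", adjusted p = %.4g", x$p_adjusted) else "",
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Zero differences are
#' dropped (classic convention). For `n <= exact_max` non-zero differences
#' the p value comes from full enumeration of all `2^n` sign assignments of
#' the midranks of `|d|` (exact even under ties); above that, from the
#' normal approximation with the tie-corrected variance `sum(r^2)/4` and a
#' continuity correction. If every difference is zero, the test is
#' degenerate and returns p = 1 with `degenerate = TRUE`.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest n for which the exact null is enumerated.
#' @param name,family Identifiers stored in the result.
#' @return A `test_result` with statistic `W` (sum of positive-difference
#'   ranks).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 15, name = "wilcoxon",
                                 family = NA_character_) {
  if (length(x) != length(y)) stop("length mismatch between paired samples")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(.new_test_result(name, NA_real_, 1, "Wilcoxon signed-rank",
                            n = 0L, degenerate = TRUE, family = family))
  if (n < 3) stop("need >= 3 non-zero differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p <- mean(abs(w_all - mu) >= abs(w - mu) - 1e-9)
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    p <- 2 * stats::pnorm(-max(abs(w - mu) - 0.5, 0) / sigma)
    p <- min(p, 1)
  }
  .new_test_result(name, w, p, "Wilcoxon signed-rank", n = as.integer(n),
                   family = family)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment: on the sorted p values,
#' `p_adj(i) = min over j >= i of (m/j) p(j)`, capped at 1 and mapped back
#' to input order; the rejection set is `p_adj <= alpha`.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @param alpha FDR level.
#' @return List with `adjusted` (same order as input) and `rejected`
#'   (logical).
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  adj_sorted <- pmin(rev(cummin(rev(p_values[o] * m / seq_len(m)))), 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, rejected = adjusted <= alpha)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis z statistics into
#' `K^2 = z_s^2 + z_k^2`, referred to a chi-squared distribution with 2
#' degrees of freedom.
#'
#' @param x Numeric sample, n >= 8.
#' @param name,family Identifiers stored in the result.
#' @return A `test_result` with statistic `K^2`.
#' @export
dagostino_pearson <- function(x, name = "dagostino_pearson",
                              family = NA_character_) {
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson statistic undefined for n < 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance sample")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2

  # skewness z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  a <- sqrt(2 / (w2 - 1))
  zs <- delta * log(y / a + sqrt((y / a)^2 + 1))

  # kurtosis z (Anscombe-Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  zk <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))

  k2 <- zs^2 + zk^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  .new_test_result(name, k2, p, "D'Agostino-Pearson K2", n = as.integer(n),
                   family = family)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test for two independent samples. For
#' `n_a + n_b <= exact_max` the p value comes from full enumeration of all
#' `choose(n_a + n_b, n_a)` group assignments of the pooled midranks
#' (exact even under ties); above that, from the normal approximation with
#' tie-corrected variance.
#'
#' @param a,b Non-empty numeric samples.
#' @param exact_max Largest pooled size for which the exact null is
#'   enumerated.
#' @param name,family Identifiers stored in the result.
#' @return A `test_result` with statistic `U` (of sample `a`).
#' @export
mann_whitney_u <- function(a, b, exact_max = 12, name = "mann_whitney",
                           family = NA_character_) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("empty group")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  n <- na + nb
  if (n <= exact_max) {
    combos <- utils::combn(n, na)
    ra_all <- colSums(matrix(r[combos], nrow = na))
    u_all <- ra_all - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      p <- min(2 * stats::pnorm(-max(abs(u - mu) - 0.5, 0) / sigma), 1)
    }
  }
  .new_test_result(name, u, p, "Mann-Whitney U", n = as.integer(n),
                   family = family)
}

#' Pearson correlation with strength category
#'
#' Pearson correlation coefficient, least-squares regression slope and
#' coefficient of determination, plus the conventional strength category
#' of `|rho|`: < 0.2 negligible, 0.2-0.4 weak, 0.4-0.6 moderate, 0.6-0.8
#' strong, > 0.8 very strong.
#'
#' @param x Covariate (e.g. age, years).
#' @param y Response (e.g. CBF variation, ml/min/100 g).
#' @return An object of class `correlation_result`: list with `rho`,
#'   `slope_m` (units of y per unit of x), `r_squared`, `category`, `n`.
#' @export
pearson_with_category <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need n >= 3")
  if (.pop_sd(x) == 0 || .pop_sd(y) == 0) stop("constant input")
  rho <- stats::cor(x, y)
  slope <- stats::cov(x, y) / stats::var(x)
  cuts <- c(0.2, 0.4, 0.6, 0.8)
  cats <- c("negligible", "weak", "moderate", "strong", "very strong")
  category <- cats[findInterval(abs(rho), cuts, left.open = TRUE) + 1]
  structure(list(rho = rho, slope_m = slope, r_squared = rho^2,
                 category = category, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson rho = %.3f (%s), m = %.3f, R2 = %.3f, n = %d\n",
              x$rho, x$category, x$slope_m, x$r_squared, x$n))
  invisible(x)
}

#' TI-dependent CBF variation of one VOI
#'
#' `CBF(ti_b) - CBF(ti_a)` for a given subject and VOI from a regional
#' table holding both TIs; positive in distal territories and negative in
#' proximal territories under the transit-time/intravascular mechanism.
#'
#' @param table Regional table (rows from [regional_table()], both TIs).
#' @param subject Subject identifier.
#' @param voi VOI name (e.g. `"occipital"`).
#' @param hemisphere `"L"`, `"R"` or `NA` for unpaired rows.
#' @param ti_a,ti_b The two inversion times, ms.
#' @return CBF variation, ml/min/100 g.
#' @export
cbf_variation <- function(table, subject, voi, hemisphere = NA,
                          ti_a = 1500, ti_b = 2020) {
  pick <- function(ti) {
    sel <- table$subject == subject & table$voi == voi & table$ti == ti &
      (is.na(hemisphere) & is.na(table$hemisphere) |
         !is.na(table$hemisphere) & !is.na(hemisphere) &
         table$hemisphere == hemisphere)
    sel[is.na(sel)] <- FALSE
    row <- table[sel, ]
    if (nrow(row) != 1)
      stop("missing (or ambiguous) row for TI ", ti, ", VOI ", voi)
    row$mean_cbf
  }
  pick(ti_b) - pick(ti_a)
}
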