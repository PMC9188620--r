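test_that("signed-rank test matches the enumeration oracle and wilcox.test", {
  # all-positive differences, n = 5: the most extreme table, p = 2/32
  x <- c(5, 6, 7, 8, 9); y <- c(1, 2, 3, 4, 5)
  tr <- wilcoxon_signed_rank(x, y)
  expect_equal(tr$p_raw, 2 / 32)
  expect_equal(tr$statistic, 15)
  set.seed(10)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    if (i %% 3 == 0) { a <- round(a, 1); b <- round(b, 1) }  # induce ties
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    if (length(a) < 3) next
    tr <- wilcoxon_signed_rank(a, b)
    expect_equal(tr$p_raw, oracle_wilcoxon(a, b))
    if (!any(duplicated(abs(a - b))))
      expect_equal(tr$p_raw,
                   wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
  }
})

test_that("signed-rank degeneracy and preconditions are handled", {
  tr <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(tr$degenerate)
  expect_equal(tr$p_raw, 1)
  expect_error(wilcoxon_signed_rank(1:4, 1:3), "length mismatch")
  expect_error(wilcoxon_signed_rank(c(1, 2), c(2, 1)), ">= 3")
})

test_that("signed-rank exact and approximate paths agree for moderate n", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(14); y <- rnorm(14)
    pe <- wilcoxon_signed_rank(x, y, exact_max = 15)$p_raw
    pa <- wilcoxon_signed_rank(x, y, exact_max = 5)$p_raw
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(9); y <- rnorm(9)
  f <- function(v) exp(3 * v) - 1
  expect_equal(wilcoxon_signed_rank(x, y)$p_raw,
               # paired test needs a difference-monotone map: use ranks via
               # a common shift instead
               wilcoxon_signed_rank(x + 100, y + 100)$p_raw)
  a <- rnorm(5); b <- rnorm(6)
  expect_equal(mann_whitney_u(a, b)$p_raw,
               mann_whitney_u(f(a), f(b))$p_raw)
})

test_that("Benjamini-Hochberg matches the step-up oracle and p.adjust", {
  expect_equal(benjamini_hochberg(0.03)$adjusted, 0.03)
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  bh <- benjamini_hochberg(p4)
  expect_equal(bh$adjusted, oracle_bh(p4))
  expect_equal(bh$adjusted, p.adjust(p4, "BH"))
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))^sample(1:3, 1)
    adj <- benjamini_hochberg(p)$adjusted
    expect_equal(adj, oracle_bh(p))
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("BH rejections shrink as alpha decreases", {
  set.seed(14)
  p <- runif(30)^2
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  rej <- lapply(alphas, function(a) which(benjamini_hochberg(p, a)$rejected))
  for (i in 2:length(alphas))
    expect_true(all(rej[[i]] %in% rej[[i - 1]]))
})

test_that("normality test rejects skewed data and enforces minimum n", {
  expect_error(dagostino_pearson(rnorm(5)), "n < 8")
  set.seed(15)
  hits <- mean(replicate(200, dagostino_pearson(rexp(200))$p_raw < 0.05))
  expect_gte(hits, 0.9)
  # near-normal sample should usually not be rejected
  calm <- mean(replicate(200, dagostino_pearson(rnorm(200))$p_raw < 0.05))
  expect_lt(calm, 0.12)
})

test_that("Mann-Whitney matches enumeration, including the textbook case", {
  tr <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tr$statistic, 0)
  expect_equal(tr$p_raw, 0.1)
  expect_equal(mann_whitney_u(c(2, 1, 3), c(1, 2, 3))$p_raw, 1)
  set.seed(16)
  for (i in 1:25) {
    na <- sample(3:5, 1); nb <- sample(3:5, 1)
    a <- rnorm(na); b <- rnorm(nb)
    if (i %% 3 == 0) { a <- round(a); b <- round(b) }  # heavy ties
    tr <- mann_whitney_u(a, b)
    expect_equal(tr$p_raw, oracle_mann_whitney(a, b))
    if (!any(duplicated(c(a, b))))
      expect_equal(tr$p_raw, wilcox.test(a, b, exact = TRUE)$p.value)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney exact and approximate paths agree for moderate n", {
  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    pe <- mann_whitney_u(a, b, exact_max = 12)$p_raw
    pa <- mann_whitney_u(a, b, exact_max = 5)$p_raw
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Pearson correlation reports slope, R2 and strength category", {
  x <- 1:6
  cr <- pearson_with_category(x, 2 * x + 1)
  expect_equal(cr$rho, 1)
  expect_equal(cr$slope_m, 2)
  expect_equal(cr$r_squared, 1)
  expect_equal(cr$category, "very strong")
  # construct a sample with |rho| exactly 0.5
  e <- c(1, -1, 1, -1, 1, -1)
  e <- e - mean(e); e <- e / pop_sd_oracle(e)
  xs <- (x - mean(x)) / pop_sd_oracle(x)
  y5 <- 0.5 * xs + sqrt(0.75) * (e - sum(e * xs) / 6 * xs) /
    pop_sd_oracle(e - sum(e * xs) / 6 * xs)
  cr5 <- pearson_with_category(x, y5)
  expect_equal(abs(cr5$rho), 0.5, tolerance = 1e-10)
  expect_equal(cr5$category, "moderate")
  # textbook sum formula on a 5-point toy
  xt <- c(1, 3, 4, 6, 8); yt <- c(2, 3, 7, 5, 9)
  n <- 5
  num <- n * sum(xt * yt) - sum(xt) * sum(yt)
  den <- sqrt(n * sum(xt^2) - sum(xt)^2) * sqrt(n * sum(yt^2) - sum(yt)^2)
  expect_equal(pearson_with_category(xt, yt)$rho, num / den)
  expect_error(pearson_with_category(c(1, 1, 1), 1:3), "constant")
  expect_error(pearson_with_category(1:2, 1:2), "n >= 3")
})

test_that("CBF variation extracts the paired TI difference", {
  tab <- data.frame(
    subject = "s1", ti = c(1500, 2020, 1500, 2020),
    voi = c("occipital", "occipital", "cerebral_cortex", "cerebral_cortex"),
    hemisphere = c("L", "L", NA, NA),
    n_voxels = 10, mean_cbf = c(40, 45, 38, 38),
    z_voi = NA_real_, stringsAsFactors = FALSE)
  expect_equal(cbf_variation(tab, "s1", "occipital", "L"), 5)
  expect_equal(cbf_variation(tab, "s1", "cerebral_cortex", NA), 0)
  expect_error(cbf_variation(tab, "s1", "insular", "L"), "missing")
})
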