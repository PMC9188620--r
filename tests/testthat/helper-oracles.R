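# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: numeric integration for the kinetic model,
# full enumeration for the permutation nulls, explicit step-up for BH.

# plug-flow bolus with T1 decay, integrated numerically: labeled blood
# arrives at constant rate during [att, att + ti1), every element carries
# decay exp(-TI/T1b) at readout
oracle_tissue_dm <- function(f, att, ti, ti1 = 700, alpha = 0.98,
                             t1b = 1650, m0b = 1000, lambda = 0.9) {
  integrand <- function(t) {
    as.numeric(t >= att & t < att + ti1) * exp(-ti / t1b)
  }
  lo <- 0; hi <- ti
  knots <- sort(unique(pmin(pmax(c(lo, att, att + ti1, hi), lo), hi)))
  total <- 0
  for (i in seq_len(length(knots) - 1)) {
    if (knots[i + 1] > knots[i])
      total <- total + stats::integrate(integrand, knots[i], knots[i + 1],
                                        rel.tol = 1e-10)$value
  }
  2 * alpha * m0b * (f / (6000 * lambda)) * (total / 1000)
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  mean(abs(w_all - mu) >= abs(w - mu) - 1e-9)
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mann_whitney <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# literal step-up: p_adj(i) = min_{j >= i} (m / j) p_(j), capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

pop_sd_oracle <- function(x) sqrt(sum((x - mean(x))^2) / length(x))

# small phantom configuration used across module tests (fast grid)
tiny_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_subjects = 3, seed = seed,
                   grid_shape = c(16, 16, 6),
                   voxel_size = c(15, 15, 17.5))
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(cohort_config, args)
}

# noise-free, delay-free configuration for exact checks
exact_config <- function(seed = 1, ...) {
  tiny_config(seed = seed, att_pta_ms = c(0, 0), att_dta_ms = c(1, 0),
              att_watershed_ms = c(2, 0), gm_cbf = c(60, 0),
              wm_cbf = c(60, 0), abv_pta = 0, noise_sd = 0,
              att_voxel_sd = 0, cbf_voxel_sd = 0, ...)
}
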