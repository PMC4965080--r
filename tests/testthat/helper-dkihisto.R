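# Shared helpers: independent oracles and small fixture builders.

study_bvalues <- c(150, 600, 1050, 1500)

# Forward kurtosis signal by direct scalar arithmetic (independent of
# dki_signal's implementation path).
oracle_signal <- function(b, s0, d, k) {
  s0 * exp(-b * d + b^2 * d^2 * k / 6)
}

# Exact two-sided rank-sum p-value by enumeration of every group
# assignment of the pooled sample.
oracle_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  w_all <- apply(combs, 2L, function(idx) sum(r[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Rank-Pearson Spearman oracle.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small one-region phantom series with given truth.
make_uniform_series <- function(shape, s0 = 100, d = 2e-3, k = 0.6,
                                bvalues = study_bvalues) {
  region <- phantom_region("box", center = (shape + 1) / 2,
                           halfsize = shape, s0 = s0, d_app = d, k_app = k)
  simulate_dwi_phantom(shape, list(region), bvalues = bvalues, sigma = 0)
}

# Continuous (unquantised) hexcone HSV -> RGB conversion, so that hue
# round-trips exactly through rgb2hsv in tests.
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  cbind(
    ifelse(i == 0 | i == 5, v, ifelse(i == 1, q, ifelse(i == 4, t, p))),
    ifelse(i == 1 | i == 2, v, ifelse(i == 0, t, ifelse(i == 3, q, p))),
    ifelse(i == 3 | i == 4, v, ifelse(i == 2, t, ifelse(i == 5, q, p)))
  )
}

# Exact Rician mean E|S + complex noise| via the half-order Laguerre form.
rice_mean <- function(S, sigma) {
  x <- S^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) * exp(-x / 2) *
    ((1 + x) * besselI(x / 2, 0) + x * besselI(x / 2, 1))
}

# Solid-colour RGB image block.
solid_rgb <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3L))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
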