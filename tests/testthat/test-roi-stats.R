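test_that("ROI medians follow the order-statistic rules and exclude sentinels", {
  arr <- function(v) array(v, dim = c(length(v), 1, 1))
  full <- function(v) array(TRUE, dim = c(length(v), 1, 1))
  expect_equal(as.numeric(roi_median(arr(c(1, 2, 3)), full(1:3))), 2)
  expect_equal(as.numeric(roi_median(arr(c(1, 2, 3, 10)), full(1:4))), 2.5)
  m <- roi_median(arr(c(2, NaN, 4)), full(1:3))
  expect_equal(as.numeric(m), 3)
  expect_equal(attr(m, "n_excluded"), 1)
  expect_error(roi_median(arr(c(NA, NaN)), full(1:2)), "non-missing")
})

test_that("rank-sum exact p-values equal brute-force enumeration", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(rank_sum_test(c(1, 2, 3), c(101, 102, 103))$p_value, 0.1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(91)
  for (i in 1:30) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(100, n1); y <- sample(200:300, n2)[seq_len(n2)]
    r <- rank_sum_test(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, oracle_rank_sum_p(x, y), tolerance = 1e-12)
    # symmetry under group swap
    expect_equal(rank_sum_test(y, x)$p_value, r$p_value)
  }
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("large or tied samples use the normal approximation", {
  x <- c(1, 1, 2, 5); y <- c(2, 3, 3, 8)
  expect_equal(rank_sum_test(x, y)$method, "normal_approx")
  r <- rank_sum_test(rnorm(15), rnorm(15))
  expect_equal(r$method, "normal_approx")
  expect_true(r$p_value >= 0 && r$p_value <= 1)
})

test_that("Spearman correlation matches the midrank-Pearson oracle", {
  expect_equal(spearman_correlation(1:6, (1:6)^3)$statistic, 1)
  expect_equal(spearman_correlation(1:6, -(1:6))$statistic, -1)
  r <- spearman_correlation(1:4, c(1, 1, 3, 4))
  expect_equal(r$statistic, 4.5 / sqrt(22.5))
  set.seed(92)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- sample(c(rnorm(n - 2), rnorm(1)[c(1, 1)]))
    s <- spearman_correlation(x, y)
    expect_equal(s$statistic, oracle_spearman(x, y), tolerance = 1e-12)
    # invariance under strictly monotone transforms, antisymmetry
    expect_equal(spearman_correlation(exp(x), y)$statistic, s$statistic)
    expect_equal(spearman_correlation(x, -y)$statistic, -s$statistic)
    # cross-check p against the t-reference implementation in stats
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    expect_equal(s$p_value, ct$p.value, tolerance = 1e-9)
  }
  expect_error(spearman_correlation(1:5, rep(2, 5)), "constant ranks")
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

make_cohort <- function(n = 8) {
  tibble::tibble(
    patient_id = rep(sprintf("P%02d", 1:n), 2),
    roi_id = c(sprintf("P%02d_T1", 1:n), sprintf("P%02d_N1", 1:n)),
    tissue = rep(c("tumor", "normal"), each = n),
    gs_group = c(rep(c("low", "high"), n / 2), rep("none", n)),
    median_d_app = rep(seq(1.2, 2.2, length.out = n), 2),
    median_k_app = rep(seq(0.5, 1.2, length.out = n), 2),
    cellularity = rep(seq(0.2, 0.5, length.out = n), 2),
    fsm = rep(seq(0.40, 0.47, length.out = n), 2),
    luminal = 1 - rep(seq(0.40, 0.47, length.out = n), 2) -
      rep(seq(0.2, 0.5, length.out = n), 2),
    area_mm2 = 50
  )
}

test_that("the study analysis grid always has 22 rows with the fixed schema", {
  a <- run_study_analyses(make_cohort())
  expect_equal(nrow(a), 22)
  expect_equal(names(a), c("comparison", "variable", "stratum", "statistic",
                           "p_value", "n1", "n2", "method"))
  expect_equal(sum(a$comparison == "tumor_vs_normal"), 5)
  expect_equal(sum(a$comparison == "gs_high_vs_low"), 5)
  expect_equal(sum(a$comparison == "correlation"), 12)
})

test_that("identical groups give p = 1 and engineered monotone links give rho = 1", {
  co <- make_cohort()
  a <- run_study_analyses(co)
  tn <- a[a$comparison == "tumor_vs_normal", ]
  expect_true(all(tn$p_value == 1))
  # cellularity increases strictly with K_app in this table
  cell_k <- a[a$variable == "median_k_app~cellularity" & a$stratum == "tumor", ]
  expect_equal(cell_k$statistic, 1)
})

test_that("schema violations name the missing column", {
  co <- make_cohort()
  co$fsm <- NULL
  expect_error(run_study_analyses(co), "fsm")
  expect_error(run_study_analyses(co[0, ]), "missing|>= 2")
})

test_that("a default simulated cohort shows the study's significant correlations", {
  co <- simulate_cohort(20, seed = 42)
  a <- run_study_analyses(co)
  kc <- a[a$variable == "median_k_app~cellularity" & a$stratum == "tumor", ]
  dl <- a[a$variable == "median_d_app~luminal" & a$stratum == "normal", ]
  expect_gt(kc$statistic, 0)
  expect_lt(kc$p_value, 0.05)
  expect_gt(dl$statistic, 0)
  expect_lt(dl$p_value, 0.05)
})
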