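test_that("log-quadratic initialisation is exact on noiseless model data", {
  b <- study_bvalues
  s <- oracle_signal(b, 100, 2e-3, 0.6)
  p <- initialize_dki_params(s, b)
  expect_rel_equal(p[["s0"]], 100, 1e-10)
  expect_rel_equal(p[["d_app"]], 2e-3, 1e-10)
  expect_rel_equal(p[["k_app"]], 0.6, 1e-10)
  # monoexponential data start at k ~ 0
  p0 <- initialize_dki_params(100 * exp(-b * 1.8e-3), b)
  expect_lt(p0[["k_app"]], 1e-8)
  # mild perturbation stays close to the truth
  s_pert <- s; s_pert[2] <- s_pert[2] * 1.01
  pp <- initialize_dki_params(s_pert, b)
  expect_rel_equal(pp[["d_app"]], 2e-3, 0.15)
  expect_rel_equal(pp[["k_app"]], 0.6, 0.15)
  # non-positive signals fall back to fixed defaults
  pf <- initialize_dki_params(c(10, 5, 0, 1), b)
  expect_true(attr(pf, "fallback"))
  expect_equal(pf[["d_app"]], 1.5e-3)
})

test_that("noiseless voxel fits recover the generating parameters to 1e-6", {
  b <- study_bvalues
  cases <- list(c(100, 2.07e-3, 0.59),   # reported normal-tissue medians
                c(100, 1.53e-3, 0.75),   # reported tumor medians
                c(250, 1.08e-3, 1.28))
  for (cs in cases) {
    f <- fit_dki_voxel(oracle_signal(b, cs[1], cs[2], cs[3]), b)
    expect_rel_equal(f$params[["s0"]], cs[1], 1e-6)
    expect_rel_equal(f$params[["d_app"]], cs[2], 1e-6)
    expect_rel_equal(f$params[["k_app"]], cs[3], 1e-6)
    expect_lt(f$rss, 1e-12)
  }
})

test_that("noise-compensated fit inverts the bias model exactly", {
  b <- study_bvalues
  n <- 6
  biased <- sqrt(oracle_signal(b, 120, 1.53e-3, 0.75)^2 + n^2)
  f <- fit_dki_voxel(biased, b, fit_config(noise = n))
  expect_rel_equal(f$params[["d_app"]], 1.53e-3, 1e-6)
  expect_rel_equal(f$params[["k_app"]], 0.75, 1e-6)
})

test_that("a pure-noise voxel is explained by the noise floor alone", {
  b <- study_bvalues
  f <- fit_dki_voxel(rep(5, 4), b, fit_config(noise = 5))
  # the fitted noise-free signal collapses towards zero
  fitted <- dki_signal(b, f$params[["s0"]], f$params[["d_app"]],
                       f$params[["k_app"]])
  expect_true(all(fitted < 0.05))
  expect_lt(f$rss, 1e-8)
})

test_that("accepted solver steps never increase the cost", {
  b <- study_bvalues
  set.seed(31)
  for (i in 1:20) {
    s <- oracle_signal(b, 100, runif(1, 1e-3, 2.5e-3), runif(1, 0.3, 1.5)) +
      rnorm(4, 0, 2)
    f <- fit_dki_voxel(pmax(s, 0.1), b, fit_config(noise = 2))
    expect_true(all(diff(f$rss_trace) <= 1e-12))
  }
})

test_that("volume fitting maps every voxel and masks background", {
  ph <- make_uniform_series(c(4, 4, 1), s0 = 100, d = 2e-3, k = 0.6)
  maps <- fit_dki_volume(ph$series)
  expect_true(all(maps$status == 0L))
  expect_rel_equal(range(maps$d_app), 2e-3, 1e-6)
  expect_rel_equal(range(maps$k_app), 0.6, 1e-6)
  # zero volume: everything skipped
  zero <- dwi_series(array(0, c(3, 3, 1, 4)), study_bvalues)
  maps0 <- fit_dki_volume(zero)
  expect_true(all(maps0$status == 1L))
  expect_true(all(is.na(maps0$d_app)))
})

test_that("two-region noiseless phantom reproduces region medians exactly", {
  tum <- phantom_region("box", center = c(3, 5, 1), halfsize = c(2, 4, 0.4),
                        s0 = 100, d_app = 1.53e-3, k_app = 0.75)
  nor <- phantom_region("box", center = c(8, 5, 1), halfsize = c(2, 4, 0.4),
                        s0 = 100, d_app = 2.07e-3, k_app = 0.59)
  ph <- simulate_dwi_phantom(c(10, 9, 1), list(tum, nor), sigma = 0)
  maps <- fit_dki_volume(ph$series)
  m1 <- ph$truth$region == 1L
  m2 <- ph$truth$region == 2L
  expect_rel_equal(roi_median(maps$d_app, m1), 1.53e-3, 1e-6)
  expect_rel_equal(roi_median(maps$k_app, m1), 0.75, 1e-6)
  expect_rel_equal(roi_median(maps$d_app, m2), 2.07e-3, 1e-6)
  expect_rel_equal(roi_median(maps$k_app, m2), 0.59, 1e-6)
})

test_that("identical inputs give bit-identical maps", {
  ph <- simulate_dwi_phantom(
    c(6, 6, 1),
    list(phantom_region("box", c(3.5, 3.5, 1), c(2, 2, 0.4),
                        s0 = 100, d_app = 1.5e-3, k_app = 0.9)),
    sigma = 8, averages = 8, seed = 77
  )
  cfg <- fit_config(noise = estimate_noise_level(ph$noise_volume[, , 1],
                                                 window = 5))
  a <- fit_dki_volume(ph$series, cfg)
  b <- fit_dki_volume(ph$series, cfg)
  expect_identical(a$d_app, b$d_app)
  expect_identical(a$k_app, b$k_app)
  expect_identical(a$status, b$status)
})

test_that("mean-convention compensation shrinks the systematic Rician bias", {
  # Estimator bias isolated from Monte-Carlo noise: fit the exact Rician
  # expectation values (closed form) instead of sampled magnitudes.
  b <- study_bvalues
  truth_d <- 1.53e-3; truth_k <- 0.75; s0 <- 100
  for (snr in c(50, 25, 12)) {
    sigma <- s0 / snr
    em <- rice_mean(oracle_signal(b, s0, truth_d, truth_k), sigma)
    bias <- function(noise) {
      f <- fit_dki_voxel(em, b, fit_config(noise = noise))
      c(d = abs(f$params[["d_app"]] - truth_d),
        k = abs(f$params[["k_app"]] - truth_k))
    }
    comp <- bias(sigma)           # rician_mean convention: n = sigma
    unc <- bias(0)
    expect_lt(comp[["k"]], unc[["k"]])
    if (snr >= 25) expect_lt(comp[["d"]], unc[["d"]])
    # rms convention overcorrects by roughly the uncompensated undershoot
    rms <- bias(sqrt(2) * sigma)
    expect_lt(comp[["k"]], rms[["k"]])
  }
})

test_that("tidy and glance expose the voxel table and status counts", {
  ph <- make_uniform_series(c(3, 3, 1))
  maps <- fit_dki_volume(ph$series)
  td <- tidy(maps)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 9)
  expect_true(all(td$status == "ok"))
  gl <- glance(maps)
  expect_equal(gl$n_ok, 9)
  expect_equal(gl$n_skipped, 0)
})
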