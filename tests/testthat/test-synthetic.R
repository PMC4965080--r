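test_that("noiseless phantoms reproduce the forward model exactly", {
  ph <- make_uniform_series(c(5, 4, 2), s0 = 100, d = 2e-3, k = 0.6)
  b <- study_bvalues
  for (j in seq_along(b)) {
    expect_equal(unique(as.vector(ph$series$data[, , , j])),
                 oracle_signal(b[j], 100, 2e-3, 0.6))
  }
  expect_true(all(ph$noise_volume == 0))
  expect_true(all(ph$truth$d_app == 2e-3))
  expect_true(all(ph$truth$k_app == 0.6))
})

test_that("overlapping phantom regions are rejected", {
  r1 <- phantom_region("box", c(3, 3, 1), c(2, 2, 0.4), 100, 2e-3, 0.6)
  r2 <- phantom_region("box", c(4, 4, 1), c(2, 2, 0.4), 100, 1e-3, 1)
  expect_error(simulate_dwi_phantom(c(8, 8, 1), list(r1, r2)), "overlap")
})

test_that("background noise is Rayleigh with the effective sigma", {
  ph <- simulate_dwi_phantom(
    c(102, 102, 1),
    list(phantom_region("box", c(2, 2, 1), c(1, 1, 0.4), 100, 2e-3, 0.6)),
    sigma = 12, averages = 9, seed = 88
  )
  expect_equal(ph$sigma_eff, 4)
  bg <- ph$series$data[, , , 1][ph$truth$region == 0L]
  expect_gt(length(bg), 1e4)
  expect_rel_equal(mean(bg), 4 * sqrt(pi / 2), 0.03)
})

test_that("generators are bit-reproducible from their seed", {
  a <- simulate_dwi_phantom(c(6, 6, 1),
                            list(phantom_region("box", c(3.5, 3.5, 1),
                                                c(2, 2, 0.4), 100, 1.5e-3, 0.8)),
                            sigma = 5, seed = 123)
  b <- simulate_dwi_phantom(c(6, 6, 1),
                            list(phantom_region("box", c(3.5, 3.5, 1),
                                                c(2, 2, 0.4), 100, 1.5e-3, 0.8)),
                            sigma = 5, seed = 123)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$noise_volume, b$noise_volume)
  h1 <- simulate_histology_image(c(50, 50), c(0.3, 0.5, 0.2),
                                 mode = "textured", seed = 5)
  h2 <- simulate_histology_image(c(50, 50), c(0.3, 0.5, 0.2),
                                 mode = "textured", seed = 5)
  expect_identical(h1$image, h2$image)
  expect_identical(simulate_cohort(10, seed = 9), simulate_cohort(10, seed = 9))
})

test_that("exact-count histology hits the programmed class counts", {
  h <- simulate_histology_image(c(100, 100), c(0.39, 0.50, 0.11), seed = 1)
  expect_equal(sum(h$labels == 1L), 3900)
  expect_equal(sum(h$labels == 2L), 5000)
  expect_equal(sum(h$labels == 0L), 1100)
  expect_equal(unlist(h$truth[1, 1:3]),
               c(cellularity = 0.39, fsm = 0.50, luminal = 0.11))
  # all-luminal degenerate target
  hw <- simulate_histology_image(c(20, 20), c(0, 0, 1), seed = 2)
  expect_true(all(hw$labels == 0L))
  expect_error(simulate_histology_image(c(20, 20), c(0.5, 0.4, 0.4)),
               "summing to 1")
})

test_that("segmentation recovers programmed fractions exactly on clean images", {
  set.seed(61)
  for (i in 1:5) {
    f <- c(runif(1, 0.1, 0.6), runif(1, 0.1, 0.35))
    f <- c(f, 1 - sum(f))
    h <- simulate_histology_image(c(80, 80), f)
    fr <- compute_tissue_fractions(classify_pixels(h$image))
    expect_equal(fr$cellularity, h$truth$cellularity)
    expect_equal(fr$fsm, h$truth$fsm)
    expect_equal(fr$luminal, h$truth$luminal)
  }
})

test_that("cohort generator is calibrated to the reported group medians", {
  co <- simulate_cohort(2000, seed = 314)
  tum <- co[co$tissue == "tumor", ]
  nor <- co[co$tissue == "normal", ]
  expect_lt(abs(median(tum$cellularity) - 0.39), 0.03)
  expect_lt(abs(median(nor$cellularity) - 0.24), 0.03)
  expect_lt(abs(median(tum$median_d_app) - 1.53), 0.08)
  expect_lt(abs(median(nor$median_d_app) - 2.07), 0.08)
  expect_lt(abs(median(tum$median_k_app) - 0.75), 0.05)
  expect_lt(abs(median(nor$median_k_app) - 0.59), 0.05)
  # structural invariants
  expect_true(all(abs(co$cellularity + co$fsm + co$luminal - 1) < 1e-9))
  expect_true(all(co$gs_group[co$tissue == "normal"] == "none"))
  expect_true(all(table(co$patient_id, co$tissue) >= 1))
})

test_that("tumor K_app exceeds normal K_app in every seed of a sweep", {
  for (seed in 1:20) {
    co <- simulate_cohort(20, seed = seed)
    expect_gt(median(co$median_k_app[co$tissue == "tumor"]),
              median(co$median_k_app[co$tissue == "normal"]))
  }
})

test_that("noise-compensated volume fitting recovers a noisy phantom's medians", {
  reg <- phantom_region("box", c(13.5, 13.5, 1), c(10.6, 10.6, 0.4),
                        s0 = 100, d_app = 1.53e-3, k_app = 0.75)
  ph <- simulate_dwi_phantom(c(26, 26, 1), list(reg),
                             sigma = 2 * sqrt(8), averages = 8, seed = 17)
  ne <- estimate_noise_level(ph$noise_volume[, , 1])
  maps <- fit_dki_volume(ph$series, fit_config(noise = ne))
  mask <- ph$truth$region == 1L
  expect_rel_equal(roi_median(maps$d_app, mask), 1.53e-3, 0.05)
  expect_rel_equal(roi_median(maps$k_app, mask), 0.75, 0.10)
})
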