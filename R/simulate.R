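#' @importFrom stats rnorm runif rbeta rlnorm
NULL

# Draw Rician magnitudes: |(s + e1) + i e2| with per-channel sd sigma.
rician_magnitude <- function(s, sigma) {
  if (sigma == 0) return(s)
  sqrt((s + rnorm(length(s), 0, sigma))^2 + rnorm(length(s), 0, sigma)^2)
}

# Largest-remainder allocation of n units over shares (shares need not be
# normalised); returns integer counts summing to n.
largest_remainder <- function(shares, n) {
  q <- shares / sum(shares) * n
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    take <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Seeded smooth random field: uniform noise with repeated box smoothing.
smooth_field <- function(shape, scale) {
  f <- matrix(runif(prod(shape)), shape[1L], shape[2L])
  w <- max(3L, as.integer(scale) %/% 2L * 2L + 1L)
  for (i in 1:3) f <- local_mean(f, w)
  f + matrix(runif(prod(shape), 0, 1e-9), shape[1L], shape[2L]) # break ties
}

#' Geometric region for DWI phantoms
#'
#' @param geometry `"box"` or `"ellipsoid"`.
#' @param center Region centre in voxel coordinates (1-based).
#' @param halfsize Half-extent per axis, voxels.
#' @param s0,d_app,k_app True kurtosis-model parameters of the region.
#' @return A list describing the region, for [simulate_dwi_phantom()].
#' @export
phantom_region <- function(geometry = c("box", "ellipsoid"), center, halfsize,
                           s0, d_app, k_app) {
  geometry <- match.arg(geometry)
  list(geometry = geometry, center = as.numeric(center),
       halfsize = as.numeric(halfsize),
       params = c(s0 = s0, d_app = d_app, k_app = k_app))
}

region_mask <- function(region, shape) {
  g <- expand.grid(x = seq_len(shape[1L]), y = seq_len(shape[2L]),
                   z = seq_len(shape[3L]))
  d <- sweep(as.matrix(g), 2L, region$center)
  d <- sweep(abs(d), 2L, region$halfsize, "/")
  inside <- if (region$geometry == "box") {
    apply(d <= 1, 1L, all)
  } else {
    rowSums(d^2) <= 1
  }
  array(inside, dim = shape)
}

#' Simulate a multi-b diffusion-weighted phantom with Rician noise
#'
#' Builds a 4D magnitude volume from the kurtosis signal model
#' ([dki_signal()]) over user-defined regions, applies Rician magnitude
#' noise (`|(S + e1) + i e2|`, per-channel sd `sigma / sqrt(averages)`,
#' modelling a multi-average acquisition), and generates a matched
#' noise-only volume (the same acquisition with no signal). Background
#' voxels carry zero signal.
#'
#' @param shape Spatial dimensions `c(x, y, z)`.
#' @param regions List of [phantom_region()]s; must not overlap.
#' @param bvalues b-value scheme (default the study scheme
#'   150/600/1050/1500 s/mm^2).
#' @param sigma Per-channel Gaussian noise sd before averaging (0 =
#'   noiseless).
#' @param averages Number of signal averages (default 8).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   output.
#' @return List with `series` ([dwi_series()]), `truth` (list of 3D arrays
#'   `s0`, `d_app`, `k_app`, `region`), `noise_volume` (3D array) and
#'   `sigma_eff = sigma / sqrt(averages)`.
#' @export
simulate_dwi_phantom <- function(shape, regions,
                                 bvalues = c(150, 600, 1050, 1500),
                                 sigma = 0, averages = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sigma < 0 || averages < 1) {
    stop("sigma must be >= 0 and averages >= 1", call. = FALSE)
  }
  bvalues <- if (inherits(bvalues, "bvalue_scheme")) bvalues else
    bvalue_scheme(bvalues)
  shape <- as.integer(shape)
  truth <- list(s0 = array(NA_real_, shape), d_app = array(NA_real_, shape),
                k_app = array(NA_real_, shape), region = array(0L, shape))
  occupied <- array(FALSE, shape)
  for (i in seq_along(regions)) {
    m <- region_mask(regions[[i]], shape)
    if (any(m & occupied)) stop("phantom regions overlap", call. = FALSE)
    occupied <- occupied | m
    p <- regions[[i]]$params
    truth$s0[m] <- p[["s0"]]
    truth$d_app[m] <- p[["d_app"]]
    truth$k_app[m] <- p[["k_app"]]
    truth$region[m] <- i
  }
  sigma_eff <- sigma / sqrt(averages)
  nb <- length(bvalues)
  data <- array(0, dim = c(shape, nb))
  for (j in seq_len(nb)) {
    s <- array(0, shape)
    s[occupied] <- dki_signal(unclass(bvalues)[j], truth$s0[occupied],
                              truth$d_app[occupied], truth$k_app[occupied])
    data[, , , j] <- if (sigma > 0) {
      array(rician_magnitude(as.vector(s), sigma_eff), shape)
    } else {
      s
    }
  }
  noise_volume <- if (sigma > 0) {
    array(rician_magnitude(rep(0, prod(shape)), sigma_eff), shape)
  } else {
    array(0, shape)
  }
  list(series = dwi_series(data, bvalues), truth = truth,
       noise_volume = noise_volume, sigma_eff = sigma_eff)
}

default_class_colors <- function() {
  rbind(
    cellularity = as.vector(grDevices::col2rgb(grDevices::hsv(0.70, 0.75, 0.55)) / 255),
    fsm         = as.vector(grDevices::col2rgb(grDevices::hsv(0.95, 0.60, 0.85)) / 255),
    luminal     = as.vector(grDevices::col2rgb(grDevices::hsv(0.00, 0.00, 0.98)) / 255)
  )
}

#' Simulate an H&E-like histology image with programmed tissue fractions
#'
#' Generates a synthetic stained-section image of three classes —
#' hematoxylin-like cellularity, eosin-like fibromuscular stroma and
#' near-white luminal space. In `"exact_count"` mode exactly
#' `round(fraction * n_pixels)` pixels (largest-remainder rounding) receive
#' each class, arranged as seeded random blobs by thresholding a smooth
#' random field; `"textured"` mode additionally jitters pixel colours.
#'
#' @param shape Image dimensions `c(rows, cols)`.
#' @param fractions Target `(cellularity, fsm, luminal)` fractions; must
#'   sum to 1 (within 1e-6).
#' @param mode `"exact_count"` or `"textured"`.
#' @param class_colors 3 x 3 matrix of RGB rows (cellularity, fsm,
#'   luminal) in `[0, 1]`; the defaults are classifiable by the default
#'   [segmentation_settings()].
#' @param blob_scale Characteristic blob size, pixels.
#' @param jitter_sd Colour jitter sd for `"textured"` mode.
#' @param seed Optional integer seed.
#' @return List with `image` (RGB array), `labels` (true class matrix: 1
#'   cellularity, 2 fsm, 0 luminal), `roi` (rectangle polygon covering the
#'   image) and `truth` (one-row tibble of realized fractions).
#' @export
simulate_histology_image <- function(shape, fractions,
                                     mode = c("exact_count", "textured"),
                                     class_colors = default_class_colors(),
                                     blob_scale = 8, jitter_sd = 0.02,
                                     seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-6) {
    stop("fractions must be 3 non-negative values summing to 1",
         call. = FALSE)
  }
  n <- prod(shape)
  counts <- largest_remainder(fractions, n)
  if (any(counts < 0)) stop("fractions infeasible for image size", call. = FALSE)
  field <- smooth_field(shape, blob_scale)
  ord <- order(as.vector(field))
  lab <- integer(n)                         # luminal = 0
  lab[ord[seq_len(counts[1L])]] <- 1L       # cellularity in low-field blobs
  if (counts[2L] > 0) {
    lab[ord[counts[1L] + seq_len(counts[2L])]] <- 2L
  }
  labels <- matrix(lab, shape[1L], shape[2L])
  cls <- ifelse(lab == 1L, 1L, ifelse(lab == 2L, 2L, 3L))
  image <- array(0, dim = c(shape, 3L))
  for (ch in 1:3) {
    plane <- class_colors[cls, ch]
    if (mode == "textured") {
      plane <- pmin(pmax(plane + rnorm(n, 0, jitter_sd), 0), 1)
    }
    image[, , ch] <- plane
  }
  roi <- rbind(c(0, 0), c(shape[2L], 0), c(shape[2L], shape[1L]),
               c(0, shape[1L]))
  truth <- tibble::tibble(cellularity = counts[1L] / n, fsm = counts[2L] / n,
                          luminal = counts[3L] / n, n_pixels = n)
  list(image = image, labels = labels, roi = roi, truth = truth)
}

# Beta draw on [lo, hi] whose median sits at `med`, with concentration
# kappa (larger = tighter). Uses the (a - 1/3)/(a + b - 2/3) median
# approximation to place the mean.
rbeta_median <- function(n, med, lo, hi, kappa = 8) {
  t <- (med - lo) / (hi - lo)
  mu <- (t * (kappa - 2 / 3) + 1 / 3) / kappa
  mu <- min(max(mu, 0.02), 0.98)
  lo + (hi - lo) * rbeta(n, mu * kappa, (1 - mu) * kappa)
}

#' Default group-wise composition model for the cohort simulator
#'
#' Scaled Beta distributions for cellularity and luminal space matched to
#' the reported group medians with support spanning the reported ranges;
#' stroma is the complement, with draws rejected until it falls inside its
#' reported range.
#'
#' @return Nested list with entries `normal`, `tumor_low`, `tumor_high`,
#'   each holding `cellularity = c(median, lo, hi)`,
#'   `luminal = c(median, lo, hi)` and `fsm_range = c(lo, hi)`.
#' @export
cohort_composition_defaults <- function() {
  list(
    normal = list(cellularity = c(0.24, 0.10, 0.40),
                  luminal = c(0.20, 0.11, 0.33),
                  fsm_range = c(0.45, 0.65)),
    tumor_low = list(cellularity = c(0.38, 0.35, 0.47),
                     luminal = c(0.09, 0.06, 0.15),
                     fsm_range = c(0.45, 0.55)),
    tumor_high = list(cellularity = c(0.44, 0.32, 0.61),
                      luminal = c(0.09, 0.06, 0.21),
                      fsm_range = c(0.32, 0.51))
  )
}

#' Default composition-to-DKI link coefficients
#'
#' Linear links mapping tissue composition to the two kurtosis parameters:
#' `D_app = a0 + a1 * luminal - a2 * cellularity + e` (units 1e-3 mm^2/s)
#' and `K_app = b0 + b1 * cellularity - b2 * fsm + e`. Coefficients are
#' solved once from the reported group-median operating points (see
#' `scripts/calibrate-cohort.R`); noise sds set within-group spread so
#' that within-stratum rank correlations land near the reported
#' significant magnitudes (~0.5-0.65).
#'
#' @return List with `d` and `k` coefficient vectors and noise sds.
#' @export
cohort_link_defaults <- function() {
  list(
    d = c(intercept = 1.785, luminal = 3.0, cellularity = 1.3125),
    d_sd = 0.13,
    k = c(intercept = 0.96, cellularity = 0.75, fsm = 1.0),
    k_sd = 0.12
  )
}

draw_composition <- function(n, model) {
  cell <- numeric(n); lum <- numeric(n); fsm <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      ci <- rbeta_median(1, model$cellularity[1], model$cellularity[2],
                         model$cellularity[3])
      li <- rbeta_median(1, model$luminal[1], model$luminal[2],
                         model$luminal[3])
      fi <- 1 - ci - li
      if (fi >= model$fsm_range[1] && fi <= model$fsm_range[2]) break
    }
    cell[i] <- ci; lum[i] <- li; fsm[i] <- fi
  }
  tibble::tibble(cellularity = cell, fsm = fsm, luminal = lum)
}

#' Simulate a study-shaped ROI cohort
#'
#' Generates a cohort of patients, each with a Gleason-score group, 1-4
#' peripheral-zone tumor ROIs and one matched normal ROI per tumor ROI.
#' Tissue fractions come from the group-conditional composition model;
#' ROI-median `D_app` and `K_app` follow the linear composition links plus
#' Gaussian noise, clipped to physiological bounds. Deterministic given
#' `seed`.
#'
#' @param n_patients Number of patients (default 20).
#' @param roi_count_probs Probabilities of 1, 2, 3, 4 tumor ROIs per
#'   patient (mean ~2 by default).
#' @param gs_probs Probabilities of Gleason score 6, 3+4, 4+3, >=8; 6 and
#'   3+4 form the low-grade group, 4+3 and >=8 the high-grade group.
#' @param composition A [cohort_composition_defaults()]-shaped list.
#' @param link A [cohort_link_defaults()]-shaped list.
#' @param roi_area_range ROI area bounds, mm^2.
#' @param seed Optional integer seed.
#' @return Tibble with columns `patient_id`, `roi_id`, `tissue`,
#'   `gs_group`, `median_d_app` (1e-3 mm^2/s), `median_k_app`,
#'   `cellularity`, `fsm`, `luminal`, `area_mm2`.
#' @export
simulate_cohort <- function(n_patients = 20,
                            roi_count_probs = c(0.35, 0.40, 0.20, 0.05),
                            gs_probs = c(gs6 = 0.15, gs3p4 = 0.45,
                                         gs4p3 = 0.30, gs8plus = 0.10),
                            composition = cohort_composition_defaults(),
                            link = cohort_link_defaults(),
                            roi_area_range = c(3.1, 365.4),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(sum(gs_probs) - 1) < 1e-6, abs(sum(roi_count_probs) - 1) < 1e-6)
  rows <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    gs <- sample(names(gs_probs), 1L, prob = gs_probs)
    group <- if (gs %in% c("gs6", "gs3p4")) "low" else "high"
    k_rois <- sample(1:4, 1L, prob = roi_count_probs)
    tmodel <- if (group == "low") composition$tumor_low else
      composition$tumor_high
    tum <- draw_composition(k_rois, tmodel)
    nor <- draw_composition(k_rois, composition$normal)
    comp <- dplyr::bind_rows(tum, nor)
    tissue <- rep(c("tumor", "normal"), each = k_rois)
    d <- link$d[["intercept"]] + link$d[["luminal"]] * comp$luminal -
      link$d[["cellularity"]] * comp$cellularity +
      rnorm(2 * k_rois, 0, link$d_sd)
    k <- link$k[["intercept"]] + link$k[["cellularity"]] * comp$cellularity -
      link$k[["fsm"]] * comp$fsm + rnorm(2 * k_rois, 0, link$k_sd)
    area <- pmin(pmax(rlnorm(2 * k_rois, log(55), 0.85), roi_area_range[1]),
                 roi_area_range[2])
    pid <- sprintf("P%02d", p)
    rows[[p]] <- tibble::tibble(
      patient_id = pid,
      roi_id = sprintf("%s_%s%d", pid, ifelse(tissue == "tumor", "T", "N"),
                       rep(seq_len(k_rois), 2L)),
      tissue = tissue,
      gs_group = ifelse(tissue == "tumor", group, "none"),
      median_d_app = pmin(pmax(d, 0.2), 4),
      median_k_app = pmin(pmax(k, 0.02), 3),
      cellularity = comp$cellularity,
      fsm = comp$fsm,
      luminal = comp$luminal,
      area_mm2 = area
    )
  }
  dplyr::bind_rows(rows)
}
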