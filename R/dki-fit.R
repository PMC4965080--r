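#' Diffusion-weighted image series
#'
#' Container pairing a 4D magnitude volume with its b-value scheme. The
#' fourth array dimension indexes b-values.
#'
#' @param data 4D numeric array (x, y, z, b) of non-negative magnitudes.
#'   A 3D array is promoted to a single-slice 4D volume.
#' @param bvalues A [bvalue_scheme()] or numeric vector coercible to one.
#' @param voxel_dims Voxel size in mm per spatial axis.
#' @return Object of class `"dwi_series"`.
#' @export
dwi_series <- function(data, bvalues, voxel_dims = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3L])
  if (length(dim(data)) != 4L) {
    stop("data must be a 4D array (x, y, z, b)", call. = FALSE)
  }
  if (!inherits(bvalues, "bvalue_scheme")) bvalues <- bvalue_scheme(bvalues)
  if (dim(data)[4L] != length(bvalues)) {
    stop("4th dimension (", dim(data)[4L], ") must match the number of ",
         "b-values (", length(bvalues), ")", call. = FALSE)
  }
  if (any(data < 0, na.rm = TRUE)) {
    stop("magnitude intensities must be non-negative", call. = FALSE)
  }
  structure(list(data = data, bvalues = bvalues,
                 voxel_dims = as.numeric(voxel_dims)),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("<dwi_series> %s voxels, b = {%s} s/mm^2\n",
              paste(dim(x$data)[1:3], collapse = "x"),
              paste(unclass(x$bvalues), collapse = ", ")))
  invisible(x)
}

#' Fitting configuration for voxelwise DKI mapping
#'
#' @param lower,upper Box bounds for `(s0, d_app, k_app)`. The default `s0`
#'   upper bound `NA` is resolved per volume/voxel to 10x the maximum
#'   observed signal. Defaults keep `d_app` in `[1e-5, 4e-3]` mm^2/s and
#'   `k_app` in `[0, 3]`, spanning reported prostate values with headroom
#'   while excluding the degenerate large-kurtosis ridge.
#' @param max_iterations Maximum solver iterations (default 200).
#' @param tolerance Relative convergence tolerance on cost and parameter
#'   change (default 1e-8).
#' @param mask_threshold Voxels whose lowest-b signal is at or below
#'   `mask_threshold * n` are skipped (default 3; with no noise estimate
#'   only exactly-zero voxels are skipped).
#' @param noise A [estimate_noise_level()] result, a single non-negative
#'   number, or `NULL` for uncompensated fitting (n = 0).
#' @return Object of class `"dki_fit_config"`.
#' @export
fit_config <- function(lower = c(s0 = 1e-6, d_app = 1e-5, k_app = 0),
                       upper = c(s0 = NA, d_app = 4e-3, k_app = 3),
                       max_iterations = 200L, tolerance = 1e-8,
                       mask_threshold = 3, noise = NULL) {
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  n <- noise_value(noise)
  if (n < 0) stop("noise level must be non-negative", call. = FALSE)
  if (any(lower[2:3] > upper[2:3]) || lower[1] <= 0) {
    stop("invalid parameter bounds", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, mask_threshold = mask_threshold,
                 noise = n),
            class = "dki_fit_config")
}

noise_value <- function(noise) {
  if (is.null(noise)) return(0)
  if (inherits(noise, "noise_estimate")) return(noise$n)
  as.numeric(noise)
}

#' Starting values for a voxel fit
#'
#' Ordinary linear least squares on `log S = c0 + c1 b + c2 b^2` gives exact
#' starting values for noiseless model data (`s0 = exp(c0)`, `d = -c1`,
#' `k = 6 c2 / d^2`); each value is clipped into the configured bounds.
#' Non-positive signals fall back to fixed defaults
#' (`d = 1.5e-3`, `k = 0.8`, `s0 = max(signal)`).
#'
#' @param signals Per-b signal vector.
#' @param bvalues b-value scheme (same length).
#' @param config A [fit_config()].
#' @return Named numeric `(s0, d_app, k_app)` with attribute `"fallback"`.
#' @export
initialize_dki_params <- function(signals, bvalues, config = fit_config()) {
  b <- as.numeric(bvalues)
  upper <- resolve_upper(config$upper, signals)
  lower <- config$lower
  fallback <- FALSE
  if (any(signals <= 0) || length(signals) != length(b)) {
    fallback <- TRUE
  } else {
    X <- cbind(1, b, b^2)
    cf <- tryCatch(qr.solve(X, log(signals)), error = function(e) NULL)
    if (is.null(cf) || !all(is.finite(cf)) || cf[2] >= 0) {
      fallback <- TRUE
    } else {
      s0 <- exp(cf[1]); d <- -cf[2]; k <- 6 * cf[3] / d^2
    }
  }
  if (fallback) {
    s0 <- max(signals, 1e-3); d <- 1.5e-3; k <- 0.8
  }
  par <- c(s0 = min(max(s0, lower[1]), upper[1]),
           d_app = min(max(d, lower[2]), upper[2]),
           k_app = min(max(k, lower[3]), upper[3]))
  attr(par, "fallback") <- fallback
  par
}

resolve_upper <- function(upper, signals) {
  if (is.na(upper[1])) upper[1] <- 10 * max(signals, 1)
  upper
}

#' Fit the kurtosis model to one voxel
#'
#' Minimises `sum_b (signal_b - sqrt(model(b)^2 + n^2))^2` over bounded
#' `(s0, d_app, k_app)` with a box-constrained Levenberg-Marquardt solver,
#' starting from [initialize_dki_params()]. With `n = 0` this is ordinary
#' least squares on the noise-free kurtosis model.
#'
#' @inheritParams initialize_dki_params
#' @return A list with `params` (named vector), `status` (one of `"ok"`,
#'   `"non_converged"`, `"at_bound"`, `"beyond_bstar"`), `rss`, `rss_trace`
#'   (cost at each accepted step, non-increasing), `iterations` and
#'   `b_star`.
#' @export
fit_dki_voxel <- function(signals, bvalues, config = fit_config()) {
  b <- as.numeric(bvalues)
  if (length(signals) != length(b)) {
    stop("signal vector length must match the b-value scheme", call. = FALSE)
  }
  n <- config$noise
  start <- initialize_dki_params(signals, bvalues, config)
  lower <- unname(config$lower)
  upper <- unname(resolve_upper(config$upper, signals))
  resid_fn <- function(p) {
    signals - sqrt(dki_signal(b, p[1], p[2], p[3])^2 + n^2)
  }
  fit <- minpack.lm::nls.lm(
    par = unname(start), lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = config$max_iterations,
      ftol = config$tolerance, ptol = config$tolerance, gtol = 0
    )
  )
  par <- stats::setNames(fit$par, c("s0", "d_app", "k_app"))
  b_star <- max_valid_bvalue(par[["d_app"]], par[["k_app"]])
  at_bound <- any(abs(fit$par - lower) < 1e-12 * pmax(abs(lower), 1)) ||
    any(abs(fit$par - upper) < 1e-12 * pmax(abs(upper), 1))
  status <- if (fit$info == 5L || fit$info == 0L) {
    "non_converged"
  } else if (at_bound) {
    "at_bound"
  } else if (max(b) > b_star) {
    "beyond_bstar"
  } else {
    "ok"
  }
  list(params = par, status = status, rss = fit$deviance,
       rss_trace = fit$rsstrace, iterations = fit$niter, b_star = b_star)
}

dki_status_codes <- c(ok = 0L, skipped = 1L, non_converged = 2L,
                      at_bound = 3L, beyond_bstar = 4L)

#' Voxelwise kurtosis parameter mapping
#'
#' Applies [fit_dki_voxel()] independently to every voxel of a
#' [dwi_series()] whose lowest-b signal exceeds `mask_threshold * n`
#' (voxels at or below the threshold are skipped). Fits are voxel-wise
#' independent and deterministic, so the result does not depend on
#' traversal order.
#'
#' @param series A [dwi_series()].
#' @param config A [fit_config()].
#' @return Object of class `"dki_maps"`: a list of 3D arrays `s0`, `d_app`
#'   (mm^2/s), `k_app`, `rss`, integer `status` (0 ok, 1 skipped,
#'   2 non-converged, 3 at-bound, 4 beyond-b*) plus the `config` and
#'   `bvalues`. Skipped and non-converged voxels hold `NA` parameters;
#'   at-bound and beyond-b* voxels keep their values and are flagged.
#' @export
fit_dki_volume <- function(series, config = fit_config()) {
  if (!inherits(series, "dwi_series")) {
    stop("series must be a dwi_series", call. = FALSE)
  }
  dm <- dim(series$data)
  sp <- dm[1:3]
  nvox <- prod(sp)
  sig <- matrix(series$data, nrow = nvox, ncol = dm[4L])
  thr <- config$mask_threshold * config$noise
  fit_mask <- sig[, 1L] > thr & sig[, 1L] > 0
  s0 <- d <- k <- rss <- rep(NA_real_, nvox)
  status <- rep(dki_status_codes[["skipped"]], nvox)
  for (i in which(fit_mask)) {
    f <- fit_dki_voxel(sig[i, ], series$bvalues, config)
    status[i] <- dki_status_codes[[f$status]]
    rss[i] <- f$rss
    if (f$status != "non_converged") {
      s0[i] <- f$params[["s0"]]
      d[i] <- f$params[["d_app"]]
      k[i] <- f$params[["k_app"]]
    }
  }
  shape3 <- function(v) array(v, dim = sp)
  structure(list(s0 = shape3(s0), d_app = shape3(d), k_app = shape3(k),
                 rss = shape3(rss), status = shape3(status),
                 bvalues = series$bvalues, config = config),
            class = "dki_maps")
}

#' @export
print.dki_maps <- function(x, ...) {
  tab <- table(factor(names(dki_status_codes)[x$status + 1L],
                      levels = names(dki_status_codes)))
  cat(sprintf("<dki_maps> %s voxels (n = %.4g)\n",
              paste(dim(x$status), collapse = "x"), x$config$noise))
  print(tab)
  invisible(x)
}

#' Tidy voxel table of fitted parameter maps
#'
#' @param x A `"dki_maps"` object.
#' @param ... Unused.
#' @return A tibble with one row per voxel: `x`, `y`, `z`, `s0`, `d_app`,
#'   `k_app`, `rss`, `status`.
#' @method tidy dki_maps
#' @export
tidy.dki_maps <- function(x, ...) {
  idx <- arrayInd(seq_along(x$status), dim(x$status))
  out <- list(
    x = idx[, 1L], y = idx[, 2L], z = idx[, 3L],
    s0 = as.vector(x$s0), d_app = as.vector(x$d_app),
    k_app = as.vector(x$k_app), rss = as.vector(x$rss),
    status = names(dki_status_codes)[as.vector(x$status) + 1L]
  )
  tibble::as_tibble(out)
}

#' One-row fit summary of parameter maps
#'
#' @param x A `"dki_maps"` object.
#' @param ... Unused.
#' @return A tibble with voxel counts by status, the noise level used and
#'   map-wide median parameters (over fitted voxels).
#' @method glance dki_maps
#' @export
glance.dki_maps <- function(x, ...) {
  st <- as.vector(x$status)
  tibble::tibble(
    n_voxels = length(st),
    n_ok = sum(st == 0L), n_skipped = sum(st == 1L),
    n_non_converged = sum(st == 2L), n_at_bound = sum(st == 3L),
    n_beyond_bstar = sum(st == 4L),
    noise = x$config$noise,
    median_d_app = stats::median(x$d_app, na.rm = TRUE),
    median_k_app = stats::median(x$k_app, na.rm = TRUE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
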