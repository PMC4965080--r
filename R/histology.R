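#' Positive-pixel segmentation settings
#'
#' Hue/saturation/value rule for classifying H&E pixels. Hue lives on the
#' circular `[0, 1)` axis (the Aperio convention); the default
#' `hue_center = 0.7` with a total window of `0.35` targets the
#' hematoxylin-stained (blue-purple) cellular component. Pixels that are
#' nearly unsaturated or nearly white are unstained luminal space.
#'
#' @param hue_center Centre of the positive hue window in `[0, 1)`.
#' @param hue_window Total window width in hue units, in `(0, 1)`.
#' @param saturation_min Minimum saturation for a stained pixel (default
#'   0.05).
#' @param white_value_min Brightness at or above which a pixel counts as
#'   unstained (default 0.94).
#' @return Object of class `"segmentation_settings"`.
#' @export
segmentation_settings <- function(hue_center = 0.7, hue_window = 0.35,
                                  saturation_min = 0.05,
                                  white_value_min = 0.94) {
  if (hue_center < 0 || hue_center >= 1) {
    stop("hue_center must be in [0, 1)", call. = FALSE)
  }
  if (hue_window <= 0 || hue_window >= 1) {
    stop("hue_window must be in (0, 1)", call. = FALSE)
  }
  if (saturation_min < 0 || saturation_min >= 1) {
    stop("saturation_min must be in [0, 1)", call. = FALSE)
  }
  if (white_value_min <= 0 || white_value_min > 1) {
    stop("white_value_min must be in (0, 1]", call. = FALSE)
  }
  structure(list(hue_center = hue_center, hue_window = hue_window,
                 saturation_min = saturation_min,
                 white_value_min = white_value_min),
            class = "segmentation_settings")
}

#' Circular distance on the unit hue axis
#'
#' @param h1,h2 Hues in `[0, 1)`. Vectorised.
#' @return `min(|h1 - h2|, 1 - |h1 - h2|)`, at most 0.5.
#' @export
hue_distance <- function(h1, h2) {
  d <- abs(h1 - h2) %% 1
  pmin(d, 1 - d)
}

#' Classify ROI pixels as positive, negative or background
#'
#' Positive-pixel-count colour segmentation. Each ROI pixel is converted to
#' hue/saturation/value; it is labelled background (unstained, luminal) if
#' its saturation is below `saturation_min` or its value is at least
#' `white_value_min`; otherwise positive (cellularity) if its circular hue
#' distance to `hue_center` is at most `hue_window / 2`, else negative
#' (fibromuscular stroma). The three labels partition the ROI.
#'
#' @param image RGB array `h x w x 3` with intensities in `[0, 1]`.
#' @param roi_mask Logical `h x w` matrix; `NULL` selects the whole image.
#' @param settings A [segmentation_settings()].
#' @return Object of class `"pixel_classes"`: list with `labels` (integer
#'   `h x w` matrix: 1 positive, 2 negative, 0 background, `NA` outside the
#'   ROI), `roi_mask` and `settings`.
#' @export
classify_pixels <- function(image, roi_mask = NULL,
                            settings = segmentation_settings()) {
  if (length(dim(image)) != 3L || dim(image)[3L] < 3L) {
    stop("image must be an h x w x 3 RGB array", call. = FALSE)
  }
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, h, w)
  if (!identical(dim(roi_mask), c(h, w))) {
    stop("roi_mask must match the image's spatial shape", call. = FALSE)
  }
  idx <- which(roi_mask)
  if (length(idx) == 0L) stop("ROI is empty", call. = FALSE)
  rgb <- rbind(image[, , 1L][idx], image[, , 2L][idx], image[, , 3L][idx])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  labels <- matrix(NA_integer_, h, w)
  bg <- hsv[2L, ] < settings$saturation_min |
    hsv[3L, ] >= settings$white_value_min
  pos <- !bg &
    hue_distance(hsv[1L, ], settings$hue_center) <= settings$hue_window / 2
  lab <- integer(length(idx))       # background = 0
  lab[pos] <- 1L
  lab[!bg & !pos] <- 2L
  labels[idx] <- lab
  structure(list(labels = labels, roi_mask = roi_mask, settings = settings),
            class = "pixel_classes")
}

#' Fractional tissue composition of a classified ROI
#'
#' Cellularity is the fraction of ROI pixels labelled positive, stroma
#' (FSM) the fraction labelled negative, and luminal space the remainder —
#' equivalently the background fraction, since the labels partition the
#' ROI. The three fractions sum to one exactly.
#'
#' @param classes A [classify_pixels()] result.
#' @return One-row tibble: `cellularity`, `fsm`, `luminal`, `n_pixels`.
#' @export
compute_tissue_fractions <- function(classes) {
  if (!inherits(classes, "pixel_classes")) {
    stop("classes must be a pixel_classes object", call. = FALSE)
  }
  lab <- classes$labels[!is.na(classes$labels)]
  n <- length(lab)
  if (n == 0L) stop("ROI is empty", call. = FALSE)
  pos <- sum(lab == 1L)
  neg <- sum(lab == 2L)
  tibble::tibble(cellularity = pos / n, fsm = neg / n,
                 luminal = (n - pos - neg) / n, n_pixels = n)
}

#' Rasterize a polygonal ROI to a pixel mask
#'
#' A pixel belongs to the ROI iff its centre lies inside the polygon under
#' the even-odd rule. Pixel coordinates are 0-based with centres at integer
#' + 0.5; `x` runs along columns, `y` along rows.
#'
#' @param vertices Two-column matrix (or list of `c(x, y)` pairs) of
#'   polygon vertices in pixel coordinates, at least 3.
#' @param shape Image dimensions `c(rows, cols)`.
#' @return Logical `rows x cols` matrix.
#' @export
rasterize_roi <- function(vertices, shape) {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("polygon needs >= 3 vertices", call. = FALSE)
  rows <- shape[1L]; cols <- shape[2L]
  px <- rep(seq_len(cols) - 0.5, each = rows)   # x = column centre
  py <- rep(seq_len(rows) - 0.5, times = cols)  # y = row centre
  inside <- rep(FALSE, rows * cols)
  nv <- nrow(vertices)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- vertices[i, 1L]; yi <- vertices[i, 2L]
    xj <- vertices[j, 1L]; yj <- vertices[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mask <- matrix(inside, nrow = rows, ncol = cols)
  if (!any(mask)) {
    stop("polygon covers no pixel centres (degenerate or outside the image)",
         call. = FALSE)
  }
  mask
}

#' @export
print.pixel_classes <- function(x, ...) {
  fr <- compute_tissue_fractions(x)
  cat(sprintf(
    "<pixel_classes> %d ROI pixels: %.3f positive, %.3f negative, %.3f background\n",
    fr$n_pixels, fr$cellularity, fr$fsm, fr$luminal))
  invisible(x)
}
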