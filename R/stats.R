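#' Median of a parameter map over an ROI
#'
#' Median of the non-missing map values selected by the mask; voxels
#' flagged missing (`NA`/`NaN` sentinels from skipped or failed fits) are
#' excluded and their count reported via the `"n_excluded"` attribute.
#' Even voxel counts average the two central order statistics.
#'
#' @param map Numeric array (e.g. one map from [fit_dki_volume()]).
#' @param mask Logical array of the same shape selecting the ROI.
#' @return The median value, with attributes `n_used` and `n_excluded`.
#' @export
roi_median <- function(map, mask) {
  if (!identical(dim(map), dim(mask))) {
    stop("map and mask shapes differ", call. = FALSE)
  }
  v <- map[mask]
  keep <- is.finite(v)
  if (!any(keep)) {
    stop("ROI contains no non-missing voxels", call. = FALSE)
  }
  out <- stats::median(v[keep])
  attr(out, "n_used") <- sum(keep)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum (Mann-Whitney) test. Midranks are shared across
#' ties. The p-value comes from exact enumeration of all
#' `choose(n1 + n2, n1)` group assignments when `n1 + n2 <= 20` and the
#' pooled data are tie-free, and otherwise from the normal approximation
#' with tie-corrected variance and continuity correction. The reported
#' statistic is `W`, the rank sum of `x` in the pooled sample.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return One-row tibble: `statistic` (W), `p_value`, `n1`, `n2`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
rank_sum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic) + n1 * (n1 + 1) / 2,
    p_value = min(wt$p.value, 1),
    n1 = n1, n2 = n2,
    method = if (exact) "exact" else "normal_approx"
  )
}

#' Spearman rank correlation
#'
#' Spearman's rho computed as the Pearson correlation of midranks, with a
#' two-sided p-value from `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' referenced to the t distribution on `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors of equal length `n >= 3`.
#' @return One-row tibble: `statistic` (rho), `p_value`, `n1` (= n), `n2`
#'   (`NA`), `method` (`"t_approx"`).
#' @export
spearman_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must be paired", call. = FALSE)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("correlation undefined: constant ranks", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1 - 1e-15) {
    0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  tibble::tibble(statistic = rho, p_value = p, n1 = n, n2 = NA_integer_,
                 method = "t_approx")
}

cohort_schema <- c("patient_id", "roi_id", "tissue", "gs_group",
                   "median_d_app", "median_k_app", "cellularity", "fsm",
                   "luminal", "area_mm2")

check_cohort_table <- function(table) {
  missing <- setdiff(cohort_schema, names(table))
  if (length(missing) > 0L) {
    stop("cohort table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(table)
}

#' Run the full ROI-level study analysis grid
#'
#' Reproduces the study's comparison grid over a cohort table of ROI
#' records: (a) tumor-vs-normal rank-sum tests on each tissue fraction and
#' each DKI median; (b) high-grade-vs-low-grade (Gleason >= 4+3 vs <= 3+4)
#' rank-sum tests on the same quantities within tumors; (c) Spearman
#' correlations between each fraction and each DKI median, separately
#' within normal and tumor records. The unit of analysis is the ROI.
#' Always 22 rows: 5 + 5 comparisons and 12 correlations.
#'
#' @param table Cohort tibble/data frame with columns `patient_id`,
#'   `roi_id`, `tissue` (`"tumor"`/`"normal"`), `gs_group`
#'   (`"low"`/`"high"`/`"none"`), `median_d_app`, `median_k_app`,
#'   `cellularity`, `fsm`, `luminal`, `area_mm2`.
#' @return Tibble with columns `comparison`, `variable`, `stratum`,
#'   `statistic`, `p_value`, `n1`, `n2`, `method`.
#' @export
run_study_analyses <- function(table) {
  check_cohort_table(table)
  vars <- c("cellularity", "fsm", "luminal", "median_d_app", "median_k_app")
  tum <- table[table$tissue == "tumor", ]
  nor <- table[table$tissue == "normal", ]
  hi <- tum[tum$gs_group == "high", ]
  lo <- tum[tum$gs_group == "low", ]
  for (nm in c("tumor", "normal", "GS-high", "GS-low")) {
    grp <- switch(nm, tumor = tum, normal = nor, `GS-high` = hi, `GS-low` = lo)
    if (nrow(grp) < 2L) {
      stop("need >= 2 records per compared group; ", nm, " has ", nrow(grp),
           call. = FALSE)
    }
  }
  cmp_rows <- function(comparison, a, b, stratum) {
    purrr::map_dfr(vars, function(v) {
      dplyr::mutate(rank_sum_test(a[[v]], b[[v]]),
                    comparison = comparison, variable = v,
                    stratum = stratum, .before = 1L)
    })
  }
  cor_rows <- purrr::map_dfr(c("normal", "tumor"), function(strat) {
    dat <- if (strat == "tumor") tum else nor
    purrr::map_dfr(c("median_d_app", "median_k_app"), function(dki) {
      purrr::map_dfr(c("cellularity", "fsm", "luminal"), function(fr) {
        dplyr::mutate(spearman_correlation(dat[[dki]], dat[[fr]]),
                      comparison = "correlation",
                      variable = paste(dki, fr, sep = "~"),
                      stratum = strat, .before = 1L)
      })
    })
  })
  dplyr::bind_rows(
    cmp_rows("tumor_vs_normal", tum, nor, "all"),
    cmp_rows("gs_high_vs_low", hi, lo, "tumor"),
    cor_rows
  )
}

#' Human-readable study analysis report
#'
#' @param analysis Result of [run_study_analyses()].
#' @return Character vector of report lines (invisibly printed with
#'   `cat()` when called interactively via `print_study_report()`).
#' @export
format_study_report <- function(analysis) {
  lines <- c(
    "ROI-level study analysis (unit of analysis: ROI, not patient;",
    "within-patient clustering is not modelled). '*' marks p < 0.05.",
    ""
  )
  fmt <- sprintf("%-16s %-28s %-7s %9.4g %9.4g %4s %s",
                 analysis$comparison, analysis$variable, analysis$stratum,
                 analysis$statistic, analysis$p_value,
                 ifelse(is.na(analysis$n2), analysis$n1,
                        paste0(analysis$n1, "/", analysis$n2)),
                 ifelse(analysis$p_value < 0.05, "*", ""))
  c(lines, fmt)
}
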