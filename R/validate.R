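# Method-validation statistics: spike recovery, calibration linearity with
# LOD/LOQ, coefficients of variation, and the combined CV + Kendrick
# retention filter.

#' Percent coefficient of variation
#'
#' 100 * sample standard deviation / mean.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return CV as a percentage.
#' @examples
#' cv_percent(c(8, 10, 12))  # 20
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Spike recovery per class
#'
#' For each spike level, the mean over replicates of measured/expected
#' expressed as a percentage; the class recovery is the mean over levels.
#'
#' @param spikes Tibble with columns `class`, `level`, `measured`,
#'   `expected` (one row per replicate).
#' @param levels Spike levels that must be present (mg/L).
#' @return Tibble `class`, `recovery_pct`, plus per-level columns
#'   `recovery_<level>`.
#' @export
recovery <- function(spikes, levels = c(0.1, 0.5, 1)) {
  found <- sort(unique(spikes$level))
  absent <- setdiff(levels, found)
  if (length(absent))
    stop("spike level(s) ", paste(absent, collapse = ", "),
         " absent; found: ", paste(found, collapse = ", "))
  spikes <- spikes[spikes$level %in% levels, ]
  per_level <- dplyr::summarise(
    dplyr::group_by(spikes, .data$class, .data$level),
    recovery = mean(.data$measured / .data$expected) * 100, .groups = "drop")
  per_class <- dplyr::summarise(dplyr::group_by(per_level, .data$class),
                                recovery_pct = mean(.data$recovery),
                                .groups = "drop")
  wide <- tidyr::pivot_wider(per_level, names_from = "level",
                             values_from = "recovery",
                             names_prefix = "recovery_")
  dplyr::left_join(per_class, wide, by = "class")
}

#' Calibration linearity, LOD and LOQ
#'
#' Finds the longest contiguous run of calibration points whose ordinary
#' least-squares fit reaches R^2 >= `r2_min` with every back-calculated
#' concentration within `accuracy_tol` of nominal. The LOQ is the lowest
#' point of that run; the LOD is the concentration at which the predicted
#' signal-to-noise ratio reaches 3.3 (3.3 * noise / slope).
#'
#' @param conc Strictly increasing calibration concentrations (>= 5).
#' @param response Measured responses, same length.
#' @param noise Noise estimate on the response scale (calibration residual
#'   SD or blank noise). 0 yields a below-lowest-level sentinel; NULL
#'   leaves the LOD NA.
#' @param r2_min,accuracy_tol Linearity acceptance criteria.
#' @param min_points Minimum run length considered.
#' @return List: `range` (low, high), `loq`, `lod`, `slope`, `intercept`,
#'   `r2`, `flag` ("ok", "no_linear_range", "lod_below_lowest_level").
#' @export
linearity_lod <- function(conc, response, noise = NULL,
                          r2_min = 0.99, accuracy_tol = 0.20,
                          min_points = 3) {
  if (length(conc) < 5) stop("need >= 5 calibration points")
  if (is.unsorted(conc, strictly = TRUE))
    stop("calibration concentrations must be strictly increasing")
  n <- length(conc)
  best <- NULL
  for (len in n:min_points) {
    for (start in 1:(n - len + 1)) {
      i <- start:(start + len - 1)
      fit <- stats::lm(response[i] ~ conc[i])
      slope <- stats::coef(fit)[[2]]
      if (slope <= 0) next
      r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
      back <- (response[i] - stats::coef(fit)[[1]]) / slope
      acc_ok <- all(abs(back - conc[i]) / conc[i] <= accuracy_tol)
      if (r2 >= r2_min && acc_ok) {
        best <- list(i = i, slope = slope,
                     intercept = stats::coef(fit)[[1]], r2 = r2)
        break
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best))
    return(list(range = c(NA_real_, NA_real_), loq = NA_real_,
                lod = NA_real_, slope = NA_real_, intercept = NA_real_,
                r2 = NA_real_, flag = "no_linear_range"))
  lod <- if (is.null(noise)) NA_real_ else 3.3 * noise / best$slope
  flag <- "ok"
  if (!is.na(lod) && lod < min(conc[best$i]) && !is.null(noise) && noise == 0)
    flag <- "lod_below_lowest_level"
  list(range = c(min(conc[best$i]), max(conc[best$i])),
       loq = min(conc[best$i]), lod = lod,
       slope = best$slope, intercept = best$intercept, r2 = best$r2,
       flag = flag)
}

#' Filter compounds on repeatability and Kendrick grid agreement
#'
#' Retains compounds with repeatability CV <= `cv_threshold` (inclusive)
#' whose Kendrick grid flag is "pass". Intra-/inter-day thresholds can be
#' applied as additional exclusion criteria or carried descriptively.
#'
#' @param records Tibble with `transition_id`, `class`,
#'   `repeatability_cv`, `kmd_flag`, and optionally `intra_day_cv`,
#'   `inter_day_cv`.
#' @param cv_threshold Repeatability cutoff (percent; default 20).
#' @param apply_intra_inter Also exclude on intra-day (> `intra_threshold`)
#'   and inter-day (> `inter_threshold`) CV.
#' @param intra_threshold,inter_threshold Intra-/inter-day cutoffs (15/20).
#' @return List: `retained` (filtered records) and `summary` (per-class
#'   `in_method` and `validated` counts).
#' @export
validation_filter <- function(records, cv_threshold = 20,
                              apply_intra_inter = FALSE,
                              intra_threshold = 15, inter_threshold = 20) {
  keep <- records$repeatability_cv <= cv_threshold &
    records$kmd_flag == "pass"
  if (apply_intra_inter) {
    if (!all(c("intra_day_cv", "inter_day_cv") %in% names(records)))
      stop("intra/inter-day CVs requested but not present")
    keep <- keep & records$intra_day_cv <= intra_threshold &
      records$inter_day_cv <= inter_threshold
  }
  retained <- records[keep, ]
  records$.keep <- keep
  summary <- dplyr::summarise(dplyr::group_by(records, .data$class),
                              in_method = dplyr::n(),
                              validated = sum(.data$.keep),
                              .groups = "drop")
  list(retained = retained, summary = summary)
}
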