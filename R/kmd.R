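# Kendrick mass defect (CH2 base) annotation validation. On a KMD-vs-RT
# plot of a correctly annotated homologous lipid class, species with equal
# double-bond count share a KMD (horizontal alignment, RT growing with
# chain length) and species with equal carbon count fall on a diagonal
# (RT shrinking as double bonds are added).

.CH2_EXACT <- 14.01565

#' Kendrick mass and mass defect (CH2 base)
#'
#' KM = m/z * 14 / 14.01565; KMD = nearest-integer(KM) - KM, so CH2
#' homologs share KMD exactly and |KMD| <= 0.5.
#'
#' @param mz Positive numeric vector of m/z values.
#' @return Tibble with columns `mz`, `km`, `kmd`.
#' @examples
#' kendrick(14.01565)$kmd  # 0
#' @export
kendrick <- function(mz) {
  if (any(!is.finite(mz) | mz <= 0)) stop("m/z values must be positive")
  km <- mz * 14 / .CH2_EXACT
  tibble::tibble(mz = mz, km = km, kmd = round(km) - km)
}

#' Grid-structure check of annotated Kendrick points
#'
#' Flags annotation outliers from the KMD/RT grid of each class:
#' `horizontal_violation` when a point's KMD deviates from its equal-DB
#' series consensus (median) by more than `kmd_tolerance`;
#' `diagonal_violation` when retention time breaks the expected ordering
#' (increasing with carbons at fixed DB, decreasing with DB at fixed
#' carbons, with `rt_tolerance` slack). RT violations are corroborated
#' across the two grid directions where both are checkable, so a planted
#' swap is attributed to the swapped points rather than their neighbours.
#' Series with fewer than 3 members are passed with a `singleton` note.
#'
#' @param points Tibble with columns `transition_id`, `mz`, `rt`, `class`,
#'   `total_carbons`, `total_db`.
#' @param rt_tolerance RT slack in minutes (default 0.05).
#' @param kmd_tolerance KMD deviation tolerance (default 0.003; use a
#'   tighter value to catch isotope-scale m/z errors, whose KMD shift is
#'   ~0.0022, rather than double-bond annotation errors at ~0.013).
#' @return `points` with `km`, `kmd`, `flag` (pass / diagonal_violation /
#'   horizontal_violation) and `note` (checked / singleton) columns.
#' @export
grid_check <- function(points, rt_tolerance = 0.05, kmd_tolerance = 0.003) {
  need <- c("transition_id", "mz", "rt", "class", "total_carbons", "total_db")
  missing_cols <- setdiff(need, names(points))
  if (length(missing_cols))
    stop("points lacks column(s): ", paste(missing_cols, collapse = ", "))
  key <- paste(points$class, points$total_carbons, points$total_db)
  if (anyDuplicated(key))
    stop("duplicate (class, carbons, double bonds) entries make the grid ",
         "ambiguous: ", key[duplicated(key)][1])

  kd <- kendrick(points$mz)
  points$km <- kd$km
  points$kmd <- kd$kmd
  n <- nrow(points)
  horizontal <- logical(n)
  votes <- integer(n)
  checkable <- integer(n)   # number of >=3-member series each point sits in
  in_series <- logical(n)

  # adjacent-pair monotonicity votes within one ordered series
  vote_series <- function(idx, ord_by, decreasing = FALSE) {
    idx <- idx[order(points[[ord_by]][idx])]
    rt <- points$rt[idx]
    for (a in seq_len(length(idx) - 1)) {
      bad <- if (decreasing) rt[a + 1] > rt[a] + rt_tolerance
             else            rt[a + 1] < rt[a] - rt_tolerance
      if (bad) votes[idx[c(a, a + 1)]] <<- votes[idx[c(a, a + 1)]] + 1L
    }
  }

  for (grp in split(seq_len(n), paste(points$class[seq_len(n)], points$total_db))) {
    if (length(grp) >= 3) {
      in_series[grp] <- TRUE
      checkable[grp] <- checkable[grp] + 1L
      dev <- abs(points$kmd[grp] - stats::median(points$kmd[grp]))
      horizontal[grp[dev > kmd_tolerance]] <- TRUE
      vote_series(grp, "total_carbons", decreasing = FALSE)
    }
  }
  for (grp in split(seq_len(n), paste(points$class, points$total_carbons))) {
    if (length(grp) >= 3) {
      in_series[grp] <- TRUE
      checkable[grp] <- checkable[grp] + 1L
      vote_series(grp, "total_db", decreasing = TRUE)
    }
  }

  diagonal <- checkable > 0 & votes >= pmin(2L, checkable)
  points$flag <- ifelse(horizontal, "horizontal_violation",
                        ifelse(diagonal, "diagonal_violation", "pass"))
  points$note <- ifelse(in_series, "checked", "singleton")
  if (any(!in_series))
    warning(sum(!in_series), " point(s) belong to no series with >= 3 ",
            "members and were passed by default")
  points
}
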