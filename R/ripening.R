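# Ripening-trend analysis: exploratory PCA on log/Pareto-scaled
# concentrations, resampling and permutation validation of the PLS Brix
# model, and the quartile-based class-level coefficient summary.

#' Assemble the analysis matrix from a long concentration table
#'
#' @param conc Long concentration tibble (`sample_id`, `transition_id`,
#'   `class`, `conc_ug_g`), complete (post-imputation).
#' @param samples Sample metadata with `sample_id`, `brix`, and `role`;
#'   only `role == "study"` samples enter the matrix.
#' @return List: `x` (samples x compounds matrix), `brix`, `classes`
#'   (per-compound class labels, aligned with `colnames(x)`).
#' @export
analysis_matrix <- function(conc, samples) {
  study <- samples[samples$role == "study", ]
  m <- conc_matrix(conc[conc$sample_id %in% study$sample_id, ])
  if (anyNA(m)) stop("analysis matrix has missing entries; impute first")
  classes <- conc$class[match(colnames(m), conc$transition_id)]
  list(x = m,
       brix = study$brix[match(rownames(m), study$sample_id)],
       classes = stats::setNames(classes, colnames(m)))
}

#' PCA on log-transformed, Pareto-scaled concentrations
#'
#' Pareto scaling divides each centred compound by the square root of its
#' standard deviation, tempering the dominance of abundant lipids without
#' flattening variance entirely. Zero-variance compounds are dropped with
#' a warning.
#'
#' @param x Samples x compounds matrix, strictly positive, complete.
#' @param log Natural-log transform first (default TRUE).
#' @param scaling `"pareto"` (default), `"uv"` or `"none"` (centre only).
#' @return List: `scores`, `loadings`, `explained_variance` (fractions
#'   summing to 1), `sdev`.
#' @export
pareto_pca <- function(x, log = TRUE, scaling = c("pareto", "uv", "none")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("PCA needs at least 3 samples")
  if (anyNA(x)) stop("matrix has missing entries; impute first")
  if (log) {
    if (any(x <= 0)) stop("log transform requires strictly positive values")
    x <- base::log(x)
  }
  sdx <- apply(x, 2, stats::sd)
  if (any(sdx == 0)) {
    warning(sum(sdx == 0), " zero-variance compound(s) dropped")
    x <- x[, sdx > 0, drop = FALSE]
    sdx <- sdx[sdx > 0]
  }
  div <- switch(scaling, pareto = sqrt(sdx), uv = sdx,
                none = rep(1, ncol(x)))
  xs <- sweep(sweep(x, 2, colMeans(x)), 2, div, "/")
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = ev, sdev = pc$sdev)
}

# Q2 on a held-out set: 1 - PRESS / TSS, TSS centred on the training mean
q2_score <- function(y_test, pred, train_mean) {
  1 - sum((y_test - pred)^2) / sum((y_test - train_mean)^2)
}

#' Predictive Q2 distribution over repeated random splits
#'
#' Repeatedly splits the samples into training and test segments (2/3 vs
#' 1/3 by default), fits the PLS model on the training segment and scores
#' Q2 = 1 - PRESS/TSS on the held-out third (TSS centred on the training
#' mean). Degenerate splits with constant training response are skipped
#' and counted.
#'
#' @param x,y As in [fit_pls()].
#' @param n Number of random splits (default 1000).
#' @param split Training fraction (default 2/3).
#' @param ncomp Component count per split; NULL re-selects by CV on each
#'   training segment (slower).
#' @param scaling,log As in [fit_pls()].
#' @param seed Seed; the whole distribution is reproducible.
#' @param permute Permute `y` independently on each iteration (used by
#'   [permutation_null()]).
#' @return List: `q2` (numeric vector of length <= n), `median`,
#'   `n_skipped`.
#' @export
q2_resampling <- function(x, y, n = 1000, split = 2 / 3, ncomp = 2,
                          scaling = "uv", log = TRUE, seed = 1,
                          permute = FALSE) {
  if (n < 1) stop("n must be >= 1")
  x <- as.matrix(x)
  if (nrow(x) < 6) stop("need >= 6 samples for a 2/3-1/3 split")
  if (log) {
    if (any(x <= 0)) stop("log transform requires strictly positive values")
    x <- base::log(x)
  }
  n_train <- max(2, round(split * nrow(x)))
  set.seed(seed)
  q2 <- numeric(0)
  n_skipped <- 0
  for (b in seq_len(n)) {
    yb <- if (permute) sample(y) else y
    idx <- sample(nrow(x), n_train)
    if (stats::sd(yb[idx]) == 0) { n_skipped <- n_skipped + 1; next }
    keep <- apply(x[idx, , drop = FALSE], 2, stats::sd) > 0
    a <- ncomp
    if (is.null(a)) {
      a <- cv_select_ncomp(x[idx, keep, drop = FALSE], yb[idx],
                           folds = 10, max_comp = 10,
                           scaling = scaling)$ncomp
    }
    fit <- simpls_fit(x[idx, keep, drop = FALSE], yb[idx],
                      ncomp = a, scaling = scaling)
    pred <- simpls_predict(fit, x[-idx, keep, drop = FALSE])
    q2 <- c(q2, q2_score(yb[-idx], pred, mean(yb[idx])))
  }
  list(q2 = q2, median = stats::median(q2), n_skipped = n_skipped)
}

#' Permutation null of the Q2 distribution
#'
#' As [q2_resampling()], with the response permuted independently on each
#' iteration; the component count is re-selected by cross-validation per
#' permutation by default, so the null reflects the whole selection
#' procedure.
#'
#' @inheritParams q2_resampling
#' @param ncomp NULL (default) re-selects per permutation.
#' @return List: `q2`, `median`, `n_skipped`.
#' @export
permutation_null <- function(x, y, n = 1000, split = 2 / 3, ncomp = NULL,
                             scaling = "uv", log = TRUE, seed = 1) {
  q2_resampling(x, y, n = n, split = split, ncomp = ncomp,
                scaling = scaling, log = log, seed = seed, permute = TRUE)
}

#' Class-level quartile summary of PLS coefficients
#'
#' Thresholds are the 25th and 75th percentiles (type-7 interpolation) of
#' all regression coefficients; a compound sits in Q1/Q4 when its
#' coefficient is strictly below/above the threshold. Per class, the
#' count and fraction of members in each tail summarise whether the class
#' as a whole rises or falls with ripeness.
#'
#' @param coefficients Named numeric vector (one per compound), e.g.
#'   `fit$coefficients` from [fit_pls()].
#' @param classes Class label per compound (named or aligned).
#' @return Tibble: `class`, `n`, `n_q1`, `n_q4`, `frac_q1`, `frac_q4`,
#'   plus attributes `q1_threshold` and `q4_threshold`.
#' @export
quartile_class_summary <- function(coefficients, classes) {
  if (length(coefficients) != length(classes))
    stop("coefficients and classes lengths differ")
  if (!is.null(names(coefficients)) && !is.null(names(classes)))
    classes <- classes[names(coefficients)]
  if (any(is.na(classes))) stop("class label missing for some compounds")
  thr <- stats::quantile(coefficients, c(0.25, 0.75), type = 7,
                         names = FALSE)
  d <- tibble::tibble(class = as.character(classes),
                      q1 = coefficients < thr[1],
                      q4 = coefficients > thr[2])
  out <- dplyr::summarise(dplyr::group_by(d, .data$class),
                          n = dplyr::n(),
                          n_q1 = sum(.data$q1), n_q4 = sum(.data$q4),
                          frac_q1 = mean(.data$q1),
                          frac_q4 = mean(.data$q4), .groups = "drop")
  attr(out, "q1_threshold") <- thr[1]
  attr(out, "q4_threshold") <- thr[2]
  out
}
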