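# Partial least squares regression core (SIMPLS, single response).
# Weight vectors are extracted from the successively deflated covariance
# X'y; coefficients are returned on the original predictor axis. The
# full-rank model coincides with ordinary least squares and the
# one-component weight vector is proportional to X'y, which the tests use
# as independent oracles.

simpls_fit <- function(x, y, ncomp, scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n, n > 1)
  xm <- colMeans(x)
  sdx <- apply(x, 2, stats::sd)
  if (any(sdx == 0)) stop("zero-variance predictor; drop before fitting")
  xs <- switch(scaling, uv = sdx, pareto = sqrt(sdx), none = rep(1, p))
  xc <- sweep(sweep(x, 2, xm), 2, xs, "/")
  ym <- mean(y)
  yc <- y - ym

  ncomp <- min(ncomp, n - 1, p)
  s <- crossprod(xc, yc)
  V <- matrix(0, p, ncomp)
  R <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  used <- 0
  for (a in seq_len(ncomp)) {
    if (sqrt(sum(s^2)) < 1e-12) break   # residual covariance exhausted
    r <- s
    t <- xc %*% r
    nt <- sqrt(sum(t^2))
    t <- t / nt
    r <- r / nt
    pa <- crossprod(xc, t)
    q[a] <- drop(crossprod(yc, t))
    v <- pa
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pa)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    V[, a] <- v
    R[, a] <- r
    used <- a
  }
  if (used == 0) stop("response has no covariance with predictors")
  # cumulative coefficients (scaled axis) for each component count
  bscaled <- sapply(seq_len(used), function(a)
    R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)])
  beta <- sweep(matrix(bscaled, nrow = p), 1, xs, "/")
  intercept <- ym - drop(crossprod(beta, xm))
  rownames(beta) <- colnames(x)
  list(beta = beta, intercept = intercept, ncomp = used,
       xm = xm, xs = xs, ym = ym, scaling = scaling)
}

simpls_predict <- function(fit, x, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  drop(as.matrix(x) %*% fit$beta[, ncomp]) + fit$intercept[ncomp]
}

# 10-fold cross-validated RMSEP for 1..max_comp components, with the
# one-standard-error rule breaking ties toward fewer components
cv_select_ncomp <- function(x, y, folds = 10, max_comp = 10,
                            scaling = "uv") {
  n <- nrow(x)
  folds <- min(folds, n)
  max_comp <- min(max_comp, n - ceiling(n / folds) - 1, ncol(x))
  max_comp <- max(max_comp, 1)
  assign <- sample(rep(seq_len(folds), length.out = n))
  sq_err <- matrix(NA_real_, n, max_comp)
  for (f in seq_len(folds)) {
    test <- assign == f
    if (stats::sd(y[!test]) == 0) next
    keep <- apply(x[!test, , drop = FALSE], 2, stats::sd) > 0
    fit <- simpls_fit(x[!test, keep, drop = FALSE], y[!test],
                      ncomp = max_comp, scaling = scaling)
    for (a in seq_len(max_comp)) {
      pred <- simpls_predict(fit, x[test, keep, drop = FALSE], a)
      sq_err[test, a] <- (y[test] - pred)^2
    }
  }
  rmsep <- sqrt(colMeans(sq_err, na.rm = TRUE))
  per_fold <- sapply(seq_len(max_comp), function(a)
    sqrt(tapply(sq_err[, a], assign, mean, na.rm = TRUE)))
  best <- which.min(rmsep)
  se_best <- stats::sd(per_fold[, best], na.rm = TRUE) / sqrt(folds)
  ncomp <- which(rmsep <= rmsep[best] + se_best)[1]
  list(ncomp = ncomp, rmsep = rmsep)
}

#' Fit a PLS regression of a response on a compound matrix
#'
#' SIMPLS with a single response. The component count is chosen by k-fold
#' cross-validation (minimum RMSEP with a one-standard-error tie-break
#' toward fewer components) unless given. Predictors are log-transformed
#' (natural log; inputs must then be strictly positive), centred and
#' scaled; coefficients are reported on the transformed compound axis.
#'
#' @param x Samples x compounds matrix, complete (post-imputation).
#' @param y Numeric response (degrees Brix), one value per row of `x`.
#' @param ncomp Component count; NULL (default) selects by CV.
#' @param folds CV folds (default 10).
#' @param max_comp Largest component count considered.
#' @param scaling `"uv"` (unit variance, default) or `"pareto"`.
#' @param log Apply natural log to `x` first (default TRUE).
#' @param seed Seed for the CV fold assignment.
#' @return A `pls_fit`: `coefficients` (named, per compound), `intercept`,
#'   `ncomp`, `r2`, `fitted`, `rmsep` (CV curve, when selected), plus the
#'   fitted core for prediction.
#' @export
fit_pls <- function(x, y, ncomp = NULL, folds = 10, max_comp = 10,
                    scaling = c("uv", "pareto"), log = TRUE, seed = 1) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  if (nrow(x) < folds && is.null(ncomp))
    stop("need at least `folds` samples for cross-validated selection")
  if (log) {
    if (any(x <= 0)) stop("log transform requires strictly positive values")
    x <- base::log(x)
  }
  keep <- apply(x, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance compound(s) dropped")
    x <- x[, keep, drop = FALSE]
  }
  rmsep <- NULL
  if (is.null(ncomp)) {
    set.seed(seed)
    sel <- cv_select_ncomp(x, y, folds = folds, max_comp = max_comp,
                           scaling = scaling)
    ncomp <- sel$ncomp
    rmsep <- sel$rmsep
  }
  fit <- simpls_fit(x, y, ncomp = ncomp, scaling = scaling)
  fitted <- simpls_predict(fit, x)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  structure(
    list(coefficients = stats::setNames(fit$beta[, fit$ncomp], colnames(x)),
         intercept = fit$intercept[fit$ncomp], ncomp = fit$ncomp,
         r2 = r2, fitted = fitted, rmsep = rmsep, core = fit,
         log = log, scaling = scaling),
    class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("<pls_fit> ", x$ncomp, " component(s), ", length(x$coefficients),
      " compounds, R2 = ", round(x$r2, 3), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted PLS model
#' @param object A `pls_fit`.
#' @param newdata Samples x compounds matrix on the raw scale.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, names(object$coefficients), drop = FALSE]
  if (object$log) newdata <- base::log(newdata)
  drop(newdata %*% object$coefficients) + object$intercept
}
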