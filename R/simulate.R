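# Synthetic-data generators: a 13-point maturation study with known
# class-level trends and a spike/recovery design, both pure functions of
# (design, seed), with the planted truth returned alongside the data.

# mean-one log-normal multiplicative noise at a given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

#' Maturation study design
#'
#' Thirteen sampling points from veraison onward with five biological
#' replicates each except the last two points (three), a monotone Brix
#' trajectory, and planted class-level trends: LPC, LPE, PE, PG, PI rise
#' with Brix; CER, MG, LPG, DGDG, MGDG fall; all other classes are
#' neutral.
#'
#' @param n_points Number of sampling points (13).
#' @param replicates Replicates per point (5, last two points 3).
#' @param brix_range Brix at the first and last point; linear in between.
#' @param brix_jitter_sd Per-replicate Brix jitter (sd, degrees Brix).
#' @param trend_up,trend_down Class ids with rising/falling planted trends.
#' @param slope Log-concentration change per degree Brix for trend classes
#'   (sign from the trend direction; per-compound magnitude jittered by
#'   `slope_jitter`).
#' @param slope_jitter Uniform multiplicative range for per-compound slopes.
#' @param noise_cv CV of the mean-one log-normal multiplicative noise.
#' @param missing_rate Probability that a compound area is missing.
#' @param n_qc Pooled QC injections appended to the series.
#' @param weight_mg_mean,weight_mg_sd Sample powder weight distribution.
#' @param is_amount_ug Internal standard amount per sample (ug).
#' @return A `maturation_design` list.
#' @export
maturation_design <- function(n_points = 13,
                              replicates = c(rep(5, n_points - 2), 3, 3),
                              brix_range = c(14, 22),
                              brix_jitter_sd = 0.15,
                              trend_up = c("LPC", "LPE", "PE", "PG", "PI"),
                              trend_down = c("CER", "MG", "LPG", "DGDG", "MGDG"),
                              slope = 0.15, slope_jitter = c(0.5, 1.5),
                              noise_cv = 0.10, missing_rate = 0.05,
                              n_qc = 6,
                              weight_mg_mean = 100, weight_mg_sd = 3,
                              is_amount_ug = 150) {
  stopifnot(length(replicates) == n_points, all(replicates >= 1))
  structure(as.list(environment()), class = "maturation_design")
}

#' Default compound panel for simulated studies
#'
#' A deterministic subset of the enumerated species: `n_per_class`
#' evenly-spaced species from each class of interest (the ten trend
#' classes plus a set of neutral classes by default).
#'
#' @param n_per_class Species per class (default 8).
#' @param classes Class ids to include.
#' @param space Chain space used for the enumeration.
#' @return Tibble `transition_id`, `class`.
#' @export
default_study_compounds <- function(n_per_class = 8,
                                    classes = c("LPC", "LPE", "PE", "PG", "PI",
                                                "CER", "MG", "LPG", "DGDG", "MGDG",
                                                "PC", "PA", "TG", "FA", "SM"),
                                    space = chain_space()) {
  rows <- lapply(classes, function(cl) {
    sp <- enumerate_species(cl, space)
    idx <- unique(round(seq(1, nrow(sp), length.out = min(n_per_class, nrow(sp)))))
    tibble::tibble(transition_id = sp$species[idx], class = cl)
  })
  dplyr::bind_rows(rows)
}

#' Simulate a maturation study peak-area table
#'
#' Forward model: per-compound baseline abundances are log-normal; trend
#' compounds follow linear-in-Brix log-concentration with the planted
#' sign; areas are generated by inverting the internal-standard
#' quantification formula so that [semi_quantify()] recovers the planted
#' concentrations exactly when the noise is switched off. QC samples are
#' pooled means. The returned truth record carries every planted slope.
#'
#' @param design A [maturation_design()].
#' @param compounds Tibble `transition_id`, `class`
#'   (default [default_study_compounds()]).
#' @param seed Integer seed; same seed, same table.
#' @return List: `areas` (long table incl. internal-standard rows),
#'   `samples` (metadata with Brix, weights, roles), `truth` (per-compound
#'   baseline and slope, plus the design).
#' @export
simulate_maturation <- function(design = maturation_design(),
                                compounds = default_study_compounds(),
                                seed = 1) {
  stopifnot(inherits(design, "maturation_design"))
  known <- compounds$class %in% .CLASS_TABLE$class
  if (!all(known))
    stop("compound class not in registry: ", compounds$class[!known][1])
  absent <- setdiff(c(design$trend_up, design$trend_down), compounds$class)
  if (length(absent))
    stop("trend class(es) absent from the compound panel: ",
         paste(absent, collapse = ", "))
  set.seed(seed)

  n_pt <- design$n_points
  reps <- design$replicates
  brix_pt <- seq(design$brix_range[1], design$brix_range[2], length.out = n_pt)
  samples <- tibble::tibble(
    sample_id = unlist(lapply(seq_len(n_pt), function(t)
      sprintf("T%02dR%d", t, seq_len(reps[t])))),
    maturation_point = rep(seq_len(n_pt), reps),
    replicate = unlist(lapply(reps, seq_len)),
    role = "study")
  samples$brix <- brix_pt[samples$maturation_point] +
    stats::rnorm(nrow(samples), 0, design$brix_jitter_sd)
  if (design$n_qc > 0) {
    samples <- dplyr::bind_rows(samples, tibble::tibble(
      sample_id = sprintf("QC%02d", seq_len(design$n_qc)),
      maturation_point = NA_integer_, replicate = seq_len(design$n_qc),
      role = "QC", brix = NA_real_))
  }
  samples$weight_mg <- pmax(50, stats::rnorm(nrow(samples),
                                             design$weight_mg_mean,
                                             design$weight_mg_sd))

  p <- nrow(compounds)
  direction <- ifelse(compounds$class %in% design$trend_up, 1,
                      ifelse(compounds$class %in% design$trend_down, -1, 0))
  truth <- tibble::tibble(
    transition_id = compounds$transition_id, class = compounds$class,
    baseline_log = stats::rnorm(p, log(5), 1),
    slope = direction * design$slope *
      stats::runif(p, design$slope_jitter[1], design$slope_jitter[2]))

  study <- samples$role == "study"
  brix_centre <- mean(samples$brix[study])
  # planted concentration (ug/g), QC = pooled mean of the study samples
  conc_at <- function(brix) {
    exp(outer(truth$baseline_log, rep(1, length(brix))) +
          outer(truth$slope, brix - brix_centre))
  }
  conc <- matrix(NA_real_, p, nrow(samples))
  conc[, study] <- conc_at(samples$brix[study])
  if (any(!study)) conc[, !study] <- rowMeans(conc[, study, drop = FALSE])

  is_map <- internal_standards()
  is_ids <- unique(is_map$is_id)
  is_area <- matrix(1e6 * rlnorm_cv(length(is_ids) * nrow(samples),
                                    design$noise_cv),
                    nrow = length(is_ids),
                    dimnames = list(is_ids, samples$sample_id))
  compound_is <- is_map$is_id[match(compounds$class, is_map$class)]

  weight_g <- matrix(samples$weight_mg / 1000, p, nrow(samples), byrow = TRUE)
  area <- conc * weight_g / design$is_amount_ug *
    is_area[compound_is, , drop = FALSE] *
    matrix(rlnorm_cv(p * nrow(samples), design$noise_cv), p)
  if (design$missing_rate > 0)
    area[stats::runif(length(area)) < design$missing_rate] <- NA_real_

  areas <- tibble::tibble(
    sample_id = rep(samples$sample_id, each = p),
    transition_id = rep(compounds$transition_id, nrow(samples)),
    area = as.vector(area))
  is_long <- tibble::tibble(
    sample_id = rep(samples$sample_id, each = length(is_ids)),
    transition_id = rep(is_ids, nrow(samples)),
    area = as.vector(is_area))
  list(areas = dplyr::bind_rows(areas, is_long),
       samples = samples,
       truth = list(compounds = truth, design = design, seed = seed,
                    brix_centre = brix_centre))
}

#' Simulate a spike/recovery design
#'
#' Forward model consistent with [recovery()]: at each level and
#' replicate, `measured = expected * true_recovery/100 * noise`, with
#' mean-one log-normal noise, so the recovery estimator is unbiased.
#'
#' @param true_recovery Named numeric vector of planted per-class
#'   recoveries (percent).
#' @param levels Spike levels (mg/L); default 0.1, 0.5, 1.
#' @param replicates Replicates per level (default 5).
#' @param noise_cv Multiplicative noise CV (default 0.05).
#' @param seed Integer seed.
#' @return Tibble `class`, `level`, `replicate`, `expected`, `measured`.
#' @export
simulate_spike_design <- function(true_recovery,
                                  levels = c(0.1, 0.5, 1),
                                  replicates = 5, noise_cv = 0.05,
                                  seed = 1) {
  if (any(levels <= 0)) stop("spike levels must be positive")
  if (is.null(names(true_recovery)))
    stop("true_recovery must be named by class")
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), level = levels,
                      class = names(true_recovery),
                      stringsAsFactors = FALSE)
  grid$expected <- grid$level
  grid$measured <- grid$expected *
    true_recovery[grid$class] / 100 *
    rlnorm_cv(nrow(grid), noise_cv)
  tibble::as_tibble(grid[, c("class", "level", "replicate",
                             "expected", "measured")])
}
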