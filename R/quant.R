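# Internal-standard semi-quantification and missing-value imputation.
# Concentrations are reported in ug per g of fresh powder:
#   conc = area(compound) / area(class IS) * IS amount (ug) / weight (g).

#' Semi-quantify peak areas against class internal standards
#'
#' @param areas Long peak-area tibble: `sample_id`, `transition_id`,
#'   `area` (>= 0 or NA for missing). Internal-standard areas appear as
#'   rows whose `transition_id` is the IS identifier.
#' @param samples Sample metadata tibble with `sample_id` and `weight_mg`
#'   (> 0, mg of powder extracted).
#' @param compounds Tibble mapping `transition_id` to `class`; defaults to
#'   a `class` column carried in `areas`.
#' @param is_amount_ug Amount of each internal standard added per sample,
#'   in ug. The default 150 reflects 15 uL of a 10 mg/mL standard mix.
#' @param is_map Tibble mapping `class` to `is_id`; defaults to the
#'   registry assignment ([internal_standards()]).
#' @return Tibble `sample_id`, `transition_id`, `class`, `conc_ug_g`
#'   (NA areas propagate to NA concentrations for later imputation).
#' @export
semi_quantify <- function(areas, samples, compounds = NULL,
                          is_amount_ug = 150, is_map = NULL) {
  if (is.null(compounds)) {
    if (!"class" %in% names(areas))
      stop("supply `compounds` or include a class column in `areas`")
    compounds <- dplyr::distinct(areas[, c("transition_id", "class")])
  }
  if (is.null(is_map)) is_map <- internal_standards()[, c("class", "is_id")]
  if (any(!is.finite(samples$weight_mg) | samples$weight_mg <= 0))
    stop("non-positive sample weight for sample ",
         samples$sample_id[which(samples$weight_mg <= 0)[1]])

  # one IS may serve several classes (the ceramide family shares one)
  is_obs <- areas[areas$transition_id %in% is_map$is_id,
                  c("sample_id", "transition_id", "area")]
  names(is_obs) <- c("sample_id", "is_id", "is_area")
  is_areas <- dplyr::inner_join(is_map[, c("class", "is_id")], is_obs,
                                by = "is_id", relationship = "many-to-many")
  is_areas <- is_areas[, c("sample_id", "class", "is_area")]

  x <- areas[!areas$transition_id %in% is_map$is_id, ]
  x$class <- NULL
  x <- dplyr::left_join(x, compounds, by = "transition_id")
  x <- dplyr::left_join(x, is_areas, by = c("sample_id", "class"))
  bad <- !is.finite(x$is_area) | x$is_area <= 0
  if (any(bad))
    stop("missing or zero internal-standard area for class ",
         x$class[bad][1], " in sample ", x$sample_id[bad][1])
  x <- dplyr::left_join(x, samples[, c("sample_id", "weight_mg")],
                        by = "sample_id")
  x$conc_ug_g <- x$area / x$is_area * is_amount_ug / (x$weight_mg / 1000)
  x[, c("sample_id", "transition_id", "class", "conc_ug_g")]
}

#' Impute missing concentrations
#'
#' Each missing value is replaced by a uniform draw between 0 and half the
#' compound's minimum observed value; reproducible under a fixed seed.
#'
#' @param conc Long concentration tibble with `transition_id` and
#'   `conc_ug_g` (NA = missing).
#' @param seed Integer seed for the imputation draws.
#' @return `conc` with all `conc_ug_g` values filled in.
#' @export
impute_missing <- function(conc, seed = 1) {
  missing <- is.na(conc$conc_ug_g)
  if (!any(missing)) return(conc)
  mins <- suppressWarnings(
    tapply(conc$conc_ug_g, conc$transition_id, min, na.rm = TRUE))
  if (any(!is.finite(mins)))
    stop("compound(s) with no observed value cannot be imputed: ",
         names(mins)[!is.finite(mins)][1])
  set.seed(seed)
  half_min <- mins[conc$transition_id[missing]]
  conc$conc_ug_g[missing] <- stats::runif(sum(missing), 0, half_min / 2)
  conc
}

#' Concentration table as samples x compounds matrix
#'
#' @param conc Long concentration tibble (`sample_id`, `transition_id`,
#'   `conc_ug_g`).
#' @return Numeric matrix, samples in rows, compounds in columns.
#' @export
conc_matrix <- function(conc) {
  wide <- tidyr::pivot_wider(conc[, c("sample_id", "transition_id", "conc_ug_g")],
                             names_from = "transition_id",
                             values_from = "conc_ug_g")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample_id
  m
}
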