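# MRM method assembly: per-class transition lists, Q1/Q2 deduplication,
# internal-standard transitions, polarity split, and delimited-text export.

#' Build the MRM transitions of one class
#'
#' One transition per species with the class's designated leaving chain
#' (the largest chain of the sorted multiset stands in for the unresolved
#' sn2/sn3 position), or -- in audit mode -- one per distinct chain of each
#' multiset.
#'
#' @param class Registered class id.
#' @param space A [chain_space()].
#' @param leaving `"designated"` (default, one transition per species) or
#'   `"all"` (every distinct chain of the multiset as candidate leaving
#'   group; duplicates within a species merged).
#' @param recompute_fragments Passed to [product_mz()].
#' @return Transition tibble: `transition_id`, `class`, `species`, `q1`,
#'   `q2`, `polarity`, `dp`, `ep`, `ce`, `cxp`, `leaving_chain`,
#'   `is_internal_standard`.
#' @examples
#' nrow(build_class_transitions("PE"))  # 630
#' @export
build_class_transitions <- function(class, space = chain_space(),
                                    leaving = c("designated", "all"),
                                    recompute_fragments = FALSE) {
  leaving <- match.arg(leaving)
  rule <- class_rule(class)
  sp <- enumerate_species(class, space)
  chain_dep <- rule$fragment %in% c("sn_chain_carboxylate",
                                    "neutral_loss_of_chain",
                                    "neutral_loss_of_fatty_acid_with_rearrangement")

  if (leaving == "all" && chain_dep && rule$n_chains > 1) {
    cols <- seq_len(rule$n_chains)
    sp_rep <- dplyr::bind_rows(lapply(cols, function(s) {
      x <- sp
      x$leave_c <- x[[paste0("c", s)]]
      x$leave_d <- x[[paste0("d", s)]]
      x
    }))
    sp_rep <- dplyr::distinct(sp_rep, .data$species, .data$leave_c,
                              .data$leave_d, .keep_all = TRUE)
    lv <- list(carbons = sp_rep$leave_c, double_bonds = sp_rep$leave_d)
    sp <- sp_rep
  } else {
    lv <- designated_leaving_chain(sp)
  }

  all_mode <- leaving == "all" && chain_dep && rule$n_chains > 1
  tr <- tibble::tibble(
    transition_id = if (all_mode)
      paste0(sp$species, ">", chain_label(lv$carbons, lv$double_bonds))
    else sp$species,
    class = sp$class,
    species = sp$species,
    q1 = precursor_mz(sp),
    q2 = product_mz(sp, leaving = if (chain_dep) lv else NULL,
                    recompute_fragments = recompute_fragments),
    polarity = rule$polarity,
    dp = rule$dp, ep = rule$ep, ce = rule$ce, cxp = rule$cxp,
    leaving_chain = if (chain_dep) chain_label(lv$carbons, lv$double_bonds)
                    else NA_character_,
    is_internal_standard = FALSE
  )
  tr[order(tr$q1, tr$q2, tr$transition_id), ]
}

#' Merge transitions whose Q1/Q2 collide at a rounding precision
#'
#' Transitions whose (Q1, Q2, polarity) agree after rounding to
#' `q_precision` decimals are merged to one record that carries all
#' contributing species ids (`species`, ";"-joined, and `n_species`).
#' Idempotent; stable sorted output.
#'
#' @param transitions Transition tibble.
#' @param q_precision Decimals used for the collision test (default 1, the
#'   instrument-resolution scale).
#' @return Deduplicated transition tibble.
#' @export
dedup_transitions <- function(transitions, q_precision = 1) {
  stopifnot(q_precision >= 0)
  if (nrow(transitions) == 0) return(transitions)
  key <- paste(transitions$polarity,
               sprintf("%.*f", q_precision, transitions$q1),
               sprintf("%.*f", q_precision, transitions$q2))
  ord <- order(transitions$q1, transitions$q2, transitions$transition_id)
  transitions <- transitions[ord, ]
  key <- key[ord]
  merged <- dplyr::group_by(transitions, key = key)
  merged <- dplyr::summarise(
    merged,
    dplyr::across(c("transition_id", "class", "q1", "q2", "polarity",
                    "dp", "ep", "ce", "cxp", "leaving_chain",
                    "is_internal_standard"), dplyr::first),
    species = paste(sort(unique(unlist(
      strsplit(.data$species, ";", fixed = TRUE)))), collapse = ";"),
    n_species = length(strsplit(.data$species, ";", fixed = TRUE)[[1]]),
    .groups = "drop")
  merged$key <- NULL
  merged <- merged[order(merged$q1, merged$q2, merged$transition_id), ]
  merged[, c("transition_id", "class", "species", "q1", "q2", "polarity",
             "dp", "ep", "ce", "cxp", "leaving_chain",
             "is_internal_standard", "n_species")]
}

#' Internal-standard transitions
#'
#' Builds one transition per distinct internal standard (21 in the default
#' registry). The deuterium label mass is added to Q1; chain-dependent
#' product ions follow the labelled chain (the label rides on the leaving
#' chain for the deuterated standards), fixed product ions are unchanged.
#'
#' @return Transition tibble flagged `is_internal_standard = TRUE`.
#' @export
is_transitions <- function() {
  defs <- dplyr::distinct(.IS_TABLE, .data$is_id, .keep_all = TRUE)
  rows <- lapply(seq_len(nrow(defs)), function(i) {
    d <- defs[i, ]
    rule <- class_rule(d$class)
    sp <- species(d$class, d$chains)
    label_shift <- d$n_deuterium * .D_MINUS_H
    q1 <- precursor_mz(sp) + label_shift
    q2 <- product_mz(sp)
    kind <- rule$fragment
    if (kind == "sn_chain_carboxylate") q2 <- q2 + label_shift
    if (kind == "intact_deprotonated") q2 <- q1
    # neutral loss of the labelled chain removes the label again: q2 as-is
    tibble::tibble(
      transition_id = d$is_id, class = d$class, species = d$is_id,
      q1 = q1, q2 = q2, polarity = rule$polarity,
      dp = rule$dp, ep = rule$ep, ce = rule$ce, cxp = rule$cxp,
      leaving_chain = NA_character_, is_internal_standard = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Assemble the full MRM method
#'
#' Builds every registered class over its chain space, deduplicates Q1/Q2
#' collisions within each class, appends the internal-standard transitions,
#' and splits the result into the positive- and negative-mode acquisition
#' lists.
#'
#' @param space Default [chain_space()] for all classes.
#' @param class_spaces Optional named list of per-class chain spaces
#'   overriding `space`.
#' @param q_precision Dedup precision in decimals (see
#'   [dedup_transitions()]).
#' @param include_is Append the 21 internal-standard transitions.
#' @return An `mrm_method` object: list with `positive`, `negative`
#'   transition tibbles and a per-class `summary` tibble
#'   (`class`, `compounds_in_method`).
#' @examples
#' \donttest{
#' m <- build_method()
#' m$summary
#' }
#' @export
build_method <- function(space = chain_space(), class_spaces = list(),
                         q_precision = 1, include_is = TRUE) {
  bad <- setdiff(names(class_spaces), .CLASS_TABLE$class)
  if (length(bad))
    stop("class_spaces names unknown class(es): ", paste(bad, collapse = ", "))
  per_class <- lapply(.CLASS_TABLE$class, function(cl) {
    sp <- if (cl %in% names(class_spaces)) class_spaces[[cl]] else space
    dedup_transitions(build_class_transitions(cl, sp), q_precision)
  })
  all_tr <- dplyr::bind_rows(per_class)
  if (include_is) {
    ist <- is_transitions()
    ist$n_species <- 1L
    all_tr <- dplyr::bind_rows(all_tr, ist)
  }
  summary <- dplyr::count(all_tr[!all_tr$is_internal_standard, ],
                          .data$class, name = "compounds_in_method")
  structure(
    list(positive = all_tr[all_tr$polarity == "pos", ],
         negative = all_tr[all_tr$polarity == "neg", ],
         summary = summary),
    class = "mrm_method")
}

#' @export
print.mrm_method <- function(x, ...) {
  cat("<mrm_method> ", nrow(x$positive), " positive + ", nrow(x$negative),
      " negative transitions (",
      sum(x$positive$is_internal_standard) + sum(x$negative$is_internal_standard),
      " IS)\n", sep = "")
  print(x$summary, n = Inf)
  invisible(x)
}

#' All transitions of a method as one table
#' @param method An `mrm_method`.
#' @return Combined transition tibble (positive then negative).
#' @export
method_transitions <- function(method) {
  stopifnot(inherits(method, "mrm_method"))
  dplyr::bind_rows(method$positive, method$negative)
}

#' Export / import a transition list
#'
#' Plain-text comma-delimited list with the documented column contract
#' (`transition_id, class, species, q1, q2, polarity, dp, ep, ce, cxp,
#' leaving_chain, is_internal_standard`). Byte-stable for identical inputs.
#'
#' @param transitions Transition tibble (or `mrm_method`, exported as one
#'   combined table).
#' @param path Output file path.
#' @param dialect `"exact"` prints m/z at 4 decimals; `"1dp"` at 1 decimal
#'   (the published appendix style).
#' @return `path`, invisibly.
#' @export
export_transition_list <- function(transitions, path,
                                   dialect = c("exact", "1dp")) {
  dialect <- match.arg(dialect)
  if (inherits(transitions, "mrm_method"))
    transitions <- method_transitions(transitions)
  digits <- if (dialect == "1dp") 1L else 4L
  out <- transitions[, c("transition_id", "class", "species", "q1", "q2",
                         "polarity", "dp", "ep", "ce", "cxp",
                         "leaving_chain", "is_internal_standard")]
  out$q1 <- sprintf("%.*f", digits, out$q1)
  out$q2 <- sprintf("%.*f", digits, out$q2)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname export_transition_list
#' @export
read_transition_list <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(out)
}
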