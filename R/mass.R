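# Mass engine: neutral monoisotopic masses, adduct precursor m/z and
# product-ion m/z for any species of the registry. All arithmetic is
# composition-based; ion m/z carries the electron-mass correction.

.ADDUCTS <- list(
  "[M+H]+"    = list(delta = .PROTON,                        polarity = "pos"),
  "[M-H]-"    = list(delta = -.PROTON,                       polarity = "neg"),
  "[M+Na]+"   = list(delta = 22.98976928 - .ELECTRON_MASS,   polarity = "pos"),
  "[M+HCOO]-" = list(delta = 12 + 1.0078250319 + 2 * 15.9949146221 + .ELECTRON_MASS,
                     polarity = "neg"),
  # protonation with loss of one water (dehydration, 18.0106, not nominal 18)
  "[M+H-18]+" = list(delta = .PROTON - (2 * 1.0078250319 + 15.9949146221),
                     polarity = "pos")
)

#' Adduct rules known to the mass engine
#' @return Tibble of adduct name, mass delta (u) and polarity.
#' @export
adduct_rules <- function() {
  tibble::tibble(
    adduct = names(.ADDUCTS),
    delta = vapply(.ADDUCTS, function(a) a$delta, 0),
    polarity = vapply(.ADDUCTS, function(a) a$polarity, "")
  )
}

adduct_delta <- function(adduct) {
  a <- .ADDUCTS[[adduct]]
  if (is.null(a)) stop("unknown adduct '", adduct, "'")
  a$delta
}

#' Neutral monoisotopic mass of lipid species
#'
#' Assembles scaffold + free fatty-acyl chains minus one water per
#' ester/amide linkage. Vectorised over the rows of a species table.
#'
#' @param sp Species tibble from [enumerate_species()] or [species()].
#' @return Numeric vector of neutral monoisotopic masses (u).
#' @examples
#' species_mass(species("FA", "16:0"))  # 256.2402
#' @export
species_mass <- function(sp) {
  scaffold_mass <- vapply(unique(sp$class),
                          function(cl) comp_mass(class_scaffold(cl)), 0)
  n_link <- vapply(unique(sp$class), class_linkages, 0L)
  h2o <- comp_mass(.WATER)
  unname(scaffold_mass[sp$class] +
    chain_mass(sp$c1, sp$d1) + chain_mass(sp$c2, sp$d2) + chain_mass(sp$c3, sp$d3) -
    n_link[sp$class] * h2o)
}

#' Elemental composition / molecular formula of a species
#'
#' @param sp One-row species tibble.
#' @return `species_composition()` a composition vector;
#'   `species_formula()` the Hill-order formula string.
#' @examples
#' species_formula(species("PC", "16:0_18:1"))  # "C42H82NO8P"
#' @export
species_composition <- function(sp) {
  stopifnot(nrow(sp) == 1)
  comp <- class_scaffold(sp$class)
  n_link <- class_linkages(sp$class)
  for (s in 1:3) {
    cc <- sp[[paste0("c", s)]]
    if (!is.na(cc))
      comp <- comp_add(comp, chain_composition(cc, sp[[paste0("d", s)]]))
  }
  for (l in seq_len(n_link)) comp <- comp_subtract(comp, .WATER)
  comp
}

#' @rdname species_composition
#' @export
species_formula <- function(sp) comp_formula(species_composition(sp))

#' Precursor ion m/z
#'
#' @param sp Species tibble.
#' @param adduct Adduct name; defaults to the class rule's adduct (per-row).
#' @return Numeric vector of precursor m/z values.
#' @examples
#' precursor_mz(species("FA", "16:0"))  # 255.2330 for [M-H]-
#' @export
precursor_mz <- function(sp, adduct = NULL) {
  if (is.null(adduct)) {
    reg <- stats::setNames(.CLASS_TABLE$adduct, .CLASS_TABLE$class)
    adduct <- reg[sp$class]
  }
  deltas <- vapply(unique(adduct), adduct_delta, 0)
  unname(species_mass(sp) + deltas[adduct])
}

# designated leaving chain of a species: the last (largest by C, then DB)
# chain slot in use -- the conventional sn2/sn3 candidate of the sorted
# multiset. Returns carbons/double_bonds vectors.
designated_leaving_chain <- function(sp) {
  use3 <- !is.na(sp$c3)
  use2 <- !use3 & !is.na(sp$c2)
  carbons <- ifelse(use3, sp$c3, ifelse(use2, sp$c2, sp$c1))
  dbs <- ifelse(use3, sp$d3, ifelse(use2, sp$d2, sp$d1))
  list(carbons = carbons, double_bonds = dbs)
}

#' Product ion m/z
#'
#' Applies the class product-ion rule: the sn-chain carboxylate, the neutral
#' loss of the leaving fatty acid (sodiated glycerolipids and galactolipids),
#' the glycerol loss of monoacylglycerols, the intact deprotonated fatty
#' acid, or a fixed constant. Fixed constants are returned exactly as
#' printed in the published method (184.1, 264.1, 266.1, 85.1) unless
#' `recompute_fragments = TRUE`, in which case the exact composition-derived
#' m/z of the fragment is used.
#'
#' @param sp Species tibble.
#' @param leaving Optional leaving-chain spec as a list with `carbons` and
#'   `double_bonds`; defaults to the designated (largest) chain for
#'   chain-dependent rules. Must be a member of the species multiset.
#' @param recompute_fragments Recompute printed fixed fragments exactly.
#' @param mg_loss For MG: `"glycerol"` (default; neutral C3H8O3 loss giving
#'   the acylium ion) or `"radical"` (the literal C3H7O3 loss).
#' @return Numeric vector of product m/z values.
#' @export
product_mz <- function(sp, leaving = NULL, recompute_fragments = FALSE,
                       mg_loss = c("glycerol", "radical")) {
  mg_loss <- match.arg(mg_loss)
  rules <- .CLASS_TABLE[match(sp$class, .CLASS_TABLE$class), ]
  kind <- rules$fragment
  chain_dep <- kind %in% c("sn_chain_carboxylate", "neutral_loss_of_chain",
                           "neutral_loss_of_fatty_acid_with_rearrangement")
  if (is.null(leaving)) {
    leaving <- designated_leaving_chain(sp)
  } else {
    in_multiset <- mapply(function(i, c, d) {
      any(c(sp$c1[i], sp$c2[i], sp$c3[i]) == c &
            c(sp$d1[i], sp$d2[i], sp$d3[i]) == d, na.rm = TRUE)
    }, seq_len(nrow(sp)), leaving$carbons, leaving$double_bonds)
    if (any(chain_dep & !in_multiset))
      stop("leaving chain ",
           chain_label(leaving$carbons, leaving$double_bonds)[chain_dep & !in_multiset][1],
           " is not a member of the species multiset")
  }

  prec <- precursor_mz(sp)
  fa_leave <- chain_mass(leaving$carbons, leaving$double_bonds)
  out <- rep(NA_real_, nrow(sp))

  fixed <- kind == "fixed_mz"
  if (any(fixed)) {
    if (recompute_fragments) {
      exact <- vapply(.FIXED_FRAGMENT_COMP, comp_mass, 0, charge = 1)
      out[fixed] <- exact[as.character(rules$fixed_mz[fixed])]
    } else {
      out[fixed] <- rules$fixed_mz[fixed]
    }
  }
  out[kind == "intact_deprotonated"] <- prec[kind == "intact_deprotonated"]
  nl <- kind %in% c("neutral_loss_of_chain",
                    "neutral_loss_of_fatty_acid_with_rearrangement")
  out[nl] <- prec[nl] - fa_leave[nl]
  sn <- kind == "sn_chain_carboxylate"
  out[sn] <- fa_leave[sn] - .PROTON
  mg <- kind == "loss_of_glycerol"
  if (any(mg)) {
    loss <- if (mg_loss == "glycerol") comp_mass(composition(C = 3, H = 8, O = 3))
            else comp_mass(composition(C = 3, H = 7, O = 3))
    out[mg] <- prec[mg] - loss
  }
  if (anyNA(out))
    stop("unhandled fragment kind for class ", sp$class[is.na(out)][1])
  out
}
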