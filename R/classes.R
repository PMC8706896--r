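# Class registry: one rule per lipid class -- ionization mode, precursor
# adduct, product-ion rule, per-class source voltages, internal standard --
# plus the scaffold composition (backbone + head group, fully hydroxylated)
# used for neutral-mass assembly.

# scaffold elemental compositions, authored from structure:
#   glycerol backbones, glycerophospho- head groups, galactosyl heads,
#   sphingoid bases (d18:1 sphingosine / d18:0 sphinganine, sugar-extended
#   for glc/lac ceramides), sphingosylphosphorylcholine, carnitine.
.SCAFFOLDS <- list(
  none      = composition(),
  glycerol  = composition(C = 3,  H = 8,  O = 3),
  mgal_gly  = composition(C = 9,  H = 18, O = 8),            # galactosylglycerol
  dgal_gly  = composition(C = 15, H = 28, O = 13),           # digalactosylglycerol
  gpa       = composition(C = 3,  H = 9,  O = 6,  P = 1),    # glycerophosphate
  gpc       = composition(C = 8,  H = 20, N = 1, O = 6, P = 1),
  gpe       = composition(C = 5,  H = 14, N = 1, O = 6, P = 1),
  gpg       = composition(C = 6,  H = 15, O = 8,  P = 1),
  gpi       = composition(C = 9,  H = 19, O = 11, P = 1),
  gps       = composition(C = 6,  H = 14, N = 1, O = 8, P = 1),
  sph_d181  = composition(C = 18, H = 37, N = 1, O = 2),     # sphingosine
  sph_d180  = composition(C = 18, H = 39, N = 1, O = 2),     # sphinganine
  glc_d181  = composition(C = 24, H = 47, N = 1, O = 7),
  glc_d180  = composition(C = 24, H = 49, N = 1, O = 7),
  lac_d181  = composition(C = 30, H = 57, N = 1, O = 12),
  lac_d180  = composition(C = 30, H = 59, N = 1, O = 12),
  spc       = composition(C = 23, H = 49, N = 2, O = 5, P = 1), # sphingosylphosphorylcholine
  carnitine = composition(C = 7,  H = 15, N = 1, O = 3)
)

# exact compositions behind the printed fixed product ions (all +1 cations)
.FIXED_FRAGMENT_COMP <- list(
  `184.1` = composition(C = 5, H = 15, N = 1, O = 4, P = 1),  # phosphocholine
  `264.1` = composition(C = 18, H = 34, N = 1),               # d18:1 base - 2 H2O + H
  `266.1` = composition(C = 18, H = 36, N = 1),               # d18:0 base - 2 H2O + H
  `85.1`  = composition(C = 4, H = 5, O = 2)                  # acylcarnitine butenoyl cation
)

.CLASS_TABLE <- local({
  r <- function(class, category, n_chains, fixed_base, scaffold, polarity,
                adduct, fragment, fixed_mz, dp, ep, ce, cxp, is_id) {
    tibble::tibble(class = class, category = category,
                   n_chains = as.integer(n_chains), fixed_base = fixed_base,
                   scaffold = scaffold, polarity = polarity, adduct = adduct,
                   fragment = fragment, fixed_mz = fixed_mz,
                   dp = dp, ep = ep, ce = ce, cxp = cxp, is_id = is_id)
  }
  dplyr::bind_rows(
    r("CAR", "fatty acyl", 1, NA, "carnitine", "pos", "[M+H]+", "fixed_mz", 85.1, 93, 10, 31, 16, "24:0(d4) Carnitine"),
    r("CER", "sphingolipid", 1, "d18:1", "sph_d181", "pos", "[M+H-18]+", "fixed_mz", 264.1, 130, 10, 55, 10, "C15 Ceramide-d7"),
    r("DG", "glycerolipid", 2, NA, "glycerol", "pos", "[M+Na]+", "neutral_loss_of_chain", NA, 93, 9, 42, 25, "15:0-18:1(d7) DG"),
    r("DGDG", "glycerolipid", 2, NA, "dgal_gly", "pos", "[M+Na]+", "neutral_loss_of_fatty_acid_with_rearrangement", NA, 80, 10, 65, 20, "Hydrog DGDG (18:0-18:0)"),
    r("dhCER", "sphingolipid", 1, "d18:0", "sph_d180", "pos", "[M+H-18]+", "fixed_mz", 266.1, 130, 10, 55, 10, "C15 Ceramide-d7"),
    r("FA", "fatty acyl", 1, NA, "none", "neg", "[M-H]-", "intact_deprotonated", NA, -80, -10, -17, -20, "Stearic acid-d3"),
    r("glc-dhCER", "sphingolipid", 1, "d18:0", "glc_d180", "pos", "[M+H-18]+", "fixed_mz", 266.1, 130, 8, 45, 27, "C15 Ceramide-d7"),
    r("glcCER", "sphingolipid", 1, "d18:1", "glc_d181", "pos", "[M+H-18]+", "fixed_mz", 264.1, 130, 8, 45, 27, "C15 Ceramide-d7"),
    r("lac-dhCER", "sphingolipid", 1, "d18:0", "lac_d180", "pos", "[M+H-18]+", "fixed_mz", 266.1, 126, 10, 56, 15, "C15 Ceramide-d7"),
    r("lacCER", "sphingolipid", 1, "d18:1", "lac_d181", "pos", "[M+H-18]+", "fixed_mz", 264.1, 126, 10, 56, 15, "C15 Ceramide-d7"),
    r("LPA", "glycerophospholipid", 1, NA, "gpa", "neg", "[M-H]-", "sn_chain_carboxylate", NA, -80, -6, -45, -20, "17:0 Lyso PA"),
    r("LPC", "glycerophospholipid", 1, NA, "gpc", "pos", "[M+H]+", "fixed_mz", 184.1, 90, 6, 35, 20, "18:1(d7) Lyso PC"),
    r("LPE", "glycerophospholipid", 1, NA, "gpe", "neg", "[M-H]-", "sn_chain_carboxylate", NA, -88, -12, -42, -20, "18:1(d7) Lyso PE"),
    r("LPG", "glycerophospholipid", 1, NA, "gpg", "neg", "[M-H]-", "sn_chain_carboxylate", NA, -75, -10, -38, -24, "17:1 Lyso PG"),
    r("LPI", "glycerophospholipid", 1, NA, "gpi", "neg", "[M-H]-", "sn_chain_carboxylate", NA, -90, -6, -40, -24, "17:1 Lyso PI"),
    r("LPS", "glycerophospholipid", 1, NA, "gps", "neg", "[M-H]-", "sn_chain_carboxylate", NA, -72, -10, -53, -24, "17:1 Lyso PS"),
    r("MG", "glycerolipid", 1, NA, "glycerol", "pos", "[M+H]+", "loss_of_glycerol", NA, 140, 10, 16, 10, "18:1(d7) MG"),
    r("MGDG", "glycerolipid", 2, NA, "mgal_gly", "pos", "[M+Na]+", "neutral_loss_of_fatty_acid_with_rearrangement", NA, 100, 10, 50, 30, "Hydrog MGDG (18:0-16:0)"),
    r("PA", "glycerophospholipid", 2, NA, "gpa", "neg", "[M-H]-", "sn_chain_carboxylate", NA, -80, -6, -45, -20, "15:0-18:1(d7) PA"),
    r("PC", "glycerophospholipid", 2, NA, "gpc", "neg", "[M+HCOO]-", "sn_chain_carboxylate", NA, -90, -10, -50, -20, "15:0-18:1(d7) PC"),
    r("PE", "glycerophospholipid", 2, NA, "gpe", "neg", "[M-H]-", "sn_chain_carboxylate", NA, -88, -12, -42, -20, "15:0-18:1(d7) PE"),
    r("PG", "glycerophospholipid", 2, NA, "gpg", "neg", "[M-H]-", "sn_chain_carboxylate", NA, -75, -10, -38, -24, "15:0-18:1(d7) PG"),
    r("PI", "glycerophospholipid", 2, NA, "gpi", "neg", "[M-H]-", "sn_chain_carboxylate", NA, -50, -10, -55, -10, "15:0-18:1(d7) PI"),
    r("PS", "glycerophospholipid", 2, NA, "gps", "neg", "[M-H]-", "sn_chain_carboxylate", NA, -72, -10, -53, -24, "15:0-18:1(d7) PS"),
    r("SM", "sphingolipid", 1, "d18:1", "spc", "pos", "[M+H]+", "fixed_mz", 184.1, 124, 10, 32.5, 23, "d18:1-18:1(d9) SM"),
    r("TG", "glycerolipid", 3, NA, "glycerol", "pos", "[M+Na]+", "neutral_loss_of_chain", NA, 90, 10, 40, 10, "15:0-18:1(d7)-15:0 TG")
  )
})

# internal standard definitions: composition expressed as (class scaffold,
# chains, deuterium label count). Odd-carbon IS chains are legitimate here;
# the enumeration chain space does not constrain IS definitions.
.IS_TABLE <- local({
  s <- function(is_id, class, chains, n_d) {
    tibble::tibble(is_id = is_id, class = class, chains = chains,
                   n_deuterium = as.integer(n_d))
  }
  dplyr::bind_rows(
    s("24:0(d4) Carnitine", "CAR", "24:0", 4),
    s("C15 Ceramide-d7", "CER", "15:0", 7),
    s("15:0-18:1(d7) DG", "DG", "15:0_18:1", 7),
    s("Hydrog DGDG (18:0-18:0)", "DGDG", "18:0_18:0", 0),
    s("Stearic acid-d3", "FA", "18:0", 3),
    s("17:0 Lyso PA", "LPA", "17:0", 0),
    s("18:1(d7) Lyso PC", "LPC", "18:1", 7),
    s("18:1(d7) Lyso PE", "LPE", "18:1", 7),
    s("17:1 Lyso PG", "LPG", "17:1", 0),
    s("17:1 Lyso PI", "LPI", "17:1", 0),
    s("17:1 Lyso PS", "LPS", "17:1", 0),
    s("18:1(d7) MG", "MG", "18:1", 7),
    s("Hydrog MGDG (18:0-16:0)", "MGDG", "16:0_18:0", 0),
    s("15:0-18:1(d7) PA", "PA", "15:0_18:1", 7),
    s("15:0-18:1(d7) PC", "PC", "15:0_18:1", 7),
    s("15:0-18:1(d7) PE", "PE", "15:0_18:1", 7),
    s("15:0-18:1(d7) PG", "PG", "15:0_18:1", 7),
    s("15:0-18:1(d7) PI", "PI", "15:0_18:1", 7),
    s("15:0-18:1(d7) PS", "PS", "15:0_18:1", 7),
    s("d18:1-18:1(d9) SM", "SM", "18:1", 9),
    s("15:0-18:1(d7)-15:0 TG", "TG", "15:0_15:0_18:1", 7)
  )
})

#' Lipid class registry
#'
#' One rule per class: ionization polarity, precursor adduct, product-ion
#' rule, the printed fixed product m/z where the rule is a constant,
#' per-class source voltages (DP/EP/CE/CXP, signed as printed for negative
#' mode), the assigned internal standard, and the acylation count.
#'
#' @return Tibble with one row per registered class (26 classes).
#' @examples
#' lipid_classes()[, c("class", "polarity", "adduct", "fragment")]
#' @export
lipid_classes <- function() .CLASS_TABLE

#' Internal standard definitions
#'
#' The 21 internal standards of the method: identifier, the class whose
#' scaffold and rule they follow, acyl chains and deuterium label count.
#' All six ceramide-family classes share one ceramide standard.
#'
#' @return Tibble with one row per (class, standard) assignment; the
#'   distinct `is_id` values number 21.
#' @export
internal_standards <- function() {
  dplyr::left_join(.CLASS_TABLE[, c("class", "is_id")],
                   .IS_TABLE[, c("is_id", "chains", "n_deuterium")],
                   by = "is_id")
}

class_rule <- function(class) {
  rule <- .CLASS_TABLE[.CLASS_TABLE$class == class, ]
  if (nrow(rule) == 0)
    stop("unknown lipid class '", class, "'; registered classes: ",
         paste(.CLASS_TABLE$class, collapse = ", "))
  rule
}

class_scaffold <- function(class) .SCAFFOLDS[[class_rule(class)$scaffold]]

# ester/amide linkages = number of variable chains (the sphingoid base is
# part of the scaffold; its amide bond to the N-acyl chain is the one
# linkage), except free fatty acids, which are not condensed onto anything
class_linkages <- function(class) {
  rule <- class_rule(class)
  if (rule$class == "FA") 0L else rule$n_chains
}
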