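# Fatty-acyl chain space: the (carbons, double bonds) grid from which all
# lipid species of the method are assembled.

#' Define a fatty-acyl chain space
#'
#' The default space covers even-numbered acyl chains from 14 to 22 carbons
#' with 0 to 6 double bonds (35 chains), the plant-lipid convention the
#' library is built on.
#'
#' @param carbon_min,carbon_max Inclusive bounds on acyl carbons (the
#'   carboxyl carbon counts).
#' @param carbon_step Carbon increment; 2 restricts to even chains.
#' @param db_min,db_max Inclusive bounds on the number of C=C double bonds.
#' @return An object of class `chain_space`.
#' @examples
#' chain_space()           # default 35-chain space
#' chain_space(16, 16, db_max = 0)  # just 16:0
#' @export
chain_space <- function(carbon_min = 14, carbon_max = 22, carbon_step = 2,
                        db_min = 0, db_max = 6) {
  if (carbon_min > carbon_max)
    stop("empty carbon range: carbon_min (", carbon_min,
         ") exceeds carbon_max (", carbon_max, ")")
  if (db_min > db_max)
    stop("empty double-bond range: db_min (", db_min,
         ") exceeds db_max (", db_max, ")")
  if (carbon_step < 1) stop("carbon_step must be >= 1")
  structure(
    list(carbon_min = as.integer(carbon_min),
         carbon_max = as.integer(carbon_max),
         carbon_step = as.integer(carbon_step),
         db_min = as.integer(db_min),
         db_max = as.integer(db_max)),
    class = "chain_space")
}

#' @export
print.chain_space <- function(x, ...) {
  cat("<chain_space> C", x$carbon_min, "-", x$carbon_max,
      " step ", x$carbon_step, ", DB ", x$db_min, "-", x$db_max,
      " (", nrow(enumerate_chains(x)), " chains)\n", sep = "")
  invisible(x)
}

#' Enumerate all fatty-acyl chains of a space
#'
#' @param space A [chain_space()].
#' @return Tibble with columns `carbons`, `double_bonds`, `chain`
#'   (the "C:D" label), sorted by (carbons, double_bonds).
#' @examples
#' nrow(enumerate_chains(chain_space()))  # 35
#' @export
enumerate_chains <- function(space = chain_space()) {
  stopifnot(inherits(space, "chain_space"))
  carbons <- seq(space$carbon_min, space$carbon_max, by = space$carbon_step)
  grid <- expand.grid(double_bonds = space$db_min:space$db_max,
                      carbons = carbons)[, c("carbons", "double_bonds")]
  grid <- grid[order(grid$carbons, grid$double_bonds), ]
  tibble::tibble(
    carbons = as.integer(grid$carbons),
    double_bonds = as.integer(grid$double_bonds),
    chain = chain_label(grid$carbons, grid$double_bonds)
  )
}

#' Chain label helpers
#'
#' `chain_label()` renders (C, D) pairs as "C:D"; `parse_chain()` inverts it.
#'
#' @param carbons,double_bonds Integer vectors.
#' @return Character vector of labels.
#' @export
chain_label <- function(carbons, double_bonds) {
  paste0(carbons, ":", double_bonds)
}

#' @rdname chain_label
#' @param chain Character vector of "C:D" labels.
#' @export
parse_chain <- function(chain) {
  parts <- strsplit(chain, ":", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed chain label: ", chain[bad][1])
  tibble::tibble(
    carbons = as.integer(vapply(parts, `[`, "", 1)),
    double_bonds = as.integer(vapply(parts, `[`, "", 2))
  )
}

#' Elemental composition of a free fatty acid chain
#'
#' Uses the free fatty acid convention CnH(2n-2d)O2; species assembly
#' subtracts one water per ester/amide linkage.
#'
#' @param carbons,double_bonds Integer scalars or vectors (recycled).
#' @return For scalars, a composition vector; for vectors, a list of them.
#' @examples
#' comp_formula(chain_composition(16, 0))  # "C16H32O2"
#' @export
chain_composition <- function(carbons, double_bonds) {
  h <- 2 * carbons - 2 * double_bonds
  if (any(h <= 0))
    stop("chemically impossible chain: ", chain_label(carbons, double_bonds)[h <= 0][1],
         " has no hydrogens left")
  if (length(carbons) == 1 && length(double_bonds) == 1)
    return(composition(C = carbons, H = h, O = 2))
  mapply(function(c, hh) composition(C = c, H = hh, O = 2),
         carbons, h, SIMPLIFY = FALSE)
}

# vectorised free fatty acid monoisotopic mass; NA chains give mass 0 so
# unused chain slots drop out of sums
chain_mass <- function(carbons, double_bonds) {
  m <- .ATOMIC_MASS[["C"]] * carbons +
    .ATOMIC_MASS[["H"]] * (2 * carbons - 2 * double_bonds) +
    .ATOMIC_MASS[["O"]] * 2
  m[is.na(m)] <- 0
  m
}
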