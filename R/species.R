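# Per-class lipid species enumeration: species are unordered multisets of
# fatty-acyl chains on a class scaffold (sn positions unresolved), so a
# two-chain class over n chains yields choose(n + 1, 2) species and a
# three-chain class choose(n + 2, 3).

#' Enumerate lipid species of a class over a chain space
#'
#' Species identity is a multiset: `PE 16:0_18:1` and `PE 18:1_16:0` are the
#' same species, stored with chains in sorted order. Sphingolipid classes
#' carry a fixed sphingoid base plus one variable N-acyl chain, so they
#' enumerate like single-chain classes.
#'
#' @param class A registered class id (see [lipid_classes()]).
#' @param space A [chain_space()]; per-class spaces may be supplied.
#' @return Tibble with columns `class`, `species` (label), chain slots
#'   `c1,d1,c2,d2,c3,d3` (NA where unused), `total_carbons`, `total_db`,
#'   `fixed_base`. Rows are in deterministic order (total C, total DB,
#'   lexicographic chains).
#' @examples
#' nrow(enumerate_species("PE"))  # 630
#' nrow(enumerate_species("SM"))  # 35
#' @export
enumerate_species <- function(class, space = chain_space()) {
  rule <- class_rule(class)
  chains <- enumerate_chains(space)
  k <- rule$n_chains
  n <- nrow(chains)

  idx <- switch(as.character(k),
    "1" = matrix(seq_len(n), ncol = 1),
    "2" = {
      i <- rep(seq_len(n), times = n:1)
      j <- unlist(lapply(seq_len(n), function(a) a:n))
      cbind(i, j)
    },
    "3" = {
      out <- utils::combn(n + 2, 3)   # multisets via combinations with repetition
      t(out) - matrix(rep(0:2, each = ncol(out)), ncol = 3)
    },
    stop("unsupported acylation count: ", k))

  slot <- function(m, col, field) {
    if (col <= ncol(idx)) chains[[field]][idx[, col]] else rep(NA_integer_, nrow(idx))
  }
  sp <- tibble::tibble(
    class = rule$class,
    c1 = slot(idx, 1, "carbons"), d1 = slot(idx, 1, "double_bonds"),
    c2 = slot(idx, 2, "carbons"), d2 = slot(idx, 2, "double_bonds"),
    c3 = slot(idx, 3, "carbons"), d3 = slot(idx, 3, "double_bonds"),
    fixed_base = rule$fixed_base
  )
  sp$total_carbons <- rowSums(cbind(sp$c1, sp$c2, sp$c3), na.rm = TRUE)
  sp$total_db <- rowSums(cbind(sp$d1, sp$d2, sp$d3), na.rm = TRUE)
  sp$species <- species_label(sp)
  sp <- sp[order(sp$total_carbons, sp$total_db, sp$species), ]
  sp[, c("class", "species", "c1", "d1", "c2", "d2", "c3", "d3",
         "total_carbons", "total_db", "fixed_base")]
}

#' @keywords internal
species_label <- function(sp) {
  lab <- chain_label(sp$c1, sp$d1)
  for (s in c("2", "3")) {
    cc <- sp[[paste0("c", s)]]
    dd <- sp[[paste0("d", s)]]
    lab <- ifelse(is.na(cc), lab, paste0(lab, "_", chain_label(cc, dd)))
  }
  base <- ifelse(is.na(sp$fixed_base), "", paste0(sp$fixed_base, "/"))
  paste0(sp$class, " ", base, lab)
}

#' Build a species table from explicit chain labels
#'
#' Convenience constructor for single species, mainly used in tests and
#' examples: `species("PC", "16:0_18:1")`.
#'
#' @param class Registered class id.
#' @param chains Chain multiset as "C:D" labels joined by "_".
#' @return One-row species tibble in the [enumerate_species()] layout.
#' @export
species <- function(class, chains) {
  rule <- class_rule(class)
  ch <- parse_chain(strsplit(chains, "_", fixed = TRUE)[[1]])
  if (nrow(ch) != rule$n_chains)
    stop(class, " requires ", rule$n_chains, " chain(s), got ", nrow(ch))
  ch <- ch[order(ch$carbons, ch$double_bonds), ]
  pad <- function(x, i) if (i <= length(x)) x[i] else NA_integer_
  sp <- tibble::tibble(
    class = rule$class,
    c1 = pad(ch$carbons, 1), d1 = pad(ch$double_bonds, 1),
    c2 = pad(ch$carbons, 2), d2 = pad(ch$double_bonds, 2),
    c3 = pad(ch$carbons, 3), d3 = pad(ch$double_bonds, 3),
    fixed_base = rule$fixed_base
  )
  sp$total_carbons <- sum(ch$carbons)
  sp$total_db <- sum(ch$double_bonds)
  sp$species <- species_label(sp)
  sp[, c("class", "species", "c1", "d1", "c2", "d2", "c3", "d3",
         "total_carbons", "total_db", "fixed_base")]
}
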