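# Bemis-Murcko scaffold / generic framework decomposition and uniqueness
# statistics used to compare the diversity of compound subsets.

#' Bemis-Murcko scaffold
#'
#' All ring systems plus the linkers connecting them, side chains removed
#' (exocyclic double bonds attached to rings are retained, the common
#' convention). Acyclic molecules have no scaffold and return `NA`.
#'
#' @param x A `compound_set`, `chem_mol` or character vector of SMILES.
#' @return Character vector of scaffold SMILES (`NA` for acyclic).
#' @export
murcko_scaffold <- function(x) {
  murcko_of(x, "scaffold")
}

#' Bemis-Murcko generic framework
#'
#' The scaffold further abstracted: every atom becomes carbon, every bond a
#' single bond, leaving only the ring/linker topology. Benzene and pyridine
#' share one framework.
#'
#' @inheritParams murcko_scaffold
#' @return Character vector of framework SMILES (`NA` for acyclic).
#' @export
murcko_framework <- function(x) {
  murcko_of(x, "framework")
}

murcko_of <- function(x, field) {
  smiles <- smiles_of(x)
  if (length(smiles) == 0L) return(character())
  res <- rdkit_call("murcko", list(smiles = as.list(smiles)))
  vapply(res, function(r) {
    if (!isTRUE(r$ok)) return(NA_character_)
    v <- r[[field]]
    if (is.null(v) || !nzchar(v)) NA_character_ else v
  }, "")
}

#' Scaffold / framework uniqueness report
#'
#' Decomposes every compound and reports the number of distinct scaffolds
#' (or generic frameworks) and the uniqueness percentage
#' `100 * distinct / compounds`. Acyclic molecules, which have no scaffold,
#' are excluded from both numerator and denominator by default and counted
#' in `n_acyclic` (including them adds a single shared "acyclic" bucket).
#' `singleton_fraction` additionally reports the percentage of scaffolds
#' carried by exactly one compound — the alternative reading of
#' "unique" — for comparison.
#'
#' @param set A `compound_set` (or character vector of SMILES).
#' @param mode `"scaffold"` or `"framework"`.
#' @param include_acyclic Count acyclic compounds as one shared empty
#'   scaffold instead of excluding them.
#' @return A `scaffold_report`: list with `mode`, `n_compounds` (in the
#'   denominator), `n_acyclic`, `n_distinct`, `unique_fraction` (percent),
#'   `singleton_fraction` (percent of distinct scaffolds with one member),
#'   and `counts` (named member counts per scaffold, decreasing).
#' @export
scaffold_report <- function(set, mode = c("scaffold", "framework"),
                            include_acyclic = FALSE) {
  mode <- match.arg(mode)
  smiles <- smiles_of(set)
  assert_that(length(smiles) >= 1L, "scaffold_report needs a non-empty set")
  scaf <- murcko_of(smiles, mode)
  n_acyclic <- sum(is.na(scaf))
  if (include_acyclic) {
    scaf[is.na(scaf)] <- ""
  } else {
    scaf <- scaf[!is.na(scaf)]
  }
  assert_that(length(scaf) >= 1L,
              "no compounds with scaffolds (all acyclic and include_acyclic = FALSE)")
  counts <- sort(table(scaf), decreasing = TRUE)
  structure(list(
    mode = mode,
    n_compounds = length(scaf),
    n_acyclic = n_acyclic,
    n_distinct = length(counts),
    unique_fraction = 100 * length(counts) / length(scaf),
    singleton_fraction = 100 * sum(counts == 1L) / length(counts),
    counts = stats::setNames(as.integer(counts), names(counts))
  ), class = "scaffold_report")
}

#' @export
print.scaffold_report <- function(x, ...) {
  cat(sprintf("<scaffold_report> mode = %s\n", x$mode))
  cat(sprintf("  %d compounds (%d acyclic excluded), %d distinct, unique %.1f%%, singleton %.1f%%\n",
              x$n_compounds, x$n_acyclic, x$n_distinct,
              x$unique_fraction, x$singleton_fraction))
  invisible(x)
}

#' Added scaffold value of two candidate additions
#'
#' Counts, for each candidate addition set, how many scaffolds (or
#' frameworks) it brings that are absent from the base set, and their ratio
#' — the "how much new chemistry does each addition buy" comparison (e.g.
#' complex vs simple chemistry additions on a simple-chemistry background).
#'
#' @param base Background `compound_set`.
#' @param addition_a,addition_b Candidate addition sets (disjoint from
#'   `base`).
#' @param mode `"scaffold"` or `"framework"`.
#' @return List with `new_a`, `new_b` (counts of novel scaffolds),
#'   `ratio_a_over_b`, and `pct_more` (percent more new scaffolds from A
#'   than from B).
#' @export
added_value <- function(base, addition_a, addition_b,
                        mode = c("scaffold", "framework")) {
  mode <- match.arg(mode)
  base_scafs <- unique(stats::na.omit(murcko_of(smiles_of(base), mode)))
  new_in <- function(addition) {
    s <- unique(stats::na.omit(murcko_of(smiles_of(addition), mode)))
    length(setdiff(s, base_scafs))
  }
  new_a <- new_in(addition_a)
  new_b <- new_in(addition_b)
  list(mode = mode, new_a = new_a, new_b = new_b,
       ratio_a_over_b = if (new_b > 0) new_a / new_b else NA_real_,
       pct_more = if (new_b > 0) 100 * (new_a - new_b) / new_b else NA_real_)
}
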