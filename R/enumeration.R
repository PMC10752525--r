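#' Define a two-component reaction
#'
#' @param reaction_id Short identifier, e.g. `"amide"`.
#' @param transform Reaction SMARTS with two reactant templates and one
#'   product template.
#' @param role_a,role_b Names of the two building-block roles (e.g.
#'   `"amine"`, `"acid"`).
#' @param complexity Chemistry tier of the products: `"simple"` (1-2 step,
#'   cheap blocks) or `"complex"` (multistep/expensive/special purification).
#' @return A `reaction_def` object.
#' @export
reaction_def <- function(reaction_id, transform, role_a, role_b,
                         complexity = c("simple", "complex")) {
  complexity <- match.arg(complexity)
  structure(list(reaction_id = reaction_id, transform = transform,
                 role_a = role_a, role_b = role_b, complexity = complexity),
            class = "reaction_def")
}

#' Load the shipped two-component reaction definitions
#'
#' Four representative chemistries (amide coupling, sulfonamide formation,
#' reductive amination, N-arylation) expressed as reaction SMARTS over two
#' roles. Real campaigns supply their own definitions in the same JSON
#' format: a list of `{reaction_id, transform, role_a, role_b, complexity}`.
#'
#' @param path Optional path to a reactions JSON file; defaults to the
#'   fixture shipped with the package.
#' @return Named list of `reaction_def` objects.
#' @export
default_reactions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reactions.json", package = "chemfunnel")
  defs <- jsonlite::read_json(path)
  out <- lapply(defs, function(d) {
    reaction_def(d$reaction_id, d$transform, d$role_a, d$role_b, d$complexity)
  })
  names(out) <- vapply(out, `[[`, "", "reaction_id")
  out
}

#' Construct a building-block table
#'
#' @param smiles Character vector of block SMILES.
#' @param role Role label (must match a reaction's `role_a`/`role_b`).
#' @param id Optional identifiers.
#' @param cost_tier `"standard"` or `"expensive"` (recycled).
#' @return A data.frame with columns `id, smiles, role, cost_tier, mw`;
#'   `mw` is computed, and invalid SMILES raise an error (building blocks
#'   must be curated, unlike bulk vendor compound files).
#' @export
building_blocks <- function(smiles, role, id = NULL, cost_tier = "standard") {
  assert_that(is.character(smiles) && length(smiles) >= 1L,
              "smiles must be a non-empty character vector")
  id <- id %||% sprintf("%s%04d", toupper(substr(role, 1, 2)), seq_along(smiles))
  can <- rdkit_call("canonicalize", list(smiles = as.list(smiles)))
  bad <- which(!vapply(can, function(r) isTRUE(r$ok), NA))
  if (length(bad) > 0L) {
    stop("invalid building-block SMILES at rows ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  props <- rdkit_call("properties", list(smiles = as.list(smiles)))
  data.frame(
    id = as.character(id),
    smiles = vapply(can, `[[`, "", "canonical"),
    role = role,
    cost_tier = rep_len(cost_tier, length(smiles)),
    mw = vapply(props, function(p) p$mwt, 0),
    stringsAsFactors = FALSE
  )
}

#' Read building blocks from CSV
#'
#' Expected columns: `id,smiles,role` and optional `cost_tier`.
#' @param path CSV path.
#' @return A building-block data.frame as from [building_blocks()].
#' @export
read_building_blocks <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE)
  assert_that(all(c("smiles", "role") %in% names(tab)),
              "building-block CSV needs columns smiles, role")
  out <- lapply(split(tab, tab$role), function(sub) {
    building_blocks(sub$smiles, role = sub$role[[1]],
                    id = if ("id" %in% names(sub)) sub$id else NULL,
                    cost_tier = if ("cost_tier" %in% names(sub)) sub$cost_tier else "standard")
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Define a reaction-derived sublibrary
#'
#' @param reaction A [reaction_def()].
#' @param blocks_a,blocks_b Building-block tables for the two roles.
#' @param sublibrary_id Optional identifier (defaults to the reaction id).
#' @param complexity Overrides the reaction's complexity tag if given.
#' @return A `sublibrary_def` object.
#' @export
sublibrary_def <- function(reaction, blocks_a, blocks_b, sublibrary_id = NULL,
                           complexity = NULL) {
  assert_that(inherits(reaction, "reaction_def"), "reaction must be a reaction_def")
  assert_that(nrow(blocks_a) >= 1L && nrow(blocks_b) >= 1L,
              "both block lists must be non-empty")
  structure(list(reaction = reaction, blocks_a = blocks_a, blocks_b = blocks_b,
                 sublibrary_id = sublibrary_id %||% reaction$reaction_id,
                 complexity = complexity %||% reaction$complexity),
            class = "sublibrary_def")
}

# Run the reaction over explicit (a, b) block index pairs; failures are
# quarantined with reasons, successes become a compound_set.
react_pairs <- function(lib, ia, ib, provenance) {
  pairs <- Map(function(i, j) list(lib$blocks_a$smiles[i], lib$blocks_b$smiles[j]), ia, ib)
  res <- rdkit_call("react", list(rxn_smarts = lib$reaction$transform, pairs = pairs))
  ok <- vapply(res, function(r) isTRUE(r$ok), NA)
  ids <- sprintf("%s_%s_%s", lib$sublibrary_id, lib$blocks_a$id[ia], lib$blocks_b$id[ib])
  out <- compound_set(
    vapply(res[ok], `[[`, "", "product"),
    id = ids[ok], sublibrary_id = lib$sublibrary_id,
    complexity = lib$complexity, provenance = provenance
  )
  attr(out, "rejects") <- data.frame(
    row = which(!ok),
    input = sprintf("%s + %s", lib$blocks_a$smiles[ia][!ok], lib$blocks_b$smiles[ib][!ok]),
    reason = vapply(res[!ok], function(r) r$error %||% "reaction failed", ""),
    stringsAsFactors = FALSE
  )
  out
}

# Uniform sample of distinct (a, b) block index pairs without materialising
# the cross-product; the full cross-product when it fits under cap.
sample_pairs <- function(na, nb, cap, seed) {
  n_pairs <- na * nb
  if (n_pairs <= cap) {
    idx <- seq_len(n_pairs)
  } else {
    set.seed(seed)
    idx <- sample.int(n_pairs, cap)
  }
  list(ia = ((idx - 1L) %% na) + 1L, ib = ((idx - 1L) %/% na) + 1L)
}

# Lowest-MW block index within a role table; ties broken lexicographically
# by canonical SMILES (the tie rule is a package convention).
lowest_mw_index <- function(blocks) {
  order(blocks$mw, blocks$smiles)[1]
}

#' Build the basis set of a sublibrary
#'
#' A compact stand-in for the full combinatorial product space: every A-role
#' block coupled with the lowest-molecular-weight B block, plus every
#' remaining B block coupled with the lowest-molecular-weight A block —
#' `|A| + |B| - 1` products (e.g. 100 amines and 200 acids give 299 basis
#' amides). Used to review a reaction's chemotypes without enumerating the
#' cross-product.
#'
#' @param lib A [sublibrary_def()].
#' @return A `compound_set` of basis products; failed couplings are in the
#'   `rejects` attribute.
#' @export
build_basis_set <- function(lib) {
  assert_that(inherits(lib, "sublibrary_def"), "lib must be a sublibrary_def")
  a0 <- lowest_mw_index(lib$blocks_a)
  b0 <- lowest_mw_index(lib$blocks_b)
  ia <- c(seq_len(nrow(lib$blocks_a)), rep(a0, nrow(lib$blocks_b) - 1L))
  ib <- c(rep(b0, nrow(lib$blocks_a)), setdiff(seq_len(nrow(lib$blocks_b)), b0))
  react_pairs(lib, ia, ib, provenance = sprintf("basis:%s", lib$sublibrary_id))
}

#' Enumerate a capped super-set of products
#'
#' The full `|A| x |B|` cross-product when it fits under `cap`; otherwise a
#' uniform random sample of exactly `cap` distinct block pairs (sampling is
#' over pairs, so the cap is respected without materialising the
#' cross-product). Reproducible for a fixed seed.
#'
#' @param lib A [sublibrary_def()].
#' @param cap Maximum number of products (>= 1).
#' @param seed Integer seed for the pair sample.
#' @return A `compound_set` of products.
#' @export
enumerate_superset <- function(lib, cap, seed = 1L) {
  assert_that(inherits(lib, "sublibrary_def"), "lib must be a sublibrary_def")
  assert_that(is_count(cap) && cap >= 1, "cap must be a positive count")
  pr <- sample_pairs(nrow(lib$blocks_a), nrow(lib$blocks_b), cap, seed)
  react_pairs(lib, pr$ia, pr$ib,
              provenance = sprintf("superset:%s(cap=%d,seed=%d)", lib$sublibrary_id, cap, seed))
}

#' Sample triage representatives from a product set
#'
#' The review file for human triage of each reaction: the `n_low` lowest
#' molecular-weight products (ties by canonical SMILES) plus `n_rand` drawn
#' uniformly from the remainder.
#'
#' @param products A `compound_set`; molecular weights are computed if
#'   absent.
#' @param n_low,n_rand Counts (defaults 3 and 5, the classic 8-example file).
#' @param seed Integer seed for the random picks.
#' @return A `compound_set` of at most `n_low + n_rand` representatives.
#' @export
sample_representatives <- function(products, n_low = 3L, n_rand = 5L, seed = 1L) {
  if (!"mwt" %in% names(products)) products <- compute_properties(products)
  n <- nrow(products)
  if (n <= n_low + n_rand) return(subset_set(products, seq_len(n), "representatives"))
  ord <- order(products$mwt, products$smiles_canonical)
  low <- ord[seq_len(n_low)]
  rest <- setdiff(seq_len(n), low)
  set.seed(seed)
  rnd <- sample(rest, n_rand)
  subset_set(products, sort(c(low, rnd)), "representatives")
}
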