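# Synthetic fixtures: grammar-based structure generation with plantable
# labels (charge class, structural alerts, synthesis complexity, shared-core
# redundancy) so every pipeline stage can be tested against known truth
# without any external data. Structures are assembled by concatenating
# self-contained SMILES fragments, each of which continues the atom chain —
# validity is guaranteed by the grammar, not by rejection sampling.

# Fragment pools. Heads start the chain and carry the intended charge class;
# linkers and tails are charge-silent (amide/sulfonamide N is excluded from
# the base patterns); cores carry the ring systems. Complex cores are
# saturated bridged/spiro systems, mirroring the higher sp3 character of
# multistep chemistry.
SYN_HEADS <- list(
  neutral = c("C", "CC", "CCC", "CC(C)", "COC", "OC", "CC(C)C"),
  acid = c("OC(=O)", "OC(=O)C", "OC(=O)CC"),
  base = c("NC", "NCC", "CNC", "CN(C)C", "NC(C)C")
)
SYN_LINKERS <- c("C", "CC", "CO", "OC", "C(=O)N", "NC(=O)", "CS(=O)(=O)N", "CCN(C(C)=O)")
SYN_CORES_SIMPLE <- c("c1ccccc1", "c1ccncc1", "c1cncnc1", "c1ccoc1",
                      "c1cc[nH]c1", "C1CCCCC1", "C1CCOCC1", "c1ccc2ccoc2c1",
                      "c1ccc2[nH]ccc2c1", "c1cnoc1")
SYN_CORES_COMPLEX <- c("C1CC2CCC1CC2", "C1CC2CCC1C2", "C1CC2(CCC2)C1",
                       "C1CC2(C1)COC2", "C1CCC2(CC1)CCOC2", "C1CC2(CCOC2)CC1",
                       "C1CCC2CCCC2C1", "C1OC2(CCC2)C1")
SYN_TAILS <- c("", "C", "CC", "OC", "F", "C(C)C", "C#N", "CF")
# alert features: a thioether tail and a nitroaryl ring, both covered by the
# shipped default alert sets; an alert feature REPLACES the ordinary tail
# (terminal tails like F or C#N cannot be extended)
SYN_ALERT_TAILS <- c("CSC", "c1ccc([N+](=O)[O-])cc1")
SYN_DECOY_CORES <- c("c1ccc2ccccc2c1", "C1CCCCCCC1", "c1ccc2c(c1)cccc2O",
                     "C1CCNCC1")

#' Specification for a synthetic compound pool
#'
#' The stated world the generator emulates: several reaction-derived
#' sublibraries with controllable size, internal redundancy (shared-core
#' fraction driving mean pairwise similarity), and planted fractions of
#' alert-bearing / acid / base / complex members.
#'
#' @param n_sublibraries Number of sublibraries.
#' @param size Compounds per sublibrary (recycled).
#' @param redundancy Per-sublibrary redundancy in `[0, 1]`: 0 draws cores
#'   from the full core pool, 1 collapses to a single shared core
#'   (recycled). Higher redundancy yields higher mean pairwise similarity.
#' @param frac_alert,frac_acid,frac_base,frac_complex Planted label
#'   fractions in `[0, 1]`; the neutral fraction is the remainder
#'   (`frac_acid + frac_base <= 1`).
#' @param seed Master seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_sublibraries = 3L, size = 100L, redundancy = 0.3,
                         frac_alert = 0.1, frac_acid = 0.07, frac_base = 0.33,
                         frac_complex = 0.3, seed = 1L) {
  assert_that(is_count(n_sublibraries) && n_sublibraries >= 1L,
              "n_sublibraries must be >= 1")
  assert_that(all(size >= 1), "size must be >= 1")
  fr <- c(frac_alert, frac_acid, frac_base, frac_complex, redundancy)
  assert_that(all(fr >= 0 & fr <= 1), "all fractions must lie in [0, 1]")
  assert_that(frac_acid + frac_base <= 1, "frac_acid + frac_base must be <= 1")
  structure(list(n_sublibraries = as.integer(n_sublibraries),
                 size = as.integer(size), redundancy = redundancy,
                 frac_alert = frac_alert, frac_acid = frac_acid,
                 frac_base = frac_base, frac_complex = frac_complex,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Assemble one molecule from the grammar; the alert fragment replaces the
# ordinary tail when present.
assemble_smiles <- function(head, linker, core, linker2, core2, tail, alert_tail = "") {
  paste0(head, linker, core, linker2, core2,
         if (nzchar(alert_tail)) alert_tail else tail)
}

#' Generate synthetic building-block tables
#'
#' Role-appropriate structures from the fragment grammar: amines carry a
#' reactive N-H (or are N-H heterocycles), acids a carboxylic acid,
#' sulfonyl chlorides, aldehydes and aryl bromides their respective handles.
#' All blocks are valid, distinct and reproducible for a fixed seed.
#'
#' @param n_per_role Number of blocks per role.
#' @param roles Subset of `c("amine", "acid", "sulfonyl_chloride",
#'   "aldehyde", "aryl_bromide")`.
#' @param seed Integer seed.
#' @return Named list of building-block data.frames (see
#'   [building_blocks()]).
#' @export
generate_blocks <- function(n_per_role, roles = c("amine", "acid"), seed = 1L) {
  assert_that(is_count(n_per_role) && n_per_role >= 1L, "n_per_role must be >= 1")
  roles <- match.arg(roles, c("amine", "acid", "sulfonyl_chloride",
                              "aldehyde", "aryl_bromide"), several.ok = TRUE)
  chains <- c("C", "CC", "CCC", "CC(C)C", "CCO", "COC", "CCOC", "CC(C)",
              "CCC(C)", "CCCC")
  heads <- c(amine = "NC", acid = "OC(=O)", sulfonyl_chloride = "ClS(=O)(=O)C",
             aldehyde = "O=CC", aryl_bromide = "Br")
  out <- lapply(roles, function(role) {
    set.seed(stage_seed(seed, match(role, names(heads))))
    smis <- character(0)
    tries <- 0L
    while (length(smis) < n_per_role && tries < 40L) {
      tries <- tries + 1L
      n_want <- 2L * (n_per_role - length(smis))
      cand <- vapply(seq_len(n_want), function(i) {
        core <- if (role == "aryl_bromide") {
          sample(grep("^c", SYN_CORES_SIMPLE, value = TRUE), 1L)
        } else if (stats::runif(1) < 0.6) sample(SYN_CORES_SIMPLE, 1L) else ""
        paste0(heads[[role]], sample(chains, 1L), core,
               if (nzchar(core)) sample(c("", "C", "F"), 1L) else "")
      }, "")
      res <- rdkit_call("canonicalize", list(smiles = as.list(cand)))
      ok <- vapply(res, function(r) isTRUE(r$ok), NA)
      keys <- vapply(res[ok], `[[`, "", "key")
      new <- cand[ok][!duplicated(keys) & !(keys %in% attr(smis, "keys"))]
      newkeys <- keys[!duplicated(keys) & !(keys %in% attr(smis, "keys"))]
      smis <- c(smis, new)
      attr(smis, "keys") <- c(attr(smis, "keys"), newkeys)
      smis <- smis[!duplicated(attr(smis, "keys"))]
    }
    assert_that(length(smis) >= n_per_role,
                sprintf("could not generate %d distinct %s blocks", n_per_role, role))
    building_blocks(utils::head(as.character(smis), n_per_role), role = role)
  })
  stats::setNames(out, roles)
}

#' Generate labelled synthetic sublibrary pools
#'
#' Builds `n_sublibraries` pools with exact planted label counts
#' (largest-remainder of the spec fractions): charge class via the head
#' fragment, structural alerts via a thioether tail or nitroaryl ring,
#' complexity via saturated bridged/spiro cores. Each sublibrary draws its
#' ring cores from a pool whose size shrinks with `redundancy`, so high
#' redundancy produces high mean pairwise similarity. Every structure is
#' validated and canonicalized; a truth table records the intended labels.
#'
#' @param spec A [fixture_spec()].
#' @return List with `pools` (named list of `compound_set`s, properties not
#'   yet computed) and `truth` (data.frame `id, sublibrary_id, charge,
#'   alert, complexity, core`).
#' @export
generate_pool <- function(spec) {
  assert_that(inherits(spec, "fixture_spec"), "spec must be a fixture_spec")
  sizes <- rep_len(spec$size, spec$n_sublibraries)
  redun <- rep_len(spec$redundancy, spec$n_sublibraries)
  pools <- list()
  truth <- list()
  for (s in seq_len(spec$n_sublibraries)) {
    set.seed(stage_seed(spec$seed, s))
    n <- sizes[s]
    lib_id <- sprintf("SUB%02d", s)
    n_cores_s <- max(1L, round((1 - redun[s]) * length(SYN_CORES_SIMPLE)))
    n_cores_c <- max(1L, round((1 - redun[s]) * length(SYN_CORES_COMPLEX)))
    cores_s <- sample(SYN_CORES_SIMPLE, n_cores_s)
    cores_c <- sample(SYN_CORES_COMPLEX, n_cores_c)
    charge <- rep(c("acid", "base", "neutral"),
                  largest_remainder(c(spec$frac_acid, spec$frac_base,
                                      1 - spec$frac_acid - spec$frac_base), n))
    complexity <- rep(c("complex", "simple"),
                      largest_remainder(c(spec$frac_complex, 1 - spec$frac_complex), n))
    alert <- rep(c(TRUE, FALSE),
                 largest_remainder(c(spec$frac_alert, 1 - spec$frac_alert), n))
    charge <- sample(charge); complexity <- sample(complexity); alert <- sample(alert)
    smi <- vapply(seq_len(n), function(i) {
      core1 <- if (complexity[i] == "complex") sample(cores_c, 1L) else sample(cores_s, 1L)
      two_rings <- stats::runif(1) < 0.75
      core2 <- if (two_rings) sample(cores_s, 1L) else ""
      assemble_smiles(
        head = sample(SYN_HEADS[[charge[i]]], 1L),
        linker = sample(SYN_LINKERS, 1L),
        core = core1,
        linker2 = if (two_rings) sample(SYN_LINKERS, 1L) else "",
        core2 = core2,
        tail = sample(SYN_TAILS, 1L),
        alert_tail = if (alert[i]) sample(SYN_ALERT_TAILS, 1L) else ""
      )
    }, "")
    ids <- sprintf("%s_%04d", lib_id, seq_len(n))
    cs <- compound_set(smi, id = ids, sublibrary_id = lib_id,
                       provenance = sprintf("synthetic:%s", lib_id))
    if (nrow(attr(cs, "rejects")) > 0L) {
      stop("synthetic grammar produced invalid SMILES: ",
           paste(utils::head(attr(cs, "rejects")$input, 3), collapse = ", "),
           call. = FALSE)
    }
    cs$complexity <- complexity
    pools[[lib_id]] <- cs
    truth[[lib_id]] <- data.frame(id = ids, sublibrary_id = lib_id,
                                  charge = charge, alert = alert,
                                  complexity = complexity, smiles = smi,
                                  stringsAsFactors = FALSE)
  }
  list(pools = pools, truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate a synthetic exclusion set
#'
#' A stand-in for a disclosed-compound set: `overlap_fraction` of the pool
#' is represented by planted near-duplicates (single fragment edits,
#' verified to have Tanimoto similarity > 0.5 to their parents, re-edited
#' otherwise) plus unrelated decoys.
#'
#' @param pool A `compound_set`.
#' @param overlap_fraction Fraction of the pool with a planted
#'   near-duplicate in the exclusion set.
#' @param seed Integer seed.
#' @param n_decoys Number of unrelated decoys (default: half the overlap
#'   count, at least 5).
#' @return A `compound_set`; the parent pool ids of the planted
#'   near-duplicates are in `attr(, "planted_parents")`.
#' @export
generate_exclusion <- function(pool, overlap_fraction, seed = 1L, n_decoys = NULL) {
  assert_that(overlap_fraction >= 0 && overlap_fraction <= 1,
              "overlap_fraction must lie in [0, 1]")
  set.seed(stage_seed(seed, 97L))
  k <- round(overlap_fraction * nrow(pool))
  n_decoys <- n_decoys %||% max(5L, ceiling(k / 2))
  parents <- if (k > 0L) sample(seq_len(nrow(pool)), k) else integer()
  near <- character(0)
  kept_parents <- character(0)
  if (k > 0L) {
    base_smis <- pool$smiles_input[parents]
    edits <- function(s) c(paste0(s, "C"), paste0("C", s), paste0(s, "CC"), paste0("CC", s))
    cand <- lapply(base_smis, edits)
    flat <- unlist(cand)
    res <- rdkit_call("canonicalize", list(smiles = as.list(flat)))
    ok <- vapply(res, function(r) isTRUE(r$ok), NA)
    # similarity of every valid candidate to its parent, one bridge batch
    valid_idx <- which(ok)
    sims <- rep(NA_real_, length(flat))
    if (length(valid_idx) > 0L) {
      fp_c <- fingerprint(flat[valid_idx])
      fp_p <- fingerprint(pool[parents[ceiling(valid_idx / 4)], , drop = FALSE])
      sims[valid_idx] <- vapply(seq_along(valid_idx), function(j) {
        tanimoto_matrix(fp_set(fp_c$bits[j], fp_c$n_bits),
                        fp_set(fp_p$bits[j], fp_p$n_bits))[1, 1]
      }, 0)
    }
    for (i in seq_len(k)) {
      slots <- (i - 1L) * 4L + 1:4
      hit <- slots[which(!is.na(sims[slots]) & sims[slots] > 0.5)[1]]
      if (!is.na(hit)) {
        near <- c(near, flat[hit])
        kept_parents <- c(kept_parents, pool$id[parents[i]])
      }
    }
  }
  decoys <- vapply(seq_len(n_decoys), function(i) {
    paste0(sample(c("CCCC", "CCCCC", "CCOCC"), 1L), sample(SYN_DECOY_CORES, 1L),
           sample(c("", "C", "CC"), 1L))
  }, "")
  out <- compound_set(c(near, decoys),
                      id = sprintf("EXCL%05d", seq_len(length(near) + n_decoys)),
                      provenance = sprintf("exclusion(overlap=%g,seed=%d)",
                                           overlap_fraction, seed))
  attr(out, "planted_parents") <- kept_parents
  out
}
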