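# Morgan fingerprints, Tanimoto similarity, exact pairwise statistics and
# novelty filtering against exclusion sets.

#' Construct a fingerprint set from explicit on-bits
#'
#' Mostly for tests and boundary-condition work; pipeline code uses
#' [fingerprint()].
#'
#' @param bits List of integer vectors of 1-based on-bit positions.
#' @param n_bits Fingerprint length.
#' @param ids Optional identifiers.
#' @return An `fp_set`.
#' @export
fp_set <- function(bits, n_bits = 1024L, ids = NULL) {
  assert_that(is.list(bits), "bits must be a list of integer vectors")
  bits <- lapply(bits, as.integer)
  assert_that(all(vapply(bits, function(b) length(b) == 0L || (min(b) >= 1L && max(b) <= n_bits), NA)),
              "bit positions must lie in [1, n_bits]")
  structure(list(bits = bits, n_bits = as.integer(n_bits), radius = NA_integer_,
                 ids = ids %||% as.character(seq_along(bits))),
            class = "fp_set")
}

#' Morgan (circular) fingerprints
#'
#' Hashed circular fingerprints, by default radius 2 over 1024 bits —
#' stereo-insensitive, deterministic, invariant to input atom ordering.
#'
#' @param x A `compound_set`, `chem_mol` or character vector of SMILES.
#' @param radius Circular radius in bonds.
#' @param n_bits Fingerprint length.
#' @return An `fp_set`: list with `bits` (1-based on-bit positions per
#'   molecule), `n_bits`, `radius`, `ids`.
#' @export
fingerprint <- function(x, radius = 2L, n_bits = 1024L) {
  smiles <- smiles_of(x)
  ids <- if (inherits(x, "compound_set")) x$id else as.character(seq_along(smiles))
  if (length(smiles) == 0L) return(fp_set(list(), n_bits))
  res <- rdkit_call("morgan", list(smiles = as.list(smiles),
                                   radius = radius, n_bits = n_bits))
  bad <- vapply(res, is.null, NA)
  assert_that(!any(bad), paste0("unparseable SMILES at positions ",
                                paste(utils::head(which(bad), 5), collapse = ", ")))
  out <- fp_set(lapply(res, function(b) unlist(b) + 1L), n_bits, ids)
  out$radius <- as.integer(radius)
  out
}

#' @export
print.fp_set <- function(x, ...) {
  cat(sprintf("<fp_set> %d fingerprints, %d bits, radius %s\n",
              length(x$bits), x$n_bits, x$radius))
  invisible(x)
}

fp_bit_matrix <- function(fp, idx = seq_along(fp$bits)) {
  m <- matrix(0, nrow = length(idx), ncol = fp$n_bits)
  for (i in seq_along(idx)) m[i, fp$bits[[idx[i]]]] <- 1
  m
}

# Dense blocked Tanimoto between two fp_sets. 0/0 (two empty fingerprints)
# is defined as 0; real molecules always set at least one bit.
tanimoto_matrix <- function(fa, fb, block = 2000L) {
  assert_that(fa$n_bits == fb$n_bits, "fingerprint lengths differ")
  na <- length(fa$bits); nb <- length(fb$bits)
  out <- matrix(0, na, nb)
  pa <- vapply(fa$bits, length, 0L)
  pb <- vapply(fb$bits, length, 0L)
  for (i0 in seq(1L, na, by = block)) {
    i1 <- min(i0 + block - 1L, na)
    ma <- fp_bit_matrix(fa, i0:i1)
    for (j0 in seq(1L, nb, by = block)) {
      j1 <- min(j0 + block - 1L, nb)
      mb <- fp_bit_matrix(fb, j0:j1)
      inter <- ma %*% t(mb)
      uni <- outer(pa[i0:i1], pb[j0:j1], `+`) - inter
      s <- inter / uni
      s[uni == 0] <- 0
      out[i0:i1, j0:j1] <- s
    }
  }
  out
}

#' Tanimoto similarity
#'
#' `|intersection| / |union|` of set bits: 1 for identical fingerprints, 0
#' for disjoint ones, symmetric.
#'
#' @param a,b `fp_set` objects of equal `n_bits` (each may hold one or many
#'   fingerprints).
#' @return A scalar when both hold one fingerprint, else the
#'   `length(a) x length(b)` similarity matrix.
#' @export
tanimoto <- function(a, b) {
  assert_that(inherits(a, "fp_set") && inherits(b, "fp_set"),
              "a and b must be fp_set objects")
  m <- tanimoto_matrix(a, b)
  if (length(a$bits) == 1L && length(b$bits) == 1L) m[1, 1] else m
}

#' Exact pairwise similarity statistics of a set
#'
#' The full similarity matrix over all ordered pairs excluding self-pairs
#' (`n * (n-1)` values; the mean is identical to the unordered mean by
#' symmetry), computed exactly in blocks — no sampling at any size.
#'
#' @param x A `compound_set` or `fp_set`.
#' @param bins Number of histogram bins over `[0, 1]` (right-closed).
#' @param block Block edge for the blocked computation.
#' @return A `similarity_stats`: list with `n`, `n_pairs`, `mean`,
#'   `histogram` (data.frame `lower, upper, count`).
#' @export
pairwise_stats <- function(x, bins = 50L, block = 2000L) {
  fp <- if (inherits(x, "fp_set")) x else fingerprint(x)
  n <- length(fp$bits)
  assert_that(n >= 2L, "pairwise statistics need at least 2 compounds")
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- integer(bins)
  total <- 0
  pa <- vapply(fp$bits, length, 0L)
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(i0 + block - 1L, n)
    ma <- fp_bit_matrix(fp, i0:i1)
    for (j0 in seq(1L, n, by = block)) {
      j1 <- min(j0 + block - 1L, n)
      if (j1 < i0) next  # upper triangle only; doubled below
      mb <- fp_bit_matrix(fp, j0:j1)
      inter <- ma %*% t(mb)
      uni <- outer(pa[i0:i1], pa[j0:j1], `+`) - inter
      s <- inter / uni
      s[uni == 0] <- 0
      keep <- outer(i0:i1, j0:j1, `<`)
      vals <- s[keep]
      if (length(vals) > 0L) {
        counts <- counts + graphics::hist(vals, breaks = breaks, plot = FALSE,
                                          include.lowest = TRUE, right = TRUE)$counts
        total <- total + sum(vals)
      }
    }
  }
  counts <- counts * 2L  # unordered -> ordered pairs
  structure(list(n = n, n_pairs = n * (n - 1), mean = 2 * total / (n * (n - 1)),
                 histogram = data.frame(lower = breaks[-length(breaks)],
                                        upper = breaks[-1], count = counts)),
            class = "similarity_stats")
}

#' @export
print.similarity_stats <- function(x, ...) {
  cat(sprintf("<similarity_stats> n = %d, %d ordered pairs, mean Tanimoto = %.4f\n",
              x$n, x$n_pairs, x$mean))
  invisible(x)
}

# Max similarity of each pool member against an exclusion fp_set.
max_similarity <- function(fp_pool, fp_excl, block = 2000L) {
  s <- tanimoto_matrix(fp_pool, fp_excl, block = block)
  list(sim = apply(s, 1L, max), which = apply(s, 1L, which.max))
}

#' Remove compounds similar to an exclusion set
#'
#' A record is removed iff its maximum Tanimoto similarity to the exclusion
#' set STRICTLY exceeds `threshold` — a compound sitting exactly at the
#' threshold is retained. Removal reasons record the nearest exclusion
#' member and the similarity.
#'
#' @param set A `compound_set`.
#' @param exclusion A `compound_set` of disclosed/known compounds.
#' @param threshold Similarity threshold (default 0.5).
#' @param radius,n_bits Fingerprint parameters.
#' @param fps,fps_exclusion Optional precomputed `fp_set`s (row-aligned with
#'   `set`/`exclusion`), e.g. for boundary tests with hand-built bits.
#' @return The filtered `compound_set`; removals (with
#'   `nearest_excluded_id`, `similarity`) in `attr(, "removed")`.
#' @export
novelty_filter <- function(set, exclusion, threshold = 0.5,
                           radius = 2L, n_bits = 1024L,
                           fps = NULL, fps_exclusion = NULL) {
  if (nrow(exclusion) == 0L) {
    warning("empty exclusion set: all compounds retained")
    out <- subset_set(set, seq_len(nrow(set)), "novelty:empty-exclusion")
    attr(out, "removed") <- data.frame(id = character(),
                                       nearest_excluded_id = character(),
                                       similarity = numeric())
    return(out)
  }
  fps <- fps %||% fingerprint(set, radius, n_bits)
  fps_exclusion <- fps_exclusion %||% fingerprint(exclusion, radius, n_bits)
  ms <- max_similarity(fps, fps_exclusion)
  keep <- !(ms$sim > threshold)
  out <- subset_set(set, keep, sprintf("novelty(>%g)", threshold))
  attr(out, "removed") <- data.frame(
    id = set$id[!keep],
    nearest_excluded_id = exclusion$id[ms$which[!keep]],
    similarity = ms$sim[!keep], stringsAsFactors = FALSE
  )
  out
}

#' Remove exact catalog matches
#'
#' Commercial-availability removal implemented as an exact join on the
#' stereochemistry-free canonical key (not a similarity search).
#'
#' @param set A `compound_set`.
#' @param catalog A `compound_set` of known/available compounds.
#' @return The filtered `compound_set`; matches in `attr(, "removed")`.
#' @export
remove_known <- function(set, catalog) {
  hit <- set$smiles_key %in% catalog$smiles_key
  out <- subset_set(set, !hit, "catalog-removal")
  attr(out, "removed") <- data.frame(id = set$id[hit],
                                     smiles = set$smiles_canonical[hit],
                                     stringsAsFactors = FALSE)
  out
}
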