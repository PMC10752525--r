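# Diverse-subset selection: greedy MaxMin picking on fingerprint distances,
# and redundancy-driven per-sublibrary quota allocation.

#' MaxMin diverse-subset selection
#'
#' Greedy picking on Tanimoto distance (1 - similarity): the first pick is
#' pseudo-random from the seed; each subsequent pick maximizes its minimum
#' distance to everything already picked. Ties (within 1e-12) are broken by
#' canonical SMILES order, so runs are fully deterministic for a fixed seed.
#'
#' @param pool A `compound_set`.
#' @param k Number of compounds to select, `1 <= k <= nrow(pool)`.
#' @param seed Integer seed (first pick).
#' @param fps Optional precomputed `fp_set` row-aligned with `pool`.
#' @param first Optional explicit first-pick row index, overriding the
#'   seeded random start.
#' @return A `compound_set` of `k` records, in pick order; pick indices in
#'   `attr(, "pick_order")`.
#' @export
maxmin_select <- function(pool, k, seed = 1L, fps = NULL, first = NULL) {
  n <- nrow(pool)
  assert_that(is_count(k) && k >= 1, "k must be a positive count")
  if (k > n) stop("k (", k, ") exceeds pool size (", n, ")", call. = FALSE)
  fps <- fps %||% fingerprint(pool)
  set.seed(seed)
  first <- first %||% sample.int(n, 1L)
  picked <- integer(k)
  picked[1L] <- first
  if (k > 1L) {
    key <- pool$smiles_canonical
    mind <- 1 - tanimoto_matrix(fps, fp_set(fps$bits[first], fps$n_bits))[, 1]
    for (t in 2:k) {
      mind[picked[seq_len(t - 1L)]] <- -Inf
      best <- max(mind)
      cand <- which(mind >= best - 1e-12)
      pick <- cand[order(key[cand])][1L]
      picked[t] <- pick
      d_new <- 1 - tanimoto_matrix(fps, fp_set(fps$bits[pick], fps$n_bits))[, 1]
      mind <- pmin(mind, d_new)
    }
  }
  out <- subset_set(pool, picked, sprintf("maxmin(k=%d,seed=%d)", k, seed))
  attr(out, "pick_order") <- picked
  out
}

#' Per-sublibrary pool statistics
#'
#' @param pools Named list of `compound_set` pools.
#' @return data.frame `sublibrary_id, pool_size, mean_sim` (mean pairwise
#'   Tanimoto; 0 for pools of size < 2).
#' @export
sublibrary_stats <- function(pools) {
  assert_that(is.list(pools) && length(pools) > 0L && !is.null(names(pools)),
              "pools must be a non-empty named list")
  data.frame(
    sublibrary_id = names(pools),
    pool_size = vapply(pools, nrow, 0L),
    mean_sim = vapply(pools, function(p) {
      if (nrow(p) < 2L) 0 else pairwise_stats(p)$mean
    }, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Allocate per-sublibrary selection quotas
#'
#' Quotas proportional to `pool_size^exponent * (1 - mean_sim)`: larger and
#' internally less redundant sublibraries contribute more. Largest-remainder
#' rounding, clamping to pool sizes with redistribution, fully
#' deterministic. A pool of identical compounds (mean similarity 1) gets
#' weight 0 before redistribution.
#'
#' @param x Either a named list of `compound_set` pools or a data.frame as
#'   returned by [sublibrary_stats()].
#' @param total Total number of compounds to select.
#' @param exponent Size exponent in the weight (default 1).
#' @return A `quota_plan` data.frame
#'   (`sublibrary_id, pool_size, mean_sim, quota`); any infeasible shortfall
#'   is reported in `attr(, "shortfall")`.
#' @export
allocate_quotas <- function(x, total, exponent = 1) {
  stats <- if (is.data.frame(x)) x else sublibrary_stats(x)
  assert_that(all(c("sublibrary_id", "pool_size", "mean_sim") %in% names(stats)),
              "need columns sublibrary_id, pool_size, mean_sim")
  assert_that(is_count(total), "total must be a count")
  if (all(stats$pool_size == 0L)) stop("all pools are empty", call. = FALSE)
  shortfall <- max(0L, total - sum(stats$pool_size))
  if (shortfall > 0L) {
    warning("requested total ", total, " exceeds pooled size ",
            sum(stats$pool_size), "; shortfall ", shortfall)
    total <- sum(stats$pool_size)
  }
  w <- stats$pool_size^exponent * (1 - stats$mean_sim)
  if (sum(w) == 0) w <- as.numeric(stats$pool_size > 0)  # degenerate: all fully redundant
  stats$quota <- capped_allocation(w, stats$pool_size, total)
  # weights can strand capacity (all positive-weight pools saturated);
  # spread the remainder over pools that still have room, by size
  left <- total - sum(stats$quota)
  if (left > 0L) {
    room <- stats$pool_size - stats$quota
    stats$quota <- stats$quota + capped_allocation(as.numeric(room > 0), room, left)
  }
  attr(stats, "shortfall") <- shortfall
  class(stats) <- c("quota_plan", "data.frame")
  stats
}

#' Run MaxMin selection across sublibraries under a quota plan
#'
#' Applies [maxmin_select()] to each sublibrary pool in turn with its quota;
#' per-library seeds are fanned out deterministically from `seed`, so any
#' library's selection can be reproduced in isolation.
#'
#' @param pools Named list of `compound_set` pools.
#' @param plan A `quota_plan` from [allocate_quotas()].
#' @param seed Master integer seed.
#' @return A `compound_set` union of the per-library selections, with
#'   `sublibrary_id` provenance.
#' @export
diversity_select <- function(pools, plan, seed = 1L) {
  assert_that(inherits(plan, "quota_plan"), "plan must be a quota_plan")
  assert_that(all(plan$sublibrary_id %in% names(pools)),
              "plan names a sublibrary not present in pools")
  parts <- lapply(seq_len(nrow(plan)), function(i) {
    q <- plan$quota[i]
    if (q == 0L) return(NULL)
    maxmin_select(pools[[plan$sublibrary_id[i]]], q, seed = stage_seed(seed, i))
  })
  parts <- Filter(Negate(is.null), parts)
  assert_that(length(parts) > 0L, "quota plan selects nothing")
  df <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(df) <- NULL
  new_compound_set(df, provenance = c("diversity_select",
                                      sprintf("seed=%d,total=%d", seed, sum(plan$quota))))
}
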