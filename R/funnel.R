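# End-to-end selection funnel: enumerated pools -> alert filter -> wide
# window -> crude window + per-library caps -> diversity quotas -> agreed
# window + novelty filter -> duplicate/catalog removal -> composition-
# constrained final draw. Every stage is logged and the whole run is
# reproducible from one master seed.

#' Configure a selection funnel
#'
#' @param windows Named list of `property_window`s with stages `wide`,
#'   `crude`, `agreed` (default [default_windows()]).
#' @param alerts An `alert_set` (default [default_alerts()]); `NULL` skips
#'   the alert stage.
#' @param alert_mode `"remove"` or `"flag"`.
#' @param exclusion Optional `compound_set` for the similarity novelty
#'   filter.
#' @param catalog Optional `compound_set` for exact-match removal
#'   (commercially available compounds).
#' @param include_sublibraries Optional character vector: the reproducible
#'   stand-in for human triage — only these sublibraries pass stage 1.
#' @param crude_cap Per-sublibrary cap applied with the crude window
#'   (default 250000, uniform random down-sampling).
#' @param diversity_total Total size of the diversity selection across
#'   sublibraries.
#' @param quota_exponent Exponent in [allocate_quotas()].
#' @param novelty_threshold Strict Tanimoto threshold (default 0.5).
#' @param charge_targets Named fractions for `neutral`, `base`, `acid`
#'   (default 60/33/7; must sum to 1).
#' @param simple_fraction Target fraction of simple chemistry in the final
#'   draw (default 0.7).
#' @param final_size,reserve_size Sizes of the final library and the
#'   back-fill reserve (defaults 30000 and 15000).
#' @param seed Master seed; per-stage seeds are fanned out deterministically.
#' @return A `funnel_config` list.
#' @export
funnel_config <- function(windows = default_windows(),
                          alerts = default_alerts(),
                          alert_mode = c("remove", "flag"),
                          exclusion = NULL, catalog = NULL,
                          include_sublibraries = NULL,
                          crude_cap = 250000L,
                          diversity_total = NULL,
                          quota_exponent = 1,
                          novelty_threshold = 0.5,
                          charge_targets = c(neutral = 0.60, base = 0.33, acid = 0.07),
                          simple_fraction = 0.7,
                          final_size = 30000L, reserve_size = 15000L,
                          seed = 1L) {
  alert_mode <- match.arg(alert_mode)
  assert_that(all(c("wide", "crude", "agreed") %in% names(windows)),
              "windows must contain stages wide, crude, agreed")
  assert_that(all(sort(names(charge_targets)) == c("acid", "base", "neutral")),
              "charge_targets must be named acid, base, neutral")
  assert_that(abs(sum(charge_targets) - 1) < 1e-9, "charge_targets must sum to 1")
  assert_that(simple_fraction >= 0 && simple_fraction <= 1,
              "simple_fraction must lie in [0, 1]")
  structure(list(windows = windows, alerts = alerts, alert_mode = alert_mode,
                 exclusion = exclusion, catalog = catalog,
                 include_sublibraries = include_sublibraries,
                 crude_cap = as.integer(crude_cap),
                 diversity_total = diversity_total,
                 quota_exponent = quota_exponent,
                 novelty_threshold = novelty_threshold,
                 charge_targets = charge_targets,
                 simple_fraction = simple_fraction,
                 final_size = as.integer(final_size),
                 reserve_size = as.integer(reserve_size),
                 seed = as.integer(seed)),
            class = "funnel_config")
}

# Stratified draw hitting the simple:complex ratio exactly (+-1 compound by
# rounding) and the charge fractions as closely as each complexity stratum
# allows; shortfalls relax proportionally (largest remainder) with a warning.
stratified_draw <- function(pool, charge_targets, simple_fraction, size, seed) {
  assert_that(all(c("charge_class", "complexity") %in% names(pool)),
              "pool must carry charge_class and complexity labels")
  assert_that(size <= nrow(pool), "draw size exceeds pool")
  set.seed(seed)
  comp_levels <- c("simple", "complex")
  charge_levels <- names(charge_targets)
  comp_target <- largest_remainder(c(simple_fraction, 1 - simple_fraction), size)
  avail <- table(factor(pool$complexity, comp_levels),
                 factor(pool$charge_class, charge_levels))
  # relax the complexity split if a stratum cannot fill its target
  if (any(comp_target > rowSums(avail))) {
    warning("complexity stratum smaller than target; relaxing split")
    over <- pmax(0L, comp_target - as.integer(rowSums(avail)))
    comp_target <- pmin(comp_target, as.integer(rowSums(avail)))
    room <- as.integer(rowSums(avail)) - comp_target
    comp_target <- comp_target + capped_allocation(as.numeric(room > 0), room, sum(over))
  }
  take <- integer(0)
  for (ci in seq_along(comp_levels)) {
    want <- comp_target[ci]
    if (want == 0L) next
    cap <- as.integer(avail[ci, ])
    ideal <- largest_remainder(charge_targets, want)
    tgt <- capped_allocation(charge_targets, cap, want)
    if (any(ideal > cap)) {
      warning("charge target for ", paste(charge_levels[ideal > cap], collapse = ","),
              " not met in the '", comp_levels[ci],
              "' stratum (pool too small); other classes rescaled")
    }
    for (hi in seq_along(charge_levels)) {
      if (tgt[hi] == 0L) next
      idx <- which(pool$complexity == comp_levels[ci] &
                     pool$charge_class == charge_levels[hi])
      take <- c(take, if (length(idx) == 1L) idx else sample(idx, tgt[hi]))
    }
  }
  sort(take)
}

#' Composition-constrained final draw
#'
#' Draws the final library and the back-fill reserve from the post-filter
#' pool by stratified random sampling over complexity x charge class: the
#' simple:complex ratio is hit exactly (+-1 by rounding) and the charge
#' fractions as closely as the pool allows (largest-remainder rounding,
#' proportional relaxation with a warning when a stratum runs short). The
#' reserve is drawn from the remainder with the same stratification.
#'
#' @param pool A `compound_set` with `charge_class` and `complexity` labels.
#' @param charge_targets,simple_fraction,seed See [funnel_config()].
#' @param size,reserve Final and reserve sizes.
#' @return List with `final` and `reserve` `compound_set`s and
#'   `achieved` (a data.frame of realized complexity/charge fractions of the
#'   final set).
#' @export
compose_final <- function(pool, charge_targets = c(neutral = 0.60, base = 0.33, acid = 0.07),
                          simple_fraction = 0.7, size, reserve = 0L, seed = 1L) {
  assert_that(size + reserve <= nrow(pool),
              sprintf("final + reserve (%d) exceeds pool (%d)", size + reserve, nrow(pool)))
  idx_final <- stratified_draw(pool, charge_targets, simple_fraction, size,
                               seed = stage_seed(seed, 1L))
  rest <- subset_set(pool, setdiff(seq_len(nrow(pool)), idx_final))
  final <- subset_set(pool, idx_final, "compose_final")
  reserve_set <- if (reserve > 0L) {
    idx_res <- stratified_draw(rest, charge_targets, simple_fraction,
                               min(reserve, nrow(rest)), seed = stage_seed(seed, 2L))
    subset_set(rest, idx_res, "compose_reserve")
  } else {
    subset_set(pool, integer(), "compose_reserve")
  }
  achieved <- data.frame(
    simple = mean(final$complexity == "simple"),
    neutral = mean(final$charge_class == "neutral"),
    base = mean(final$charge_class == "base"),
    acid = mean(final$charge_class == "acid")
  )
  list(final = final, reserve = reserve_set, achieved = achieved)
}

#' Run the full selection funnel
#'
#' Executes the staged pipeline over enumerated sublibrary pools, recording
#' an auditable ledger (stage, parameters, n_in, n_out, rejects) with
#' chain-consistent counts, and returns the final library plus reserve.
#'
#' @param config A [funnel_config()].
#' @param pools Named list of `compound_set` pools (one per sublibrary),
#'   each labelled with `sublibrary_id` and `complexity`.
#' @return A `funnel_result`: list with `ledger` (data.frame), `final`,
#'   `reserve`, `achieved`, `rejects` (per-stage list), `quota_plan`.
#' @export
run_funnel <- function(config, pools) {
  assert_that(inherits(config, "funnel_config"), "config must be a funnel_config")
  assert_that(is.list(pools) && length(pools) > 0L && !is.null(names(pools)),
              "pools must be a non-empty named list")
  ledger <- list()
  rejects <- list()
  log_stage <- function(name, n_in, n_out, params = "") {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      stage = name, n_in = n_in, n_out = n_out, params = params,
      stringsAsFactors = FALSE)
  }

  df <- do.call(rbind, lapply(unname(pools), as.data.frame))
  rownames(df) <- NULL
  set <- new_compound_set(df, provenance = "funnel:pools")
  n0 <- nrow(set)

  # stage 1: sublibrary triage (explicit include list, the auditable
  # stand-in for review-by-eye)
  if (!is.null(config$include_sublibraries)) {
    keep <- set$sublibrary_id %in% config$include_sublibraries
    set <- subset_set(set, keep, "triage")
    log_stage("triage", n0, nrow(set),
              paste0("keep=", length(config$include_sublibraries), " sublibraries"))
  } else {
    log_stage("triage", n0, nrow(set), "all sublibraries retained")
  }

  # stage 2: structural alerts
  if (!is.null(config$alerts)) {
    n_in <- nrow(set)
    set <- filter_alerts(set, config$alerts, mode = config$alert_mode)
    rejects$alerts <- attr(set, "rejects")
    log_stage("alerts", n_in, nrow(set),
              paste0("mode=", config$alert_mode, ",set=", config$alerts$name))
  }

  # properties are computed once, then reused by every window
  set <- compute_properties(set)

  # stage 3: wide window
  n_in <- nrow(set)
  set <- apply_property_filter(set, config$windows$wide, "window:wide")
  rejects$wide <- attr(set, "rejects")
  log_stage("window_wide", n_in, nrow(set), window_string(config$windows$wide))

  # stage 4: crude window + per-sublibrary random cap
  n_in <- nrow(set)
  set <- apply_property_filter(set, config$windows$crude, "window:crude")
  rejects$crude <- attr(set, "rejects")
  by_lib <- split(seq_len(nrow(set)), set$sublibrary_id)
  capped <- unlist(lapply(seq_along(by_lib), function(i) {
    idx <- by_lib[[i]]
    if (length(idx) <= config$crude_cap) return(idx)
    set.seed(stage_seed(config$seed, 100L + i))
    sort(sample(idx, config$crude_cap))
  }))
  set <- subset_set(set, sort(capped), "crude_cap")
  log_stage("window_crude_cap", n_in, nrow(set),
            paste0(window_string(config$windows$crude), ",cap=", config$crude_cap))

  # stage 5: redundancy-driven quotas + per-sublibrary MaxMin
  n_in <- nrow(set)
  lib_pools <- lapply(split(seq_len(nrow(set)), set$sublibrary_id),
                      function(idx) subset_set(set, idx))
  total <- config$diversity_total %||% nrow(set)
  total <- min(total, nrow(set))
  plan <- allocate_quotas(lib_pools, total, exponent = config$quota_exponent)
  set <- diversity_select(lib_pools, plan, seed = stage_seed(config$seed, 200L))
  log_stage("diversity", n_in, nrow(set),
            paste0("total=", total, ",exponent=", config$quota_exponent))

  # stage 6: agreed window + novelty filter
  n_in <- nrow(set)
  set <- apply_property_filter(set, config$windows$agreed, "window:agreed")
  rejects$agreed <- attr(set, "rejects")
  if (!is.null(config$exclusion) && nrow(config$exclusion) > 0L) {
    set <- novelty_filter(set, config$exclusion, threshold = config$novelty_threshold)
    rejects$novelty <- attr(set, "removed")
  }
  log_stage("agreed_novelty", n_in, nrow(set),
            paste0(window_string(config$windows$agreed),
                   ",novelty>", config$novelty_threshold))

  # stage 7: duplicate and catalog removal
  n_in <- nrow(set)
  set <- deduplicate(set)
  if (!is.null(config$catalog) && nrow(config$catalog) > 0L) {
    set <- remove_known(set, config$catalog)
    rejects$catalog <- attr(set, "removed")
  }
  log_stage("dedup_catalog", n_in, nrow(set), "")

  # stage 8: composition-constrained final draw
  n_in <- nrow(set)
  final_size <- min(config$final_size, nrow(set))
  reserve_size <- min(config$reserve_size, nrow(set) - final_size)
  if (final_size < config$final_size) {
    warning("pool after filters (", nrow(set), ") smaller than final_size (",
            config$final_size, ")")
  }
  res <- compose_final(set, config$charge_targets, config$simple_fraction,
                       size = final_size, reserve = reserve_size,
                       seed = stage_seed(config$seed, 300L))
  log_stage("compose_final", n_in, nrow(res$final),
            paste0("final=", final_size, ",reserve=", reserve_size, ",split=",
                   config$simple_fraction))

  ledger <- do.call(rbind, ledger)
  structure(list(ledger = ledger, final = res$final, reserve = res$reserve,
                 achieved = res$achieved, rejects = rejects, quota_plan = plan,
                 seed = config$seed),
            class = "funnel_result")
}

window_string <- function(w) {
  paste(vapply(names(w), function(nm) {
    sprintf("%s=[%g,%g]", nm, w[[nm]][1], w[[nm]][2])
  }, ""), collapse = ",")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("<funnel_result>\n")
  print(x$ledger[, c("stage", "n_in", "n_out")], row.names = FALSE)
  cat(sprintf("final: %d compounds, reserve: %d\n", nrow(x$final), nrow(x$reserve)))
  cat("achieved composition:\n")
  print(round(x$achieved, 3), row.names = FALSE)
  invisible(x)
}

#' Post-hoc audit of a funnel result
#'
#' Re-checks every remove-mode constraint on the final library: no member
#' matches an alert, violates the agreed window, or exceeds the novelty
#' threshold against the exclusion set.
#'
#' @param result A `funnel_result`.
#' @param config The `funnel_config` that produced it.
#' @return `TRUE` invisibly; stops with a message on any violation.
#' @export
audit_funnel <- function(result, config) {
  final <- result$final
  if (!is.null(config$alerts) && config$alert_mode == "remove") {
    hits <- vapply(match_alerts(final, config$alerts), length, 0L)
    assert_that(all(hits == 0L), "audit: final library contains alert matches")
  }
  survivors <- apply_property_filter(final, config$windows$agreed)
  assert_that(nrow(survivors) == nrow(final),
              "audit: final library violates the agreed window")
  if (!is.null(config$exclusion) && nrow(config$exclusion) > 0L) {
    ms <- max_similarity(fingerprint(final), fingerprint(config$exclusion))
    assert_that(all(ms$sim <= config$novelty_threshold),
                "audit: final library exceeds the novelty threshold")
  }
  invisible(TRUE)
}
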