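# scaled-down funnel configuration: paper-shaped stages over the synthetic
# fixture pool (window bounds widened from the production defaults so the
# small pool keeps enough survivors to exercise every stage)
fx_funnel_cfg <- function(exclusion = NULL, seed = 99L) {
  w <- default_windows()
  w$crude$mwt <- c(250, 450); w$crude$slogp <- c(-1, 5)
  w$agreed$mwt <- c(250, 420); w$agreed$slogp <- c(0, 4)
  funnel_config(windows = w, exclusion = exclusion, crude_cap = 90L,
                diversity_total = 150L, final_size = 30L, reserve_size = 10L,
                seed = seed)
}

test_that("funnel ledger is chain-consistent and monotone", {
  sp <- fx_generated()
  excl <- generate_exclusion(sp$pools[[1]], overlap_fraction = 0.1, seed = 3L)
  res <- run_funnel(fx_funnel_cfg(exclusion = excl), sp$pools)
  led <- res$ledger
  expect_true(all(led$n_out <= led$n_in))
  expect_equal(led$n_in[-1], led$n_out[-nrow(led)])
  expect_equal(led$n_in[1], sum(vapply(sp$pools, nrow, 0L)))
  expect_equal(nrow(res$final), 30L)
  expect_equal(nrow(res$reserve), 10L)
  # no overlap between final and reserve
  expect_length(intersect(res$final$id, res$reserve$id), 0L)
  # post-hoc audit re-checks every remove-mode constraint
  expect_true(audit_funnel(res, fx_funnel_cfg(exclusion = excl)))
})

test_that("two identically-seeded funnel runs are byte-identical", {
  sp <- fx_generated()
  r1 <- run_funnel(fx_funnel_cfg(), sp$pools)
  r2 <- run_funnel(fx_funnel_cfg(), sp$pools)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_compound_table(r1$final, f1)
  write_compound_table(r2$final, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(r1$ledger, r2$ledger)
  # a different master seed moves the selection
  r3 <- run_funnel(fx_funnel_cfg(seed = 100L), sp$pools)
  expect_false(identical(r1$final$id, r3$final$id))
})

test_that("stage pass counts match independent predicates on the fixture", {
  pool <- fx_pool()
  truth <- fx_truth()
  # alert stage removes exactly the planted alert carriers
  removed <- filter_alerts(pool, default_alerts(), mode = "remove")
  expect_setequal(removed$id, pool$id[!truth$alert])
  # agreed-window stage report equals a hand predicate (known pass count)
  w <- fx_funnel_cfg()$windows$agreed
  expected_pass <- with(as.data.frame(pool),
                        mwt >= w$mwt[1] & mwt <= w$mwt[2] &
                          slogp >= w$slogp[1] & slogp <= w$slogp[2] &
                          hba <= w$hba[2] & hbd <= w$hbd[2] &
                          sfi >= w$sfi[1] & sfi <= w$sfi[2] &
                          rotb >= w$rotb[1] & rotb <= w$rotb[2])
  filtered <- apply_property_filter(pool, w)
  expect_equal(nrow(filtered), sum(expected_pass))
})

test_that("compose_final hits the 70:30 split exactly on feasible pools", {
  pool <- fx_pool()
  # feasibility: the fixture plants 30% complex across charges
  res <- compose_final(pool, size = 100L, reserve = 40L, seed = 17L)
  expect_equal(sum(res$final$complexity == "simple"), 70L)
  expect_equal(sum(res$final$complexity == "complex"), 30L)
  expect_equal(nrow(res$reserve), 40L)
  expect_equal(sum(res$reserve$complexity == "simple"), 28L)
  # charge composition tracks the 60/33/7 targets on this pool
  expect_equal(as.numeric(res$achieved[, c("neutral", "base", "acid")]),
               c(0.60, 0.33, 0.07), tolerance = 0.08)
  # reproducible
  res2 <- compose_final(pool, size = 100L, reserve = 40L, seed = 17L)
  expect_identical(res$final$id, res2$final$id)
  expect_identical(res$reserve$id, res2$reserve$id)
})

test_that("compose_final relaxes infeasible charge targets with a warning", {
  pool <- fx_pool()
  no_acids <- pool[pool$charge_class != "acid", ]
  expect_warning(expect_warning(
    res <- compose_final(no_acids, size = 60L, seed = 2L), "not met"))
  expect_equal(nrow(res$final), 60L)
  expect_equal(sum(res$final$charge_class == "acid"), 0L)
  expect_error(compose_final(pool, size = nrow(pool) + 1L, seed = 1L), "exceeds")
})

test_that("triage include-lists restrict sublibraries reproducibly", {
  sp <- fx_generated()
  cfg <- fx_funnel_cfg()
  cfg$include_sublibraries <- c("SUB01", "SUB03")
  cfg$diversity_total <- 100L
  cfg$final_size <- 20L; cfg$reserve_size <- 5L
  res <- run_funnel(cfg, sp$pools)
  expect_setequal(unique(res$final$sublibrary_id), c("SUB01", "SUB03"))
  expect_equal(res$ledger$n_out[res$ledger$stage == "triage"], 200L)
})
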