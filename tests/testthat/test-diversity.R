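test_that("maxmin equals the exhaustive per-step oracle on small pools", {
  pool <- fx_pool()[1:18, ]
  fps <- fp_set(fx_fps()$bits[1:18], 1024L)
  dist_m <- 1 - tanimoto_matrix_oracle(fps)
  for (seed in c(1L, 7L, 23L)) {
    got <- maxmin_select(pool, 9L, seed = seed, fps = fps)
    set.seed(seed)
    first <- sample.int(18L, 1L)
    expect_equal(attr(got, "pick_order"),
                 maxmin_oracle(dist_m, pool$smiles_canonical, 9L, first),
                 info = paste("seed", seed))
  }
})

test_that("maxmin handles duplicates, full pools and bad k", {
  pool <- fx_pool()[1:12, ]
  expect_setequal(maxmin_select(pool, 12L, seed = 1L)$id, pool$id)
  expect_error(maxmin_select(pool, 13L, seed = 1L), "exceeds pool size")

  # pool {A, A', C}: A' identical to A, C dissimilar; starting from A the
  # second pick must be C (brute force over both candidates)
  smi <- c(fx_pool()$smiles_canonical[1], fx_pool()$smiles_canonical[1],
           "c1ccc2ccccc2c1")
  tri <- compound_set(smi, id = c("A", "Adup", "C"))
  two <- maxmin_select(tri, 2L, first = 1L)
  expect_setequal(two$id, c("A", "C"))

  # duplicate-insensitivity with a fixed first pick: adding a copy of an
  # already-selected compound never changes the selected structures
  base_sel <- maxmin_select(pool, 5L, first = 2L)
  dup_row <- transform(as.data.frame(pool)[2, ], id = "dup")
  aug <- chemfunnel:::new_compound_set(rbind(as.data.frame(pool), dup_row))
  aug_sel <- maxmin_select(aug, 5L, first = 2L)
  expect_setequal(aug_sel$smiles_canonical, base_sel$smiles_canonical)
})

test_that("maxmin dominates random subsets in minimum pairwise distance", {
  idx <- 1:40
  pool <- fx_pool()[idx, ]
  fps <- fp_set(fx_fps()$bits[idx], 1024L)
  dist_m <- 1 - chemfunnel:::tanimoto_matrix(fps, fps)
  sel <- attr(maxmin_select(pool, 6L, seed = 3L, fps = fps), "pick_order")
  min_d <- function(ix) min(dist_m[ix, ix][upper.tri(diag(length(ix)))])
  sel_min <- min_d(sel)
  set.seed(99)
  rand_min <- replicate(1000, min_d(sample(40L, 6L)))
  expect_gte(sel_min, max(rand_min))
})

test_that("quota allocation is proportional, conserving and clamped", {
  # symmetry: equal size, equal redundancy -> equal quotas (+-1)
  st <- data.frame(sublibrary_id = c("a", "b"), pool_size = c(50L, 50L),
                   mean_sim = c(0.3, 0.3))
  q <- allocate_quotas(st, 30L)
  expect_equal(sum(q$quota), 30L)
  expect_lte(abs(diff(q$quota)), 1L)

  # fully redundant library gets weight 0
  st2 <- data.frame(sublibrary_id = c("a", "b"), pool_size = c(50L, 50L),
                    mean_sim = c(1, 0.2))
  q2 <- allocate_quotas(st2, 40L)
  expect_equal(q2$quota[q2$sublibrary_id == "a"], 0L)
  expect_equal(q2$quota[q2$sublibrary_id == "b"], 40L)

  # conservation and caps over 100 random configurations
  set.seed(5)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    st <- data.frame(sublibrary_id = paste0("s", 1:k),
                     pool_size = sample(1:200, k, replace = TRUE),
                     mean_sim = runif(k, 0, 0.95))
    tot <- sample(1:sum(st$pool_size), 1)
    q <- allocate_quotas(st, tot)
    expect_equal(sum(q$quota), tot)
    expect_true(all(q$quota >= 0L & q$quota <= q$pool_size))
  }

  # infeasible total clamps with a warning and reports the shortfall
  st3 <- data.frame(sublibrary_id = "a", pool_size = 5L, mean_sim = 0.1)
  expect_warning(q3 <- allocate_quotas(st3, 9L), "shortfall")
  expect_equal(sum(q3$quota), 5L)
  expect_equal(attr(q3, "shortfall"), 4L)

  expect_error(allocate_quotas(
    data.frame(sublibrary_id = "a", pool_size = 0L, mean_sim = 0), 3L), "empty")
})

test_that("diversity_select composes per-library maxmin runs", {
  sp <- fx_generated()
  pools <- lapply(sp$pools, function(p) p[1:25, ])
  plan <- allocate_quotas(pools, 12L)
  sel <- diversity_select(pools, plan, seed = 8L)
  expect_equal(nrow(sel), 12L)
  expect_equal(unname(table(sel$sublibrary_id)[plan$sublibrary_id]),
               plan$quota, ignore_attr = TRUE)
  # deterministic
  expect_identical(sel$id, diversity_select(pools, plan, seed = 8L)$id)
  # compositionality: each library's slice equals an independent maxmin run
  for (i in seq_len(nrow(plan))) {
    lib <- plan$sublibrary_id[i]
    solo <- maxmin_select(pools[[lib]], plan$quota[i],
                          seed = chemfunnel:::stage_seed(8L, i))
    expect_setequal(sel$id[sel$sublibrary_id == lib], solo$id)
  }
})
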