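tanimoto_matrix <- chemfunnel:::tanimoto_matrix

test_that("fingerprints are deterministic, order-invariant and discriminating", {
  f <- fingerprint(c("CCO", "OCC", "c1ccccc1", "c1ccncc1"))
  expect_equal(f$radius, 2L)
  expect_equal(f$n_bits, 1024L)
  expect_identical(f$bits[[1]], f$bits[[2]])        # same molecule
  expect_false(identical(f$bits[[3]], f$bits[[4]])) # benzene vs pyridine
  expect_true(all(vapply(f$bits, length, 0L) >= 1L))
})

test_that("tanimoto matches hand and oracle values, is symmetric and bounded", {
  a <- fp_set(list(c(1L, 2L, 3L)), 16L)
  b <- fp_set(list(c(2L, 3L, 4L)), 16L)
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(a, b), 0.5)  # |I|=2, |U|=4 by hand
  expect_equal(tanimoto(fp_set(list(1:3), 16L), fp_set(list(4:6), 16L)), 0)
  expect_error(tanimoto(a, fp_set(list(1:3), 32L)), "lengths differ")

  fps <- random_fp_set(12, seed = 9)
  m <- tanimoto(fps, fps)
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(diag(m), rep(1, 12))
  expect_equal(m, tanimoto_matrix_oracle(fps), tolerance = 1e-12)
})

test_that("pairwise statistics equal the brute-force oracle and count n(n-1)", {
  # 3 identical compounds
  same <- fingerprint(rep("c1ccccc1", 3))
  ps <- pairwise_stats(same)
  expect_equal(ps$mean, 1.0)
  expect_equal(ps$n_pairs, 6L)
  expect_equal(sum(ps$histogram$count), 6L)

  # 2 compounds: mean equals their similarity
  two <- fingerprint(c("c1ccccc1", "c1ccncc1"))
  expect_equal(pairwise_stats(two)$mean, tanimoto_matrix(two, two)[1, 2])

  # 10 fixture compounds against the double-loop oracle
  fp10 <- fp_set(fx_fps()$bits[1:10], 1024L)
  om <- tanimoto_matrix_oracle(fp10)
  expect_equal(pairwise_stats(fp10)$mean,
               sum(om[row(om) != col(om)]) / (10 * 9), tolerance = 1e-12)

  # blocked computation is exact, not approximate
  fp30 <- fp_set(fx_fps()$bits[1:30], 1024L)
  expect_equal(pairwise_stats(fp30, block = 7L)$mean, pairwise_stats(fp30)$mean,
               tolerance = 1e-12)
  expect_equal(sum(pairwise_stats(fp30)$histogram$count), 30L * 29L)

  expect_error(pairwise_stats(fingerprint("CCO")), "at least 2")
})

test_that("novelty filter removes strictly above the threshold only", {
  pool <- fx_pool()[1:20, ]
  # identical member: similarity 1.0 -> removed
  excl <- compound_set(pool$smiles_canonical[3], id = "X1")
  kept <- novelty_filter(pool, excl)
  expect_false(pool$id[3] %in% kept$id)
  rem <- attr(kept, "removed")
  expect_true(pool$id[3] %in% rem$id)
  expect_equal(rem$similarity[rem$id == pool$id[3]], 1.0)
  expect_equal(rem$nearest_excluded_id[rem$id == pool$id[3]], "X1")

  # exactly 0.5 is retained (strict inequality), hand-built bits
  set2 <- compound_set(c("CCO", "CCC"))
  fps <- fp_set(list(c(1L, 2L, 3L), c(10L, 11L)), 1024L)
  fpe <- fp_set(list(c(2L, 3L, 4L)), 1024L)
  out <- novelty_filter(set2, compound_set("CCCC"), threshold = 0.5,
                        fps = fps, fps_exclusion = fpe)
  expect_equal(nrow(out), 2L)  # 0.5 not > 0.5
  out049 <- novelty_filter(set2, compound_set("CCCC"), threshold = 0.49,
                           fps = fps, fps_exclusion = fpe)
  expect_equal(nrow(out049), 1L)

  # empty exclusion: warning, unchanged
  expect_warning(all_kept <- novelty_filter(pool, compound_set(character())),
                 "empty exclusion")
  expect_equal(nrow(all_kept), nrow(pool))

  # S vs S: every member matches itself at 1.0
  expect_equal(nrow(novelty_filter(pool, pool)), 0L)
})

test_that("catalog removal joins on the stereo-free canonical key", {
  pool <- fx_pool()[1:10, ]
  catalog <- compound_set(pool$smiles_canonical[c(2, 5)], id = c("c1", "c2"))
  out <- remove_known(pool, catalog)
  expect_equal(nrow(out), 8L)
  expect_setequal(attr(out, "removed")$id, pool$id[c(2, 5)])
})
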