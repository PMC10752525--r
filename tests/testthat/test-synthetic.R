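test_that("generated building blocks are valid, distinct and role-true", {
  b <- fx_blocks()
  expect_equal(nrow(b$amine), 12L)
  expect_equal(nrow(b$acid), 12L)
  expect_false(anyDuplicated(b$acid$smiles) > 0)
  # role self-consistency against the classifier's own patterns
  expect_true(all(classify_charge(b$acid$smiles) == "acid"))
  expect_true(all(classify_charge(b$amine$smiles) == "base"))
  # reproducible for a fixed seed
  b2 <- generate_blocks(12L, roles = c("amine", "acid"), seed = 42L)
  expect_identical(b$amine$smiles, b2$amine$smiles)
  expect_identical(b$acid$smiles, b2$acid$smiles)
  # other roles generate parseable structures
  more <- generate_blocks(5L, roles = c("sulfonyl_chloride", "aldehyde",
                                        "aryl_bromide"), seed = 3L)
  for (r in names(more)) expect_equal(nrow(more[[r]]), 5L, info = r)
})

test_that("generated pools realize their planted labels exactly", {
  sp <- fx_generated()
  pool <- fx_pool()
  truth <- fx_truth()
  spec <- fixture_spec(n_sublibraries = 3L, size = 100L, seed = 7L)

  # everything parses and canonicalizes (constructor would have rejected)
  expect_equal(nrow(pool), 300L)
  expect_false(any(is.na(pool$smiles_canonical)))

  # charge classes: planted intent recovered by the classifier, and the
  # realized fractions match the spec by construction
  expect_identical(pool$charge_class, truth$charge)
  expect_equal(mean(truth$charge == "acid"), spec$frac_acid, tolerance = 0.02)
  expect_equal(mean(truth$charge == "base"), spec$frac_base, tolerance = 0.02)

  # alerts: the default alert sets flag exactly the planted carriers
  flagged <- vapply(match_alerts(pool, default_alerts()), length, 0L) > 0
  expect_identical(unname(flagged), truth$alert)
  expect_equal(mean(truth$alert), spec$frac_alert, tolerance = 0.03)

  # complexity labels carried onto the compound sets
  expect_identical(pool$complexity, truth$complexity)
  expect_equal(mean(truth$complexity == "complex"), spec$frac_complex,
               tolerance = 0.02)

  # full determinism
  sp2 <- generate_pool(spec)
  expect_identical(sp2$truth$smiles, truth$smiles)
})

test_that("redundancy drives mean pairwise similarity (ordering oracle)", {
  lo <- generate_pool(fixture_spec(n_sublibraries = 1L, size = 60L,
                                   redundancy = 0, seed = 13L))
  hi <- generate_pool(fixture_spec(n_sublibraries = 1L, size = 60L,
                                   redundancy = 0.9, seed = 13L))
  m_lo <- pairwise_stats(lo$pools[[1]])$mean
  m_hi <- pairwise_stats(hi$pools[[1]])$mean
  expect_gt(m_hi, m_lo)
})

test_that("exclusion sets plant recoverable near-duplicates", {
  sp <- fx_generated()
  pool <- sp$pools[[1]]

  # zero overlap: novelty filter removes (almost) nothing
  none <- generate_exclusion(pool, overlap_fraction = 0, seed = 5L)
  kept <- novelty_filter(pool, none)
  expect_gte(nrow(kept), nrow(pool) - 2L)

  # planted overlap: at least the parents of planted near-duplicates fall
  ex <- generate_exclusion(pool, overlap_fraction = 0.2, seed = 5L)
  parents <- attr(ex, "planted_parents")
  expect_gte(length(parents), round(0.2 * nrow(pool)) - 2L)
  kept2 <- novelty_filter(pool, ex)
  removed_ids <- attr(kept2, "removed")$id
  expect_true(all(parents %in% removed_ids))
  expect_gte(length(removed_ids), length(parents))

  # planted pairs were verified > 0.5 similar at generation time
  near <- ex[seq_along(parents), ]
  sims <- vapply(seq_along(parents), function(i) {
    chemfunnel:::max_similarity(
      fingerprint(near[i, , drop = FALSE]),
      fingerprint(pool[pool$id == parents[i], , drop = FALSE]))$sim
  }, 0)
  expect_true(all(sims > 0.5))

  # determinism
  ex2 <- generate_exclusion(pool, overlap_fraction = 0.2, seed = 5L)
  expect_identical(ex$smiles_canonical, ex2$smiles_canonical)
})

test_that("fixture_spec validates its stated world", {
  expect_error(fixture_spec(frac_acid = 0.6, frac_base = 0.6), "<= 1")
  expect_error(fixture_spec(frac_alert = 1.2), "\\[0, 1\\]")
  expect_error(fixture_spec(n_sublibraries = 0), ">= 1")
})
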