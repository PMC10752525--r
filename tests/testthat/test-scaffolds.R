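test_that("Murcko scaffolds keep rings and linkers, drop side chains", {
  benzene <- canonicalize("c1ccccc1")
  expect_equal(murcko_scaffold("c1ccccc1"), benzene)
  expect_equal(murcko_scaffold("Cc1ccccc1"), benzene)  # methyl removed
  # diphenylmethane: the CH2 linker is retained
  dpm <- canonicalize("C(c1ccccc1)c1ccccc1")
  expect_equal(murcko_scaffold("C(c1ccccc1)c1ccccc1"), dpm)
  expect_equal(murcko_scaffold("CCC(c1ccccc1)c1ccccc1"), dpm)
  # acyclic molecules have no scaffold
  expect_true(is.na(murcko_scaffold("CCO")))
  # idempotence
  s <- murcko_scaffold(fx_pool()$smiles_canonical[1:10])
  expect_equal(murcko_scaffold(s), s)
})

test_that("generic frameworks abstract atoms and bonds", {
  ch <- canonicalize("C1CCCCC1")
  expect_equal(murcko_framework("c1ccncc1"), ch)
  expect_equal(murcko_framework("c1ccccc1"), murcko_framework("c1ccncc1"))
  # frameworks are idempotent under re-decomposition
  f <- murcko_framework(fx_pool()$smiles_canonical[1:10])
  expect_equal(murcko_framework(f), f)
  # every framework is an abstraction of the scaffold: never more distinct
  # frameworks than scaffolds
  pool <- fx_pool()
  expect_lte(length(unique(na.omit(murcko_framework(pool)))),
             length(unique(na.omit(murcko_scaffold(pool)))))
})

test_that("scaffold_report computes distinct counts and uniqueness", {
  r <- scaffold_report(compound_set(c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1")))
  expect_equal(r$n_distinct, 1L)
  expect_equal(r$unique_fraction, 100 / 3, tolerance = 1e-9)

  unrelated <- compound_set(c("c1ccccc1", "C1CCNCC1", "c1ccc2ccccc2c1",
                              "C1CC1", "c1ccoc1"))
  expect_equal(scaffold_report(unrelated)$unique_fraction, 100)

  # acyclic handling moves the denominator
  mix <- compound_set(c("c1ccccc1", "CCO", "CCCC"))
  excl <- scaffold_report(mix)
  expect_equal(excl$n_compounds, 1L)
  expect_equal(excl$n_acyclic, 2L)
  incl <- scaffold_report(mix, include_acyclic = TRUE)
  expect_equal(incl$n_compounds, 3L)
  expect_equal(incl$n_distinct, 2L)  # benzene + the shared acyclic bucket

  # consistency between the count map and the totals, framework mode
  pool <- fx_pool()
  fr <- scaffold_report(pool, mode = "framework")
  expect_equal(sum(fr$counts), fr$n_compounds)
  expect_equal(length(fr$counts), fr$n_distinct)
  expect_equal(fr$singleton_fraction,
               100 * sum(fr$counts == 1L) / fr$n_distinct)

  expect_error(scaffold_report(compound_set(character())), "non-empty")
})

test_that("added_value counts novel scaffolds against a base set", {
  base <- compound_set(c("c1ccccc1", "Cc1ccccc1", "c1ccncc1"))
  same <- compound_set(c("CCc1ccccc1", "CCCc1ccncc1"))   # nothing new
  novel <- compound_set(c("c1ccc2ccccc2c1", "C1CCNCC1"))  # two new ring systems
  av <- added_value(base, novel, same)
  expect_equal(av$new_b, 0L)
  expect_equal(av$new_a, 2L)

  # set-difference oracle on fixture slices
  pool <- fx_pool()
  b <- pool[1:40, ]; a1 <- pool[41:70, ]; a2 <- pool[71:100, ]
  av2 <- added_value(b, a1, a2, mode = "framework")
  oracle <- function(addn) {
    length(setdiff(unique(na.omit(murcko_framework(addn))),
                   unique(na.omit(murcko_framework(b)))))
  }
  expect_equal(av2$new_a, oracle(a1))
  expect_equal(av2$new_b, oracle(a2))
  if (av2$new_b > 0) {
    expect_equal(av2$pct_more, 100 * (av2$new_a - av2$new_b) / av2$new_b)
  }
})

test_that("complex additions bring more new frameworks than simple ones", {
  # the design rationale for the 70:30 simple/complex split, checked on
  # synthetic pools with known complexity labels
  sp <- generate_pool(fixture_spec(n_sublibraries = 1L, size = 220L,
                                   frac_complex = 0.5, seed = 31L))
  pool <- sp$pools[[1]]
  simple <- which(pool$complexity == "simple")
  complx <- which(pool$complexity == "complex")
  base <- pool[simple[1:60], ]
  add_complex <- pool[complx[1:40], ]
  add_simple <- pool[simple[61:100], ]
  av <- added_value(base, add_complex, add_simple, mode = "framework")
  expect_gt(av$new_a, av$new_b)
})
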