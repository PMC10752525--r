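test_that("parse_structure perceives aromaticity and strips salts", {
  m <- parse_structure("c1ccccc1")
  expect_s3_class(m, "chem_mol")
  expect_equal(m$n_aromatic, 6L)
  expect_equal(m$n_heavy, 6L)

  # largest-fragment rule: HCl stripped, checked by atom count against the
  # bare ethanol parse
  salt <- parse_structure("CCO.Cl")
  expect_equal(salt$smiles_canonical, parse_structure("CCO")$smiles_canonical)
  expect_equal(salt$n_heavy, 3L)

  err <- tryCatch(parse_structure("C1CC"), error = identity)
  expect_s3_class(err, "chemfunnel_parse_error")
  expect_match(conditionMessage(err), "C1CC")
  expect_error(parse_structure(""), "non-empty")
})

test_that("canonicalization is order-invariant and idempotent", {
  expect_identical(canonicalize("OCC"), canonicalize("CCO"))
  smi <- "CC(=O)Nc1ccc(OCC(C)C)cc1"  # 20-ish heavy atoms
  can <- canonicalize(smi)
  expect_identical(canonicalize(can), can)
  # permutation oracle: random atom-order renderings all collapse to one
  # canonical string
  perms <- unlist(chemfunnel:::rdkit_call(
    "random_smiles", list(smiles = list(smi), n = 100, seed = 5)))
  expect_gt(length(unique(perms)), 10L)  # renderings genuinely differ
  expect_length(unique(canonicalize(perms)), 1L)
  expect_identical(unique(canonicalize(perms)), can)
})

test_that("compound_set quarantines bad rows and read/write round-trips (csv)", {
  cs <- compound_set(c("CCO", "C1CC", "c1ccccc1"))
  expect_equal(nrow(cs), 2L)
  rej <- attr(cs, "rejects")
  expect_equal(nrow(rej), 1L)
  expect_equal(rej$input, "C1CC")

  tmp <- tempfile(fileext = ".csv")
  writeLines(c("ID,SMILES,batch", "a,CCO,b1", "b,not_a_smiles,b2", "c,c1ccccc1,b3"), tmp)
  rd <- read_compound_table(tmp, "csv")
  expect_equal(nrow(rd), 2L)
  expect_equal(nrow(attr(rd, "rejects")), 1L)
  expect_equal(rd$batch, c("b1", "b3"))  # metadata carried for surviving rows

  out <- tempfile(fileext = ".csv")
  write_compound_table(rd, out, "csv")
  back <- read_compound_table(out, "csv")
  expect_setequal(back$smiles_canonical, rd$smiles_canonical)

  # structure column auto-detection and failure
  tmp2 <- tempfile(fileext = ".csv")
  writeLines(c("ID,Canonical_Smiles", "x,CCO"), tmp2)
  expect_equal(nrow(read_compound_table(tmp2, "csv")), 1L)
  tmp3 <- tempfile(fileext = ".csv")
  writeLines(c("ID,foo", "x,CCO"), tmp3)
  expect_error(read_compound_table(tmp3, "csv"), "structure column")

  tmp4 <- tempfile(fileext = ".csv")
  writeLines("ID,SMILES", tmp4)
  expect_warning(empty <- read_compound_table(tmp4, "csv"), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("sdf write/read round-trips the canonical structure multiset", {
  cs <- compound_set(c("CCO", "c1ccccc1", "CC(=O)Nc1ccccc1"))
  tmp <- tempfile(fileext = ".sdf")
  write_compound_table(cs, tmp, "sdf")
  back <- read_compound_table(tmp, "sdf")
  expect_setequal(back$smiles_canonical, cs$smiles_canonical)
  expect_setequal(back$id, cs$id)
})

test_that("deduplicate keeps first occurrence, is idempotent and stereo-blind", {
  cs <- compound_set(c("CCO", "OCC", "c1ccccc1"))
  dd <- deduplicate(cs)
  expect_equal(nrow(dd), 2L)
  expect_equal(attr(dd, "duplicates_removed"), 1L)
  expect_equal(dd$id[1], cs$id[1])  # first occurrence wins

  expect_equal(nrow(deduplicate(dd)), nrow(dd))  # idempotent

  n <- 6L
  copies <- compound_set(rep("c1ccncc1", n))
  one <- deduplicate(copies)
  expect_equal(nrow(one), 1L)
  expect_equal(attr(one, "duplicates_removed"), n - 1L)

  # enantiomer pair shares the stereo-free key
  st <- deduplicate(compound_set(c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O")))
  expect_equal(nrow(st), 1L)

  # duplicate-free set unchanged
  clean <- fx_pool()[1:10, ]
  expect_equal(nrow(deduplicate(fx_pool()[1:10, ])), 10L)
})
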