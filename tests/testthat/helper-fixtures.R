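# Shared fixtures, generated once per test run and cached (every bridge call
# costs a python start-up, so fixtures are memoised and batched).

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# 3 sublibraries x 100 compounds, default label fractions, with properties.
fx_generated <- function() memo("generated", {
  generate_pool(fixture_spec(n_sublibraries = 3L, size = 100L, seed = 7L))
})

fx_pool <- function() memo("pool", {
  sp <- fx_generated()
  df <- do.call(rbind, lapply(sp$pools, as.data.frame))
  rownames(df) <- NULL
  compute_properties(chemfunnel:::new_compound_set(df, provenance = "fixture"))
})

fx_truth <- function() fx_generated()$truth

fx_fps <- function() memo("fps", fingerprint(fx_pool()))

fx_blocks <- function() memo("blocks", {
  generate_blocks(12L, roles = c("amine", "acid"), seed = 42L)
})

fx_amide_lib <- function() memo("amide_lib", {
  b <- fx_blocks()
  sublibrary_def(default_reactions()$amide, b$amine, b$acid, "amide_fx")
})

fx_basis <- function() memo("basis", compute_properties(build_basis_set(fx_amide_lib())))

# independent per-step MaxMin oracle: exhaustive argmax over the full
# distance matrix with the same documented tie rule (canonical string order)
maxmin_oracle <- function(dist_m, key, k, first) {
  picked <- first
  while (length(picked) < k) {
    mind <- apply(dist_m[, picked, drop = FALSE], 1L, min)
    mind[picked] <- -Inf
    cand <- which(mind >= max(mind) - 1e-12)
    picked <- c(picked, cand[order(key[cand])][1L])
  }
  picked
}

# independent Tanimoto oracle on explicit bit vectors
tanimoto_oracle <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# independent full similarity matrix from an fp_set, double loop
tanimoto_matrix_oracle <- function(fp) {
  n <- length(fp$bits)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) m[i, j] <- tanimoto_oracle(fp$bits[[i]], fp$bits[[j]])
  }
  m
}

# random fp_set for property-style tests
random_fp_set <- function(n, n_bits = 64L, seed = 1L) {
  set.seed(seed)
  fp_set(lapply(seq_len(n), function(i) {
    sort(sample.int(n_bits, sample(3:12, 1L)))
  }), n_bits = n_bits)
}

# where the deposited supplementary structure tables would live if supplied
ghcdl_path <- function(which = c("v1", "v2")) {
  which <- match.arg(which)
  system.file("extdata", "ghcdl", paste0("ghcdl_", which, ".csv"),
              package = "chemfunnel")
}
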