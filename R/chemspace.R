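# Chemical-space comparison of libraries: 2D descriptor matrix, PCA -> t-SNE
# embedding, and KMeans cluster composition.

#' 2D molecular descriptor matrix
#'
#' Computes a fixed panel of 200 two-dimensional molecular descriptors (the
#' first 200 of the RDKit canonical descriptor list; names are recorded so
#' runs are comparable). Constant and all-missing columns are dropped with a
#' warning, and remaining missing values are imputed with the column median.
#'
#' @param set A `compound_set` or character vector of SMILES.
#' @param n_descriptors Size of the descriptor panel (default 200).
#' @return A numeric matrix, one row per compound (row names = ids),
#'   descriptor names as column names; dropped column names in
#'   `attr(, "dropped")`.
#' @export
descriptor_matrix <- function(set, n_descriptors = 200L) {
  smiles <- smiles_of(set)
  assert_that(length(smiles) >= 1L, "descriptor_matrix needs a non-empty set")
  res <- rdkit_call("descriptors",
                    list(smiles = as.list(smiles), n_descriptors = n_descriptors))
  names_d <- unlist(res$names)
  rows <- lapply(res$rows, function(r) {
    if (is.null(r)) rep(NA_real_, length(names_d))
    else vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- names_d
  rownames(m) <- if (inherits(set, "compound_set")) set$id else NULL
  bad <- apply(m, 2L, function(col) {
    all(is.na(col)) || isTRUE(max(col, na.rm = TRUE) == min(col, na.rm = TRUE))
  })
  if (any(bad)) {
    warning("dropping ", sum(bad), " constant/all-missing descriptor columns")
  }
  dropped <- colnames(m)[bad]
  m <- m[, !bad, drop = FALSE]
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
  }
  attr(m, "dropped") <- dropped
  m
}

#' PCA -> t-SNE chemical-space embedding
#'
#' Standardizes the descriptor columns (zero mean, unit variance — otherwise
#' molecular weight dominates), reduces to `pca_dims` principal components,
#' then embeds with t-SNE (defaults: 30 components, perplexity 50, 15000
#' iterations). Reproducible for a fixed seed.
#'
#' @param m Descriptor matrix from [descriptor_matrix()].
#' @param pca_dims Number of principal components retained.
#' @param perplexity,iterations t-SNE parameters. Requires
#'   `nrow(m) >= 3 * perplexity`; reduce `perplexity` for small sets.
#' @param seed Integer seed.
#' @param library_label Optional per-row library labels (for composition
#'   analysis and plotting).
#' @return A `chem_embedding`: list with `coords` (n x 2), `pca_scores`
#'   (n x pca_dims), `library_label`, `params`.
#' @export
embed_chemspace <- function(m, pca_dims = 30L, perplexity = 50, iterations = 15000L,
                            seed = 1L, library_label = NULL) {
  assert_that(is.matrix(m) && nrow(m) >= 4L, "m must be a matrix with >= 4 rows")
  if (nrow(m) < 3 * perplexity) {
    stop("t-SNE needs nrow >= 3 * perplexity; reduce perplexity below ",
         floor(nrow(m) / 3), call. = FALSE)
  }
  keep <- apply(m, 2L, function(col) stats::sd(col) > 0)
  ms <- scale(m[, keep, drop = FALSE])
  pca_dims <- min(pca_dims, ncol(ms), nrow(ms) - 1L)
  pca <- stats::prcomp(ms, center = FALSE, scale. = FALSE, rank. = pca_dims)
  scores <- pca$x
  res <- rdkit_call("tsne", list(data = unname(apply(scores, 1L, as.numeric, simplify = FALSE)),
                                 perplexity = perplexity, iterations = iterations,
                                 seed = seed))
  coords <- do.call(rbind, lapply(res$coords, unlist))
  rownames(coords) <- rownames(m)
  structure(list(coords = coords, pca_scores = scores,
                 library_label = library_label %||% rep("all", nrow(m)),
                 params = list(pca_dims = pca_dims, perplexity = perplexity,
                               iterations = iterations, seed = seed)),
            class = "chem_embedding")
}

#' @export
print.chem_embedding <- function(x, ...) {
  p <- x$params
  cat(sprintf("<chem_embedding> %d compounds, pca_dims=%d, perplexity=%g, iterations=%d, seed=%d\n",
              nrow(x$coords), p$pca_dims, p$perplexity, p$iterations, p$seed))
  invisible(x)
}

#' KMeans cluster composition of an embedding
#'
#' Clusters in the retained PCA space (not the 2-D t-SNE coordinates, which
#' distort distances) and cross-tabulates cluster membership against the
#' library label — which library contributes what to each region of
#' chemical space.
#'
#' @param e A `chem_embedding`.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return List with `table` (data.frame `cluster, library, count`; counts
#'   sum to the number of compounds) and `cluster` (per-row assignment).
#' @export
cluster_composition <- function(e, k = 8L, seed = 1L) {
  assert_that(inherits(e, "chem_embedding"), "e must be a chem_embedding")
  n <- nrow(e$pca_scores)
  if (k > n) stop("k (", k, ") exceeds number of compounds (", n, ")", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(e$pca_scores, centers = k, nstart = 10L, iter.max = 100L)
  tab <- as.data.frame(table(cluster = km$cluster, library = e$library_label),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab$cluster <- as.integer(tab$cluster)
  list(table = tab, cluster = km$cluster)
}
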