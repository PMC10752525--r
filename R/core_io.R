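#' Parse a SMILES string into a molecule handle
#'
#' Parses one SMILES string, perceives aromaticity, strips salts and solvents
#' down to the largest organic fragment (most heavy atoms, ties broken by
#' molecular weight), and returns a lightweight molecule handle carrying the
#' canonical SMILES and a stereochemistry-free canonical key used for
#' deduplication and novelty joins.
#'
#' @param text A single non-empty SMILES string.
#' @return An object of class `chem_mol`: a list with elements
#'   `smiles_canonical`, `smiles_key` (canonical SMILES with stereochemistry
#'   removed), `n_heavy` and `n_aromatic`.
#' @export
#' @examples
#' \dontrun{
#' m <- parse_structure("c1ccccc1")
#' m$n_aromatic  # 6
#' }
parse_structure <- function(text) {
  assert_that(is.character(text) && length(text) == 1L && nzchar(text),
              "text must be a single non-empty SMILES string")
  res <- rdkit_call("canonicalize", list(smiles = list(text)))[[1]]
  if (!isTRUE(res$ok)) {
    cond <- structure(
      class = c("chemfunnel_parse_error", "error", "condition"),
      list(message = sprintf("cannot parse structure '%s': %s", text, res$error),
           call = sys.call(-1), input = text)
    )
    stop(cond)
  }
  structure(list(smiles_canonical = res$canonical, smiles_key = res$key,
                 n_heavy = res$n_heavy, n_aromatic = res$n_aromatic),
            class = "chem_mol")
}

#' Canonical SMILES of a molecule or character vector
#'
#' Canonicalization is invariant under input atom reordering and idempotent.
#' Character input is vectorised; invalid entries yield `NA` with a warning.
#'
#' @param x A `chem_mol` from [parse_structure()] or a character vector of
#'   SMILES.
#' @return Character vector of canonical SMILES.
#' @export
canonicalize <- function(x) {
  if (inherits(x, "chem_mol")) return(x$smiles_canonical)
  assert_that(is.character(x), "x must be a chem_mol or a character vector")
  if (length(x) == 0L) return(character())
  res <- rdkit_call("canonicalize", list(smiles = as.list(x)))
  out <- vapply(res, function(r) if (isTRUE(r$ok)) r$canonical else NA_character_, "")
  if (anyNA(out)) warning(sum(is.na(out)), " SMILES failed to parse")
  out
}

new_compound_set <- function(df, provenance = character(), rejects = NULL) {
  rejects <- rejects %||% data.frame(row = integer(), input = character(),
                                     reason = character())
  structure(df, class = c("compound_set", "data.frame"),
            provenance = provenance, rejects = rejects)
}

#' Construct a compound set from SMILES
#'
#' The tabular container the whole pipeline passes around: a `data.frame`
#' subclass with one row per compound and columns `id`, `smiles_input`,
#' `smiles_canonical`, `smiles_key` (stereo-free canonical key),
#' `sublibrary_id`, `complexity` and `flags`. Unparseable inputs are
#' quarantined in the `rejects` attribute (columns `row,input,reason`) rather
#' than aborting — vendor files routinely contain a few bad rows.
#'
#' @param smiles Character vector of SMILES.
#' @param id Optional identifiers (default `CMPD000001`, ...).
#' @param sublibrary_id,complexity Optional per-compound labels; `complexity`
#'   is `"simple"` or `"complex"`.
#' @param provenance Character vector of stage labels.
#' @return A `compound_set`. Attributes: `provenance`, `rejects`.
#' @export
compound_set <- function(smiles, id = NULL, sublibrary_id = NA_character_,
                         complexity = NA_character_, provenance = "constructed") {
  assert_that(is.character(smiles), "smiles must be a character vector")
  n <- length(smiles)
  id <- id %||% sprintf("CMPD%06d", seq_len(n))
  assert_that(length(id) == n, "id must match length of smiles")
  assert_that(!anyDuplicated(id), "ids must be unique within a compound set")
  if (n == 0L) {
    df <- data.frame(id = character(), smiles_input = character(),
                     smiles_canonical = character(), smiles_key = character(),
                     sublibrary_id = character(), complexity = character(),
                     flags = character(), stringsAsFactors = FALSE)
    return(new_compound_set(df, provenance))
  }
  res <- rdkit_call("canonicalize", list(smiles = as.list(smiles)))
  ok <- vapply(res, function(r) isTRUE(r$ok), NA)
  rejects <- data.frame(
    row = which(!ok), input = smiles[!ok],
    reason = vapply(res[!ok], function(r) r$error %||% "parse error", ""),
    stringsAsFactors = FALSE
  )
  df <- data.frame(
    id = as.character(id)[ok],
    smiles_input = smiles[ok],
    smiles_canonical = vapply(res[ok], `[[`, "", "canonical"),
    smiles_key = vapply(res[ok], `[[`, "", "key"),
    sublibrary_id = rep_len(as.character(sublibrary_id), n)[ok],
    complexity = rep_len(as.character(complexity), n)[ok],
    flags = "",
    stringsAsFactors = FALSE
  )
  new_compound_set(df, provenance, rejects)
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set> %d compounds", nrow(x)))
  nl <- unique(x$sublibrary_id)
  if (length(nl) > 1L || !all(is.na(nl))) cat(sprintf(", %d sublibraries", length(nl)))
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej) > 0L) cat(sprintf(", %d rejects", nrow(rej)))
  cat("\n  provenance:", paste(attr(x, "provenance"), collapse = " -> "), "\n")
  if (nrow(x) > 0L) {
    print(utils::head(as.data.frame(x)[, intersect(
      c("id", "smiles_canonical", "sublibrary_id", "complexity", "mwt",
        "slogp", "sfi", "charge_class"), names(x)), drop = FALSE], 6L))
    if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  }
  invisible(x)
}

# Row subsetting that keeps the class and provenance (rejects are dropped:
# they describe the original parse, not the subset).
subset_set <- function(set, idx, stage = NULL) {
  prov <- attr(set, "provenance")
  if (!is.null(stage)) prov <- c(prov, stage)
  df <- as.data.frame(set)[idx, , drop = FALSE]
  rownames(df) <- NULL
  new_compound_set(df, prov)
}

#' Read a compound table (CSV or SDF)
#'
#' CSV files need a header; the structure column defaults to `SMILES` and is
#' auto-detected case-insensitively (any column whose name contains
#' "smiles" or "structure") when absent. Unparseable rows are quarantined in
#' the `rejects` attribute. SDF (V2000) is read through the RDKit bridge.
#'
#' @param path File path.
#' @param format `"csv"` or `"sdf"`.
#' @param smiles_column,id_column CSV column names.
#' @return A `compound_set`; extra CSV metadata columns are carried along.
#' @export
read_compound_table <- function(path, format = c("csv", "sdf"),
                                smiles_column = "SMILES", id_column = "ID") {
  format <- match.arg(format)
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (format == "sdf") {
    res <- rdkit_call("read_sdf", list(path = path))
    ok <- vapply(res, function(r) isTRUE(r$ok), NA)
    smi <- vapply(res[ok], `[[`, "", "smiles")
    ids <- vapply(res[ok], function(r) as.character(r$id %||% ""), "")
    ids[!nzchar(ids)] <- sprintf("SDF%06d", which(ok)[!nzchar(ids)])
    out <- compound_set(smi, id = make.unique(ids), provenance = paste0("read:", basename(path)))
    attr(out, "rejects") <- data.frame(
      row = which(!ok), input = rep("<sdf record>", sum(!ok)),
      reason = vapply(res[!ok], function(r) r$error %||% "parse error", ""))
    return(out)
  }
  tab <- data.table::fread(path, colClasses = "character", data.table = FALSE)
  if (nrow(tab) == 0L) {
    warning("empty compound table: ", path)
    return(compound_set(character(), provenance = paste0("read:", basename(path))))
  }
  scol <- smiles_column
  if (!scol %in% names(tab)) {
    hit <- grep("smiles|structure", names(tab), ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L) {
      stop("no structure column found (looked for '", smiles_column,
           "' or names containing 'smiles'/'structure') in ", path, call. = FALSE)
    }
    scol <- hit[[1]]
  }
  ids <- if (id_column %in% names(tab)) make.unique(tab[[id_column]]) else NULL
  out <- compound_set(tab[[scol]], id = ids, provenance = paste0("read:", basename(path)))
  meta <- setdiff(names(tab), c(scol, id_column))
  if (length(meta) > 0L) {
    keep <- !seq_len(nrow(tab)) %in% attr(out, "rejects")$row
    for (m in meta) out[[m]] <- tab[[m]][keep]
  }
  out
}

#' Write a compound set to CSV or SDF
#'
#' @param set A `compound_set`.
#' @param path Output path.
#' @param format `"csv"` or `"sdf"`.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(set, path, format = c("csv", "sdf")) {
  format <- match.arg(format)
  if (format == "sdf") {
    rdkit_call("write_sdf", list(path = path, smiles = as.list(set$smiles_canonical),
                                 ids = as.list(set$id)))
    return(invisible(path))
  }
  df <- as.data.frame(set)
  out <- data.frame(ID = df$id, SMILES = df$smiles_canonical, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c("id", "smiles_input", "smiles_canonical", "smiles_key"))
  for (nm in extra) out[[nm]] <- df[[nm]]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Remove duplicate structures from a compound set
#'
#' Duplicates are detected on the stereochemistry-free canonical key (the
#' same key the novelty/catalog joins use, matching the stereo-insensitivity
#' of 1024-bit circular fingerprints); the first occurrence is kept.
#'
#' @param set A `compound_set`.
#' @return The deduplicated `compound_set`; the number removed is in
#'   `attr(, "duplicates_removed")`.
#' @export
deduplicate <- function(set) {
  keep <- !duplicated(set$smiles_key)
  out <- subset_set(set, keep, stage = "deduplicate")
  attr(out, "duplicates_removed") <- sum(!keep)
  out
}

#' Write the rejects report of a compound set
#'
#' @param set A `compound_set`.
#' @param path CSV output path (columns `row,input,reason`).
#' @return `path`, invisibly.
#' @export
write_rejects <- function(set, path) {
  data.table::fwrite(attr(set, "rejects") %||%
                       data.frame(row = integer(), input = character(),
                                  reason = character()), path)
  invisible(path)
}
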