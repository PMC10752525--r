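# Physicochemical profiling: the property vector, SFI, charge class, and the
# staged windows (wide -> crude -> agreed) used along the selection funnel.

# Substructure definitions of ionizable groups at pH 7.4. Deliberately
# pattern-based, not pKa-based: deterministic and dependency-free. Acids:
# carboxylic acid, tetrazole (both NH tautomers), acyl sulfonamide. Bases:
# aliphatic amines (amides, anilines, sulfonamides, azoles, N-N and N-O
# excluded), amidines/guanidines.
ACID_SMARTS <- c(
  carboxylic_acid = "[CX3](=O)[OX2H1]",
  tetrazole_1 = "c1nn[nH]n1",
  tetrazole_2 = "c1n[nH]nn1",
  acyl_sulfonamide = "[SX4](=O)(=O)[NX3H][CX3]=O"
)
BASE_SMARTS <- c(
  aliphatic_amine = "[NX3;!a;!$([NX3]C=O);!$([NX3]C=S);!$([NX3]S(=O)=O);!$([NX3]c);!$([NX3][NX3]);!$([NX3][OX2]);!$([NX3]C=N)]",
  amidine_guanidine = "[NX3][CX3]=[NX2]"
)

#' Solubility Forecast Index
#'
#' `SFI = clogD(pH 7.4) + #aromatic rings`; lower values forecast better
#' aqueous solubility. The agreed design window keeps the library in
#' `2 <= SFI <= 6`.
#'
#' @param clogd Numeric clogD at pH 7.4.
#' @param arom_rings Non-negative aromatic ring count.
#' @return `clogd + arom_rings`.
#' @export
#' @examples
#' compute_sfi(2.5, 2)  # 4.5
compute_sfi <- function(clogd, arom_rings) {
  assert_that(all(arom_rings >= 0), "arom_rings must be >= 0")
  clogd + arom_rings
}

#' Classify compounds as acid, base or neutral
#'
#' Pattern-based ionization classes at pH 7.4: a compound is an `acid` if it
#' carries an acidic ionizable group (carboxylic acid, tetrazole, acyl
#' sulfonamide), else a `base` if it carries a basic amine (aliphatic
#' primary/secondary/tertiary amine, amidine, guanidine; amides, anilines,
#' sulfonamides and azoles are excluded), else `neutral`. Acid takes
#' precedence when both match (amino acids classify as acids).
#'
#' @param x A `compound_set`, `chem_mol`, or character vector of SMILES.
#' @return Character vector in `{"acid","base","neutral"}`.
#' @export
classify_charge <- function(x) {
  smiles <- smiles_of(x)
  if (length(smiles) == 0L) return(character())
  hits <- rdkit_call("smarts_match",
                     list(smiles = as.list(smiles),
                          smarts = as.list(unname(c(ACID_SMARTS, BASE_SMARTS)))))
  n_acid <- length(ACID_SMARTS)
  vapply(hits, function(h) {
    if (is.null(h)) return(NA_character_)
    idx <- unlist(h) + 1L
    if (any(idx <= n_acid)) "acid" else if (length(idx) > 0L) "base" else "neutral"
  }, "")
}

smiles_of <- function(x) {
  if (inherits(x, "chem_mol")) return(x$smiles_canonical)
  if (inherits(x, "compound_set") || is.data.frame(x)) return(x$smiles_canonical)
  assert_that(is.character(x), "expected compound_set, chem_mol or SMILES vector")
  x
}

# clogD approximation: slogP minus a fixed 1.0 ionization penalty for
# compounds classified acid or base (monoprotic ionization at pH 7.4 lowers
# logD), 0 for neutrals. Pluggable via the `clogd_fun` argument of
# compute_properties().
default_clogd <- function(slogp, charge_class) {
  slogp - ifelse(charge_class %in% c("acid", "base"), 1.0, 0)
}

#' Compute the physicochemical property vector
#'
#' Populates MWt, slogP, TPSA, HBD, HBA, rotatable bonds (amide C-N
#' excluded), aromatic ring count, sp3 carbon fraction, charge class, clogD
#' (approximated from slogP and the charge class unless `clogd_fun` is
#' supplied) and `SFI = clogD + #aromatic rings`.
#'
#' @param x A `compound_set` (columns are appended) or character vector of
#'   SMILES (a data.frame is returned).
#' @param clogd_fun Function `(slogp, charge_class) -> clogd`; the default
#'   applies a fixed 1.0 ionization penalty to acids and bases.
#' @return Same shape as `x` with property columns
#'   `mwt, slogp, tpsa, hbd, hba, rotb, arom_rings, sp3_fraction,
#'   charge_class, clogd, sfi`.
#' @export
compute_properties <- function(x, clogd_fun = default_clogd) {
  smiles <- smiles_of(x)
  is_set <- inherits(x, "compound_set") || is.data.frame(x)
  if (length(smiles) == 0L) {
    return(if (is_set) x else data.frame())
  }
  res <- rdkit_call("properties", list(smiles = as.list(smiles)))
  num <- function(field) vapply(res, function(r) {
    if (isTRUE(r$ok)) as.numeric(r[[field]]) else NA_real_
  }, 0)
  props <- data.frame(
    mwt = num("mwt"), slogp = num("slogp"), tpsa = num("tpsa"),
    hbd = as.integer(num("hbd")), hba = as.integer(num("hba")),
    rotb = as.integer(num("rotb")), arom_rings = as.integer(num("arom_rings")),
    sp3_fraction = num("sp3_fraction"), stringsAsFactors = FALSE
  )
  props$charge_class <- classify_charge(smiles)
  props$clogd <- clogd_fun(props$slogp, props$charge_class)
  props$sfi <- compute_sfi(props$clogd, props$arom_rings)
  if (is_set) {
    for (nm in names(props)) x[[nm]] <- props[[nm]]
    x
  } else {
    cbind(data.frame(smiles = smiles, stringsAsFactors = FALSE), props)
  }
}

#' Define a property window
#'
#' A named set of closed ranges over property-vector fields. All bounds are
#' inclusive: a compound with MWt exactly 320 or 380 passes the `[320, 380]`
#' window.
#'
#' @param ... Named length-2 numeric vectors, e.g. `mwt = c(320, 380)`.
#' @return A `property_window` (named list of `c(lo, hi)`).
#' @export
#' @examples
#' property_window(mwt = c(320, 380), slogp = c(1, 3))
property_window <- function(...) {
  w <- list(...)
  assert_that(length(w) > 0L && !is.null(names(w)) && all(nzchar(names(w))),
              "window ranges must be named")
  for (nm in names(w)) {
    r <- w[[nm]]
    assert_that(is.numeric(r) && length(r) == 2L && r[1] <= r[2],
                sprintf("range '%s' must be numeric c(lo, hi) with lo <= hi", nm))
  }
  structure(w, class = "property_window")
}

#' The staged default property windows
#'
#' Three stages of lead-like filtering: `wide` (MWt <= 450, slogP <= 5,
#' HBD <= 4, HBA <= 8, RotB <= 8), `crude` (MWt 320-420, slogP 0-4.5,
#' HBD 0-3, HBA 0-8, RotB 1-8) and `agreed` (MWt 320-380, slogP 1-3,
#' HBA 0-8, HBD 0-3, SFI 2-6, RotB 1-7).
#'
#' @param path Optional JSON file with the same structure as the shipped
#'   default (stage -> field -> [lo, hi]).
#' @return Named list of `property_window` objects.
#' @export
default_windows <- function(path = NULL) {
  path <- path %||% system.file("extdata", "windows.json", package = "chemfunnel")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(stage) do.call(property_window, as.list(as.data.frame(stage))))
}

#' Filter a compound set by a property window
#'
#' A record is retained iff every named field lies inside its closed range.
#' Per-field rejection counts (a record can fail several fields) are in
#' `attr(, "rejected_by")`; rejected records with their first failing field
#' are in `attr(, "rejects")`.
#'
#' @param set A `compound_set` with properties computed.
#' @param window A [property_window()].
#' @param stage Label recorded in the provenance.
#' @return The filtered `compound_set`.
#' @export
apply_property_filter <- function(set, window, stage = "property_filter") {
  assert_that(inherits(window, "property_window"), "window must be a property_window")
  missing <- setdiff(names(window), names(set))
  if (length(missing) > 0L) {
    stop("window names fields absent from the property vector: ",
         paste(missing, collapse = ", "), " (run compute_properties first?)",
         call. = FALSE)
  }
  if (nrow(set) == 0L) return(subset_set(set, integer(), stage))
  fail <- sapply(names(window), function(nm) {
    v <- set[[nm]]
    is.na(v) | v < window[[nm]][1] | v > window[[nm]][2]
  })
  fail <- matrix(fail, nrow = nrow(set))
  keep <- rowSums(fail) == 0L
  out <- subset_set(set, keep, stage)
  attr(out, "rejected_by") <- stats::setNames(colSums(fail), names(window))
  first_fail <- apply(fail[!keep, , drop = FALSE], 1L, function(r) names(window)[which(r)[1]])
  attr(out, "rejects") <- data.frame(
    row = which(!keep), input = set$smiles_canonical[!keep],
    reason = as.character(first_fail), stringsAsFactors = FALSE
  )
  out
}
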