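# SMARTS structural alerts: PAINS, reactive/toxic functionality and
# project-specific additions, used to flag or remove compounds.

#' Load a SMARTS alert set
#'
#' Accepts the package's three-column CSV (`alert_id,smarts,description`) or
#' the two-column `smarts,name` layout common to distributed PAINS lists.
#' Every SMARTS must compile; a malformed pattern fails the whole load with
#' the offending line numbers — alerts must never silently vanish.
#'
#' @param path CSV path.
#' @param name Alert-set name (defaults to the file name).
#' @return An `alert_set`: list with `name`, `source` and a data.frame
#'   `patterns` (`alert_id, smarts, description`).
#' @export
load_alert_set <- function(path, name = NULL) {
  assert_that(file.exists(path), paste0("alert file not found: ", path))
  tab <- data.table::fread(path, colClasses = "character", data.table = FALSE)
  if (all(c("alert_id", "smarts") %in% names(tab))) {
    pat <- data.frame(alert_id = tab$alert_id, smarts = tab$smarts,
                      description = tab$description %||% "", stringsAsFactors = FALSE)
  } else if (ncol(tab) >= 2L) {
    pat <- data.frame(alert_id = tab[[2]], smarts = tab[[1]],
                      description = "", stringsAsFactors = FALSE)
  } else {
    stop("alert file needs columns alert_id,smarts[,description] or smarts,name",
         call. = FALSE)
  }
  assert_that(!anyDuplicated(pat$alert_id), "alert_ids must be unique within a set")
  ok <- vapply(rdkit_call("smarts_compile", list(smarts = as.list(pat$smarts))),
               function(r) isTRUE(r$ok), NA)
  if (!all(ok)) {
    stop("malformed SMARTS in ", path, " at line(s) ",
         paste(which(!ok) + 1L, collapse = ", "), ": ",
         paste(pat$alert_id[!ok], collapse = ", "), call. = FALSE)
  }
  structure(list(name = name %||% sub("\\.csv$", "", basename(path)),
                 source = path, patterns = pat),
            class = "alert_set")
}

#' The shipped alert fixtures
#'
#' Three sets: a public PAINS subset, reactive/toxic functionality (aromatic
#' nitro, acid halides, Michael acceptors, ...), and a project set of
#' later-added alerts (thioethers, sulfoxides, ...). Institutional alert
#' collections in the same CSV layouts load unchanged via
#' [load_alert_set()].
#'
#' @param which One or more of `"pains"`, `"reactive"`, `"project"`.
#' @return A single merged `alert_set`.
#' @export
default_alerts <- function(which = c("pains", "reactive", "project")) {
  which <- match.arg(which, several.ok = TRUE)
  files <- c(pains = "alerts_pains_subset.csv",
             reactive = "alerts_reactive_toxic.csv",
             project = "alerts_project.csv")[which]
  sets <- lapply(unname(files), function(f) {
    load_alert_set(system.file("extdata", f, package = "chemfunnel"))
  })
  structure(list(name = paste(which, collapse = "+"),
                 source = paste(files, collapse = ";"),
                 patterns = do.call(rbind, lapply(sets, `[[`, "patterns"))),
            class = "alert_set")
}

#' Match alerts against molecules
#'
#' An alert is reported when its SMARTS has at least one substructure match
#' (presence only — occurrences are not counted).
#'
#' @param x A `compound_set`, `chem_mol`, or character vector of SMILES.
#' @param alerts An `alert_set`.
#' @return For a single molecule, a character vector of matched alert ids
#'   (empty = clean); otherwise a list of such vectors, one per compound.
#' @export
match_alerts <- function(x, alerts) {
  assert_that(inherits(alerts, "alert_set"), "alerts must be an alert_set")
  smiles <- smiles_of(x)
  single <- inherits(x, "chem_mol") || (is.character(x) && length(x) == 1L)
  if (length(smiles) == 0L) return(list())
  hits <- rdkit_call("smarts_match",
                     list(smiles = as.list(smiles),
                          smarts = as.list(alerts$patterns$smarts)))
  out <- lapply(hits, function(h) {
    if (is.null(h)) return(NA_character_)
    alerts$patterns$alert_id[unlist(h) + 1L]
  })
  if (single) out[[1]] else out
}

#' Flag or remove alert-matching compounds
#'
#' @param set A `compound_set`.
#' @param alerts An `alert_set`.
#' @param mode `"flag"` annotates the `flags` column; `"remove"` drops
#'   matching records, reporting per-alert hit counts in
#'   `attr(, "alert_hits")` (their sum can exceed the number removed when a
#'   compound carries several alerts) and the removals in `attr(, "rejects")`.
#' @return The annotated or filtered `compound_set`.
#' @export
filter_alerts <- function(set, alerts, mode = c("flag", "remove")) {
  mode <- match.arg(mode)
  matched <- match_alerts(set, alerts)
  if (nrow(set) == 0L) return(subset_set(set, integer(), paste0("alerts:", mode)))
  n_hits <- vapply(matched, length, 0L)
  if (mode == "flag") {
    joined <- vapply(matched, paste, "", collapse = ";")
    out <- subset_set(set, seq_len(nrow(set)), paste0("alerts:flag:", alerts$name))
    out$flags <- ifelse(
      nzchar(joined),
      ifelse(nzchar(out$flags), paste(out$flags, joined, sep = ";"), joined),
      out$flags)
    return(out)
  }
  keep <- n_hits == 0L
  out <- subset_set(set, keep, paste0("alerts:remove:", alerts$name))
  hits <- table(factor(unlist(matched), levels = alerts$patterns$alert_id))
  attr(out, "alert_hits") <- stats::setNames(as.integer(hits), names(hits))
  attr(out, "rejects") <- data.frame(
    row = which(!keep), input = set$smiles_canonical[!keep],
    reason = vapply(matched[!keep], paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  out
}
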