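#' @keywords internal
"_PACKAGE"

# Batched JSON bridge to the bundled RDKit helper script. Every chemistry
# primitive (parsing, SMARTS, Morgan bits, Murcko, descriptors, reactions,
# SDF I/O) and sklearn t-SNE goes through rdkit_call(); all calls are
# vectorised so a whole CompoundSet costs one interpreter start-up.

bridge_env <- new.env(parent = emptyenv())

chem_python <- function() {
  py <- getOption("chemfunnel.python", "")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) {
    stop("No python interpreter found; set options(chemfunnel.python = ...)",
         call. = FALSE)
  }
  py
}

bridge_script <- function() {
  path <- system.file("python", "rdkit_bridge.py", package = "chemfunnel")
  if (!nzchar(path) || !file.exists(path)) {
    stop("rdkit_bridge.py not found in the installed package", call. = FALSE)
  }
  path
}

rdkit_call <- function(op, payload = list(), simplify = FALSE) {
  req <- tempfile(fileext = ".json")
  resp <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, resp)), add = TRUE)
  jsonlite::write_json(c(list(op = op), payload), req,
                       auto_unbox = TRUE, digits = NA, null = "null")
  status <- suppressWarnings(system2(
    chem_python(), c(shQuote(bridge_script()), shQuote(req), shQuote(resp)),
    stdout = TRUE, stderr = TRUE
  ))
  if (!file.exists(resp)) {
    stop("RDKit bridge failed for op '", op, "': ",
         paste(status, collapse = "\n"), call. = FALSE)
  }
  out <- jsonlite::read_json(resp, simplifyVector = simplify)
  ok <- if (simplify) isTRUE(out[["ok"]]) else isTRUE(out$ok)
  if (!ok) {
    stop("RDKit bridge error in op '", op, "': ", out$error, call. = FALSE)
  }
  out$result
}

#' Check that the RDKit bridge is operational
#'
#' Runs a no-op round trip through the bundled Python helper and returns the
#' RDKit version it found.
#'
#' @return A character scalar, the RDKit version string.
#' @export
#' @examples
#' \dontrun{bridge_version()}
bridge_version <- function() {
  res <- rdkit_call("ping")
  res$rdkit
}
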