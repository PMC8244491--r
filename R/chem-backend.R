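## Molecular-perception backend: a batch Python/RDKit sidecar.
##
## All SMILES/SDF parsing, canonicalisation, fingerprinting, atom-property
## perception and 3D embedding are delegated to one subprocess call per batch
## (inst/python/chem.py).  Everything downstream (fields, energies,
## similarity, screening) is computed in this package.

chem_python <- function() {
  py <- getOption("olfscreen.python")
  if (!is.null(py) && nzchar(py)) return(py)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop2("no 'python' interpreter found on PATH (RDKit backend required)")
}

chem_script <- function() {
  p <- system.file("python", "chem.py", package = "olfscreen")
  if (!nzchar(p)) stop2("chem.py sidecar not found in installed package")
  p
}

run_sidecar <- function(args) {
  out <- suppressWarnings(
    system2(chem_python(), c(shQuote(chem_script()), args),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    stop2("chemistry backend failed (exit %d):\n%s", status,
          paste(utils::tail(out, 10), collapse = "\n"))
  invisible(out)
}

#' @return parsed JSON payload from the sidecar's featurize command.
#' @keywords internal
#' @noRd
chem_featurize <- function(path, format = c("smiles", "sdf"),
                           embed3d = FALSE, seed = 0L) {
  format <- match.arg(format)
  out_json <- tempfile(fileext = ".json")
  on.exit(unlink(out_json), add = TRUE)
  args <- c("featurize", "--in", shQuote(path), "--format", format,
            "--out", shQuote(out_json), "--seed", as.integer(seed))
  if (embed3d) args <- c(args, "--embed3d")
  run_sidecar(args)
  jsonlite::fromJSON(out_json, simplifyVector = FALSE)
}

chem_embed_sdf <- function(smi_path, sdf_path, seed = 0L) {
  run_sidecar(c("embed-sdf", "--in", shQuote(smi_path),
                "--out", shQuote(sdf_path), "--seed", as.integer(seed)))
  invisible(sdf_path)
}
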