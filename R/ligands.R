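## Small-molecule I/O, fingerprints and Tanimoto ligand-profile comparison.
##
## Parsing, canonicalisation and fingerprinting run through the RDKit
## sidecar in one batch per file; similarity arithmetic is computed here.
## Fingerprints are MACCS structural keys (167 bits) standing in for the
## PubChem/CACTVS 881-bit scheme, whose exact implementation is not
## available; the scheme name and bit length are recorded on every object so
## downstream reports are self-describing.

new_ligand <- function(rec) {
  atoms <- NULL
  conformer <- NULL
  if (length(rec$atoms)) {
    atoms <- do.call(rbind, lapply(rec$atoms, function(a)
      data.frame(element = a$element, donor = a$donor, acceptor = a$acceptor,
                 sp2 = a$sp2, lipophilicity = a$lipophilicity, size = a$size,
                 electronegativity = a$electronegativity, charge = a$charge,
                 stringsAsFactors = FALSE)))
    if (!is.null(rec$atoms[[1]]$x))
      conformer <- t(vapply(rec$atoms, function(a) c(a$x, a$y, a$z), numeric(3)))
  }
  structure(list(id = rec$id, smiles = rec$smiles, atoms = atoms,
                 conformer = conformer,
                 fp_bits = unlist(rec$fingerprint$bits) %||% integer(0),
                 fp_scheme = rec$fingerprint$scheme %||% NA_character_,
                 fp_nbits = rec$fingerprint$nbits %||% NA_integer_),
            class = "ligand")
}

#' @export
print.ligand <- function(x, ...) {
  cat(sprintf("<ligand> %s  %s  (%d heavy atoms%s)\n", x$id, x$smiles,
              if (is.null(x$atoms)) 0L else nrow(x$atoms),
              if (is.null(x$conformer)) "" else ", 3D"))
  invisible(x)
}

ligands_from_payload <- function(payload, what = "ligand file") {
  mols <- payload$molecules
  valid <- Filter(function(m) isTRUE(m$valid), mols)
  n_bad <- payload$n_invalid %||% (length(mols) - length(valid))
  if (n_bad > 0) {
    bad_ids <- vapply(Filter(function(m) !isTRUE(m$valid), mols),
                      function(m) m$id %||% "?", "")
    warning(sprintf("%d invalid entr%s skipped in %s: %s", n_bad,
                    if (n_bad == 1) "y" else "ies", what,
                    paste(bad_ids, collapse = ", ")), call. = FALSE)
  }
  if (!length(valid)) stop2("no valid molecules in %s", what)
  out <- lapply(valid, new_ligand)
  attr(out, "n_invalid") <- n_bad
  attr(out, "fingerprint_scheme") <- payload$fingerprint_scheme
  out
}

#' Read ligands from a SMILES or SDF file
#'
#' SMILES files are one molecule per line (`SMILES<space>id`); SDF V2000
#' files keep their 3D conformers.  Invalid entries are skipped with a
#' warning and counted in the `n_invalid` attribute of the result.
#'
#' @param path input file.
#' @param format `"smiles"` or `"sdf"`.
#' @param embed3d generate a 3D conformer for each molecule (distance
#'   geometry, seeded)?
#' @param seed embedding seed (ignored unless `embed3d`).
#' @return list of `ligand` objects, order preserved.
#' @export
read_ligands <- function(path, format = c("smiles", "sdf"),
                         embed3d = FALSE, seed = 0L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("ligand file not found: %s", path)
  payload <- chem_featurize(path, format, embed3d = embed3d, seed = seed)
  ligands_from_payload(payload, path)
}

#' Fingerprint of a ligand
#'
#' @param ligand a `ligand` object (fingerprints are computed at parse time;
#'   this accessor re-shapes them as a named bit set).
#' @return object of class `fingerprint`: integer vector of set-bit indices
#'   with attributes `nbits`, `scheme`, `ligand_id`.
#' @export
fingerprint <- function(ligand) {
  if (!inherits(ligand, "ligand")) stop2("not a ligand object")
  structure(as.integer(ligand$fp_bits), class = "fingerprint",
            nbits = ligand$fp_nbits, scheme = ligand$fp_scheme,
            ligand_id = ligand$id)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`; defined as 0 when both fingerprints are all-zero.
#'
#' @param a,b [fingerprint()] objects of equal length.
#' @return value in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (!identical(attr(a, "nbits"), attr(b, "nbits")))
    stop2("fingerprint length mismatch (%s vs %s)",
          attr(a, "nbits"), attr(b, "nbits"))
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Cross-similarity of target and template ligand sets
#'
#' Computes the full Tanimoto matrix between every template ligand (rows)
#' and every target ligand (columns), and ranks the template ligands by a
#' robust aggregate against the target set.
#'
#' @param target_ligands,template_ligands non-empty lists of `ligand`
#'   objects.
#' @param aggregate `"median"` (default, robust to one odd ligand) or
#'   `"mean"`.
#' @return list of class `ligand_profile`: `matrix` (templates x targets),
#'   `aggregate` (named vector per template), `ranking` (template ids, best
#'   first, ties broken by id), `scheme`.
#' @export
profile_compare <- function(target_ligands, template_ligands,
                            aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!length(target_ligands) || !length(template_ligands))
    stop2("both ligand lists must be non-empty")
  fps_t <- lapply(target_ligands, fingerprint)
  fps_m <- lapply(template_ligands, fingerprint)
  m <- matrix(0, length(fps_m), length(fps_t),
              dimnames = list(vapply(template_ligands, `[[`, "", "id"),
                              vapply(target_ligands, `[[`, "", "id")))
  for (i in seq_along(fps_m))
    for (j in seq_along(fps_t))
      m[i, j] <- tanimoto(fps_m[[i]], fps_t[[j]])
  agg_fun <- if (aggregate == "median") stats::median else mean
  agg <- apply(m, 1, agg_fun)
  ord <- order(-agg, rownames(m))
  structure(list(matrix = m, aggregate = agg,
                 ranking = rownames(m)[ord], aggregate_fun = aggregate,
                 scheme = attr(fps_t[[1]], "scheme")),
            class = "ligand_profile")
}

#' Write a similarity matrix as tidy CSV
#'
#' @param profile [profile_compare()] result.
#' @param path output CSV (`ligand_a`, `ligand_b`, `tanimoto`).
#' @export
write_similarity_csv <- function(profile, path) {
  m <- profile$matrix
  df <- data.frame(ligand_a = rep(rownames(m), ncol(m)),
                   ligand_b = rep(colnames(m), each = nrow(m)),
                   tanimoto = as.vector(m), stringsAsFactors = FALSE)
  df <- df[order(df$ligand_a, df$ligand_b), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
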