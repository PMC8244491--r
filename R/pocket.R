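## Orthosteric-pocket extraction (by Ballesteros-Weinstein position) and
## pocket similarity scoring with a substitution matrix.
##
## The bundled class A orthosteric definition has 24 BW positions; the
## OR-important subset (mutagenesis-supported) has 11.  Scores are unweighted
## sums of matrix entries over positions resolvable in both receptors.  The
## "similar" predicate for percentage reporting is configurable: a positive
## matrix score (default) or strict residue identity.

#' Pocket definition
#'
#' @param name label.
#' @param bw_positions character vector of unique, well-formed BW labels
#'   ("h.pp").
#' @return object of class `pocket_definition`.
#' @export
pocket_definition <- function(name, bw_positions) {
  bw_positions <- as.character(bw_positions)
  if (!all(grepl("^[1-7]\\.[0-9]{1,2}$", bw_positions)))
    stop2("malformed BW label(s): %s",
          paste(bw_positions[!grepl("^[1-7]\\.[0-9]{1,2}$", bw_positions)],
                collapse = ", "))
  if (anyDuplicated(bw_positions)) stop2("duplicated BW positions")
  structure(list(name = name, bw_positions = bw_positions),
            class = "pocket_definition")
}

#' Load a substitution matrix from a TSV file
#'
#' File format: comment lines (`#`), then a header `res<TAB>A<TAB>R...`, then
#' 20 rows.  Symmetry and completeness over the canonical alphabet are
#' enforced.
#'
#' @param path TSV file.
#' @param name matrix name recorded on the result.
#' @return 20 x 20 numeric matrix with attribute `"matrix_name"`.
#' @export
read_substitution_matrix <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (!all(AA_CANONICAL %in% rownames(m)) || !all(AA_CANONICAL %in% colnames(m)))
    stop2("substitution matrix must cover the 20 canonical residues")
  m <- m[AA_CANONICAL, AA_CANONICAL]
  if (!isTRUE(all.equal(m, t(m)))) stop2("substitution matrix is not symmetric")
  attr(m, "matrix_name") <- name
  m
}

#' Extract pocket residues of a receptor
#'
#' @param seq [receptor_sequence()].
#' @param bw [assign_bw_numbers()] result.
#' @param pocket [pocket_definition()].
#' @return list of class `pocket_residues`: `residues` (named character
#'   vector, BW label -> residue, resolvable positions only) and `missing`
#'   (labels not resolvable under the annotation; data, not an error).
#' @export
extract_pocket <- function(seq, bw, pocket) {
  res <- vapply(pocket$bw_positions, function(p) bw_residue(seq, bw, p),
                NA_character_)
  structure(list(residues = res[!is.na(res)],
                 missing = pocket$bw_positions[is.na(res)],
                 receptor_id = seq$id, pocket_name = pocket$name),
            class = "pocket_residues")
}

similar_predicate <- function(ra, rb, matrix, predicate) {
  switch(predicate,
         "positive-score" = matrix[cbind(ra, rb)] > 0,
         "identity"       = ra == rb,
         stop2("unknown similarity predicate '%s'", predicate))
}

#' Score two pockets with a substitution matrix
#'
#' @param resA,resB [extract_pocket()] results (or named BW -> residue
#'   character vectors).
#' @param matrix symmetric substitution matrix (see
#'   [read_substitution_matrix()]; `load_table("gpcrtm")` returns the bundled
#'   stand-in).
#' @param predicate similarity predicate used for `similar_pct`:
#'   `"positive-score"` (matrix value > 0, default) or `"identity"`.
#' @return list of class `pocket_comparison`: `positions_used`, `missing`,
#'   `score` (sum of matrix values over shared positions), `similar_pct`.
#' @export
pocket_score <- function(resA, resB, matrix, predicate = "positive-score") {
  va <- if (inherits(resA, "pocket_residues")) resA$residues else resA
  vb <- if (inherits(resB, "pocket_residues")) resB$residues else resB
  shared <- intersect(names(va), names(vb))
  all_pos <- union(names(va), names(vb))
  if (inherits(resA, "pocket_residues"))
    all_pos <- union(all_pos, union(resA$missing, resB$missing))
  if (!length(shared)) stop2("no shared resolvable pocket positions")
  ra <- unname(va[shared]); rb <- unname(vb[shared])
  terms <- matrix[cbind(ra, rb)]
  sim <- similar_predicate(ra, rb, matrix, predicate)
  structure(list(positions_used = shared,
                 missing = setdiff(all_pos, shared),
                 score = sum(terms),
                 per_position = stats::setNames(terms, shared),
                 similar_pct = round(100 * mean(sim)),
                 predicate = predicate,
                 matrix_name = attr(matrix, "matrix_name") %||% "unnamed"),
            class = "pocket_comparison")
}

#' Hot-spot overlap percentage
#'
#' Percent of hot-spot positions (resolvable in both receptors) whose residue
#' pair meets the similarity predicate, rounded to the nearest integer.
#'
#' @inheritParams pocket_score
#' @param hotspots [pocket_definition()] of hot-spot positions.
#' @return integer percent.
#' @export
hotspot_overlap <- function(resA, resB, hotspots, matrix,
                            predicate = "positive-score") {
  va <- if (inherits(resA, "pocket_residues")) resA$residues else resA
  vb <- if (inherits(resB, "pocket_residues")) resB$residues else resB
  pos <- intersect(hotspots$bw_positions, intersect(names(va), names(vb)))
  if (!length(pos)) stop2("no hot-spot positions resolvable in both receptors")
  sim <- similar_predicate(unname(va[pos]), unname(vb[pos]), matrix, predicate)
  round(100 * mean(sim))
}
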