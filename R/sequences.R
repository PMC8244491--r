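## Receptor sequences, TM annotation, Ballesteros-Weinstein numbering and
## pairwise alignment metrics.
##
## Alignment convention (documented, user-visible): Needleman-Wunsch global
## alignment with BLOSUM62 scoring and affine gaps (open 10, extend 0.5 in
## matrix units), computed by Biostrings.  Identity is the percent of
## identical pairs among aligned columns after excluding terminal-gap runs;
## coverage is the percent of target residues aligned opposite a non-gap
## template residue.

#' Receptor sequence object
#'
#' @param id accession or name.
#' @param residues one-letter amino-acid string (20 canonical letters only;
#'   ambiguity codes such as X/B/Z are rejected).
#' @param source free-text provenance.
#' @return an object of class `receptor_sequence`.
#' @export
receptor_sequence <- function(id, residues, source = "") {
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop2("residues must be a non-empty character scalar")
  residues <- toupper(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_CANONICAL))
  if (length(bad))
    stop2("non-canonical residue '%s' at position %d in sequence '%s'",
          chars[bad[1]], bad[1], id)
  structure(list(id = as.character(id), residues = residues,
                 source = as.character(source)),
            class = "receptor_sequence")
}

#' @export
print.receptor_sequence <- function(x, ...) {
  cat(sprintf("<receptor_sequence> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' @export
length.receptor_sequence <- function(x) nchar(x$residues)

seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1]]

#' Read receptor sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return list of [receptor_sequence()] (empty list for an empty file).
#'   The first whitespace-delimited header token is used as the id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop2("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(list())
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop2("malformed FASTA: line %d does not start a record ('>')", nonblank[1])
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop2("malformed FASTA (%s): %s",
                                            path, conditionMessage(e)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  lapply(seq_along(set), function(i)
    receptor_sequence(ids[i], as.character(set[[i]]), source = path))
}

#' TM-helix annotation table
#'
#' @param helix character vector of helix ids `TM1`..`TM7` (any ordered
#'   subset).
#' @param start,end 1-based inclusive residue indices.
#' @param seq_length parent sequence length used for bounds checking
#'   (optional).
#' @return data.frame of class `tm_annotation`, ordered TM1..TM7.
#' @export
tm_annotation <- function(helix, start, end, seq_length = NULL) {
  df <- data.frame(helix = as.character(helix), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (!all(grepl("^TM[1-7]$", df$helix)))
    stop2("helix ids must be TM1..TM7")
  if (anyDuplicated(df$helix)) stop2("duplicated helix id")
  df <- df[order(df$helix), , drop = FALSE]
  if (any(df$start < 1L) || any(df$end < df$start))
    stop2("need 1 <= start <= end for every helix")
  if (!is.null(seq_length) && any(df$end > seq_length))
    stop2("helix annotation extends beyond sequence length %d", seq_length)
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)]))
    stop2("helices must be non-overlapping and ordered TM1..TM7")
  rownames(df) <- NULL
  class(df) <- c("tm_annotation", "data.frame")
  df
}

#' Read a TM-annotation table (TSV: helix, start, end, anchor)
#'
#' @param path TSV file with columns `helix`, `start`, `end`, `anchor`.
#' @param seq_length optional parent sequence length for validation.
#' @return list with elements `tms` ([tm_annotation()]) and `anchors`
#'   (named integer vector, helix -> anchor residue index).
#' @export
read_tm_annotations <- function(path, seq_length = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("helix", "start", "end", "anchor")
  if (!all(need %in% names(df)))
    stop2("TM annotation table must have columns: %s", paste(need, collapse = ", "))
  tms <- tm_annotation(df$helix, df$start, df$end, seq_length)
  anchors <- stats::setNames(as.integer(df$anchor), df$helix)[tms$helix]
  list(tms = tms, anchors = anchors)
}

#' Assign Ballesteros-Weinstein numbers
#'
#' The anchor residue of helix *h* is labelled `h.50`; the residue at
#' anchor + k is `h.(50+k)` within the helix span.
#'
#' @param seq [receptor_sequence()].
#' @param tms [tm_annotation()].
#' @param anchors named integer vector (helix -> anchor residue index; each
#'   anchor must lie inside its helix).
#' @return data.frame of class `bw_map` with columns `index`, `helix`,
#'   `bw` (numeric position within helix) and `label` ("h.pp").
#' @export
assign_bw_numbers <- function(seq, tms, anchors) {
  rows <- lapply(seq_len(nrow(tms)), function(i) {
    h <- tms$helix[i]
    if (!h %in% names(anchors)) stop2("no anchor supplied for %s", h)
    a <- anchors[[h]]
    if (a < tms$start[i] || a > tms$end[i])
      stop2("anchor %d for %s lies outside its span [%d, %d]",
            a, h, tms$start[i], tms$end[i])
    idx <- tms$start[i]:tms$end[i]
    pos <- 50L + (idx - a)
    hnum <- sub("^TM", "", h)
    data.frame(index = idx, helix = h, bw = pos,
               label = paste0(hnum, ".", pos), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$label)) stop2("BW labelling is not bijective")
  if (any(out$index > length(seq)))
    stop2("annotation extends beyond sequence '%s'", seq$id)
  class(out) <- c("bw_map", "data.frame")
  out
}

#' Residue at a BW label
#'
#' @param seq [receptor_sequence()].
#' @param bw [assign_bw_numbers()] result.
#' @param label BW label such as "3.50".
#' @return single residue letter, or `NA_character_` if the label is not
#'   resolvable in this receptor's annotation.
#' @export
bw_residue <- function(seq, bw, label) {
  i <- match(label, bw$label)
  if (is.na(i)) return(NA_character_)
  substr(seq$residues, bw$index[i], bw$index[i])
}

## ---- pairwise alignment -------------------------------------------------

align_global <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  mat <- get_blosum62()
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  list(aligned_a = as.character(Biostrings::alignedPattern(al)),
       aligned_b = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

trim_terminal_gaps <- function(ca, cb) {
  n <- length(ca)
  first <- 1L
  while (first <= n && (ca[first] == "-" || cb[first] == "-")) first <- first + 1L
  last <- n
  while (last >= first && (ca[last] == "-" || cb[last] == "-")) last <- last - 1L
  if (first > last) return(integer(0))
  first:last
}

#' Global percent sequence identity
#'
#' Percent of identical residue pairs among the aligned columns of a global
#' alignment, excluding columns falling in terminal gap runs; reported to one
#' decimal.
#'
#' @param a,b [receptor_sequence()] objects.
#' @return percent in `[0, 100]`.
#' @export
global_identity <- function(a, b) {
  al <- align_global(a, b)
  ca <- strsplit(al$aligned_a, "")[[1]]
  cb <- strsplit(al$aligned_b, "")[[1]]
  keep <- trim_terminal_gaps(ca, cb)
  if (!length(keep)) return(0)
  round(100 * sum(ca[keep] == cb[keep] & ca[keep] != "-") / length(keep), 1)
}

#' Query coverage of a target by a template
#'
#' Percent of target residues aligned opposite a non-gap template residue in
#' the global alignment.
#'
#' @param target,template [receptor_sequence()] objects.
#' @return percent in `[0, 100]`, one decimal.
#' @export
query_coverage <- function(target, template) {
  al <- align_global(target, template)
  ca <- strsplit(al$aligned_a, "")[[1]]
  cb <- strsplit(al$aligned_b, "")[[1]]
  round(100 * sum(ca != "-" & cb != "-") / length(seq_chars(target)), 1)
}

#' Centre-tethered helix alignment
#'
#' Pairs two helix substrings by tethering their centre residues (index
#' `floor((L + 1) / 2)`, 1-based) and extending symmetrically; overhangs are
#' dropped.
#'
#' @param tm_a,tm_b residue strings (no gaps).
#' @return two-column integer matrix (`a`, `b`) of paired 1-based indices,
#'   strictly increasing in both columns.
#' @export
center_tether_align <- function(tm_a, tm_b) {
  la <- nchar(tm_a); lb <- nchar(tm_b)
  if (la == 0L || lb == 0L) stop2("empty helix string")
  ca <- (la + 1L) %/% 2L
  cb <- (lb + 1L) %/% 2L
  k <- max(1L - ca, 1L - cb):min(la - ca, lb - cb)
  cbind(a = ca + k, b = cb + k)
}
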