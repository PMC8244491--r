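## Moving-window hydrophobicity profiles and per-helix correspondence
## scoring.
##
## H_n is the arithmetic mean of the Eisenberg-scale values over the
## 11-residue window centred at n; only full windows are evaluated, so a
## helix of length L yields L - 10 profile values.  The correspondence
## between a template and a target helix is the sum of squared differences
## (SSD) of their profiles over positions paired by the centre-tethered
## alignment; SSD / N, with N the number of paired profile positions, is the
## per-residue value, with > 0.1 flagging poor correspondence.

#' Load a hydrophobicity scale
#'
#' @param name currently `"eisenberg"` (normalized consensus scale).
#' @return named numeric vector over the 20 canonical residues, with
#'   attribute `"scale_name"`.
#' @export
hydro_scale <- function(name = "eisenberg") {
  tab <- load_table(name)
  v <- stats::setNames(tab$hydrophobicity, tab$residue)
  if (!all(AA_CANONICAL %in% names(v)))
    stop2("scale '%s' is missing canonical residues", name)
  attr(v, "scale_name") <- name
  v
}

#' Windowed hydrophobicity profile of a helix
#'
#' @param helix residue string (length >= window).
#' @param scale named numeric vector (see [hydro_scale()]).
#' @param window odd window size; 11 is the transmembrane-helix convention.
#' @param helix_id label carried into the result.
#' @return object of class `hydro_profile`: numeric vector of window means
#'   (one per full window, named by 1-based centre position), with
#'   attributes `helix_id`, `window`, `scale_name`.
#' @export
windowed_profile <- function(helix, scale, window = 11L, helix_id = "") {
  if (window %% 2L != 1L) stop2("window must be odd")
  L <- nchar(helix)
  if (L < window)
    stop2("helix %s'%s' is shorter (%d) than the window (%d)",
          if (nzchar(helix_id)) paste0(helix_id, " ") else "", helix, L, window)
  chars <- strsplit(helix, "")[[1]]
  bad <- which(!(chars %in% names(scale)))
  if (length(bad)) stop2("residue '%s' not in scale", chars[bad[1]])
  h <- unname(scale[chars])
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(L - half)
  cs <- c(0, cumsum(h))
  vals <- (cs[centers + half + 1L] - cs[centers - half]) / window
  structure(stats::setNames(vals, centers), class = "hydro_profile",
            helix_id = helix_id, window = window,
            scale_name = attr(scale, "scale_name") %||% "custom")
}

#' Per-helix SSD correspondence between two profiles
#'
#' @param profile_template,profile_target [windowed_profile()] results for
#'   the same scale.
#' @param pairing two-column index matrix from [center_tether_align()] run on
#'   the two helices, in helix coordinates; only pairs where both profiles
#'   are defined (full windows) contribute.
#' @param threshold per-residue SSD above which correspondence is flagged
#'   poor (0.1 for the Eisenberg scale).
#' @return list of class `ssd_report`: `helix_id`, `n` (paired profile
#'   positions), `ssd`, `ssd_per_residue`, `poor_correspondence`.
#' @export
ssd <- function(profile_template, profile_target, pairing, threshold = 0.1) {
  st <- attr(profile_template, "scale_name")
  sg <- attr(profile_target, "scale_name")
  if (!identical(st, sg))
    stop2("profiles come from different scales (%s vs %s)", st, sg)
  if (is.null(pairing) || nrow(pairing) == 0L) stop2("empty pairing")
  ia <- match(as.character(pairing[, 1]), names(profile_template))
  ib <- match(as.character(pairing[, 2]), names(profile_target))
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) stop2("no paired positions have defined profile values")
  d <- unclass(profile_template)[ia[ok]] - unclass(profile_target)[ib[ok]]
  n <- sum(ok)
  s <- sum(d^2)
  structure(list(helix_id = attr(profile_template, "helix_id"),
                 n = n, ssd = s, ssd_per_residue = s / n,
                 poor_correspondence = (s / n) > threshold),
            class = "ssd_report")
}

helix_string <- function(seq, tms, helix) {
  i <- match(helix, tms$helix)
  if (is.na(i)) stop2("receptor '%s' lacks an annotation for %s", seq$id, helix)
  substr(seq$residues, tms$start[i], tms$end[i])
}

helix_ssd <- function(target, target_tms, template, template_tms, helix,
                      scale, window = 11L, threshold = 0.1) {
  ht <- helix_string(target, target_tms, helix)
  hm <- helix_string(template, template_tms, helix)
  pairing <- center_tether_align(hm, ht)   # template first, target second
  pt <- windowed_profile(hm, scale, window, helix_id = helix)
  pg <- windowed_profile(ht, scale, window, helix_id = helix)
  ssd(pt, pg, pairing, threshold)
}

#' Hydrophobicity-correspondence table for candidate templates
#'
#' One row per template: per-helix SSD per residue (TM1..TM7) plus global
#' sequence identity against the target.
#'
#' @param target list with elements `seq` ([receptor_sequence()]) and `tms`
#'   ([tm_annotation()] covering TM1..TM7).
#' @param templates named list of the same shape (names = template ids), or
#'   unnamed (ids taken from each `seq$id`).
#' @param scale hydrophobicity scale, default [hydro_scale()].
#' @param window window size.
#' @param threshold poor-correspondence threshold on SSD per residue.
#' @return data.frame (rows ordered by template id) with columns
#'   `template_id`, `TM1`..`TM7` (SSD per residue), `identity_pct`, and
#'   `poor_helices` (comma-separated helices above threshold).
#' @export
correspondence_table <- function(target, templates, scale = hydro_scale(),
                                 window = 11L, threshold = 0.1) {
  helices <- paste0("TM", 1:7)
  if (!all(helices %in% target$tms$helix))
    stop2("target '%s' must have all 7 TM annotations", target$seq$id)
  ids <- names(templates) %||% vapply(templates, function(t) t$seq$id, "")
  if (is.null(names(templates))) names(templates) <- ids
  ord <- order(ids)
  rows <- lapply(ord, function(i) {
    tpl <- templates[[i]]
    if (!all(helices %in% tpl$tms$helix))
      stop2("template '%s' must have all 7 TM annotations", ids[i])
    per <- vapply(helices, function(h)
      helix_ssd(target$seq, target$tms, tpl$seq, tpl$tms, h,
                scale, window, threshold)$ssd_per_residue, 0)
    poor <- helices[per > threshold]
    c(list(template_id = ids[i]), as.list(per),
      list(identity_pct = global_identity(target$seq, tpl$seq),
           poor_helices = paste(poor, collapse = ",")))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
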