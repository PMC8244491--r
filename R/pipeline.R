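## Template-selection cascade and stage-1 screening orchestration.
##
## Stages (each toggleable): resolution/state filter -> hydrophobicity
## correspondence shortlist + identity -> query coverage -> ligand-profile
## comparison -> orthosteric-pocket comparison.  The default final ranking
## is lexicographic -- pocket score (desc), mean per-helix SSD (asc), query
## coverage (desc) -- one documented formalisation of a judgment call the
## underlying metrics do not uniquely determine.

#' Template candidate
#'
#' @param pdb_id structure id.
#' @param receptor distinct receptor name (used by "best structure per
#'   receptor" filtering).
#' @param resolution resolution in Angstrom (> 0).
#' @param activity_state `"active"` or `"inactive"`.
#' @param seq [receptor_sequence()].
#' @param tms [tm_annotation()] with 7 helices.
#' @param anchors named anchors per helix.
#' @param ligand optional `ligand` object (the template's bound ligand).
#' @return list of class `template_candidate`.
#' @export
template_candidate <- function(pdb_id, receptor, resolution, activity_state,
                               seq, tms, anchors, ligand = NULL) {
  if (!is.numeric(resolution) || resolution <= 0)
    stop2("resolution must be > 0")
  activity_state <- match.arg(activity_state, c("active", "inactive"))
  if (nrow(tms) != 7L) stop2("candidate %s needs 7 TM annotations", pdb_id)
  structure(list(pdb_id = pdb_id, receptor = receptor,
                 resolution = resolution, activity_state = activity_state,
                 seq = seq, tms = tms, anchors = anchors, ligand = ligand),
            class = "template_candidate")
}

#' Resolution / activity-state filter
#'
#' Keeps candidates at or under the resolution cutoff in the requested
#' activity state, then retains the single best-resolved structure per
#' distinct receptor (ties broken by pdb id).
#'
#' @param candidates list of [template_candidate()].
#' @param cutoff resolution cutoff, Angstrom.
#' @param state required activity state.
#' @return filtered candidate list (possibly empty), sorted by pdb id.
#' @export
filter_resolution <- function(candidates, cutoff = 2.5, state = "inactive") {
  keep <- Filter(function(x) x$resolution <= cutoff &&
                   x$activity_state == state, candidates)
  if (!length(keep)) return(list())
  df <- data.frame(pdb = vapply(keep, `[[`, "", "pdb_id"),
                   rec = vapply(keep, `[[`, "", "receptor"),
                   res = vapply(keep, `[[`, 0, "resolution"))
  df <- df[order(df$rec, df$res, df$pdb), ]
  best <- df$pdb[!duplicated(df$rec)]
  out <- keep[match(sort(best), vapply(keep, `[[`, "", "pdb_id"))]
  out
}

#' Hydrophobicity-correspondence shortlist
#'
#' Survivors are the templates achieving the minimum per-residue SSD in at
#' least one TM helix column of the correspondence table (ties all
#' retained).
#'
#' @param ct [correspondence_table()] result with `TM1`..`TM7` columns.
#' @return character vector of surviving template ids (sorted).
#' @export
hc_shortlist <- function(ct) {
  helices <- paste0("TM", 1:7)
  if (!all(helices %in% names(ct))) stop2("correspondence table incomplete")
  winners <- unlist(lapply(helices, function(h) {
    ct$template_id[ct[[h]] <= min(ct[[h]]) + 1e-12]
  }))
  sort(unique(winners))
}

default_selection_config <- function() {
  list(resolution_cutoff = 2.5, activity_state = "inactive",
       stages = list(resolution = TRUE, hc = TRUE, coverage = TRUE,
                     ligand_profile = TRUE, pocket = TRUE),
       coverage_min = 80, ligand_aggregate = "median",
       pocket_predicate = "positive-score",
       scale = "eisenberg", window = 11L, ssd_threshold = 0.1)
}

#' Run the template-selection cascade
#'
#' @param target list with `seq`, `tms`, `anchors` and optionally
#'   `ligands` (known actives of the target, for the ligand-profile stage).
#' @param candidates list of [template_candidate()].
#' @param config named list; see `default_selection_config()` internals --
#'   any subset may be supplied and is merged over the defaults.
#' @param pocket [pocket_definition()] for the pocket stage (default: the
#'   bundled 24-position orthosteric definition).
#' @param matrix substitution matrix for the pocket stage (default: the
#'   bundled GPCRtm stand-in).
#' @return list of class `selection_report`: `stages` (named list of
#'   survivor id vectors, in execution order), `metrics` (one row per
#'   candidate), `ranking` (ids, best first), `stage_empty` (flag), `config`.
#' @export
run_selection <- function(target, candidates, config = list(),
                          pocket = load_table("orthosteric24"),
                          matrix = load_table("gpcrtm")) {
  cfg <- utils::modifyList(default_selection_config(), config)
  cfg$stages <- utils::modifyList(default_selection_config()$stages,
                                  as.list(config$stages %||% list()))
  ids_of <- function(cands) sort(vapply(cands, `[[`, "", "pdb_id"))
  all_ids <- ids_of(candidates)
  stages <- list(input = all_ids)
  surv <- candidates

  if (isTRUE(cfg$stages[["resolution"]])) {
    surv <- filter_resolution(surv, cfg$resolution_cutoff, cfg$activity_state)
    stages$resolution <- ids_of(surv)
  }

  metrics <- data.frame(template_id = ids_of(surv), stringsAsFactors = FALSE)
  scale <- hydro_scale(cfg$scale)
  if (nrow(metrics)) {
    tpl_list <- stats::setNames(surv, vapply(surv, `[[`, "", "pdb_id"))
    ct <- correspondence_table(target, tpl_list, scale, cfg$window,
                               cfg$ssd_threshold)
    metrics <- merge(metrics, ct, by = "template_id", sort = TRUE)
    metrics$resolution <- vapply(tpl_list[metrics$template_id], `[[`, 0,
                                 "resolution")
    metrics$mean_ssd <- rowMeans(metrics[, paste0("TM", 1:7)])
    if (isTRUE(cfg$stages[["hc"]])) {
      keep <- hc_shortlist(ct)
      surv <- surv[ids_of(surv) %in% keep]
      stages$hc <- ids_of(surv)
    }
  } else if (isTRUE(cfg$stages[["hc"]])) stages$hc <- character(0)

  if (isTRUE(cfg$stages[["coverage"]]) && length(surv)) {
    metrics$coverage_pct <- vapply(metrics$template_id, function(id) {
      i <- match(id, vapply(surv, `[[`, "", "pdb_id"))
      if (is.na(i)) NA_real_ else query_coverage(target$seq, surv[[i]]$seq)
    }, 0)
    surv <- Filter(function(x)
      query_coverage(target$seq, x$seq) >= cfg$coverage_min, surv)
    stages$coverage <- ids_of(surv)
  }

  if (isTRUE(cfg$stages[["ligand_profile"]]) && length(surv) &&
      length(target$ligands %||% list())) {
    tpl_ligs <- Filter(Negate(is.null), lapply(surv, `[[`, "ligand"))
    if (length(tpl_ligs)) {
      prof <- profile_compare(target$ligands, tpl_ligs,
                              aggregate = cfg$ligand_aggregate)
      lig_by_tpl <- vapply(surv, function(x)
        if (is.null(x$ligand)) NA_character_ else x$ligand$id, "")
      metrics$ligand_profile <- prof$aggregate[
        lig_by_tpl[match(metrics$template_id, vapply(surv, `[[`, "", "pdb_id"))]]
      stages$ligand_profile <- ids_of(surv)   # metric recorded, no gating
    }
  }

  if (isTRUE(cfg$stages[["pocket"]]) && length(surv)) {
    tgt_bw <- assign_bw_numbers(target$seq, target$tms, target$anchors)
    tgt_pocket <- extract_pocket(target$seq, tgt_bw, pocket)
    metrics$pocket_score <- vapply(metrics$template_id, function(id) {
      i <- match(id, vapply(surv, `[[`, "", "pdb_id"))
      if (is.na(i)) NA_real_ else {
        bw <- assign_bw_numbers(surv[[i]]$seq, surv[[i]]$tms, surv[[i]]$anchors)
        pocket_score(tgt_pocket, extract_pocket(surv[[i]]$seq, bw, pocket),
                     matrix, cfg$pocket_predicate)$score
      }
    }, 0)
    stages$pocket <- ids_of(surv)
  }

  final_ids <- ids_of(surv)
  rk <- metrics[metrics$template_id %in% final_ids, , drop = FALSE]
  col_or_zero <- function(nm, sgn = 1)
    if (nm %in% names(rk)) sgn * rk[[nm]] else rep(0, nrow(rk))
  ord <- order(col_or_zero("pocket_score", -1), col_or_zero("mean_ssd"),
               col_or_zero("coverage_pct", -1), rk$template_id)
  structure(list(stages = stages, metrics = metrics,
                 ranking = rk$template_id[ord],
                 stage_empty = length(final_ids) == 0L, config = cfg),
            class = "selection_report")
}

#' Write a selection report as CSV (+ JSON manifest)
#'
#' Deterministic output: fixed column order, sorted rows, no timestamps.
#'
#' @param report [run_selection()] result.
#' @param out_dir output directory (created if needed).
#' @param seed seed recorded in the manifest.
#' @return invisibly, the paths written.
#' @export
write_selection_report <- function(report, out_dir, seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "selection_metrics.csv")
  m <- report$metrics
  num <- vapply(m, is.numeric, NA)
  m[num] <- lapply(m[num], function(x) round(x, 6))
  utils::write.csv(m, csv, row.names = FALSE, quote = FALSE)
  manifest <- file.path(out_dir, "selection_manifest.json")
  jsonlite::write_json(
    list(tool = "olfscreen", report = "select-template", seed = seed,
         config = report$config, stages = report$stages,
         ranking = report$ranking, stage_empty = report$stage_empty),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, manifest = manifest))
}

#' Run the stage-1 APF screen
#'
#' Builds a consensus pharmacophore from the actives (each active is
#' superposed onto the designated template active by APF superposition),
#' screens the library, and returns the hit table plus a provenance block.
#'
#' @param actives list of `ligand` objects with conformers; the first (or
#'   the one named by `template_id`) is the superposition template.
#' @param library list of `ligand` objects to screen (may be empty).
#' @param config named list: `kernel_sigma` (1.0), `spacing` (0.5),
#'   `padding` (3.0), `fraction` (0.75), `presence_cutoff` (0.05),
#'   `n_restarts` (16), `threshold` (`NULL` = 95th percentile of the
#'   screened library's scores), `template_id` (`NULL` = first active).
#' @param seed RNG seed for superposition restarts.
#' @return list of class `stage1_result`: `hits` (see [screen()]),
#'   `pharmacophore`, `provenance`.
#' @export
run_stage1_screen <- function(actives, library, config = list(), seed = 0L) {
  cfg <- utils::modifyList(
    list(kernel_sigma = 1.0, spacing = 0.5, padding = 3.0, fraction = 0.75,
         presence_cutoff = 0.05, n_restarts = 16L, threshold = NULL,
         template_id = NULL), config)
  if (length(actives) < 2L) stop2("need >= 2 actives to build a consensus")
  ids <- vapply(actives, `[[`, "", "id")
  ti <- if (is.null(cfg$template_id)) 1L else match(cfg$template_id, ids)
  if (is.na(ti)) stop2("template active '%s' not found", cfg$template_id)
  template <- actives[[ti]]
  if (is.null(template$conformer))
    stop2("template active '%s' has no conformer", template$id)

  tpl_field <- build_field(list(template), cfg$kernel_sigma, cfg$spacing,
                           cfg$padding)
  posed <- lapply(seq_along(actives), function(k) {
    lig <- actives[[k]]
    if (k == ti) return(lig)
    sp <- superpose(lig, tpl_field, n_restarts = cfg$n_restarts,
                    seed = seed + 1000L + k)
    lig$conformer <- sp$coords
    lig
  })
  grid <- apf_grid(posed, cfg$spacing, cfg$padding)
  fields <- lapply(posed, function(l)
    build_field(list(l), cfg$kernel_sigma, cfg$spacing, cfg$padding,
                grid = grid))
  pharm <- consensus(fields, cfg$fraction, cfg$presence_cutoff)

  if (length(library)) {
    hits <- screen(library, pharm, threshold = cfg$threshold, seed = seed,
                   n_restarts = cfg$n_restarts)
    if (is.null(cfg$threshold)) {
      thr <- calibrate_threshold(hits$score, 0.95)
      hits$hit <- hits$score >= thr
      attr(hits, "threshold") <- thr
    }
  } else {
    hits <- structure(data.frame(ligand_id = character(0), score = numeric(0),
                                 n_atoms_outside_grid = integer(0),
                                 hit = logical(0)),
                      class = c("apf_hits", "data.frame"))
  }
  prov <- list(tool = "olfscreen", report = "apf-screen", seed = seed,
               template_active = template$id,
               n_actives = length(actives), n_library = length(library),
               kernel = list(form = "gaussian", sigma = cfg$kernel_sigma,
                             spacing = cfg$spacing, padding = cfg$padding),
               consensus = list(fraction = cfg$fraction,
                                presence_cutoff = cfg$presence_cutoff,
                                included = as.list(pharm$included)),
               threshold = attr(hits, "threshold"),
               n_restarts = cfg$n_restarts)
  structure(list(hits = hits, pharmacophore = pharm, provenance = prov),
            class = "stage1_result")
}

#' Write stage-1 screen outputs (hits CSV + provenance JSON)
#'
#' @param result [run_stage1_screen()] result.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
write_stage1_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "apf_hits.csv")
  h <- result$hits
  h$score <- round(h$score, 6)
  utils::write.csv(h, csv, row.names = FALSE, quote = FALSE)
  manifest <- file.path(out_dir, "apf_manifest.json")
  jsonlite::write_json(result$provenance, manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv = csv, manifest = manifest))
}
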