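## Embedded reference tables (checksummed) and synthetic-data generators.
##
## Generators are pure functions of their spec (seed included): the same
## spec always yields the same receptor or library, byte for byte.

fixture_files <- c(
  eisenberg = "eisenberg.tsv",
  gpcrtm = "gpcrtm_synthetic.tsv",
  orthosteric24 = "orthosteric24.tsv",
  or_important11 = "or_important11.tsv",
  known_or1a2_ligands = "known_or1a2_ligands_synthetic.tsv",
  mmgbsa_reference = "mmgbsa_reference_components.csv")

#' Load a bundled reference table
#'
#' Tables are checksummed against the package manifest at load time.  Note
#' that `gpcrtm` and `known_or1a2_ligands` are clearly-labelled synthetic
#' stand-ins (see the files' headers): the published GPCR substitution
#' matrix and the full 13-ligand list are not redistributable here.
#'
#' @param name one of `"eisenberg"`, `"gpcrtm"`, `"orthosteric24"`,
#'   `"or_important11"`, `"known_or1a2_ligands"`, `"mmgbsa_reference"`.
#' @return a data.frame, substitution matrix or [pocket_definition()]
#'   depending on the table.
#' @export
load_table <- function(name) {
  if (!name %in% names(fixture_files))
    stop2("unknown table '%s'; available: %s", name,
          paste(names(fixture_files), collapse = ", "))
  path <- system.file("extdata", fixture_files[[name]], package = "olfscreen")
  if (!nzchar(path)) stop2("bundled table file missing for '%s'", name)
  manifest <- utils::read.delim(
    system.file("extdata", "manifest.tsv", package = "olfscreen"),
    stringsAsFactors = FALSE)
  want <- manifest$md5[manifest$name == name]
  got <- unname(tools::md5sum(path))
  if (!length(want) || !identical(got, want))
    stop2("checksum mismatch for table '%s'", name)
  switch(name,
    eisenberg = utils::read.delim(path, comment.char = "#",
                                  stringsAsFactors = FALSE),
    gpcrtm = read_substitution_matrix(path, name = "GPCRtm-synthetic-standin"),
    orthosteric24 = pocket_definition(
      "orthosteric24",
      utils::read.delim(path, comment.char = "#",
                        colClasses = "character")$bw_position),
    or_important11 = pocket_definition(
      "or_important11",
      utils::read.delim(path, comment.char = "#",
                        colClasses = "character")$bw_position),
    known_or1a2_ligands = utils::read.delim(path, comment.char = "#",
                                            stringsAsFactors = FALSE),
    mmgbsa_reference = utils::read.csv(path, comment.char = "#",
                                       stringsAsFactors = FALSE))
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

HYDROPHILIC_POOL <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P", "H")

#' Synthetic receptor spec
#'
#' @param n_helices number of TM helices (7 for a GPCR).
#' @param helix_length_range inclusive range of helix lengths (min >= 11,
#'   the hydropathy window).
#' @param loop_length_range inclusive range of inter-helix loop lengths.
#' @param target_hydro target mean Eisenberg hydrophobicity per helix
#'   (scalar, recycled); must lie inside the scale's achievable range.
#' @param mutation_rate per-residue substitution probability when deriving a
#'   mutant from a base receptor (see [mutate_receptor()]).
#' @param seed RNG seed.
#' @return list of class `receptor_spec`.
#' @export
receptor_spec <- function(n_helices = 7L, helix_length_range = c(22L, 28L),
                          loop_length_range = c(8L, 16L),
                          target_hydro = 0.8, mutation_rate = 0,
                          seed = 1L) {
  if (min(helix_length_range) < 11L)
    stop2("helix lengths must be >= 11 (hydropathy window)")
  structure(list(n_helices = as.integer(n_helices),
                 helix_length_range = as.integer(helix_length_range),
                 loop_length_range = as.integer(loop_length_range),
                 target_hydro = target_hydro,
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "receptor_spec")
}

gen_helix <- function(L, target, scale, tol = 0.05, max_iter = 500L) {
  vals <- scale
  if (target < min(vals) || target > max(vals))
    stop2("infeasible hydrophobicity target %.2f (scale range %.2f..%.2f)",
          target, min(vals), max(vals))
  hydro_pool <- names(vals)[vals > 0.2]
  res <- sample(hydro_pool, L, replace = TRUE)
  for (i in seq_len(max_iter)) {
    m <- mean(vals[res])
    if (abs(m - target) <= tol) break
    j <- sample.int(L, 1)
    cand <- if (m < target) names(vals)[vals[res[j]] < vals]
            else names(vals)[vals[res[j]] > vals]
    if (length(cand)) res[j] <- sample(cand, 1)
  }
  if (abs(mean(vals[res]) - target) > 2 * tol)
    stop2("could not reach hydrophobicity target %.2f", target)
  paste(res, collapse = "")
}

#' Generate a synthetic TM receptor
#'
#' Seven (by default) hydrophobic helices with controlled mean Eisenberg
#' hydrophobicity, joined by hydrophilic loops; deterministic per seed.
#'
#' @param spec [receptor_spec()].
#' @param id sequence id.
#' @return list with `seq` ([receptor_sequence()]), `tms`
#'   ([tm_annotation()]), `anchors` (named vector, helix midpoints) and
#'   `spec`.
#' @export
make_receptor <- function(spec, id = sprintf("synthetic_receptor_s%d", spec$seed)) {
  scale_tab <- load_table("eisenberg")
  scale <- stats::setNames(scale_tab$hydrophobicity, scale_tab$residue)
  targets <- rep_len(spec$target_hydro, spec$n_helices)
  with_local_seed(spec$seed, {
    rlen <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)
    nterm <- paste(sample(HYDROPHILIC_POOL, rlen(c(10L, 18L)), TRUE), collapse = "")
    parts <- nterm
    starts <- integer(0); ends <- integer(0)
    pos <- nchar(nterm)
    for (h in seq_len(spec$n_helices)) {
      hl <- rlen(spec$helix_length_range)
      helix <- gen_helix(hl, targets[h], scale)
      starts <- c(starts, pos + 1L); ends <- c(ends, pos + hl)
      pos <- pos + hl
      loop <- paste(sample(HYDROPHILIC_POOL, rlen(spec$loop_length_range), TRUE),
                    collapse = "")
      parts <- c(parts, helix, if (h < spec$n_helices) loop)
      if (h < spec$n_helices) pos <- pos + nchar(loop)
    }
    cterm <- paste(sample(HYDROPHILIC_POOL, rlen(c(8L, 14L)), TRUE), collapse = "")
    residues <- paste(c(parts, cterm), collapse = "")
    helices <- paste0("TM", seq_len(spec$n_helices))
    tms <- tm_annotation(helices, starts, ends, nchar(residues))
    anchors <- stats::setNames((starts + ends) %/% 2L, helices)
    list(seq = receptor_sequence(id, residues, source = "synthetic generator"),
         tms = tms, anchors = anchors, spec = spec)
  })
}

#' Derive a mutant receptor
#'
#' Substitutes each residue independently with probability `rate` (uniform
#' over the other 19 canonical residues); annotation is preserved.
#'
#' @param receptor [make_receptor()] result (or compatible list).
#' @param rate per-residue substitution probability.
#' @param seed RNG seed.
#' @param id mutant id.
#' @return same shape as [make_receptor()].
#' @export
mutate_receptor <- function(receptor, rate, seed = 1L,
                            id = paste0(receptor$seq$id, "_mut")) {
  chars <- seq_chars(receptor$seq)
  with_local_seed(seed, {
    hit <- stats::runif(length(chars)) < rate
    chars[hit] <- vapply(chars[hit], function(r)
      sample(setdiff(AA_CANONICAL, r), 1), "")
  })
  out <- receptor
  out$seq <- receptor_sequence(id, paste(chars, collapse = ""),
                               source = sprintf("mutant rate=%g of %s", rate,
                                                receptor$seq$id))
  out
}

ACTIVE_TEMPLATE <- "O=CC({R})CCC=C(C)C"   # citronellal-like aldehyde scaffold
ACTIVE_DECOR <- c("C", "CC", "CCC", "CCCC", "CO", "CCO", "C(C)C", "CN",
                  "CCN", "C(C)O", "CCCO", "CC(C)C")
DECOY_TEMPLATES <- c(
  "{R}c1ccccc1", "OC(=O){R}", "{R}C(N)C(O)=O", "{R}c1ccc(O)cc1",
  "{R}C(=O)N", "{R}c1ccncc1", "OCC(O)C(O){R}", "{R}S(=O)(=O)O",
  "{R}N1CCOCC1", "{R}C1CCCCC1", "{R}c1ccco1", "{R}n1ccnc1",
  "NC(=O)N{R}", "O=C1CCCCC1{R}", "{R}OC(=O)C")
DECOY_DECOR <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CO", "CCO", "CCN",
                 "C(C)C", "CCCCCC")

#' Synthetic ligand-library spec
#'
#' @param scaffold active scaffold template containing the literal `{R}`
#'   decoration slot (default: a citronellal-like monoterpenoid aldehyde).
#' @param n_actives number of actives (>= 2; consensus needs two).
#' @param n_decoys number of decoys drawn from unrelated metabolite-like
#'   scaffolds.
#' @param seed RNG seed (controls decoration sampling and 3D embedding).
#' @return list of class `library_spec`.
#' @export
library_spec <- function(scaffold = ACTIVE_TEMPLATE, n_actives = 10L,
                         n_decoys = 90L, seed = 0L) {
  if (n_actives < 2L) stop2("n_actives must be >= 2")
  structure(list(scaffold = scaffold, n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed)),
            class = "library_spec")
}

library_smiles <- function(spec) {
  with_local_seed(spec$seed, {
    dec <- if (spec$n_actives <= length(ACTIVE_DECOR))
      sample(ACTIVE_DECOR, spec$n_actives)
    else sample(ACTIVE_DECOR, spec$n_actives, replace = TRUE)
    actives <- vapply(dec, function(d)
      sub("{R}", d, spec$scaffold, fixed = TRUE), "")
    combos <- expand.grid(tpl = DECOY_TEMPLATES, dec = DECOY_DECOR,
                          stringsAsFactors = FALSE)
    pick <- sample.int(nrow(combos), spec$n_decoys,
                       replace = spec$n_decoys > nrow(combos))
    decoys <- vapply(pick, function(i)
      sub("{R}", combos$dec[i], combos$tpl[i], fixed = TRUE), "")
    data.frame(
      id = c(sprintf("active_%02d", seq_len(spec$n_actives)),
             sprintf("decoy_%02d", seq_len(spec$n_decoys))),
      smiles = c(actives, decoys),
      role = rep(c("active", "decoy"), c(spec$n_actives, spec$n_decoys)),
      stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic active/decoy library with 3D conformers
#'
#' Actives share the scaffold with small decorations; decoys come from
#' unrelated metabolite-like scaffolds.  Conformers are generated by seeded
#' distance-geometry embedding (RDKit ETKDG); the embedder and seed are
#' recorded in SDF output.  Deterministic per seed.
#'
#' @param spec [library_spec()].
#' @param sdf_path optional path: also write the library as an SDF V2000
#'   file with 3D coordinates (byte-identical for a given spec).
#' @return list with `actives` and `decoys` (lists of `ligand` objects with
#'   conformers) and `table` (id/smiles/role data.frame).
#' @export
make_library <- function(spec, sdf_path = NULL) {
  tab <- library_smiles(spec)
  smi <- tempfile(fileext = ".smi")
  on.exit(unlink(smi), add = TRUE)
  writeLines(paste(tab$smiles, tab$id), smi)
  payload <- chem_featurize(smi, "smiles", embed3d = TRUE, seed = spec$seed)
  ligs <- ligands_from_payload(payload, "synthetic library")
  if (!is.null(sdf_path)) chem_embed_sdf(smi, sdf_path, seed = spec$seed)
  ids <- vapply(ligs, `[[`, "", "id")
  list(actives = ligs[ids %in% tab$id[tab$role == "active"]],
       decoys = ligs[ids %in% tab$id[tab$role == "decoy"]],
       table = tab)
}
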