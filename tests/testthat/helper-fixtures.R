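# Session-cached fixtures (the RDKit sidecar costs ~1 s per batch call, so
# shared molecule sets are built once per test run).

.fx_cache <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- builder()
  .fx_cache[[key]]
}

fx_small_library <- function() {
  fx_cached("lib_small", function()
    make_library(library_spec(n_actives = 4, n_decoys = 6, seed = 0)))
}

fx_receptor <- function() {
  fx_cached("receptor1", function() make_receptor(receptor_spec(seed = 1)))
}

# Receptor with helices long enough to resolve all 24 orthosteric positions
# (anchor at midpoint of a 45-residue helix spans BW 28..58 comfortably).
fx_wide_receptor <- function() {
  fx_cached("receptor_wide", function()
    make_receptor(receptor_spec(helix_length_range = c(45L, 45L), seed = 3),
                  id = "wide_receptor"))
}

# One-heavy-atom pseudo-ligand with a chosen 7-channel property vector;
# bypasses the chemistry backend so grid arithmetic can be pinned exactly.
fx_point_ligand <- function(id, xyz, phi) {
  atoms <- as.data.frame(as.list(stats::setNames(phi, olfscreen:::APF_CHANNELS)))
  atoms$element <- "C"
  structure(list(id = id, smiles = NA_character_, atoms = atoms,
                 conformer = matrix(xyz, 1, 3),
                 fp_bits = integer(0), fp_scheme = "none", fp_nbits = 0L),
            class = "ligand")
}

fx_blosum62 <- function() {
  fx_cached("blosum62", function() {
    env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
    env$BLOSUM62
  })
}

random_aa_string <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Synthetic template-candidate cascade: a designed winner (near-identical
# helices to the target) plus progressively scrambled decoys.
make_candidate_set <- function(target, n = 5L, rates = NULL, res = NULL,
                               states = NULL) {
  rates <- rates %||% seq(0, 0.6, length.out = n)
  res <- res %||% rep(2.0, n)
  states <- states %||% rep("inactive", n)
  lapply(seq_len(n), function(i) {
    mut <- mutate_receptor(target, rates[i], seed = 100 + i,
                           id = sprintf("tpl%02d", i))
    template_candidate(sprintf("tpl%02d", i), sprintf("receptor%02d", i),
                       res[i], states[i], mut$seq, mut$tms, mut$anchors)
  })
}
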