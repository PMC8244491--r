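# Independent oracles: deliberately naive re-implementations (plain loops,
# no shared code with the package internals) used to pin expected values.

# Gotoh affine-gap global alignment, returning the optimal score.  Gap model
# matches the documented convention: first gap position costs open + extend,
# each further position costs extend.
oracle_nw_score <- function(a, b, mat, open = 10, extend = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in B (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in A (B consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - extend * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend,
                     Y[i - 1, j] - open - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend,
                     X[i, j - 1] - open - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

oracle_window_profile <- function(helix, scale, window = 11L) {
  chars <- strsplit(helix, "")[[1]]
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(length(chars) - half)
  vapply(centers, function(n) {
    s <- 0
    for (i in (n - half):(n + half)) s <- s + scale[[chars[i]]]
    s / window
  }, 0)
}

oracle_ssd <- function(vals_template, vals_target) {
  s <- 0
  for (k in seq_along(vals_template))
    s <- s + (vals_template[k] - vals_target[k])^2
  unname(s)
}

# Naive Gaussian field accumulation at a single grid node.
oracle_field_value <- function(ligands, node_xyz, channel_idx, sigma,
                               cutoff_sd = 4.0) {
  total <- 0
  for (lig in ligands) {
    phi <- assign_properties(lig)
    xyz <- lig$conformer
    for (a in seq_len(nrow(xyz))) {
      d2 <- sum((node_xyz - xyz[a, ])^2)
      if (d2 <= (cutoff_sd * sigma)^2)
        total <- total + phi[a, channel_idx] * exp(-d2 / (2 * sigma^2))
    }
  }
  unname(total / length(ligands))
}

# Nearest-node pseudo-energy (no interpolation): exact when atoms sit on
# grid nodes.
oracle_energy_nearest <- function(field, coords, phi) {
  E <- 0
  for (a in seq_len(nrow(coords))) {
    ijk <- round((coords[a, ] - field$origin) / field$spacing) + 1
    if (any(ijk < 1) || any(ijk > field$dims)) next
    for (ch in seq_along(field$channels))
      E <- E - phi[a, ch] * field$data[ijk[1], ijk[2], ijk[3], ch]
  }
  unname(E)
}

# Exhaustive per-column minima of a correspondence table.
oracle_column_minima <- function(ct) {
  winners <- character(0)
  for (h in paste0("TM", 1:7)) {
    best <- Inf; ids <- character(0)
    for (r in seq_len(nrow(ct))) {
      v <- ct[[h]][r]
      if (v < best - 1e-12) { best <- v; ids <- ct$template_id[r] }
      else if (abs(v - best) <= 1e-12) ids <- c(ids, ct$template_id[r])
    }
    winners <- c(winners, ids)
  }
  sort(unique(winners))
}
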