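## Atomic-property-field (APF) pharmacophore engine.
##
## Seven channels per heavy atom -- hydrogen-bond donor, acceptor, sp2
## hybridisation, lipophilicity, size, electronegativity and partial charge
## -- are splatted onto a regular 3D grid with an isotropic Gaussian kernel
## (G(0) = 1, default sigma 1.0 A, spacing 0.5 A, padding 3.0 A).  A pose is
## scored by the pseudo-energy E = -sum_j sum_i phi_i^j P_i(r_j) with
## trilinear interpolation; the reported score is S = -E, so larger is
## better.  A consensus pharmacophore keeps only channels exhibited by a
## configurable fraction (default 75%) of the contributing ligands.

APF_CHANNELS <- c("donor", "acceptor", "sp2", "lipophilicity", "size",
                  "electronegativity", "charge")

#' Per-atom APF property vectors of a ligand
#'
#' Properties are perceived at parse time by the RDKit backend (Lipinski-style
#' donors/acceptors, perceived sp2 hybridisation, Crippen atomic logP,
#' normalised van der Waals volume, Pauling electronegativity relative to
#' carbon, Gasteiger partial charge with hydrogens merged).
#'
#' @param ligand a `ligand` object.
#' @return numeric matrix, heavy atoms x 7 named channels.
#' @export
assign_properties <- function(ligand) {
  if (!inherits(ligand, "ligand")) stop2("not a ligand object")
  if (is.null(ligand$atoms)) stop2("ligand '%s' has no perceived atoms", ligand$id)
  m <- as.matrix(ligand$atoms[, APF_CHANNELS])
  rownames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

ligand_coords <- function(ligand) {
  if (is.null(ligand$conformer))
    stop2("ligand '%s' has no 3D conformer", ligand$id)
  ligand$conformer
}

#' Grid geometry covering a set of ligands
#'
#' @param ligands list of `ligand` objects with conformers.
#' @param spacing grid spacing in Angstrom.
#' @param padding margin added around the atom bounding box, Angstrom.
#' @return list with `origin`, `spacing`, `dims` (nx, ny, nz).
#' @export
apf_grid <- function(ligands, spacing = 0.5, padding = 3.0) {
  coords <- do.call(rbind, lapply(ligands, ligand_coords))
  lo <- apply(coords, 2, min) - padding
  hi <- apply(coords, 2, max) + padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  list(origin = unname(lo), spacing = spacing, dims = unname(dims))
}

#' Build a seven-channel property field
#'
#' `P_i(r) = (1/n_ligands) * sum_atoms phi_i * exp(-|r - r_atom|^2 / 2
#' sigma^2)` on a regular grid covering all atoms plus padding.
#'
#' @param ligands non-empty list of aligned `ligand` objects with conformers.
#' @param kernel_sigma Gaussian width, Angstrom.
#' @param spacing grid spacing, Angstrom.
#' @param padding grid margin, Angstrom.
#' @param grid optional precomputed geometry (see [apf_grid()]) so several
#'   fields share identical geometry.
#' @param cutoff_sd kernel truncation radius in standard deviations.
#' @return object of class `property_field`: `origin`, `spacing`, `dims`,
#'   `data` (4D array nx x ny x nz x 7), `channels`, `kernel_sigma`,
#'   `n_ligands`.
#' @export
build_field <- function(ligands, kernel_sigma = 1.0, spacing = 0.5,
                        padding = 3.0, grid = NULL, cutoff_sd = 4.0) {
  if (!length(ligands)) stop2("empty ligand list")
  if (kernel_sigma <= 0 || spacing <= 0) stop2("sigma and spacing must be > 0")
  if (is.null(grid)) grid <- apf_grid(ligands, spacing, padding)
  dims4 <- c(grid$dims, length(APF_CHANNELS))
  acc <- numeric(prod(dims4))
  for (lig in ligands) {
    acc <- acc + cpp_accumulate_field(
      as.integer(dims4), as.numeric(grid$origin), grid$spacing,
      ligand_coords(lig), assign_properties(lig), kernel_sigma, cutoff_sd)
  }
  structure(list(origin = grid$origin, spacing = grid$spacing,
                 dims = grid$dims,
                 data = array(acc / length(ligands), dim = dims4),
                 channels = APF_CHANNELS, kernel_sigma = kernel_sigma,
                 n_ligands = length(ligands)),
            class = "property_field")
}

#' @export
print.property_field <- function(x, ...) {
  cat(sprintf("<property_field> %d x %d x %d @ %.2f A, sigma %.2f, %d ligand(s)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$kernel_sigma,
              x$n_ligands))
  invisible(x)
}

#' Consensus pharmacophore from per-ligand fields
#'
#' A channel is included iff the number of ligands "exhibiting" it (their
#' per-ligand field exceeds `presence_cutoff` x the channel's global maximum
#' somewhere on the grid, in absolute value) reaches
#' `ceiling(fraction * n_ligands)`.  The consensus field is the mean of the
#' per-ligand fields with excluded channels zeroed.
#'
#' @param fields list of >= 2 [build_field()] results on identical geometry
#'   (build them with a shared `grid`).
#' @param fraction inclusion fraction, default 0.75.
#' @param presence_cutoff relative presence threshold, default 0.05.
#' @return object of class `pharmacophore`: a `property_field` plus
#'   `included` (named logical per channel), `n_contributing` (named integer
#'   per channel), `fraction`, `presence_cutoff`.
#' @export
consensus <- function(fields, fraction = 0.75, presence_cutoff = 0.05) {
  if (length(fields) < 2L) stop2("consensus needs >= 2 per-ligand fields")
  geo <- function(f) list(f$origin, f$spacing, f$dims)
  for (f in fields[-1])
    if (!isTRUE(all.equal(geo(f), geo(fields[[1]]))))
      stop2("field geometry mismatch; build per-ligand fields on a shared grid")
  n <- length(fields)
  nch <- length(APF_CHANNELS)
  chan_max <- vapply(seq_len(nch), function(ch)
    max(vapply(fields, function(f) max(abs(f$data[, , , ch])), 0)), 0)
  presence <- vapply(seq_len(nch), function(ch) {
    if (chan_max[ch] == 0) return(0L)
    sum(vapply(fields, function(f)
      max(abs(f$data[, , , ch])) > presence_cutoff * chan_max[ch], NA))
  }, 0L)
  included <- presence >= ceiling(fraction * n)
  names(included) <- names(presence) <- APF_CHANNELS
  mean_data <- Reduce(`+`, lapply(fields, `[[`, "data")) / n
  for (ch in which(!included)) mean_data[, , , ch] <- 0
  structure(list(origin = fields[[1]]$origin, spacing = fields[[1]]$spacing,
                 dims = fields[[1]]$dims, data = mean_data,
                 channels = APF_CHANNELS,
                 kernel_sigma = fields[[1]]$kernel_sigma,
                 n_ligands = n, included = included,
                 n_contributing = presence, fraction = fraction,
                 presence_cutoff = presence_cutoff),
            class = c("pharmacophore", "property_field"))
}

#' APF pseudo-energy of a pose
#'
#' @param ligand a `ligand` with conformer, or a list with `coords` (n x 3)
#'   and `phi` (n x 7).
#' @param field a `property_field` or `pharmacophore`.
#' @return object of class `apf_score`: `energy` (E), `score` (S = -E),
#'   `per_channel` (terms summing to E), `n_outside` (atoms outside the
#'   grid, contributing zero).  Errors if every atom lies outside.
#' @export
apf_energy <- function(ligand, field) {
  if (inherits(ligand, "ligand")) {
    coords <- ligand_coords(ligand)
    phi <- assign_properties(ligand)
  } else {
    coords <- ligand$coords
    phi <- ligand$phi
  }
  res <- cpp_apf_energy(as.numeric(field$data),
                        as.integer(c(field$dims, length(field$channels))),
                        as.numeric(field$origin), field$spacing, coords, phi)
  if (res$n_outside >= nrow(coords))
    stop2("no atoms inside the field grid")
  per_channel <- stats::setNames(-res$overlap, field$channels)
  structure(list(energy = sum(per_channel), score = -sum(per_channel),
                 per_channel = per_channel, n_outside = res$n_outside),
            class = "apf_score")
}

## ---- rigid transforms ---------------------------------------------------

#' Rigid transform
#'
#' @param rotation 3 x 3 orthonormal matrix, det +1 (tolerance 1e-6).
#' @param translation length-3 vector, Angstrom.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (!isTRUE(all.equal(crossprod(rotation), diag(3), tolerance = 1e-6)) ||
      abs(det(rotation) - 1) > 1e-6)
    stop2("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param transform [rigid_transform()].
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(coords %*% t(transform$rotation), 2, transform$translation, `+`)
}

rotation_from_axis_angle <- function(w) {
  theta <- sqrt(sum(w^2))
  if (theta < 1e-12) return(diag(3))
  k <- w / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## Uniform rotation on SO(3) from a unit quaternion (Shoemake's method).
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

## Pose parameterisation: x' = R(w) (x - centroid) + centroid + t,
## params = c(w, t).
pose_coords <- function(coords, centroid, par) {
  R <- rotation_from_axis_angle(par[1:3])
  sweep(sweep(coords, 2, centroid) %*% t(R), 2, centroid + par[4:6], `+`)
}

## Flattened-field context reused across many pose evaluations (avoids
## copying the grid array on every objective call).
field_ctx <- function(field) {
  list(fl = as.numeric(field$data),
       dims4 = as.integer(c(field$dims, length(field$channels))),
       origin = as.numeric(field$origin), spacing = field$spacing)
}

pose_score <- function(coords, phi, centroid, par, ctx) {
  res <- cpp_apf_energy(ctx$fl, ctx$dims4, ctx$origin, ctx$spacing,
                        pose_coords(coords, centroid, par), phi)
  sum(res$overlap)   # score S = -E
}

## Cyclic coordinate descent over the 6 pose parameters.
refine_pose <- function(coords, phi, centroid, par, ctx,
                        rot_step = 0.25, trans_step = 0.5,
                        rot_tol = 0.005, trans_tol = 0.02, max_cycles = 60L) {
  best <- pose_score(coords, phi, centroid, par, ctx)
  steps <- c(rep(rot_step, 3), rep(trans_step, 3))
  tols <- c(rep(rot_tol, 3), rep(trans_tol, 3))
  for (cyc in seq_len(max_cycles)) {
    improved <- FALSE
    for (p in 1:6) {
      repeat {
        cand_up <- par; cand_up[p] <- par[p] + steps[p]
        cand_dn <- par; cand_dn[p] <- par[p] - steps[p]
        s_up <- pose_score(coords, phi, centroid, cand_up, ctx)
        s_dn <- pose_score(coords, phi, centroid, cand_dn, ctx)
        if (s_up > best && s_up >= s_dn) {
          par <- cand_up; best <- s_up; improved <- TRUE
        } else if (s_dn > best) {
          par <- cand_dn; best <- s_dn; improved <- TRUE
        } else break
      }
    }
    if (!improved) {
      steps <- steps / 2
      if (all(steps < tols)) break
    }
  }
  list(par = par, score = best)
}

#' Superpose a ligand onto a pharmacophore
#'
#' Rigid-body pose optimisation: the input pose plus `n_restarts` random
#' initial poses (rotations uniform over SO(3); translations centring the
#' ligand on the field with Gaussian jitter) are each refined by cyclic
#' coordinate descent over the six pose parameters; the best-scoring pose
#' wins.  Deterministic for a fixed seed.  `n_restarts = 0` returns the
#' input pose unrefined.
#'
#' @param ligand `ligand` with conformer.
#' @param pharmacophore `property_field` or `pharmacophore`.
#' @param n_restarts number of random restarts.
#' @param seed RNG seed.
#' @return list of class `superposition`: `transform` ([rigid_transform()]
#'   mapping the input pose to the best pose), `score` ([apf_energy()] of
#'   the best pose), `coords` (posed coordinates).
#' @export
superpose <- function(ligand, pharmacophore, n_restarts = 32L, seed = 0L) {
  coords <- ligand_coords(ligand)
  phi <- assign_properties(ligand)
  centroid <- colMeans(coords)
  eval_final <- function(par) {
    posed <- pose_coords(coords, centroid, par)
    list(par = par, posed = posed,
         score = apf_energy(list(coords = posed, phi = phi), pharmacophore))
  }
  if (n_restarts == 0L) {
    out <- eval_final(rep(0, 6))
  } else {
    field_center <- pharmacophore$origin +
      (pharmacophore$dims - 1) * pharmacophore$spacing / 2
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    starts <- c(list(rep(0, 6)), lapply(seq_len(n_restarts - 1L), function(i) {
      R <- random_rotation()
      ## axis-angle of R
      theta <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
      w <- if (theta < 1e-8) c(0, 0, 0) else
        theta / (2 * sin(theta)) *
          c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
      c(w, field_center - centroid + stats::rnorm(3, 0, 1.0))
    }))
    ctx <- field_ctx(pharmacophore)
    best <- NULL
    for (st in starts) {
      r <- refine_pose(coords, phi, centroid, st, ctx)
      if (is.null(best) || r$score > best$score) best <- r
    }
    out <- eval_final(best$par)
  }
  structure(list(
    transform = rigid_transform(rotation_from_axis_angle(out$par[1:3]),
                                out$par[4:6] + centroid -
                                  rotation_from_axis_angle(out$par[1:3]) %*% centroid),
    score = out$score, coords = out$posed, ligand_id = ligand$id),
    class = "superposition")
}

#' Screen a ligand library against a pharmacophore
#'
#' Each library ligand is superposed ([superpose()]) and its best score
#' recorded; the table is sorted by descending score with ties broken by
#' ligand id.  Ligands lacking conformers are skipped with a warning.
#'
#' @param library non-empty list of `ligand` objects.
#' @param pharmacophore `pharmacophore` or `property_field`.
#' @param threshold absolute hit threshold on the score `S`; `NULL` marks no
#'   hits (callers typically calibrate one, e.g. a decoy-score quantile --
#'   see [calibrate_threshold()]).
#' @param seed base RNG seed; ligand k uses `seed + k` so results do not
#'   depend on library order pairings.
#' @param n_restarts restarts per ligand.
#' @return data.frame of class `apf_hits` with columns `ligand_id`, `score`,
#'   `n_atoms_outside_grid`, `hit`; attribute `threshold`.
#' @export
screen <- function(library, pharmacophore, threshold = NULL, seed = 0L,
                   n_restarts = 16L) {
  if (!length(library)) stop2("empty library")
  has_conf <- vapply(library, function(l) !is.null(l$conformer), NA)
  if (any(!has_conf))
    warning(sprintf("%d ligand(s) without conformers skipped: %s",
                    sum(!has_conf),
                    paste(vapply(library[!has_conf], `[[`, "", "id"),
                          collapse = ", ")), call. = FALSE)
  lib <- library[has_conf]
  rows <- lapply(seq_along(lib), function(k) {
    sp <- superpose(lib[[k]], pharmacophore, n_restarts = n_restarts,
                    seed = seed + k)
    data.frame(ligand_id = lib[[k]]$id, score = sp$score$score,
               n_atoms_outside_grid = sp$score$n_outside,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$ligand_id), , drop = FALSE]
  rownames(out) <- NULL
  out$hit <- if (is.null(threshold)) FALSE else out$score >= threshold
  attr(out, "threshold") <- threshold
  class(out) <- c("apf_hits", "data.frame")
  out
}

#' Calibrate a screening threshold from decoy scores
#'
#' The default operating point is the 95th percentile of decoy scores on a
#' synthetic benchmark (the absolute score scale depends on the kernel, so a
#' fixed literature cutoff does not transfer).
#'
#' @param decoy_scores numeric vector of decoy scores.
#' @param quantile quantile used, default 0.95.
#' @return scalar threshold.
#' @export
calibrate_threshold <- function(decoy_scores, quantile = 0.95) {
  stats::quantile(decoy_scores, quantile, names = FALSE, type = 7)
}

#' Save / load a pharmacophore as JSON (text, self-describing header)
#'
#' @param field `property_field` or `pharmacophore`.
#' @param path output file.
#' @return `path` (write) or the reconstructed object (read).
#' @export
write_pharmacophore <- function(field, path) {
  obj <- list(header = list(origin = field$origin, spacing = field$spacing,
                            shape = field$dims, channels = field$channels,
                            kernel_sigma = field$kernel_sigma,
                            n_ligands = field$n_ligands,
                            included = as.list(field$included %||% NULL),
                            fraction = field$fraction %||% NULL),
              data = as.numeric(field$data))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pharmacophore
#' @export
read_pharmacophore <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  h <- obj$header
  out <- list(origin = h$origin, spacing = h$spacing, dims = h$shape,
              data = array(obj$data, dim = c(h$shape, length(h$channels))),
              channels = h$channels, kernel_sigma = h$kernel_sigma,
              n_ligands = h$n_ligands)
  cls <- "property_field"
  if (length(h$included)) {
    out$included <- unlist(h$included)
    out$fraction <- h$fraction
    cls <- c("pharmacophore", cls)
  }
  structure(out, class = cls)
}
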