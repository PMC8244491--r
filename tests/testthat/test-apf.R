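test_that("atom property perception: definitional cases", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CO methanol", "c1ccccc1 benzene"), f)
  ligs <- read_ligands(f, "smiles")
  meth <- assign_properties(ligs[[1]])
  o_row <- which(ligs[[1]]$atoms$element == "O")
  expect_equal(unname(meth[o_row, "donor"]), 1)
  expect_equal(unname(meth[o_row, "acceptor"]), 1)
  benz <- assign_properties(ligs[[2]])
  expect_true(all(benz[, "sp2"] == 1))
  expect_true(all(benz[, "donor"] == 0))
  expect_true(all(benz[, "acceptor"] == 0))
  expect_true(all(benz[, "size"] == 1))   # carbons, normalised to C

  ## channel sums agree with an independent re-perception pass
  ligs2 <- read_ligands(f, "smiles")
  expect_equal(colSums(assign_properties(ligs2[[1]])), colSums(meth),
               tolerance = 1e-9)
})

test_that("field construction matches direct summation", {
  ## unit-donor point atom on a grid node: peak value G(0) = 1
  lig <- fx_point_ligand("pt", c(0, 0, 0), c(1, 0, 0, 0, 0, 0, 0))
  f <- build_field(list(lig), kernel_sigma = 1, spacing = 0.5, padding = 3)
  don <- f$data[, , , 1]
  expect_equal(max(don), 1)
  peak <- which(don == max(don), arr.ind = TRUE)
  node <- f$origin + (peak[1, ] - 1) * f$spacing
  expect_equal(unname(node), c(0, 0, 0))

  ## two identical superimposed ligands: same field as one (per-ligand mean)
  f2 <- build_field(list(lig, lig), kernel_sigma = 1, spacing = 0.5,
                    padding = 3)
  expect_equal(f2$data, f$data, tolerance = 1e-12)

  ## two-atom toy on a coarse grid vs naive double loop at every node
  ligA <- fx_point_ligand("a", c(0.3, -0.2, 0.6),
                          c(1, 0, 0, 0.8, 1.2, -0.3, 0.1))
  ligB <- fx_point_ligand("b", c(-0.9, 0.4, -0.1),
                          c(0, 1, 1, -0.5, 0.9, 0.2, -0.2))
  fc <- build_field(list(ligA, ligB), kernel_sigma = 0.8, spacing = 1.0,
                    padding = 2.0)
  for (ch in c(1L, 4L, 7L)) {
    for (node in list(c(1, 1, 1), c(3, 2, 4), fc$dims)) {
      xyz <- fc$origin + (node - 1) * fc$spacing
      expect_equal(fc$data[node[1], node[2], node[3], ch],
                   oracle_field_value(list(ligA, ligB), xyz, ch, 0.8),
                   tolerance = 1e-9)
    }
  }

  expect_error(build_field(list()), "empty ligand list")
})

test_that("consensus: ceiling arithmetic and channel masking", {
  mk_fields <- function(present) {  # logical vector over ligands: donor on?
    grid <- list(origin = c(0, 0, 0), spacing = 1, dims = c(4L, 4L, 4L))
    lapply(present, function(on)
      build_field(list(fx_point_ligand("p", c(1.5, 1.5, 1.5),
                                       c(as.numeric(on), 0, 0, 1, 0, 0, 0))),
                  kernel_sigma = 1, grid = grid))
  }
  ## 4 ligands, channel in 3 -> included (3 >= ceil(0.75*4) = 3)
  ph <- consensus(mk_fields(c(TRUE, TRUE, TRUE, FALSE)))
  expect_true(ph$included[["donor"]])
  ## 4 ligands, channel in 2 -> excluded
  ph2 <- consensus(mk_fields(c(TRUE, TRUE, FALSE, FALSE)))
  expect_false(ph2$included[["donor"]])
  expect_true(all(ph2$data[, , , 1] == 0))          # masked channel zeroed
  expect_true(ph2$included[["lipophilicity"]])      # present in all
  ## 13 ligands: present in 9 -> excluded; in 10 -> included
  ph9 <- consensus(mk_fields(rep(c(TRUE, FALSE), c(9, 4))))
  expect_false(ph9$included[["donor"]])
  ph10 <- consensus(mk_fields(rep(c(TRUE, FALSE), c(10, 3))))
  expect_true(ph10$included[["donor"]])
  ## raising the fraction never adds channels
  for (fr in c(0.5, 0.75, 0.9, 1)) {
    inc_lo <- consensus(mk_fields(rep(c(TRUE, FALSE), c(10, 3))), fraction = fr)
    if (fr > 0.5)
      expect_true(all(inc_lo$included <= prev_inc))
    prev_inc <- inc_lo$included
  }
  ## geometry mismatch is an error
  ga <- build_field(list(fx_point_ligand("p", c(0, 0, 0), rep(1, 7))),
                    spacing = 0.5)
  gb <- build_field(list(fx_point_ligand("p", c(9, 9, 9), rep(1, 7))),
                    spacing = 0.5)
  expect_error(consensus(list(ga, gb)), "geometry mismatch")
})

test_that("pseudo-energy: exact node cases, oracle, linearity", {
  ## all-zero field -> E = 0
  zero <- structure(list(origin = c(0, 0, 0), spacing = 1, dims = c(3L, 3L, 3L),
                         data = array(0, c(3, 3, 3, 7)),
                         channels = olfscreen:::APF_CHANNELS,
                         kernel_sigma = 1, n_ligands = 1),
                    class = "property_field")
  lig <- fx_point_ligand("pt", c(1, 1, 1), c(1, 0, 0, 0, 0, 0, 0))
  s0 <- apf_energy(lig, zero)
  expect_equal(s0$energy, 0)
  expect_equal(s0$score, 0)

  ## unit phi at a node where P_i = p -> E = -p
  f <- zero
  f$data[2, 2, 2, 1] <- 0.73
  s1 <- apf_energy(lig, f)
  expect_equal(s1$energy, -0.73)
  expect_equal(s1$score, 0.73)
  expect_equal(sum(s1$per_channel), s1$energy)

  ## atoms exactly on nodes: trilinear equals the nearest-node oracle
  ligA <- fx_point_ligand("a", c(1, 0, 2), c(1, 0, 1, 0.5, 1, -0.2, 0.1))
  ligB <- fx_point_ligand("b", c(2, 1, 1), c(0, 1, 0, -0.3, 1.1, 0.4, -0.5))
  fld <- build_field(list(ligA, ligB), kernel_sigma = 0.9, spacing = 1,
                     padding = 2)
  both <- list(coords = rbind(ligA$conformer, ligB$conformer),
               phi = rbind(assign_properties(ligA), assign_properties(ligB)))
  got <- apf_energy(both, fld)
  expect_equal(got$energy,
               oracle_energy_nearest(fld, both$coords, both$phi),
               tolerance = 1e-9)

  ## linearity over disjoint atom subsets
  ea <- apf_energy(ligA, fld)$energy
  eb <- apf_energy(ligB, fld)$energy
  expect_equal(got$energy, ea + eb, tolerance = 1e-9)

  ## atoms outside the grid: counted, zero contribution; all-out errors
  out1 <- list(coords = rbind(c(1, 1, 1), c(99, 99, 99)),
               phi = rbind(rep(1, 7), rep(1, 7)))
  r <- apf_energy(out1, fld)
  expect_equal(r$n_outside, 1L)
  allout <- list(coords = matrix(99, 1, 3), phi = matrix(1, 1, 7))
  expect_error(apf_energy(allout, fld), "no atoms inside")
})

test_that("energy is invariant under rigid motion of ligand + field frame", {
  lib <- fx_small_library()
  a <- lib$actives[[1]]
  f <- build_field(list(a), kernel_sigma = 1, spacing = 0.4)
  e0 <- apf_energy(a, f)$energy

  ## translation by an exact multiple of the spacing: shift both
  tr <- rigid_transform(diag(3), c(2.0, -1.2, 0.8))
  a_t <- a; a_t$conformer <- apply_transform(a$conformer, tr)
  f_t <- f; f_t$origin <- f$origin + tr$translation
  expect_equal(apf_energy(a_t, f_t)$energy, e0, tolerance = 1e-9)

  ## general rotation: rebuild the field in the rotated frame
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr2 <- rigid_transform(R, c(1.1, 0.3, -0.6))
  a_r <- a; a_r$conformer <- apply_transform(a$conformer, tr2)
  f_r <- build_field(list(a_r), kernel_sigma = 1, spacing = 0.4)
  e_r <- apf_energy(a_r, f_r)$energy
  expect_equal(e_r, e0, tolerance = abs(e0) * 0.02)  # grid re-discretisation
})

test_that("superposition: self-recovery, zero restarts, determinism", {
  lib <- fx_small_library()
  a <- lib$actives[[2]]
  f <- build_field(list(a))
  inplace <- apf_energy(a, f)$score

  sp0 <- superpose(a, f, n_restarts = 0)
  expect_equal(sp0$score$score, inplace, tolerance = 1e-12)
  expect_equal(sp0$coords, a$conformer, tolerance = 1e-12)

  sp <- superpose(a, f, n_restarts = 4, seed = 2)
  expect_gte(sp$score$score, 0.98 * inplace)  # refinement from identity start

  sp_again <- superpose(a, f, n_restarts = 4, seed = 2)
  expect_identical(sp$score$score, sp_again$score$score)
  expect_identical(sp$coords, sp_again$coords)
})

test_that("screening: self-ranking, thresholds, byte determinism", {
  lib <- fx_small_library()
  a <- lib$actives[[1]]
  f <- build_field(list(a))
  pool <- c(lib$actives[1], lib$decoys[1:3])
  ht <- screen(pool, f, seed = 3, n_restarts = 6)
  expect_equal(ht$ligand_id[1], a$id)      # template tops its own field
  expect_true(all(diff(ht$score) <= 0))

  ht_thr <- screen(pool, f, threshold = max(ht$score) + 1, seed = 3,
                   n_restarts = 6)
  expect_equal(sum(ht_thr$hit), 0L)

  ht2 <- screen(pool, f, seed = 3, n_restarts = 6)
  expect_identical(ht, ht2)

  ## conformer-less ligands are skipped with a warning
  noconf <- lib$actives[[3]]; noconf$conformer <- NULL
  expect_warning(screen(c(pool, list(noconf)), f, seed = 3, n_restarts = 2),
                 "without conformers")
})

test_that("pharmacophore JSON round-trip preserves geometry and data", {
  grid <- list(origin = c(0, 0, 0), spacing = 1, dims = c(4L, 4L, 4L))
  flds <- lapply(1:2, function(i)
    build_field(list(fx_point_ligand("p", c(1.5, 1.5, 1.5),
                                     c(1, 0, 0, 1, 0, 0, 0))),
                kernel_sigma = 1, grid = grid))
  ph <- consensus(flds)
  path <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore(ph, path)
  back <- read_pharmacophore(path)
  expect_s3_class(back, "pharmacophore")
  expect_equal(back$data, ph$data, tolerance = 1e-12)
  expect_equal(back$origin, ph$origin)
  expect_equal(unname(back$included), unname(ph$included))
})
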