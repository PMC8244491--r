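scale <- hydro_scale()

test_that("windowed profile: constant helices and brute-force oracle", {
  p <- windowed_profile(strrep("L", 11), scale)
  expect_length(p, 1L)
  expect_equal(as.numeric(p), unname(scale[["L"]]))

  for (L in c(12L, 20L, 31L)) {
    p <- windowed_profile(strrep("V", L), scale)
    expect_length(p, L - 10L)
    expect_true(all(abs(unclass(p) - scale[["V"]]) < 1e-12))
  }

  set.seed(21)
  for (k in 1:20) {
    helix <- random_aa_string(sample(11:25, 1))
    p <- windowed_profile(helix, scale)
    expect_equal(as.numeric(p), oracle_window_profile(helix, scale),
                 tolerance = 1e-12)
    expect_true(all(unclass(p) >= min(scale) & unclass(p) <= max(scale)))
  }

  expect_error(windowed_profile(strrep("A", 10), scale, helix_id = "TM2"),
               "TM2")
})

test_that("SSD: zero, constant-offset algebra and naive-loop oracle", {
  h <- "ILVFAWGMILVCAPL"
  p <- windowed_profile(h, scale, helix_id = "TMx")
  pairing <- center_tether_align(h, h)
  rep0 <- ssd(p, p, pairing)
  expect_equal(rep0$ssd, 0)
  expect_equal(rep0$ssd_per_residue, 0)
  expect_false(rep0$poor_correspondence)

  ## profiles differing by a constant c at N positions -> ssd = N c^2
  c0 <- 0.37
  p2 <- p; p2[] <- unclass(p) + c0
  repc <- ssd(p, p2, pairing)
  expect_equal(repc$n, length(p))
  expect_equal(repc$ssd, length(p) * c0^2, tolerance = 1e-12)
  expect_equal(repc$ssd_per_residue, c0^2, tolerance = 1e-12)
  expect_true(repc$poor_correspondence)   # 0.37^2 > 0.1

  expect_error(ssd(p, p, pairing[0, , drop = FALSE]), "empty pairing")

  set.seed(8)
  for (k in 1:10) {
    ha <- random_aa_string(sample(13:24, 1))
    hb <- random_aa_string(sample(13:24, 1))
    pa <- windowed_profile(ha, scale); pb <- windowed_profile(hb, scale)
    pr <- center_tether_align(ha, hb)
    rp <- ssd(pa, pb, pr)
    ## oracle over the same centre pairs
    ia <- intersect(as.integer(names(pa)), pr[, 1])
    pairs <- pr[pr[, 1] %in% as.integer(names(pa)) &
                pr[, 2] %in% as.integer(names(pb)), , drop = FALSE]
    ora <- oracle_ssd(unclass(pa)[as.character(pairs[, 1])],
                      unclass(pb)[as.character(pairs[, 2])])
    expect_equal(rp$ssd, ora, tolerance = 1e-12)
    expect_equal(rp$poor_correspondence, rp$ssd_per_residue > 0.1)
    ## symmetry
    rp2 <- ssd(pb, pa, pr[, c(2, 1)])
    expect_equal(rp2$ssd, rp$ssd, tolerance = 1e-12)
  }
})

test_that("SSD is invariant under a constant scale shift", {
  shifted <- scale + 1.7
  attr(shifted, "scale_name") <- attr(scale, "scale_name")
  set.seed(12)
  for (k in 1:5) {
    ha <- random_aa_string(15); hb <- random_aa_string(17)
    pr <- center_tether_align(ha, hb)
    r1 <- ssd(windowed_profile(ha, scale), windowed_profile(hb, scale), pr)
    r2 <- ssd(windowed_profile(ha, shifted), windowed_profile(hb, shifted), pr)
    expect_equal(r1$ssd, r2$ssd, tolerance = 1e-10)
  }
})

test_that("a more extreme point mutation never decreases SSD", {
  base <- strrep("A", 15)
  pr <- center_tether_align(base, base)
  p0 <- windowed_profile(base, scale)
  ## mutate the centre residue to residues of increasing |delta h| from A
  deltas <- abs(scale - scale[["A"]])
  ord <- names(sort(deltas))
  prev <- -1
  for (r in ord) {
    mut <- paste0(substr(base, 1, 7), r, substr(base, 9, 15))
    s <- ssd(p0, windowed_profile(mut, scale), pr)$ssd
    expect_gte(s, prev - 1e-12)
    prev <- s
  }
})

test_that("correspondence table: self-zero, matched vs scrambled, shapes", {
  r1 <- fx_receptor()
  ct_self <- correspondence_table(r1, list(self = r1))
  expect_equal(nrow(ct_self), 1L)
  expect_true(all(abs(as.numeric(ct_self[1, paste0("TM", 1:7)])) < 1e-12))
  expect_equal(ct_self$identity_pct, 100)

  matched <- mutate_receptor(r1, 0, seed = 4, id = "matched")
  scrambled <- mutate_receptor(r1, 0.6, seed = 4, id = "scrambled")
  ct <- correspondence_table(r1, list(matched = matched,
                                      scrambled = scrambled))
  expect_equal(ct$template_id, c("matched", "scrambled"))  # sorted ids
  for (h in paste0("TM", 1:7))
    expect_lt(ct[[h]][1], ct[[h]][2])

  ## missing helix annotation is an error naming receptor and helix
  broken <- matched
  broken$tms <- broken$tms[broken$tms$helix != "TM4", ]
  expect_error(correspondence_table(r1, list(broken = broken)), "TM")
})
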