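test_that("FASTA round-trip, empty files and invalid residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  set.seed(11)
  s1 <- random_aa_string(310); s2 <- random_aa_string(348)
  writeLines(c(">recA some description", s1, ">recB", s2), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(vapply(recs, `[[`, "", "id"), c("recA", "recB"))
  expect_equal(vapply(recs, length, 0L), c(310L, 348L))
  expect_equal(recs[[1]]$residues, s1)

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_length(read_fasta(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r", "MKTXAY"), bad)
  expect_error(read_fasta(bad), "non-canonical residue 'X' at position 4")

  notfasta <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MKTAY", ">r", "MKTAY"), notfasta)
  expect_error(read_fasta(notfasta), "line 1")
})

test_that("BW numbering offsets, anchors and round-trip", {
  seq <- receptor_sequence("r", strrep("A", 60))
  tms <- tm_annotation("TM3", 21, 40, 60)        # 20 residues
  bw <- assign_bw_numbers(seq, tms, c(TM3 = 30))  # anchor = 10th of helix
  expect_equal(bw$label[bw$index == 30], "3.50")
  expect_equal(bw$label[bw$index == 21], "3.41")
  expect_equal(bw$label[bw$index == 40], "3.60")

  bw2 <- assign_bw_numbers(seq, tms, c(TM3 = 21))  # anchor at helix start
  expect_equal(bw2$label, paste0("3.", 50:69))

  expect_error(assign_bw_numbers(seq, tms, c(TM3 = 20)), "outside its span")

  ## label -> residue -> label round-trip on an annotated receptor
  r <- fx_receptor()
  bw3 <- assign_bw_numbers(r$seq, r$tms, r$anchors)
  for (lab in sample(bw3$label, 10)) {
    i <- bw3$index[bw3$label == lab]
    expect_identical(bw_residue(r$seq, bw3, lab),
                     substr(r$seq$residues, i, i))
  }
})

test_that("tm_annotation rejects malformed tables", {
  expect_error(tm_annotation("TM8", 1, 10), "TM1..TM7")
  expect_error(tm_annotation(c("TM1", "TM2"), c(1, 5), c(10, 15)),
               "non-overlapping")
  expect_error(tm_annotation("TM1", 5, 3), "start <= end")
  expect_error(tm_annotation("TM1", 1, 99, seq_length = 50), "beyond sequence")
})

test_that("global identity: exact cases and DP-oracle score equivalence", {
  a <- receptor_sequence("a", "MKTAYIAKQR")
  expect_equal(global_identity(a, a), 100)

  b <- receptor_sequence("b", "MKTWYIAKQL")  # 2 substitutions, no gaps
  expect_equal(global_identity(a, b), 80)
  expect_equal(global_identity(b, a), 80)

  ## alignment engine achieves the independent Gotoh optimum
  mat <- fx_blosum62()
  set.seed(42)
  for (k in 1:8) {
    x <- receptor_sequence("x", random_aa_string(sample(8:16, 1)))
    y <- receptor_sequence("y", random_aa_string(sample(8:16, 1)))
    al <- olfscreen:::align_global(x, y)
    expect_equal(al$score, oracle_nw_score(x$residues, y$residues, mat),
                 tolerance = 1e-9)
  }

  ## identity invariant under id renaming, for generated sequences
  set.seed(7)
  s <- random_aa_string(40)
  expect_equal(global_identity(receptor_sequence("p", s),
                               receptor_sequence("q", s)), 100)
})

test_that("query coverage: identity, half-template and DP-checked pair", {
  set.seed(5)
  s <- random_aa_string(60)
  tgt <- receptor_sequence("t", s)
  expect_equal(query_coverage(tgt, tgt), 100)

  half <- receptor_sequence("h", substr(s, 1, 30))
  expect_equal(query_coverage(tgt, half), 50)

  ## 12-mer / 8-mer toy: template is an exact substring, so the optimal
  ## alignment is unique and coverage is the substring fraction
  t12 <- receptor_sequence("t12", "MKWTAYIAKQRD")
  t8  <- receptor_sequence("t8", "WTAYIAKQ")
  mat <- fx_blosum62()
  expect_equal(olfscreen:::align_global(t12, t8)$score,
               oracle_nw_score("MKWTAYIAKQRD", "WTAYIAKQ", mat))
  expect_equal(query_coverage(t12, t8), round(100 * 8 / 12, 1))
  ## identity excludes the terminal-gap columns
  expect_equal(global_identity(t12, t8), 100)
})

test_that("center-tether alignment: parity conventions and symmetry", {
  expect_equal(center_tether_align(strrep("A", 11), strrep("L", 11)),
               cbind(a = 1:11, b = 1:11))
  expect_equal(center_tether_align(strrep("A", 11), strrep("L", 9)),
               cbind(a = 2:10, b = 1:9))
  ## mixed parity fixed by the floor((L+1)/2) centre convention
  got <- center_tether_align(strrep("A", 10), strrep("L", 9))
  floor_conv <- cbind(a = (5 + (-4:4)), b = (5 + (-4:4)))
  ceil_conv  <- cbind(a = (6 + (-4:3)), b = (5 + (-4:3)))
  expect_equal(got, floor_conv)
  expect_false(isTRUE(all.equal(got, ceil_conv)))

  expect_error(center_tether_align("", "AAA"), "empty helix")

  set.seed(3)
  for (k in 1:10) {
    la <- sample(5:30, 1); lb <- sample(5:30, 1)
    p <- center_tether_align(strrep("A", la), strrep("V", lb))
    expect_true(all(diff(p[, 1]) == 1) && all(diff(p[, 2]) == 1))
    q <- center_tether_align(strrep("V", lb), strrep("A", la))
    expect_equal(unname(p[, c(2, 1)]), unname(q))
    expect_equal(nrow(p), min(la, lb))
  }
})

test_that("receptor_sequence enforces the canonical alphabet", {
  expect_error(receptor_sequence("r", "MKB"), "non-canonical residue 'B'")
  expect_error(receptor_sequence("r", ""), "non-empty")
  expect_silent(receptor_sequence("r", "acdefghiklmnpqrstvwy"))
})
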