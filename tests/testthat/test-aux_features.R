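aas <- unname(aa_three_to_one())

test_that("substitution matrices are complete, symmetric and diagonal-dominant", {
  for (wt in aas) for (mt in aas) {
    sc <- substitution_scores(wt, mt)
    expect_length(sc, 2L)
    expect_true(all(is.finite(sc)))
    expect_identical(sc, substitution_scores(mt, wt))
  }
  # identity maximises each BLOSUM62 row
  for (wt in aas) {
    row <- vapply(aas, function(mt) substitution_scores(wt, mt)["BLOSUM62"], numeric(1))
    expect_equal(names(which.max(row)), wt)
  }
})

test_that("AAindex2 parser round-trips and tables are complete", {
  db <- read_aaindex2()
  expect_setequal(names(db), c("BENS940104", "HELX_SYN01"))
  for (id in names(db)) {
    m <- db[[id]]
    expect_equal(dim(m), c(20L, 20L))
    expect_true(all(is.finite(m)))
    expect_equal(m, t(m))                      # symmetric by construction
  }
  for (wt in aas) {
    expect_true(is.finite(aaindex_scores(wt, wt, "BENS940104", db)))
  }
  # reserialise one entry in the dialect and reparse: identical table
  m <- db[["BENS940104"]]
  ord <- rownames(m)
  f <- tempfile()
  lines <- c("H BENS940104",
             sprintf("M rows = %s, cols = %s", paste(ord, collapse = ""),
                     paste(ord, collapse = "")))
  for (i in seq_along(ord)) {
    lines <- c(lines, paste0(" ", paste(sprintf("%.1f", m[i, seq_len(i)]),
                                        collapse = " ")))
  }
  writeLines(c(lines, "//"), f)
  expect_equal(read_aaindex2(f)[["BENS940104"]], m)
  expect_error(aaindex_scores("A", "C", "NOPE", db), class = "gs_data_error")
})

test_that("identity flags mark the special substitutions", {
  expect_equal(identity_flags("P", "A"),
               c(FromPro = 1L, ToAla = 1L, FromGly = 0L, ToPro = 0L))
  expect_equal(sum(identity_flags("A", "V")), 0L)
  from_pro <- vapply(aas, function(wt) identity_flags(wt, "V")["FromPro"], integer(1))
  expect_equal(sum(from_pro), 1L)
  to_pro <- vapply(aas, function(mt) identity_flags("A", mt)["ToPro"], integer(1))
  expect_equal(sum(to_pro), 1L)
})

test_that("SASA agrees with an independent implementation on a fixed bundle", {
  b <- make_helical_bundle(bundle_spec(n_helices = 1, residues_per_helix = 4,
                                       sequence = "AGLK", seed = 7))
  # per-residue solvent-accessible areas of this exact structure computed
  # once with biotite (Shrake-Rupley, probe 1.4 A, 1000 points, single-atom
  # radii) and frozen here
  biotite <- c(139.93, 84.28, 99.04, 123.32)
  ref <- c(ALA = 129, GLY = 104, LEU = 201, LYS = 236)
  res <- structure_residues(b)
  for (i in 1:4) {
    ours <- relative_solvent_accessibility(b, "A", i) * ref[[res$res_name[i]]]
    expect_lt(abs(ours - biotite[i]) / biotite[i], 0.05)
  }
})

test_that("buried residues have lower RSA and higher depth than exposed ones", {
  b <- make_helical_bundle(bundle_spec(seed = 3))
  res <- structure_residues(b)
  # pick residues at mid-height: innermost vs outermost side-chain centre
  ctr <- t(vapply(seq_len(nrow(res)), function(i) {
    gpcrstab:::residue_center(b$atoms[b$atoms$res_seq == res$res_seq[i], ])
  }, numeric(3)))
  mid <- abs(ctr[, 3]) < 5
  raxis <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)
  inner <- res$res_seq[mid][which.min(raxis[mid])]
  outer <- res$res_seq[mid][which.max(raxis[mid])]
  expect_lt(relative_solvent_accessibility(b, "A", inner),
            relative_solvent_accessibility(b, "A", outer))
  expect_gt(residue_depth(b, "A", inner), residue_depth(b, "A", outer))
  # depth is a distance
  for (i in sample(res$res_seq, 10)) {
    expect_gte(residue_depth(b, "A", i), 0)
  }
})

test_that("an isolated residue's depth is the frozen probe-scale constant", {
  b <- make_helical_bundle(bundle_spec(n_helices = 1, residues_per_helix = 4,
                                       sequence = "AGLK", seed = 7))
  expect_equal(residue_depth(b, "A", 1), 3.034, tolerance = 0.01)
})

test_that("topology flags follow the slab rule and the annotation file", {
  b <- make_helical_bundle(bundle_spec(seed = 5))
  res <- structure_residues(b)
  ctr <- t(vapply(seq_len(nrow(res)), function(i) {
    gpcrstab:::residue_center(b$atoms[b$atoms$res_seq == res$res_seq[i], ])
  }, numeric(3)))
  in_slab <- res$res_seq[which.min(abs(ctr[, 3]))]
  expect_equal(topology_flags(b, "A", in_slab, half_width = 15),
               c(mem = 1L, non_cytosol = 1L))
  # a residue far below the slab
  shifted <- b
  shifted$atoms$z <- shifted$atoms$z - 50
  expect_equal(topology_flags(shifted, "A", in_slab, half_width = 15),
               c(mem = 0L, non_cytosol = 0L))

  ann <- data.frame(chain = "A", res_seq = 1:10,
                    mem = rep(c(0L, 1L), 5), non_cytosol = rep(c(1L, 0L), 5))
  for (i in 1:10) {
    expect_equal(unname(topology_flags(b, "A", i, annotation = ann)),
                 c(ann$mem[i], ann$non_cytosol[i]))
  }
})

test_that("auxiliary features are deterministic", {
  b <- make_helical_bundle(bundle_spec(n_helices = 2, residues_per_helix = 8,
                                       seed = 2))
  r1 <- relative_solvent_accessibility(b, "A", 4)
  d1 <- residue_depth(b, "A", 4)
  b2 <- make_helical_bundle(bundle_spec(n_helices = 2, residues_per_helix = 8,
                                        seed = 2))
  expect_identical(r1, relative_solvent_accessibility(b2, "A", 4))
  expect_identical(d1, residue_depth(b2, "A", 4))
})
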