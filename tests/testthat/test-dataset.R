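mk_rec <- function(uniprot, pos, wt, mt, dTm = 1, src = "t1") {
  data.frame(uniprot_id = uniprot, chain = "A", position = pos, wt_aa = wt,
             mt_aa = mt, dTm = dTm, source = src, stringsAsFactors = FALSE)
}

test_that("deduplication collapses repeated (protein, position, mutant) keys", {
  recs <- rbind(
    mk_rec("P1", 10, "A", "V"), mk_rec("P1", 11, "L", "A"),
    mk_rec("P1", 10, "A", "V", dTm = 99, src = "t2"),   # dup 1
    mk_rec("P2", 10, "A", "V"), mk_rec("P2", 20, "K", "R"),
    mk_rec("P1", 11, "L", "A", src = "t3"),             # dup 2
    mk_rec("P1", 12, "F", "Y"), mk_rec("P2", 21, "S", "T"),
    mk_rec("P2", 20, "K", "R", src = "t4"),             # dup 3
    mk_rec("P3", 5, "W", "F"), mk_rec("P3", 6, "M", "I"),
    mk_rec("P3", 7, "D", "E"))
  out <- merge_and_deduplicate(recs)
  expect_equal(nrow(out), 9L)
  # first-listed source wins, order = first occurrence
  expect_equal(out$dTm[out$uniprot_id == "P1" & out$position == 10], 1)
  expect_identical(merge_and_deduplicate(out), out)      # idempotent

  t1 <- rbind(mk_rec("P1", 1, "A", "V"), mk_rec("P1", 2, "L", "M"))
  t2 <- rbind(mk_rec("P1", 1, "A", "V", src = "t2"), mk_rec("P1", 3, "K", "R"))
  expect_equal(nrow(merge_and_deduplicate(list(t1, t2))), 2 + 2 - 1)
})

test_that("conflicting wild types at one key are a data error", {
  recs <- rbind(mk_rec("P1", 10, "A", "V"), mk_rec("P1", 10, "G", "V"))
  expect_error(merge_and_deduplicate(recs), class = "gs_data_conflict_error")
})

test_that("blind split has exact size, disjointness and determinism", {
  recs <- do.call(rbind, lapply(1:100, function(i) {
    mk_rec(paste0("P", (i %% 7) + 1), i, "A", "V")
  }))
  sp <- blind_split(recs, fraction = 0.13, seed = 1)
  expect_equal(nrow(sp$test), 13L)
  expect_equal(nrow(sp$train), 87L)
  key <- function(d) paste(d$uniprot_id, d$position, d$mt_aa)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  sp2 <- blind_split(recs, fraction = 0.13, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- blind_split(recs, fraction = 0.13, seed = 2)
  expect_false(identical(key(sp$test), key(sp3$test)))
  expect_error(blind_split(recs[1, ], 0.5), class = "gs_insufficient_data_error")
})

test_that("mutation table reader validates schema and codes", {
  f <- tempfile(fileext = ".csv")
  write.csv(mk_rec("P1", 3, "A", "V"), f, row.names = FALSE)
  tab <- read_mutation_table(f)
  expect_equal(tab$position, 3L)
  bad <- mk_rec("P1", 3, "A", "X")
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_mutation_table(f), class = "gs_format_error")
})

test_that("featurize produces the configured rectangular matrix", {
  se <- shared_small_fm()
  fm <- se$fm
  cfg <- gs_config()
  n_sig <- length(signature_feature_names(cfg$cutoffs))
  expect_equal(ncol(fm$x), n_sig + 8L + 12L)
  expect_equal(nrow(fm$x), nrow(se$muts))
  expect_false(any(is.na(fm$x)))
  expect_identical(colnames(fm$x), feature_names(cfg))

  # a 5-mutation subset gives a 5 x F matrix through the same path
  fm5 <- featurize(se$muts[1:5, ], setNames(list(se$bundle), se$muts$uniprot_id[1]))
  expect_equal(dim(fm5$x), c(5L, n_sig + 20L))
  # purity: identical inputs, identical output
  fm5b <- featurize(se$muts[1:5, ], setNames(list(se$bundle), se$muts$uniprot_id[1]))
  expect_identical(fm5$x, fm5b$x)
})

test_that("site determines the signature; substitution determines PChange", {
  se <- shared_small_fm()
  b <- se$bundle
  res <- structure_residues(b)
  wt <- unname(aa_three_to_one()[res$res_name[5]])
  mts <- setdiff(c("A", "W", "E"), wt)[1:2]
  recs <- rbind(
    data.frame(uniprot_id = "S", chain = "A", position = 5, wt_aa = wt,
               mt_aa = mts[1], dTm = NA, source = "x"),
    data.frame(uniprot_id = "S", chain = "A", position = 5, wt_aa = wt,
               mt_aa = mts[2], dTm = NA, source = "x"))
  fm <- featurize(recs, list(S = b))
  sig_cols <- signature_feature_names(gs_config()$cutoffs)
  pch_cols <- paste0("PChange.", names(pharmacophore_classes()))
  expect_identical(fm$x[1, sig_cols], fm$x[2, sig_cols])
  expect_false(identical(fm$x[1, pch_cols], fm$x[2, pch_cols]))

  # identity-mutation control row has an all-zero PChange block
  ctrl <- recs[1, ]; ctrl$mt_aa <- wt
  fmc <- featurize(ctrl, list(S = b))
  expect_true(all(fmc$x[1, pch_cols] == 0))
})

test_that("strict mode fails fast and lenient mode drops with a report", {
  se <- shared_small_fm()
  bad <- se$muts[1:3, ]
  bad$position[2] <- 9999
  expect_error(featurize(bad, setNames(list(se$bundle), bad$uniprot_id[1])),
               class = "gs_featurize_error")
  expect_warning(
    fm <- featurize(bad, setNames(list(se$bundle), bad$uniprot_id[1]),
                    strict = FALSE),
    class = "gs_featurize_warning")
  expect_equal(nrow(fm$x), 2L)
  expect_equal(sum(fm$report$status == "error"), 1L)
})
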