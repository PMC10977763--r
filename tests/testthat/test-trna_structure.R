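test_that("a perfect four-arm template folds with all arms and no mismatches", {
  tr <- generate_trna(anticodon = "TGC", seed = 101)
  expect_equal(nchar(tr$seq), 72L)
  fold <- fold_cloverleaf(tr$seq)
  expect_false(fold$failed)
  expect_true(all(fold$arm_present))
  expect_equal(fold$anticodon, "TGC")
  mr <- mismatch_report(fold)
  expect_equal(nrow(mr$mismatches), 0L)
  # determinism: identical input, identical layout
  fold2 <- fold_cloverleaf(tr$seq)
  expect_identical(fold, fold2)
})

test_that("breaking the D stem drops exactly the D arm", {
  tr <- generate_trna(arm_config = c("acceptor", "anticodon", "T"),
                      anticodon = "GCT", seed = 102)
  fold <- fold_cloverleaf(tr$seq)
  expect_false(fold$arm_present[["D"]])
  expect_null(fold$D)   # absent arm reports no pairs
  expect_true(fold$arm_present[["acceptor"]])
  expect_true(fold$arm_present[["anticodon"]])
  expect_true(fold$arm_present[["T"]])
})

test_that("the truncated T-armless template (51-nt alanine analog) is called", {
  tr <- generate_trna(arm_config = c("acceptor", "D", "anticodon"),
                      anticodon = "TGC", seed = 103)
  fold <- fold_cloverleaf(tr$seq)
  expect_false(fold$arm_present[["T"]])
  expect_null(fold$T)
  expect_true(fold$arm_present[["D"]])
})

test_that("injected mismatches and wobbles are located and classified", {
  tr <- generate_trna(anticodon = "TGC", seed = 104, mismatch_at = 3L)
  mr <- mismatch_report(fold_cloverleaf(tr$seq))
  expect_equal(nrow(mr$mismatches), 1L)
  expect_equal(mr$mismatches$arm, "acceptor")
  expect_equal(mr$mismatches$pos5, 3L)   # outermost pair is index 1

  trw <- generate_trna(anticodon = "TGC", seed = 105, wobble_at = 2L)
  mrw <- mismatch_report(fold_cloverleaf(trw$seq))
  expect_equal(nrow(mrw$mismatches), 0L)
  expect_gte(nrow(mrw$wobbles), 1L)
})

test_that("a single stem mismatch never increases the total score", {
  for (seed in 106:110) {
    clean <- generate_trna(anticodon = "TGC", seed = seed)
    dirty <- generate_trna(anticodon = "TGC", seed = seed,
                           mismatch_at = 4L)
    expect_lte(fold_cloverleaf(dirty$seq)$score,
               fold_cloverleaf(clean$seq)$score)
  }
})

test_that("hopeless sequences yield a fold-failure result, not an error", {
  short <- fold_cloverleaf("ACGTACGTACGTACGTACGT")  # 20 nt
  expect_true(short$failed)
  expect_false(any(short$arm_present))
  expect_error(fold_cloverleaf("ACGTXX"), "invalid characters")
})

test_that("dot-bracket export is balanced and matches the fold length", {
  tr <- generate_trna(anticodon = "TGC", seed = 111)
  fold <- fold_cloverleaf(tr$seq)
  db <- dot_bracket(fold)
  expect_equal(nchar(db), nchar(tr$seq))
  expect_equal(lengths(regmatches(db, gregexpr("\\(", db))),
               lengths(regmatches(db, gregexpr("\\)", db))))
})

test_that("anticodon validation decodes with third-position wobble", {
  expect_true(validate_anticodon("GTC", "Asp"))
  expect_true(validate_anticodon("TTT", "Lys"))
  expect_false(validate_anticodon("GGG", "Lys"))
  # wobble: U in anticodon position 1 also reads codons ending in G
  expect_true(validate_anticodon("TTT", "K"))
  ac <- validate_anticodon("TGC", "Ala")
  expect_true(ac)
  expect_true(all(attr(ac, "codons") %in% c("GCA", "GCG")))
  expect_error(validate_anticodon("GTC", "Xyz"), "unknown amino acid")
})
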