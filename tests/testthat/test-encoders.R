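test_that("one-hot encoding follows the fixed channel layout", {
  em <- encode_onehot("ACD")
  expect_identical(dim(em$values), c(1L, 60L))
  # alphabetical channels: A=1, C=2, D=3 within each 20-wide block
  expect_identical(unname(which(em$values[1, ] == 1)), c(1L, 22L, 43L))
  expect_identical(sum(em$values), 3)

  seqs <- c("ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTV",
            "YWVTSRQPNMLKIHGFEDCAYWVTSRQPNMLKIHGFEDCAYWVTSRQPNMLKIHGFED")
  seqs <- substr(seqs, 1, 58)
  em58 <- encode_onehot(seqs)
  expect_identical(ncol(em58$values), 1160L)   # 20 x 58
  expect_true(all(rowSums(em58$values) == 58))
  # invertibility
  expect_identical(decode_onehot(em58), seqs)

  expect_error(encode_onehot(c("AA", "AAA")), "equal-length")
  expect_error(encode_onehot("ABC"), "non-canonical")
})

test_that("physiochemical encoder emits the documented 20 descriptors", {
  em <- encode_physiochemical(c("AAA", "GLFDIVKKVVGALGSL"))
  expect_identical(ncol(em$values), 20L)
  expect_identical(em$feature_names, fitrank:::PHYSCHEM_FEATURES)
  expect_false(anyDuplicated(em$feature_names) > 0)
  expect_true(all(is.finite(em$values)))
  # scale-table lookups: single-residue means for poly-A
  expect_equal(em$values["seq_00001", "H_Eisenberg"], 0.62, tolerance = 1e-12)
  expect_equal(em$values["seq_00001", "H_Gravy"], 1.8, tolerance = 1e-12)
  expect_error(encode_physiochemical("A"), "length-1")
})

test_that("descriptors agree with independently computed reference values", {
  # frozen oracle values computed with Biopython ProteinAnalysis
  ref <- list(
    AAA = c(gravy = 1.8, arom = 0, instab = 6.666667, mw = 231.2490),
    ACDEFGHIKLMNPQRSTVWY = c(gravy = -0.49, arom = 0.15, instab = 84.74,
                             mw = 2395.7134),
    GLFDIVKKVVGALGSL = c(gravy = 1.2375, arom = 0.0625, instab = -5.9375,
                         mw = 1615.9536))
  em <- encode_physiochemical(names(ref))
  for (i in seq_along(ref)) {
    expect_equal(unname(em$values[i, "H_Gravy"]), unname(ref[[i]]["gravy"]),
                 tolerance = 1e-6)
    expect_equal(unname(em$values[i, "aromaticity"]), unname(ref[[i]]["arom"]),
                 tolerance = 1e-6)
    expect_equal(unname(em$values[i, "instability_index"]),
                 unname(ref[[i]]["instab"]), tolerance = 1e-5)
    expect_equal(unname(em$values[i, "mol_weight"]), unname(ref[[i]]["mw"]),
                 tolerance = 1e-3)
  }
})

test_that("charge and isoelectric point behave physically", {
  em <- encode_physiochemical(c("KKKKKK", "DDDDDD", "GGGGGG"))
  pi_k <- em$values[1, "isoelectric_point"]
  pi_d <- em$values[2, "isoelectric_point"]
  expect_gt(pi_k, 9)    # poly-lysine is basic
  expect_lt(pi_d, 5)    # poly-aspartate is acidic
  expect_gt(em$values[1, "charge_ph7"], 4)
  expect_lt(em$values[2, "charge_ph7"], -4)
  # net charge vanishes at the isoelectric point
  ch <- fitrank:::net_charge(strsplit("KKKKKK", "")[[1]], pi_k)
  expect_lt(abs(ch), 1e-3)
})

test_that("composition descriptors are permutation-invariant", {
  s <- "MKVLAAGGDDEERRKKWWFF"
  perm <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  em <- encode_physiochemical(c(s, perm))
  invariant <- c("length", "mol_weight", "charge_ph7", "charge_density",
                 "isoelectric_point", "aromaticity", "aliphatic_index",
                 "boman_index", "hydrophobic_ratio", "H_Eisenberg",
                 "H_Gravy", "H_Eisenberg_sd", "frac_acidic", "frac_basic",
                 "frac_polar")
  expect_equal(em$values[1, invariant], em$values[2, invariant],
               tolerance = 1e-10)
})

test_that("mock adapter is deterministic and honors its contract", {
  ad <- mock_adapter(dimension = 64, seed = 3)
  seqs <- c("MKVLAAGG", "MKVLAAGG", "WWFFYYHH")
  em <- encode_with_adapter(seqs, ad)
  expect_identical(dim(em$values), c(3L, 64L))
  expect_identical(em$values[1, ], em$values[2, ])   # identical sequences
  expect_false(isTRUE(all.equal(em$values[1, ], em$values[3, ])))
  # a fresh adapter with the same seed reproduces the matrix exactly
  em2 <- encode_with_adapter(seqs, mock_adapter(dimension = 64, seed = 3))
  expect_identical(em$values, em2$values)
  # different adapter seed changes the projection
  em3 <- encode_with_adapter(seqs, mock_adapter(dimension = 64, seed = 4))
  expect_false(isTRUE(all.equal(em$values, em3$values)))
})

test_that("adapter registry and contract violations are handled", {
  register_adapter(mock_adapter(dimension = 16))
  em <- encode_with_adapter(c("MKVL", "GGGG"), "mock")
  expect_identical(ncol(em$values), 16L)
  expect_error(get_adapter("nonexistent"), "no adapter registered")
  liar <- embedding_adapter("liar", 8,
                            function(s) matrix(0, length(s), 4))
  expect_error(encode_with_adapter(c("MKVL"), liar), "violated its contract")
  broken <- embedding_adapter("broken", 8, function(s) stop("boom"))
  expect_error(encode_with_adapter(c("MKVL"), broken), "boom")
})

test_that("encoding matrix container validates its invariants", {
  expect_error(encoding_matrix("x", matrix(c(1, NA), 1), c("a", "b"), "r1"),
               "missing")
  expect_error(encoding_matrix("x", matrix(1:4, 2), c("a", "a"), c("r1", "r2")),
               "unique")
  em <- toy_encoding("t", 4, 3)
  expect_identical(em$row_ids, rownames(em$values))
})
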