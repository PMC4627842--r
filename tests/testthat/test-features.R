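test_that("amino-acid encoding is the evenly spaced alphabetical scale", {
  expect_equal(encode_amino_acid("A"), -1)
  expect_equal(encode_amino_acid("Y"), 1)
  # C is the 2nd of the 20 one-letter codes in alphabetical order
  expect_equal(encode_amino_acid("C"), -1 + 2 * (1 / 19))
  all20 <- encode_amino_acid(idpred:::AA_ALPHABET)
  expect_equal(length(unique(all20)), 20)
  expect_equal(diff(all20), rep(2 / 19, 19))
  expect_error(encode_amino_acid("X"), "non-standard")
})

test_that("physicochemical table is standardized and injective", {
  tab <- aa_physchem()
  expect_identical(dim(tab), c(20L, 7L))
  expect_true(all(abs(colMeans(tab)) < 1e-9))
  expect_true(all(abs(apply(tab, 2, sd) - 1) < 1e-9))
  expect_false(any(duplicated(tab)))
  v <- phys_chem_features(c("M", "K"))
  expect_identical(dim(v), c(2L, 7L))
  expect_false(isTRUE(all.equal(v[1, ], v[2, ])))
})

test_that("PSSM normalization divides by nine without clamping", {
  m <- matrix(c(9, 0, -13, 5), nrow = 1)[, rep(1:4, 5), drop = FALSE]
  out <- normalize_pssm(m)
  expect_equal(out[1, 1], 1)
  expect_equal(out[1, 2], 0)
  expect_equal(out[1, 3], -13 / 9)
})

test_that("monogram/bigram match the closed form on an all-zero PSSM", {
  pn <- normalize_pssm(matrix(0L, 2, 20))
  tabs <- monogram_bigram(pn)
  expect_equal(unname(tabs$mg), rep(2 / exp(6), 20))
  expect_equal(unname(as.vector(tabs$bg)), rep(1 / exp(6), 400))
  # doubling L doubles the monogram (linearity of the sum)
  tabs4 <- monogram_bigram(normalize_pssm(matrix(0L, 4, 20)))
  expect_equal(unname(tabs4$mg), 2 * unname(tabs$mg))
  expect_error(monogram_bigram(normalize_pssm(matrix(0L, 1, 20))),
               "length < 2")
})

test_that("per-residue MG/BG is a type-indexed row lookup", {
  tabs <- monogram_bigram(normalize_pssm(matrix(0L, 2, 20)))
  v <- residue_mg_bg(tabs, "A")
  expect_length(v, 21)
  expect_equal(unname(v[1]), 2 / exp(6))
  expect_equal(unname(v[-1]), rep(1 / exp(6), 20))
  # same type anywhere in the sequence gets the same features
  expect_identical(residue_mg_bg(tabs, "K"), residue_mg_bg(tabs, "K"))
})

test_that("terminal indicator follows the graded two-ended scheme", {
  expect_equal(terminal_indicator(0, 100), -1)
  expect_equal(terminal_indicator(0:4, 100), c(-1, -0.8, -0.6, -0.4, -0.2))
  expect_equal(terminal_indicator(99:95, 100), c(1, 0.8, 0.6, 0.4, 0.2))
  expect_equal(terminal_indicator(50, 100), 0)
  # C-terminal assignment wins on contested positions of short chains
  expect_equal(terminal_indicator(4, 9), 1 - 0.2 * 4)  # L-5 beats N-pos 4
  expect_equal(terminal_indicator(7, 9), 0.8)          # position L-2
  expect_error(terminal_indicator(9, 9), "out of range")
})

test_that("assembled blocks have exactly 56 features in frozen order", {
  ds <- tiny_dataset()
  p <- ds$proteins[[1]]
  blocks <- assemble_features(p, ds$pssms[[p$id]], ds$structurals[[p$id]])
  expect_identical(ncol(blocks), 56L)
  expect_identical(nrow(blocks), nchar(p$sequence))
  expect_true(all(is.finite(blocks)))
  chars <- strsplit(p$sequence, "")[[1]]
  # spot-check the frozen layout: AA code first, terminal indicator last
  expect_equal(blocks[, 1], encode_amino_acid(chars))
  expect_equal(blocks[, 56],
               terminal_indicator(seq_along(chars) - 1, length(chars)))
  # PSSM block (cols 9-28) is the normalized profile
  expect_equal(blocks[, 9:28],
               unname(normalize_pssm(ds$pssms[[p$id]]$scores)))
  expect_error(assemble_features(p, ds$pssms[[p$id]], NULL), "missing")
})

test_that("feature assembly is deterministic across runs", {
  ds <- tiny_dataset()
  p <- ds$proteins[[2]]
  b1 <- assemble_features(p, ds$pssms[[p$id]], ds$structurals[[p$id]])
  b2 <- assemble_features(p, ds$pssms[[p$id]], ds$structurals[[p$id]])
  expect_identical(b1, b2)
})

test_that("window encoding matches the brute-force oracle", {
  set.seed(11)
  for (trial in 1:8) {
    L <- sample(5:30, 1)
    w <- sample(c(1, 3, 5, 7), 1)
    blocks <- matrix(rnorm(L * 56), L, 56)
    expect_equal(window_encode(blocks, w), window_oracle(blocks, w),
                 tolerance = 1e-12)
  }
  expect_error(window_encode(matrix(0, 5, 56), 4), "odd")
})

test_that("window-21 rows have 1176 columns and zero padding at chain ends", {
  blocks <- matrix(1, 30, 56)
  enc <- window_encode(blocks, 21)
  expect_identical(ncol(enc), 1176L)
  enc3 <- window_encode(blocks, 3)
  expect_true(all(enc3[1, 1:56] == 0))       # left neighbour of residue 1
  expect_true(all(enc3[30, 113:168] == 0))   # right neighbour of residue L
  expect_equal(window_encode(blocks, 1), blocks)  # identity window
})

test_that("scaler maps training data into [-1,1] and round-trips", {
  set.seed(5)
  x <- cbind(matrix(rnorm(200), 50, 4), 7)  # last column constant
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  expect_true(all(xs >= -1 - 1e-12 & xs <= 1 + 1e-12))
  expect_true(all(xs[, 5] == 0))
  # midpoint maps to 0
  sc2 <- fit_scaler(matrix(c(2, 4), 2, 1))
  expect_equal(apply_scaler(sc2, matrix(3, 1, 1))[1, 1], 0)
  # unscale recovers x for non-constant columns
  rng <- sc$max[1:4] - sc$min[1:4]
  back <- sweep(sweep((xs[, 1:4] + 1) / 2, 2, rng, "*"), 2, sc$min[1:4], "+")
  expect_equal(back, x[, 1:4], tolerance = 1e-12)
  # unseen data may exceed the range and is not clipped
  out <- apply_scaler(sc, matrix(c(100, 0, 0, 0, 0), 1, 5))
  expect_gt(out[1, 1], 1)
  expect_error(fit_scaler(matrix(0, 0, 3)), "empty")
})

test_that("sparse SVM-format export writes +1/-1 and drops unknowns", {
  x <- matrix(c(0, 2, 0.5, 0, 0, 1), 3, 2)
  path <- withr::local_tempfile()
  write_svm_format(x, c("D", "U", "O"), path)
  lines <- readLines(path)
  expect_length(lines, 2)
  expect_match(lines[1], "^\\+1 ")
  expect_match(lines[2], "^-1 ")
  expect_match(lines[2], "1:0.5")
})
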