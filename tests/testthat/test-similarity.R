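test_that("windowed BLOSUM62 similarity matches a lookup oracle", {
  expect_equal(s_blosum62("AAAAAAA", "AAAAAAA"), 28)
  m <- blosum62()
  withr::with_seed(21, {
    for (i in 1:40) {
      a <- random_window(7)
      b <- random_window(7)
      oracle <- sum(vapply(1:7, function(k) {
        m[substr(a, k, k), substr(b, k, k)]
      }, numeric(1)))
      expect_equal(s_blosum62(a, b), oracle)
      expect_equal(s_blosum62(a, b), s_blosum62(b, a))
      expect_equal(s_blosum62(a, a),
                   sum(vapply(1:7, function(k) {
                     m[substr(a, k, k), substr(a, k, k)]
                   }, numeric(1))))
    }
  })
  expect_error(s_blosum62("AAA", "AAAAAAA"), class = "phoskin_input_error")
})

test_that("the zero-X option drops padding contributions", {
  a <- "XXAAAAA"
  b <- "RKAAAAA"
  with_x <- s_blosum62(a, b)
  without <- s_blosum62(a, b, zero_x = TRUE)
  expect_equal(without, 5 * 4)  # only the five A-A pairs contribute
  expect_equal(with_x - without,
               unname(blosum62()["X", "R"] + blosum62()["X", "K"]))
})

test_that("the profile-profile column score reduces and sums correctly", {
  m <- blosum62()
  pa <- point_mass_profile("AR")
  pb <- point_mass_profile("KA")
  # point masses: 0.5 * (S_b[row j][a] + S_a[row i][b])
  expect_equal(ppa_score(pa, 1, pb, 2),
               0.5 * (m["A", "A"] + m["A", "A"]))
  expect_equal(ppa_score(pa, 2, pb, 1),
               0.5 * (m["K", "R"] + m["R", "K"]))
  # all-zero score vectors annihilate regardless of frequencies.
  za <- make_profile(pa$freq, matrix(0, 2, 20))
  zb <- make_profile(pb$freq, matrix(0, 2, 20))
  expect_equal(ppa_score(za, 1, zb, 1), 0)

  withr::with_seed(22, {
    for (i in 1:40) {
      A <- random_profile(3)
      B <- random_profile(4)
      ii <- sample(3, 1)
      jj <- sample(4, 1)
      oracle <- 0
      for (k in 1:20) {
        oracle <- oracle + 0.5 * (A$freq[ii, k] * B$score[jj, k] +
                                  B$freq[jj, k] * A$score[ii, k])
      }
      expect_equal(ppa_score(A, ii, B, jj), unname(oracle),
                   tolerance = 1e-12)
      expect_equal(ppa_score(A, ii, B, jj), ppa_score(B, jj, A, ii))
    }
  })
  expect_error(ppa_score(pa, 3, pb, 1), class = "phoskin_input_error")
})

test_that("one-column alignments choose between a match and two gaps", {
  par1 <- align_params(window = 1L)
  hi <- make_profile(matrix(1/20, 1, 20), matrix(5, 1, 20))
  lo <- make_profile(matrix(1/20, 1, 20), matrix(-50, 1, 20))
  # ppa = 5 beats the doubly-gapped path (-6).
  expect_equal(s_profile(hi, hi, par1), 5)
  # ppa = -50 loses to gap-open twice: -(3 + 3).
  expect_equal(s_profile(lo, lo, par1), -6)
})

test_that("alignment equals exhaustive enumeration for tiny windows", {
  withr::with_seed(23, {
    for (trial in 1:60) {
      L <- sample(1:4, 1)
      A <- random_profile(L, score_scale = 3)
      B <- random_profile(L, score_scale = 3)
      ge <- runif(1, 0.2, 1.5)
      go <- ge + runif(1, 0, 2.5)
      par <- align_params(gap_open = go, gap_extend = ge, window = L)
      S <- outer(seq_len(L), seq_len(L),
                 Vectorize(function(i, j) ppa_score(A, i, B, j)))
      expect_equal(s_profile(A, B, par), enum_align_score(S, go, ge),
                   tolerance = 1e-9)
    }
  })
})

test_that("alignment score is symmetric, gap-monotone and diagonal-bounded", {
  withr::with_seed(24, {
    for (trial in 1:25) {
      A <- random_profile(8)
      B <- random_profile(8)
      par <- align_params(window = 8L)
      s1 <- s_profile(A, B, par)
      expect_equal(s1, s_profile(B, A, par), tolerance = 1e-9)
      # the gapless diagonal is a feasible global alignment.
      diag_sum <- sum(vapply(1:8, function(i) ppa_score(A, i, B, i),
                             numeric(1)))
      expect_gte(s1 + 1e-9, diag_sum)
      # raising the gap-open penalty never helps.
      s2 <- s_profile(A, B, align_params(gap_open = 6, window = 8L))
      expect_lte(s2, s1 + 1e-9)
    }
  })
})

test_that("point-mass profiles with matrix score rows recover s_blosum62", {
  gapless <- align_params(gap_open = 1e6, gap_extend = 1e6, window = 7L)
  withr::with_seed(25, {
    for (trial in 1:30) {
      a <- random_window(7)
      b <- random_window(7)
      pa <- point_mass_profile(a)
      pb <- point_mass_profile(b)
      expect_equal(s_profile(pa, pb, gapless), s_blosum62(a, b),
                   tolerance = 1e-9)
    }
  })
})

test_that("the combined score multiplies positives and clamps otherwise", {
  par7 <- align_params(gap_open = 1e6, gap_extend = 1e6, window = 7L)
  a <- "AAAAAAA"
  res <- s_combined(a, a, point_mass_profile(a), point_mass_profile(a),
                    params = par7)
  expect_equal(res$s_blosum, 28)
  expect_equal(res$s_profile, 28)
  expect_equal(res$s_combined, 28 * 28)
  expect_equal(res$raw_product, 28 * 28)

  # W-vs-G columns score -2 each, so s_blosum < 0 and the product clamps.
  b <- "WWWWWWW"
  g <- "GGGGGGG"
  res <- s_combined(b, g, point_mass_profile(b), point_mass_profile(g),
                    params = par7)
  expect_lt(res$s_blosum, 0)
  expect_equal(res$s_combined, 0)
  expect_equal(res$raw_product, res$s_blosum * res$s_profile)
})

test_that("similarity matrices are symmetric and match pairwise calls", {
  ref <- separable_refset(n_pos = 3L, n_neg = 3L)
  sim <- similarity_matrix(ref)
  expect_identical(sim$s_combined, t(sim$s_combined))
  expect_identical(sim$s_blosum, t(sim$s_blosum))
  pep <- tidy(ref)
  for (idx in list(c(1L, 2L), c(2L, 5L), c(4L, 6L))) {
    i <- pep$id[idx[1]]
    j <- pep$id[idx[2]]
    direct <- s_combined(pep$window7[idx[1]], pep$window7[idx[2]],
                         ref$profiles[[i]], ref$profiles[[j]])
    expect_equal(sim$s_blosum[i, j], direct$s_blosum)
    expect_equal(sim$s_profile[i, j], direct$s_profile, tolerance = 1e-9)
    expect_equal(sim$s_combined[i, j], direct$s_combined, tolerance = 1e-9)
  }
})

test_that("similarity caches round-trip through TSV", {
  ref <- separable_refset(n_pos = 3L, n_neg = 4L)
  cache <- withr::local_tempfile(fileext = ".tsv")
  sim <- similarity_matrix(ref, cache = cache)
  expect_true(file.exists(cache))
  back <- similarity_matrix(ref, cache = cache)
  off <- upper.tri(sim$s_combined)
  expect_equal(back$s_combined[off], sim$s_combined[off], tolerance = 1e-9)
  expect_equal(back$s_profile[off], sim$s_profile[off], tolerance = 1e-9)
})

test_that("empty peptide sets give empty matrices", {
  ref <- separable_refset(n_pos = 2L, n_neg = 2L)
  ref$peptides <- ref$peptides[0, ]
  sim <- similarity_matrix(ref)
  expect_identical(dim(sim$s_combined), c(0L, 0L))
  expect_identical(nrow(tidy(sim)), 0L)
})
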