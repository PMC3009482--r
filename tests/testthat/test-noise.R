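test_that("top_hits sorts by score with deterministic tie-breaking", {
  sc <- c(A = 0.9, B = 0.5, C = 0.1)
  expect_identical(top_hits(sc, 2), c("A", "B"))
  # tie at the boundary: lexicographically smaller id retained.
  sc <- c(Z = 0.5, A = 0.5, M = 0.9)
  expect_identical(top_hits(sc, 2), c("M", "A"))
  expect_warning(got <- top_hits(sc, 5), "clamping")
  expect_identical(got, c("M", "A", "Z"))

  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(3:30, 1)
      sc <- setNames(round(runif(n), 2), paste0("x", sample(100, n)))
      k <- sample(n, 1)
      ord <- order(-sc, names(sc))
      expect_identical(top_hits(sc, k), names(sc)[ord][1:k])
    }
  })
})

test_that("the indirect matrix keeps each hit's top-alpha neighbours", {
  fx <- figure1_fixture()
  M <- indirect_matrix(fx$query, fx$sim, 1)
  expect_identical(rownames(M), "P2")
  expect_identical(sum(M != 0), 1L)  # P2's single best neighbour
  expect_equal(unname(M["P2", "P1"]), 0.61)

  M <- indirect_matrix(fx$query, fx$sim, fx$params$alpha)
  expect_identical(rownames(M), c("P2", "P5", "N1", "N4", "N5"))
  expect_false(fx$query %in% colnames(M))
  expect_true(all(rowSums(M != 0) <= fx$params$alpha))
  expect_true(all(M >= 0))
  # per-row independent recomputation of the nonzero pattern.
  S <- fx$sim$s_combined
  ref_ids <- setdiff(rownames(S), fx$query)
  for (j in rownames(M)) {
    row <- S[j, setdiff(ref_ids, j)]
    keep <- names(row)[order(-row, names(row))][seq_len(fx$params$alpha)]
    expect_setequal(colnames(M)[M[j, ] != 0], keep[row[keep] > 0])
  }
})

test_that("indirect scores reproduce the worked-example arithmetic", {
  labels <- c(P1 = "positive", P2 = "positive", P4 = "positive",
              N3 = "negative")
  M <- matrix(0, 1, 3, dimnames = list("P2", c("P1", "P4", "N3")))
  M["P2", ] <- c(0.61, 0.01, 0.50)
  sc <- indirect_scores(M, labels, weight = 10)
  expect_equal(unname(sc["P2"]), 10 * (0.61 + 0.01) - 0.50)
  expect_equal(unname(sc["P2"]), 5.70)
  # both endpoints receive contributions.
  expect_equal(unname(sc["P1"]), 10 * 0.61)
  expect_equal(unname(sc["N3"]), -10 * 0.50)
  # peptides with no relationships score zero.
  M0 <- matrix(0, 1, 3, dimnames = dimnames(M))
  expect_true(all(indirect_scores(M0, labels, 10) == 0))
  expect_error(indirect_scores(M, labels[-1], 10),
               class = "phoskin_input_error")
})

test_that("indirect scores match a brute-force contribution oracle", {
  oracle <- function(M, labels, w) {
    sc <- setNames(numeric(ncol(M)), colnames(M))
    for (j in rownames(M)) {
      for (i in colnames(M)) {
        v <- M[j, i]
        if (v == 0) next
        sgn <- if (labels[[j]] == labels[[i]]) 1 else -1
        sc[j] <- sc[j] + sgn * (if (labels[[i]] == "positive") w else 1) * v
        sc[i] <- sc[i] + sgn * (if (labels[[j]] == "positive") w else 1) * v
      }
    }
    sc
  }
  withr::with_seed(32, {
    for (trial in 1:25) {
      n <- sample(4:10, 1)
      ids <- paste0("r", seq_len(n))
      labels <- setNames(sample(c("positive", "negative"), n, TRUE), ids)
      hits <- sample(ids, sample(2:n, 1))
      M <- matrix(rbinom(length(hits) * n, 1, 0.4) * round(runif(length(hits) * n), 2),
                  length(hits), n, dimnames = list(hits, ids))
      for (h in hits) M[h, h] <- 0
      w <- sample(c(1, 5, 10), 1)
      expect_equal(indirect_scores(M, labels, w), oracle(M, labels, w),
                   tolerance = 1e-12)
    }
  })
})

test_that("classification reproduces the worked example decision", {
  fx <- figure1_fixture()
  res <- classify_peptide(fx$query, fx$sim, fx$params)
  expect_true(res$predicted)
  expect_equal(res$confidence, 0.75)
  expect_identical(res$n_pos_top_beta, 3L)
})

test_that("boundary and degenerate decisions follow strict-gamma semantics", {
  # 10 labelled peptides plus query; direct scores rank negatives first.
  ids <- c(paste0("p", 1:3), paste0("n", 1:7), "q")
  S <- matrix(0, 11, 11, dimnames = list(ids, ids))
  S["q", ] <- c(1, 1, 1, 9, 8, 7, 6, 5, 4, 3, 0)
  S[, "q"] <- S["q", ]
  labels <- setNames(c(rep("positive", 3), rep("negative", 7), "unknown"),
                     ids)
  sim <- injected_similarity(S, labels)
  # top-beta all negatives: confidence 0, predicted negative.
  res <- classify_peptide("q", sim, noise_params(3, 4, 1, 10),
                          feature = "combined")
  expect_false(res$predicted)
  expect_equal(res$confidence, 0)
  # exactly gamma positives in the top beta is still negative.
  S["q", c("p1", "p2")] <- c(10, 9.5)
  S[, "q"] <- S["q", ]
  sim <- injected_similarity(S, labels)
  res <- classify_peptide("q", sim, noise_params(3, 4, 2, 10),
                          feature = "combined")
  expect_identical(res$n_pos_top_beta, 2L)
  expect_false(res$predicted)
  res <- classify_peptide("q", sim, noise_params(3, 4, 1, 10),
                          feature = "combined")
  expect_true(res$predicted)
})

test_that("rankings are invariant to positive rescaling of the scores", {
  fx <- figure1_fixture()
  base <- classify_peptide(fx$query, fx$sim, fx$params)
  scaled <- injected_similarity(fx$sim$s_combined * 37.5, fx$labels)
  res <- classify_peptide(fx$query, scaled, fx$params)
  expect_identical(res$predicted, base$predicted)
  expect_identical(res$confidence, base$confidence)
  expect_identical(res$n_pos_top_beta, base$n_pos_top_beta)
})

test_that("global label swaps leave indirect scores unchanged at weight 1", {
  # Same-label relationships are signal whichever label the pair shares, so
  # a global positive/negative swap preserves every contribution when the
  # positive weight is 1.
  withr::with_seed(33, {
    for (trial in 1:10) {
      sim <- random_injected_sim(4, 4, seed = trial)
      M <- indirect_matrix("qry", sim, 3)
      labels <- sim$labels
      flipped <- ifelse(labels == "positive", "negative",
                        ifelse(labels == "negative", "positive", labels))
      names(flipped) <- names(labels)
      expect_equal(indirect_scores(M, labels, weight = 1),
                   indirect_scores(M, flipped, weight = 1))
    }
  })
})

test_that("a hit without indirect support ranks below supported peptides", {
  fx <- figure1_fixture()
  S <- fx$sim$s_combined
  # strip N5's relationships: it keeps its direct rank but loses support.
  S["N5", c("N2", "N3")] <- 0
  S[c("N2", "N3"), "N5"] <- 0
  sim <- injected_similarity(S, fx$labels)
  M <- indirect_matrix(fx$query, sim, fx$params$alpha)
  sc <- indirect_scores(M, fx$labels, fx$params$weight)
  expect_equal(unname(sc["N5"]), 0)
  supported <- names(sc)[sc > 0]
  ranking <- names(sort(sc, decreasing = TRUE))
  expect_true(all(match(supported, ranking) < match("N5", ranking)))
})

test_that("equal indirect scores fall back to direct-similarity order", {
  # With one positive and one negative hit whose rows are dense and equal,
  # every non-hit's contributions cancel, so the top-beta is decided by
  # direct similarity alone -- the k-NN majority-vote limit.
  ids <- c(paste0("p", 1:4), paste0("n", 1:4), "q")
  S <- matrix(0, 9, 9, dimnames = list(ids, ids))
  S["q", ] <- c(9, 4, 3.5, 3, 8, 2.5, 2, 1.5, 0)  # hits: p1 and n1
  S[, "q"] <- S["q", ]
  for (h in c("p1", "n1")) {
    others <- setdiff(ids, c("p1", "n1", "q"))
    S[h, others] <- 1
    S[others, h] <- 1
  }
  labels <- setNames(c(rep("positive", 4), rep("negative", 4), "unknown"),
                     ids)
  sim <- injected_similarity(S, labels)
  res <- classify_peptide("q", sim, noise_params(2, 4, 1, 1))
  M <- indirect_matrix("q", sim, 2)
  sc <- indirect_scores(M, labels, 1)
  non_hits <- setdiff(names(sc), c("p1", "n1"))
  expect_true(all(sc[non_hits] == 0))
  # direct order among the zero-scored: p2, p3, p4, n2 -> 3 positives.
  expect_identical(res$n_pos_top_beta, 3L)
  expect_true(res$predicted)
})

test_that("direct-feature classification demotes unsupported direct hits", {
  fx <- figure1_fixture()
  direct_res <- classify_peptide(fx$query, fx$sim, fx$params,
                                 feature = "combined")
  noise_res <- classify_peptide(fx$query, fx$sim, fx$params)
  # N1 is the 3rd-best direct hit but has no positive indirect support.
  S <- fx$sim$s_combined
  ref_ids <- setdiff(rownames(S), fx$query)
  direct_rank <- match("N1", ref_ids[order(-S[fx$query, ref_ids], ref_ids)])
  M <- indirect_matrix(fx$query, fx$sim, fx$params$alpha)
  sc <- indirect_scores(M, fx$labels, fx$params$weight)
  indirect_rank <- match("N1", names(sort(sc, decreasing = TRUE)))
  expect_identical(direct_rank, 3L)
  expect_gt(indirect_rank, direct_rank)
  # direct ranking sees only 2 positives in its top-4 and misses the call;
  # the indirect re-ranking rescues it.
  expect_false(direct_res$predicted)
  expect_true(noise_res$predicted)
})

test_that("the alternative weight mode only boosts positive pairs", {
  labels <- c(P1 = "positive", P2 = "positive", N1 = "negative",
              N2 = "negative")
  M <- matrix(0, 2, 4, dimnames = list(c("P1", "N1"), names(labels)))
  M["P1", "P2"] <- 1
  M["P1", "N2"] <- 1
  M["N1", "N2"] <- 1
  partner <- indirect_scores(M, labels, 10)
  pp <- indirect_scores(M, labels, 10, weight_mode = "pos_pairs")
  expect_equal(unname(partner["P1"]), 10 - 1)     # +w(P2) - w(N2)
  expect_equal(unname(pp["P1"]), 10 - 1)          # pp pair still weighted
  expect_equal(unname(partner["N2"]), -10 + 1)    # partner weight on P1
  expect_equal(unname(pp["N2"]), -1 + 1)          # cross pair unweighted
})
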