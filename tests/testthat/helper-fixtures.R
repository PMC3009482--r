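# Shared helpers: random peptides/profiles, an independent brute-force
# affine-alignment enumerator, and small hand-built reference sets.

AA <- aa_alphabet(padding = FALSE)

random_window <- function(n = 7L) {
  paste(sample(AA, n, replace = TRUE), collapse = "")
}

make_profile <- function(freq, score) {
  phoskin:::new_profile(freq, score, "synthetic")
}

random_profile <- function(L, score_scale = 2) {
  freq <- matrix(runif(L * 20L), L, 20L)
  freq <- freq / rowSums(freq)
  score <- matrix(runif(L * 20L, -score_scale, score_scale), L, 20L)
  make_profile(freq, score)
}

# Point-mass profile of a residue string: frequency 1 on the observed
# residue, score row = the substitution-matrix row.
point_mass_profile <- function(window, matrix = blosum62()) {
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  freq <- base::matrix(0, L, 20L, dimnames = list(NULL, AA))
  score <- base::matrix(0, L, 20L, dimnames = list(NULL, AA))
  for (i in seq_len(L)) {
    freq[i, chars[i]] <- 1
    score[i, ] <- matrix[chars[i], AA]
  }
  make_profile(freq, score)
}

# Independent oracle: enumerate every global alignment, costing each
# maximal gap run as open + (len - 1) * extend (switching gap type opens a
# new run). Exponential; only for lengths <= 4.
enum_align_score <- function(S, gap_open, gap_extend) {
  n <- nrow(S)
  m <- ncol(S)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i == n && j == m) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, "M", acc + S[i + 1L, j + 1L])
    if (i < n) {
      rec(i + 1L, j, "X",
          acc - (if (identical(last, "X")) gap_extend else gap_open))
    }
    if (j < m) {
      rec(i, j + 1L, "Y",
          acc - (if (identical(last, "Y")) gap_extend else gap_open))
    }
  }
  rec(0L, 0L, "", 0)
  best
}

# A hand-built reference set: windows over a restricted alphabet so the
# classes are cleanly separable (positives basic R/K flanks, negatives
# small G/A/V flanks, both centred on S).
separable_refset <- function(n_pos = 12L, n_neg = 24L, seed = 42L) {
  withr::with_seed(seed, {
    mk <- function(alphabet, n) {
      vapply(seq_len(n), function(i) {
        w <- sample(alphabet, 41L, replace = TRUE)
        w[21L] <- "S"
        paste(w, collapse = "")
      }, character(1))
    }
    w41 <- c(mk(c("R", "K"), n_pos), mk(c("G", "A", "V"), n_neg))
    ids <- c(sprintf("POS%02d", seq_len(n_pos)),
             sprintf("NEG%02d", seq_len(n_neg)))
    peptides <- tibble::tibble(
      protein_id = ids, position = 21L, residue = "S", id = ids,
      window7 = substr(w41, 18L, 24L), window41 = w41,
      kinase = "SEP", label = rep(c("positive", "negative"),
                                  c(n_pos, n_neg)))
    profiles <- lapply(w41, pseudo_profile)
    names(profiles) <- ids
    phoskin:::new_ref_set("SEP", peptides, profiles,
                          neg_ratio = n_neg %/% n_pos, seed = seed)
  })
}

# Mixed-centre fixture for reference-set construction: one long protein
# with annotated S and T sites for two kinases.
mixed_site_fixture <- function(seed = 7L) {
  withr::with_seed(seed, {
    chars <- sample(AA, 6000L, replace = TRUE)
    seqs <- c(PROT1 = paste(chars, collapse = ""))
    sty <- which(chars %in% c("S", "T"))
    s_pos <- sty[chars[sty] == "S"]
    t_pos <- sty[chars[sty] == "T"]
    sites <- tibble::tibble(
      protein_id = "PROT1",
      position = c(s_pos[1:16], t_pos[1:8], s_pos[17:20]),
      residue = c(rep("S", 16), rep("T", 8), rep("S", 4)),
      kinase = c(rep("KIN_A", 24), rep("KIN_B", 4)))
    list(sequences = seqs, sites = sites)
  })
}

# Injected similarity object over labelled peptides from a dense random
# score table (symmetric, zero diagonal).
random_injected_sim <- function(n_pos, n_neg, seed, query = TRUE) {
  withr::with_seed(seed, {
    ids <- c(sprintf("p%02d", seq_len(n_pos)),
             sprintf("n%02d", seq_len(n_neg)), if (query) "qry")
    n <- length(ids)
    S <- matrix(0, n, n, dimnames = list(ids, ids))
    S[upper.tri(S)] <- round(runif(n * (n - 1) / 2, 0, 5), 2)
    S <- S + t(S)
    labels <- setNames(c(rep("positive", n_pos), rep("negative", n_neg),
                         if (query) "unknown"), ids)
    injected_similarity(S, labels)
  })
}
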