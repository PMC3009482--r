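# Seeded generators: planted-motif positive peptides, background
# negatives, synthetic parent proteins and profiles, plus the miniature
# worked-example fixture for the indirect scorer.

#' Position-weight-matrix motif model for synthetic phosphopeptides
#'
#' A 7-window motif around a fixed S/T/Y centre. Each informative column
#' mixes a point mass on a consensus residue with the background
#' distribution: `strength * delta + (1 - strength) * background`; columns
#' without a consensus residue, and all flanking positions of the
#' 41-window, are pure background. The default consensus is a basophilic
#' kinase-like pattern (R at -3 and -2, a hydrophobic L at +1).
#'
#' @param center Centre residue, one of `"S"`, `"T"`, `"Y"`.
#' @param strength Mixing coefficient between 0 and 1; 0 makes positives
#'   indistinguishable from background, 1 makes the motif deterministic at
#'   the consensus positions.
#' @param consensus Named character vector of consensus residues by offset
#'   (as characters `"-3"` ... `"3"`, centre excluded).
#' @return Object of class `motif_model` with the 20 x 7 column-stochastic
#'   `pwm` (columns = offsets -3 ... +3).
#' @export
motif_model <- function(center = "S", strength = 0.9,
                        consensus = c("-3" = "R", "-2" = "R", "1" = "L")) {
  stopifnot(center %in% PHOSPHO_RESIDUES, strength >= 0, strength <= 1,
            all(consensus %in% AA20))
  offsets <- as.character(-3:3)
  pwm <- matrix(rep(BLOSUM62_BACKGROUND, 7L), nrow = 20L,
                dimnames = list(AA20, offsets))
  for (off in names(consensus)) {
    col <- (1 - strength) * BLOSUM62_BACKGROUND
    col[consensus[[off]]] <- col[consensus[[off]]] + strength
    pwm[, off] <- col
  }
  centre_col <- numeric(20L)
  names(centre_col) <- AA20
  centre_col[center] <- 1
  pwm[, "0"] <- centre_col
  if (any(abs(colSums(pwm) - 1) > 1e-9)) {
    abort("motif columns must sum to 1", class = "phoskin_input_error")
  }
  structure(list(pwm = pwm, center = center, strength = strength),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> centre %s, strength %.2f\n",
              x$center, x$strength))
  invisible(x)
}

sample_background <- function(n) {
  paste(sample(AA20, n, replace = TRUE, prob = BLOSUM62_BACKGROUND),
        collapse = "")
}

# One synthetic substrate protein with the 7-mer motif planted at `pos`.
# The rest of the planted site's 41-window is kept free of the centre
# residue type, so that every candidate negative is a genuine background
# window rather than a window overlapping the planted motif.
plant_motif <- function(motif, length_protein, pos) {
  chars <- strsplit(sample_background(length_protein), "", fixed = TRUE)[[1L]]
  for (k in -3:3) {
    chars[pos + k] <- sample(AA20, 1L, prob = motif$pwm[, as.character(k)])
  }
  flank <- setdiff(max(1L, pos - 20L):min(length_protein, pos + 20L), pos)
  clash <- flank[chars[flank] == motif$center]
  if (length(clash) > 0) {
    bg <- BLOSUM62_BACKGROUND[setdiff(AA20, motif$center)]
    chars[clash] <- sample(names(bg), length(clash), replace = TRUE,
                           prob = bg)
  }
  paste(chars, collapse = "")
}

# Dirichlet-style jitter of profile frequency rows: row' ~ normalised
# Gamma(concentration * row). Larger concentration = milder noise.
jitter_profile <- function(profile, concentration) {
  freq <- profile$freq
  for (r in seq_len(nrow(freq))) {
    g <- rgamma(20L, shape = concentration * pmax(freq[r, ], 1e-6))
    freq[r, ] <- g / sum(g)
  }
  new_profile(freq, profile$score, "synthetic")
}

#' Generate a synthetic reference set with a planted motif
#'
#' Synthesises parent proteins (one 360-residue substrate per positive,
#' carrying the motif at a random interior position, plus additional
#' background proteins if the negative pool would fall short), builds the
#' phosphosite table for the planted sites, and assembles the reference set
#' through [build_ref_set()] -- so the generated data take exactly the
#' path real FASTA/TSV input would. Negatives are background S/T/Y
#' occurrences at `neg_ratio` per positive. Profiles are deterministic
#' pseudo-profiles, optionally jittered (`profile_noise > 0` applies a
#' seeded Dirichlet perturbation with concentration `1 / profile_noise`).
#'
#' @param n_pos Number of positive peptides (>= 2).
#' @param motif A [motif_model()].
#' @param neg_ratio Negatives per positive (default 10).
#' @param seed Integer seed controlling all randomness.
#' @param profile_noise 0 (default) for deterministic pseudo-profiles, or a
#'   positive noise level.
#' @param kinase Name recorded for the synthetic kinase group.
#' @return A `ref_set` with attributes `"sequences"` (named character
#'   vector) and `"sites"` (the planted-site tibble), so the dataset can be
#'   round-tripped through [write_fasta()] / [write_sites()].
#' @export
simulate_refset <- function(n_pos = 30L, motif = motif_model(),
                            neg_ratio = 10L, seed = 1L, profile_noise = 0,
                            kinase = "SYNTH") {
  if (n_pos < 2) {
    abort("n_pos must be at least 2", class = "phoskin_input_error")
  }
  dat <- withr::with_seed(seed, {
    sub_len <- 360L
    positions <- sample(21:(sub_len - 20L), n_pos, replace = TRUE)
    substrates <- vapply(positions, function(p) {
      plant_motif(motif, sub_len, p)
    }, character(1))
    names(substrates) <- sprintf("SUB%03d", seq_len(n_pos))
    # Background proteins until the negative pool is comfortably larger
    # than the sample size (centre-type matched).
    bg <- character(0)
    need <- as.integer(ceiling(1.25 * neg_ratio * n_pos))
    count_candidates <- function(seqs) {
      sum(vapply(seqs, function(s) {
        lengths(regmatches(s, gregexpr(motif$center, s, fixed = TRUE)))
      }, integer(1)))
    }
    while (count_candidates(c(substrates, bg)) - n_pos < need) {
      bg <- c(bg, setNames(sample_background(240L),
                           sprintf("BG%03d", length(bg) + 1L)))
    }
    list(sequences = c(substrates, bg), positions = positions)
  })
  sites <- tibble(protein_id = names(dat$sequences)[seq_len(n_pos)],
                  position = dat$positions,
                  residue = motif$center, kinase = kinase)
  ref <- build_ref_set(sites, dat$sequences, kinase, neg_ratio = neg_ratio,
                       min_sites = 2L, seed = seed + 1000L)
  if (profile_noise > 0) {
    ref$profiles <- withr::with_seed(seed + 2000L, {
      purrr::map(ref$profiles, jitter_profile,
                 concentration = 1 / profile_noise)
    })
  }
  attr(ref, "sequences") <- dat$sequences
  attr(ref, "sites") <- sites
  ref
}

#' Miniature worked-example fixture for the indirect scorer
#'
#' A 10-peptide reference set (5 positives `P1..P5`, 5 negatives
#' `N1..N5`) plus a query `QRY`, with an injected combined-score table in
#' which the query's top-5 hits are two positives and three negatives and
#' the positive hit `P2`'s indirect relationships carry the values 0.61
#' (to `P1`), 0.01 (to `P4`) and 0.50 (to `N3`). With a positive weight of
#' 10, `P2`'s indirect score is `10 * (0.61 + 0.01) - 0.50 = 5.70`; the
#' top-4 peptides by indirect score are `P3`, `P2`, `P4` and `N2`, so with
#' `beta = 4` and `gamma = 2` the query is predicted positive with
#' confidence 0.75.
#'
#' @return List with elements `sim` (an [injected_similarity()] object
#'   over the 11 peptides), `query` (`"QRY"`), `params`
#'   ([noise_params()] with alpha 5, beta 4, gamma 2, weight 10) and
#'   `labels`.
#' @export
figure1_fixture <- function() {
  ids <- c(paste0("P", 1:5), paste0("N", 1:5), "QRY")
  labels <- setNames(c(rep("positive", 5), rep("negative", 5), "unknown"),
                     ids)
  S <- matrix(0, 11L, 11L, dimnames = list(ids, ids))
  set_pair <- function(a, b, v) {
    S[a, b] <<- v
    S[b, a] <<- v
  }
  # Query direct scores: top-5 = P2, P5, N1, N4, N5 (2 positives, 3
  # negatives).
  qs <- c(P2 = 5.0, P5 = 4.5, N1 = 4.2, N4 = 4.1, N5 = 4.05,
          P1 = 1.0, P3 = 0.9, P4 = 0.8, N2 = 0.7, N3 = 0.6)
  for (id in names(qs)) set_pair("QRY", id, qs[[id]])
  # Reference-reference relationships. Scores between any two hits are
  # zero, so each relationship appears in exactly one row of the indirect
  # matrix and every contribution is single-counted; in particular P2's
  # score is exactly 10 * (0.61 + 0.01) - 0.50 = 5.70.
  set_pair("P2", "P1", 0.61)
  set_pair("P2", "P4", 0.01)
  set_pair("P2", "N3", 0.50)
  set_pair("P5", "P3", 0.60)
  set_pair("P5", "P4", 0.55)
  set_pair("P5", "N3", 7.5)
  set_pair("N1", "P1", 2.0)
  set_pair("N4", "N2", 2.2)
  set_pair("N4", "N3", 0.3)
  set_pair("N5", "N2", 2.1)
  set_pair("N5", "N3", 0.2)
  list(sim = injected_similarity(S, labels), query = "QRY",
       params = noise_params(alpha = 5L, beta = 4L, gamma = 2L,
                             weight = 10),
       labels = labels)
}
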