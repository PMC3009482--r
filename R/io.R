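# Readers and writers for the external formats (FASTA, phosphosite TSV,
# reference-set directory) and reference-set construction with 10:1
# negative sampling.

#' Read protein sequences from FASTA
#'
#' Ids are the first whitespace-delimited token of each header; sequences
#' are upper-cased and any character outside the 20-letter alphabet is
#' mapped to `X` (a warning reports how many).
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA ", path, ": ",
                                     conditionMessage(e)),
                              class = "phoskin_format_error"))
  if (length(set) == 0) {
    abort(paste0("empty FASTA file: ", path), class = "phoskin_format_error")
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  cleaned <- gsub(sprintf("[^%s]", paste(AA20, collapse = "")), "X", seqs)
  n_sub <- sum(nchar(gsub(sprintf("[%s]", paste(AA20, collapse = "")), "",
                          seqs)))
  if (n_sub > 0) {
    warn(sprintf("%d non-standard residue(s) mapped to X in %s", n_sub, path))
  }
  cleaned
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a phosphosite table
#'
#' Expects a tab-separated file with header columns `protein_id`,
#' `position`, `residue`, `kinase` (Phospho.ELM-style, 1-based
#' coordinates). Rows with a residue outside S/T/Y, a non-positive
#' position, or (when `sequences` is given) a residue disagreeing with the
#' protein sequence are rejected; the rejected rows and reasons are
#' attached as attribute `"rejected"` and counted in a warning.
#'
#' @param path TSV file.
#' @param sequences Optional named sequences for validation.
#' @return Tibble of validated site records.
#' @export
read_sites <- function(path, sequences = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("protein_id", "position", "residue", "kinase")
  if (!all(need %in% names(df))) {
    abort(paste0("phosphosite table ", path, " lacks column(s): ",
                 paste(setdiff(need, names(df)), collapse = ", ")),
          class = "phoskin_format_error")
  }
  df <- df[need]
  pos_num <- suppressWarnings(as.integer(df$position))
  bad_pos <- which(is.na(pos_num) & !is.na(df$position))
  if (length(bad_pos) > 0) {
    abort(sprintf("non-integer position at data row %d of %s",
                  bad_pos[1L], path), class = "phoskin_format_error")
  }
  df$position <- pos_num
  df$residue <- toupper(df$residue)

  reason <- rep(NA_character_, nrow(df))
  reason[!(df$residue %in% PHOSPHO_RESIDUES)] <- "residue not S/T/Y"
  reason[is.na(reason) & (is.na(df$position) | df$position < 1L)] <-
    "invalid position"
  if (!is.null(sequences)) {
    idx <- which(is.na(reason))
    for (i in idx) {
      p <- df$protein_id[i]
      if (!p %in% names(sequences)) {
        reason[i] <- "protein not in FASTA"
      } else if (df$position[i] > nchar(sequences[[p]])) {
        reason[i] <- "position beyond sequence end"
      } else if (substr(sequences[[p]], df$position[i], df$position[i]) !=
                 df$residue[i]) {
        reason[i] <- "residue disagrees with sequence"
      }
    }
  }
  keep <- is.na(reason)
  rejected <- dplyr::mutate(df[!keep, ], reason = reason[!keep])
  if (nrow(rejected) > 0) {
    warn(sprintf("rejected %d of %d site row(s) in %s",
                 nrow(rejected), nrow(df), path))
  }
  out <- as_tibble(df[keep, ])
  attr(out, "rejected") <- as_tibble(rejected)
  out
}

#' @rdname read_sites
#' @param sites Site tibble to write.
#' @export
write_sites <- function(sites, path) {
  readr::write_tsv(sites[c("protein_id", "position", "residue", "kinase")],
                   path, progress = FALSE)
  invisible(path)
}

# Allocate a total count over types proportionally to `target` counts,
# floors first, then largest remainders.
proportional_allocation <- function(target, total) {
  share <- target / sum(target) * total
  base <- floor(share)
  rem <- share - base
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(rem, names(target), decreasing = c(TRUE, FALSE),
                   method = "radix")[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Build a labelled reference set for one kinase
#'
#' Positives are every validated site of `kinase` (at least `min_sites` of
#' them; the published filter keeps kinase groups with more than 20 known
#' sites, hence the default of 21). Candidate negatives are every S/T/Y
#' occurrence in the same protein collection that is not annotated as
#' phosphorylated by any kinase in `sites`; they are sampled without
#' replacement, `neg_ratio` per positive, with centre-residue types matched
#' proportionally to the positives. Every peptide gets a 41-window profile,
#' either sliced from a supplied whole-protein profile or derived with
#' [pseudo_profile()].
#'
#' @param sites Validated site tibble (all kinases; used both for the
#'   positives and to exclude known sites from the negative pool).
#' @param sequences Named protein sequences.
#' @param kinase Kinase (group) name to build the set for.
#' @param neg_ratio Negatives sampled per positive (default 10).
#' @param min_sites Minimum number of positives (default 21).
#' @param seed Integer seed for the negative sampling.
#' @param profiles Optional named list of whole-protein `peptide_profile`s
#'   (names = protein ids), e.g. from [read_pssm()].
#' @param force_weight Optional fixed positive weight for the noise reducer.
#' @param pool `"pooled"` (default): negatives drawn from the pooled
#'   candidate list across all proteins; `"per_protein"`: each type's
#'   quota is first allocated across proteins proportionally to their
#'   candidate counts.
#' @return Object of class `ref_set`: peptide tibble (`id`, `protein_id`,
#'   `position`, `residue`, `window7`, `window41`, `label`, `kinase`), a
#'   profile list keyed by peptide id, and the sampling metadata.
#' @export
build_ref_set <- function(sites, sequences, kinase, neg_ratio = 10L,
                          min_sites = 21L, seed = 1L, profiles = NULL,
                          force_weight = NULL,
                          pool = c("pooled", "per_protein")) {
  stopifnot(is.data.frame(sites))
  pool <- match.arg(pool)
  pos_sites <- dplyr::filter(sites, .data$kinase == !!kinase)
  if (nrow(pos_sites) < min_sites) {
    abort(sprintf(
      "kinase '%s' below minimum: %d site(s), need at least %d",
      kinase, nrow(pos_sites), min_sites), class = "phoskin_min_sites_error")
  }
  pos <- peptide_windows(pos_sites, sequences)
  pos$label <- "positive"

  known <- paste0(sites$protein_id, "_", sites$position)
  types <- sort(unique(pos$residue))
  cand <- purrr::map_dfr(names(sequences), function(p) {
    chars <- strsplit(sequences[[p]], "", fixed = TRUE)[[1L]]
    hit <- which(chars %in% types)
    tibble(protein_id = p, position = hit, residue = chars[hit])
  })
  cand <- dplyr::filter(cand,
                        !paste0(.data$protein_id, "_", .data$position) %in% known)

  n_target <- as.integer(neg_ratio) * nrow(pos)
  pos_counts <- table(factor(pos$residue, levels = types))
  want <- setNames(proportional_allocation(as.numeric(pos_counts), n_target),
                   types)
  neg <- withr::with_seed(seed, {
    purrr::map_dfr(types, function(tp) {
      avail <- dplyr::filter(cand, .data$residue == tp)
      take <- want[[tp]]
      if (nrow(avail) < take) {
        warn(sprintf(
          "only %d candidate negatives with centre %s (wanted %d); taking all",
          nrow(avail), tp, take))
        take <- nrow(avail)
      }
      if (pool == "pooled" || take == nrow(avail)) {
        return(avail[sample.int(nrow(avail), take), ])
      }
      by_prot <- split(seq_len(nrow(avail)), avail$protein_id)
      quota <- proportional_allocation(lengths(by_prot), take)
      picked <- unlist(purrr::map2(by_prot, quota, function(rows, q) {
        rows[sample.int(length(rows), min(q, length(rows)))]
      }), use.names = FALSE)
      avail[picked, ]
    })
  })
  neg$kinase <- kinase
  neg <- peptide_windows(neg, sequences)
  neg$label <- "negative"

  peptides <- dplyr::arrange(
    dplyr::bind_rows(pos, neg),
    dplyr::desc(.data$label), .data$protein_id, .data$position)

  prof_list <- purrr::map(seq_len(nrow(peptides)), function(i) {
    p <- peptides$protein_id[i]
    if (!is.null(profiles) && p %in% names(profiles)) {
      profile_window(profiles[[p]], peptides$position[i], 20L)
    } else {
      pseudo_profile(peptides$window41[i])
    }
  })
  names(prof_list) <- peptides$id

  new_ref_set(kinase = kinase, peptides = peptides, profiles = prof_list,
              neg_ratio = as.integer(neg_ratio), seed = as.integer(seed),
              force_weight = force_weight)
}

new_ref_set <- function(kinase, peptides, profiles, neg_ratio, seed,
                        force_weight = NULL) {
  stopifnot(!anyDuplicated(peptides$id),
            all(peptides$id %in% names(profiles)))
  peptides <- as_tibble(peptides)
  attr(peptides, "rejected") <- NULL
  structure(list(kinase = kinase, peptides = as_tibble(peptides),
                 profiles = profiles[peptides$id],
                 neg_ratio = neg_ratio, seed = seed,
                 force_weight = force_weight),
            class = "ref_set")
}

#' @export
print.ref_set <- function(x, ...) {
  n_pos <- sum(x$peptides$label == "positive")
  n_neg <- sum(x$peptides$label == "negative")
  cat(sprintf("<ref_set> kinase '%s': %d positives, %d negatives (seed %d)\n",
              x$kinase, n_pos, n_neg, x$seed))
  invisible(x)
}

#' @method tidy ref_set
#' @export
tidy.ref_set <- function(x, ...) x$peptides

ref_labels <- function(ref) {
  setNames(ref$peptides$label, ref$peptides$id)
}

ref_counts <- function(ref) {
  c(n_positive = sum(ref$peptides$label == "positive"),
    n_negative = sum(ref$peptides$label == "negative"))
}

#' Write / read a reference set directory
#'
#' Layout: `meta.json` (kinase, counts, seed, ratio), `positives.tsv` and
#' `negatives.tsv` (peptide tables), and `profiles/<id>.tsv` with a
#' `profiles/index.json` mapping peptide ids to files and sources. All
#' plain text.
#'
#' @param ref A `ref_set`.
#' @param dir Directory to create.
#' @return `dir` (write) or a `ref_set` (read).
#' @export
write_ref_set <- function(ref, dir) {
  dir.create(file.path(dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
  meta <- list(kinase = ref$kinase,
               n_positive = unname(ref_counts(ref)[["n_positive"]]),
               n_negative = unname(ref_counts(ref)[["n_negative"]]),
               neg_ratio = ref$neg_ratio, seed = ref$seed,
               force_weight = ref$force_weight)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       null = "null")
  for (lab in c("positive", "negative")) {
    readr::write_tsv(dplyr::filter(ref$peptides, .data$label == lab),
                     file.path(dir, paste0(lab, "s.tsv")), progress = FALSE)
  }
  index <- purrr::imap(ref$profiles, function(pr, id) {
    f <- paste0(id, ".tsv")
    write_profile(pr, ref$peptides$window41[match(id, ref$peptides$id)],
                  file.path(dir, "profiles", f))
    list(file = f, source = pr$source)
  })
  jsonlite::write_json(index, file.path(dir, "profiles", "index.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_ref_set
#' @export
read_ref_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  peptides <- dplyr::bind_rows(
    readr::read_tsv(file.path(dir, "positives.tsv"), show_col_types = FALSE,
                    progress = FALSE),
    readr::read_tsv(file.path(dir, "negatives.tsv"), show_col_types = FALSE,
                    progress = FALSE))
  peptides$position <- as.integer(peptides$position)
  index <- jsonlite::read_json(file.path(dir, "profiles", "index.json"))
  profiles <- purrr::imap(index, function(entry, id) {
    read_profile(file.path(dir, "profiles", entry$file),
                 source = entry$source)
  })
  new_ref_set(kinase = meta$kinase, peptides = peptides, profiles = profiles,
              neg_ratio = meta$neg_ratio, seed = meta$seed,
              force_weight = meta$force_weight)
}
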