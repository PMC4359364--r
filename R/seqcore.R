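# Sequence core: translation, pairwise alignment, translated search and
# E-value calibration.  Every downstream module funnels its homology
# detection through search_protein_vs_transcripts().

.seq_cache <- new.env(parent = emptyenv())

# BLOSUM62 with the ambiguity translation X scoring 0 against everything,
# so runs of ambiguous codons neither attract nor repel alignments.
substitution_matrix <- function() {
  if (!is.null(.seq_cache$blosum62x)) return(.seq_cache$blosum62x)
  mat <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()), envir = environment())
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  .seq_cache$blosum62x <- mat
  mat
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1..+3 read the forward strand with offsets 0..2; frames -1..-3
#' read the reverse complement the same way.  Translation uses the
#' standard genetic code; stop codons are rendered as `*` (never dropped)
#' and codons containing `N` as `X`.
#'
#' @param seq A single nucleotide string over `A,C,G,T,N` (at least 3 nt).
#' @return A named character vector of length 6 with names
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @examples
#' translate_six_frames("ATGGCC")[["+1"]]  # "MA"
#' @export
translate_six_frames <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 3L) {
    stop("`seq` must be a single nucleotide string of length >= 3", call. = FALSE)
  }
  fwd <- toupper(seq)
  rev <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", fwd), "", fixed = TRUE)[[1]]),
               collapse = "")
  one <- function(x, offset) {
    n <- nchar(x)
    len <- ((n - offset) %/% 3L) * 3L
    if (len < 3L) return("")
    starts <- seq.int(offset + 1L, offset + len, by = 3L)
    codons <- substring(x, starts, starts + 2L)
    aa <- Biostrings::GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"  # any codon containing N (or other ambiguity)
    paste(aa, collapse = "")
  }
  c(
    `+1` = one(fwd, 0L), `+2` = one(fwd, 1L), `+3` = one(fwd, 2L),
    `-1` = one(rev, 0L), `-2` = one(rev, 1L), `-3` = one(rev, 2L)
  )
}

frame_translation <- function(seq, frame) {
  translate_six_frames(seq)[[frame_name(frame)]]
}

frame_name <- function(frame) {
  ifelse(frame > 0, paste0("+", frame), as.character(frame))
}

# Six-frame translations of a whole assembly as one AAStringSet plus a
# lookup table; this is the database every translated search scans.
assembly_frames <- function(transcripts) {
  stopifnot(is.data.frame(transcripts), nrow(transcripts) > 0)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  per_tx <- lapply(seq_len(nrow(transcripts)), function(i) {
    translate_six_frames(transcripts$seq[i])
  })
  info <- tibble::tibble(
    subject_id = rep(transcripts$id, each = 6L),
    frame = rep(c(1L, 2L, 3L, -1L, -2L, -3L), times = nrow(transcripts)),
    protein = unlist(per_tx, use.names = FALSE)
  )
  info <- info[nchar(info$protein) > 0L, ]
  list(
    aa = Biostrings::AAStringSet(info$protein),
    info = info,
    db_len = sum(nchar(transcripts$seq))
  )
}

#' Optimal pairwise protein alignment
#'
#' Needleman-Wunsch-style alignment under BLOSUM62 with affine gap costs
#' (a gap of length k costs `gap_open + k * gap_extend`).  `type =
#' "global"` penalises end gaps; `"overlap"` leaves both sequence ends
#' free, which is the mode used to lay a candidate protein onto the
#' canonical H3 annotation; `"local"` is Smith-Waterman.
#'
#' @param a,b Protein strings (query and subject; non-empty).
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @param type Alignment type.
#' @param query_id,subject_id Optional labels carried into the result.
#' @return An object of class `aa_alignment`: list with `score`,
#'   `pident`, `frame` (0 for protein-protein), absolute coordinates
#'   `q_start`, `q_end`, `s_start`, `s_end`, and the gapped aligned
#'   strings `q_aln`, `s_aln`.  Use [alignment_map()] for the per-column
#'   coordinate map.
#' @examples
#' aln <- align_global("MKVLA", "MKVLA")
#' aln$pident  # 100
#' @export
align_global <- function(a, b, gap_open = 11, gap_extend = 1,
                         type = c("global", "overlap", "local"),
                         query_id = "query", subject_id = "subject") {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend, type = type
  )
  structure(list(
    query_id = query_id, subject_id = subject_id,
    score = Biostrings::score(pa),
    pident = Biostrings::pid(pa),
    frame = 0L,
    q_start = Biostrings::start(Biostrings::pattern(pa)),
    q_end = Biostrings::end(Biostrings::pattern(pa)),
    s_start = Biostrings::start(Biostrings::subject(pa)),
    s_end = Biostrings::end(Biostrings::subject(pa)),
    q_aln = as.character(Biostrings::alignedPattern(pa)),
    s_aln = as.character(Biostrings::alignedSubject(pa))
  ), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %s vs %s  score=%.1f  pident=%.1f%%\n",
              x$query_id, x$subject_id, x$score, x$pident))
  cat(x$q_aln, "\n", x$s_aln, "\n", sep = "")
  invisible(x)
}

#' Per-column coordinate map of an alignment
#'
#' @param aln An `aa_alignment` from [align_global()].
#' @return A tibble with one row per alignment column: `column`, `q_pos`,
#'   `s_pos` (absolute residue positions, `NA` in gap columns), `q_res`,
#'   `s_res`.  Positions are strictly increasing outside gaps.
#' @export
alignment_map <- function(aln) {
  qc <- strsplit(aln$q_aln, "", fixed = TRUE)[[1]]
  sc <- strsplit(aln$s_aln, "", fixed = TRUE)[[1]]
  q_pos <- ifelse(qc == "-", NA_integer_, cumsum(qc != "-") + aln$q_start - 1L)
  s_pos <- ifelse(sc == "-", NA_integer_, cumsum(sc != "-") + aln$s_start - 1L)
  tibble::tibble(
    column = seq_along(qc),
    q_pos = as.integer(q_pos), s_pos = as.integer(s_pos),
    q_res = qc, s_res = sc
  )
}

# --- E-values -------------------------------------------------------------

# Cached Karlin-Altschul-style constants for the package's local search
# under BLOSUM62, gap open 11 / extend 1, uniform residue background.
# Regenerate with: calibrate_evalue(n_trials = 300, seed = 7)
EVALUE_CONSTANTS <- list(lambda = 0.3087772, K = 0.1009773)

#' E-value of a translated-search score
#'
#' Expected number of alignments of at least `score` between a random
#' query of `query_len` residues and a random nucleotide database of
#' `db_len` bases, under the extreme-value model E = K * m * n *
#' exp(-lambda * score).  The constants are calibrated empirically for
#' this package's scoring scheme with [calibrate_evalue()]; only
#' threshold comparisons of E-values are meaningful.
#'
#' @param score Alignment score(s).
#' @param query_len Query length in amino acids (> 0).
#' @param db_len Database length in nucleotides (> 0).
#' @param constants List with `lambda` and `K`.
#' @return Numeric E-value(s), >= 0, decreasing in `score`.
#' @examples
#' evalue_of(100, 135, 3e4) < evalue_of(50, 135, 3e4)
#' @export
evalue_of <- function(score, query_len, db_len, constants = EVALUE_CONSTANTS) {
  if (any(query_len <= 0) || any(db_len <= 0)) {
    stop("`query_len` and `db_len` must be positive", call. = FALSE)
  }
  constants$K * query_len * db_len * exp(-constants$lambda * score)
}

#' Calibrate E-value constants for the package's scoring scheme
#'
#' Runs `n_trials` translated searches of random protein queries against
#' random nucleotide transcript databases (all six frames, as in the real
#' search path), collects the per-search maximum local score, and fits a
#' Gumbel law by the method of moments:
#' `lambda = pi / (sd * sqrt(6))`, `K = exp(lambda * mu) / (m * n)` with
#' `mu` the Gumbel location, `m` the query length in aa and `n` the
#' database length in nt.  The shipped `EVALUE_CONSTANTS` are a cached
#' run of this routine.
#'
#' @param n_trials Number of null searches.
#' @param query_len Query length (aa) per trial.
#' @param n_seqs,seq_len Database composition per trial (transcripts, nt).
#' @param seed RNG seed.
#' @return List with `lambda` and `K`.
#' @export
calibrate_evalue <- function(n_trials = 300L, query_len = 200L,
                             n_seqs = 20L, seq_len = 450L, seed = 7L) {
  mat <- substitution_matrix()
  nt <- c("A", "C", "G", "T")
  mx <- with_seed(seed, {
    vapply(seq_len(n_trials), function(i) {
      q <- Biostrings::AAString(random_protein(query_len))
      tx <- tibble::tibble(
        id = paste0("t", seq_len(n_seqs)),
        seq = replicate(n_seqs, paste(sample(nt, seq_len, TRUE), collapse = ""))
      )
      frames <- assembly_frames(tx)
      max(Biostrings::pairwiseAlignment(
        frames$aa, q, substitutionMatrix = mat,
        gapOpening = 11, gapExtension = 1, type = "local", scoreOnly = TRUE
      ))
    }, numeric(1))
  })
  lambda <- pi / (stats::sd(mx) * sqrt(6))
  mu <- mean(mx) - 0.5772156649 / lambda
  K <- exp(lambda * mu) / (query_len * n_seqs * seq_len)
  list(lambda = lambda, K = K)
}

# --- Translated search ----------------------------------------------------

#' Search protein queries against six-frame translated transcripts
#'
#' The tblastn-style operation at the heart of the pipeline: each query is
#' locally aligned against all six reading frames of every transcript;
#' per (query, transcript) pair only the best frame is kept, scored with
#' [evalue_of()] against the whole-assembly search space, and hits below
#' the significance threshold are returned sorted by ascending E-value.
#'
#' @param query A protein string or a named character vector of queries.
#' @param transcripts A data frame with columns `id` and `seq` (nucleotide).
#' @param sig_threshold E-value significance cutoff.
#' @return A tibble of hits: `query`, `subject`, `frame`, `score`,
#'   `pident`, `evalue`, `q_start`, `q_end`, `s_start`, `s_end` (amino
#'   acid coordinates within the hit frame's translation).  Zero rows when
#'   nothing is significant.
#' @examples
#' tx <- tibble::tibble(id = "t1", seq = back_translate("MKVLAEQRKDFW", seed = 1))
#' search_protein_vs_transcripts("MKVLAEQRKDFW", tx, sig_threshold = 1)
#' @export
search_protein_vs_transcripts <- function(query, transcripts,
                                          sig_threshold = 1e-10) {
  if (!is.data.frame(transcripts) || nrow(transcripts) == 0) {
    stop("`transcripts` must be a non-empty data frame", call. = FALSE)
  }
  if (is.null(names(query))) {
    names(query) <- if (length(query) == 1L) "query" else paste0("query", seq_along(query))
  }
  frames <- assembly_frames(transcripts)
  hits <- purrr::map_dfr(names(query), function(qn) {
    best_frame_hits(query[[qn]], qn, frames, sig_threshold)
  })
  if (nrow(hits) == 0) return(hits)
  dplyr::arrange(hits, .data$evalue)
}

# Score all frames for one query, keep the best frame per transcript, and
# compute full alignments only for significant hits.
best_frame_hits <- function(qseq, qname, frames, sig_threshold) {
  mat <- substitution_matrix()
  scores <- Biostrings::pairwiseAlignment(
    frames$aa, Biostrings::AAString(qseq),
    substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
    type = "local", scoreOnly = TRUE
  )
  info <- frames$info
  info$score <- scores
  best <- info |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  best$evalue <- evalue_of(best$score, nchar(qseq), frames$db_len)
  best <- best[best$evalue < sig_threshold, ]
  if (nrow(best) == 0) {
    return(tibble::tibble(
      query = character(), subject = character(), frame = integer(),
      score = numeric(), pident = numeric(), evalue = numeric(),
      q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer()
    ))
  }
  details <- purrr::map(seq_len(nrow(best)), function(i) {
    align_global(qseq, best$protein[i], type = "local",
                 query_id = qname, subject_id = best$subject_id[i])
  })
  tibble::tibble(
    query = qname,
    subject = best$subject_id,
    frame = best$frame,
    score = best$score,
    pident = purrr::map_dbl(details, "pident"),
    evalue = best$evalue,
    q_start = purrr::map_int(details, "q_start"),
    q_end = purrr::map_int(details, "q_end"),
    s_start = purrr::map_int(details, "s_start"),
    s_end = purrr::map_int(details, "s_end")
  )
}

# Early-exit detector used by the completeness survey: does `qseq` have at
# least one hit below `sig_threshold` anywhere in the assembly?  Scans the
# frame database in chunks and stops at the first significant hit.  The
# scan order puts frames sharing protein 4-mers with the query first —
# ordering only, so the result is identical to a full scan, but homologs
# are typically confirmed in the first chunk.
has_significant_hit <- function(qseq, frames, sig_threshold, chunk = 12L) {
  mat <- substitution_matrix()
  n <- length(frames$aa)
  m <- nchar(qseq)
  q <- Biostrings::AAString(qseq)
  ord <- order(kmer_screen(qseq, frames), decreasing = TRUE)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    sc <- Biostrings::pairwiseAlignment(
      frames$aa[ord[i:j]], q, substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1, type = "local", scoreOnly = TRUE
    )
    if (any(evalue_of(sc, m, frames$db_len) < sig_threshold)) return(TRUE)
    i <- j + 1L
  }
  FALSE
}

# shared protein 4-mer count between a query and every frame translation
kmer_screen <- function(qseq, frames, k = 4L) {
  if (nchar(qseq) < k) return(numeric(length(frames$aa)))
  qk <- unique(substring(qseq, 1:(nchar(qseq) - k + 1L), k:nchar(qseq)))
  vapply(frames$info$protein, function(p) {
    if (nchar(p) < k) return(0)
    sum(substring(p, 1:(nchar(p) - k + 1L), k:nchar(p)) %in% qk)
  }, numeric(1), USE.NAMES = FALSE)
}
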