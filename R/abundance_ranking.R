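# Length-normalised transcript abundance and rank percentiles: the
# expression-level control.  A claimed absence is more credible when the
# gene's transcript is well-expressed (high percentile) in the species
# where it is found.

#' Length-normalised transcript abundance table with rank percentiles
#'
#' Normalises mapped-read counts to transcript length (reads per kilobase;
#' per million mapped reads when `library_size` is supplied — RPKM), keeps
#' transcripts longer than `min_rank_len`, and assigns each an ascending
#' rank percentile `100 * rank / N` with ties sharing the mean rank.  Low
#' percentiles correspond to low abundance; the most abundant of N
#' distinct transcripts sits at percentile 100.
#'
#' @param transcripts A data frame with columns `id`, `count` and either
#'   `length` or `seq`; a `synthetic_assembly` also works.
#' @param library_size Optional library size (total mapped reads).  Ranks
#'   are identical with or without it.
#' @param min_rank_len Minimum transcript length for inclusion in the
#'   ranking (default 200 nt).
#' @return A tibble of class `abundance_table`: `id`, `count`, `length`,
#'   `norm_abundance`, `percentile`.
#' @examples
#' tx <- tibble::tibble(id = c("a", "b"), count = c(10, 100), length = c(1000, 500))
#' normalize_abundance(tx, library_size = 1e6)
#' @export
normalize_abundance <- function(transcripts, library_size = NULL,
                                min_rank_len = 200L) {
  if (inherits(transcripts, "synthetic_assembly")) {
    transcripts <- transcripts$transcripts
  }
  tx <- tibble::as_tibble(transcripts)
  if (is.null(tx$length)) tx$length <- nchar(tx$seq)
  if (any(tx$length <= 0)) stop("transcript lengths must be positive", call. = FALSE)
  if (any(tx$count < 0)) stop("counts must be >= 0", call. = FALSE)
  denom <- tx$length / 1000
  if (!is.null(library_size)) {
    if (library_size <= 0) stop("`library_size` must be positive", call. = FALSE)
    denom <- denom * library_size / 1e6
  }
  tx$norm_abundance <- tx$count / denom
  tx <- tx[tx$length > min_rank_len, ]
  n <- nrow(tx)
  tx$percentile <- if (n > 0) 100 * rank(tx$norm_abundance, ties.method = "average") / n else numeric(0)
  out <- tx[, c("id", "count", "length", "norm_abundance", "percentile")]
  class(out) <- c("abundance_table", class(out))
  out
}

#' Rank percentile of one transcript
#'
#' @param table An `abundance_table` from [normalize_abundance()].
#' @param transcript_id Transcript identifier (must be in the table).
#' @return The percentile (numeric in (0, 100]).
#' @export
percentile_rank <- function(table, transcript_id) {
  i <- match(transcript_id, table$id)
  if (is.na(i)) {
    stop(sprintf("transcript '%s' not in abundance table", transcript_id),
         call. = FALSE)
  }
  table$percentile[i]
}

#' Assign reads to transcripts by exact matching
#'
#' Each read is assigned to the first transcript (input order; the
#' deterministic tie-break) containing it as an exact substring on either
#' strand; unassignable reads are dropped.  This is a rank-faithful
#' stand-in for a read mapper at synthetic-data scale, not an aligner:
#' reads from the bundled shredder carry no sequencing errors.
#'
#' @param reads Tibble with columns `read_id`, `seq`.
#' @param transcripts Assembly tibble with `id`, `seq`.
#' @return A tibble `id`, `count` covering every transcript (zeros
#'   included), summing to at most `nrow(reads)`.
#' @export
assign_counts <- function(reads, transcripts) {
  if (inherits(transcripts, "synthetic_assembly")) {
    transcripts <- transcripts$transcripts
  }
  counts <- stats::setNames(integer(nrow(transcripts)), transcripts$id)
  if (nrow(reads) > 0 && nrow(transcripts) > 0) {
    subj <- Biostrings::DNAStringSet(transcripts$seq)
    for (r in seq_len(nrow(reads))) {
      rd <- reads$seq[r]
      hit <- which(Biostrings::vcountPattern(rd, subj) > 0)
      if (length(hit) == 0) {
        rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
        hit <- which(Biostrings::vcountPattern(rc, subj) > 0)
      }
      if (length(hit) > 0) {
        counts[hit[1]] <- counts[hit[1]] + 1L
      }
    }
  }
  tibble::tibble(id = transcripts$id, count = unname(counts))
}
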