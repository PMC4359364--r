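# Transcriptome completeness: the fraction of a benchmark proteome
# recoverable from an assembly by translated search.  This is the control
# that licenses absence calls: a gene can only be declared missing from an
# assembly that demonstrably recovers its general gene complement.

#' Length and isoform filtering of an assembly
#'
#' Removes transcripts shorter than `min_len` and keeps one transcript
#' per locus: the longest isoform, with ties broken deterministically by
#' lexicographically smallest `isoform_id`.
#'
#' @param transcripts Assembly tibble with `id`, `seq` and (optionally)
#'   `locus_id`, `isoform_id`; rows lacking locus information are treated
#'   as single-isoform loci.
#' @param min_len Minimum transcript length in nt (default 250, the
#'   coverage-survey cutoff).
#' @param isoform_rule `"longest"` (only rule implemented).
#' @return The filtered tibble.
#' @examples
#' tx <- tibble::tibble(
#'   id = c("g1.i1", "g1.i2"), locus_id = "g1", isoform_id = c("i1", "i2"),
#'   seq = c(strrep("ATG", 100), strrep("ATG", 200))
#' )
#' filter_transcripts(tx)$id  # the 600 nt isoform
#' @export
filter_transcripts <- function(transcripts, min_len = 250L,
                               isoform_rule = "longest") {
  stopifnot(identical(isoform_rule, "longest"))
  if (inherits(transcripts, "synthetic_assembly")) {
    transcripts <- transcripts$transcripts
  }
  if (nrow(transcripts) == 0) return(transcripts)
  tx <- transcripts
  if (is.null(tx$locus_id)) tx$locus_id <- tx$id
  if (is.null(tx$isoform_id)) tx$isoform_id <- "i1"
  tx$length <- nchar(tx$seq)
  tx <- tx[tx$length >= min_len, ]
  if (nrow(tx) == 0) return(tx)
  tx |>
    dplyr::arrange(.data$locus_id, dplyr::desc(.data$length), .data$isoform_id) |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$id, transcripts$id))
}

#' Benchmark-proteome recovery fraction of an assembly
#'
#' Searches every benchmark protein against the six-frame translated
#' assembly; a protein counts as recovered iff it has at least one
#' significant hit on at least one transcript (each protein-transcript
#' pair contributes at most one alignment).  Reports the recovered
#' fraction plus the raw count of significant protein-transcript
#' alignments.
#'
#' @param benchmark Named character vector of benchmark proteins, or a
#'   tibble with columns `id` and `seq`.  Must be non-empty.
#' @param transcripts A (typically [filter_transcripts()]-filtered)
#'   assembly tibble.
#' @param sig_threshold E-value cutoff for counting an alignment.
#' @param assembly_id,benchmark_id Labels for the report.
#' @param count_alignments Also count the raw significant
#'   protein-transcript alignments (`n_alignments`; slower, off by
#'   default - the per-protein indicator is what the control consumes).
#' @return A one-row tibble of class `coverage_report`: `assembly_id`,
#'   `benchmark_id`, `n_benchmark`, `n_recovered`, `fraction`,
#'   `n_alignments`, `min_len` (attr of filtering left to caller),
#'   `sig_threshold`; attribute `per_protein` holds the indicator tibble.
#' @examples
#' bm <- c(p1 = "MKVLAEQRKDFWTNSHGY")
#' tx <- tibble::tibble(id = "t1", seq = back_translate(bm[[1]], seed = 1))
#' coverage_fraction(bm, tx, sig_threshold = 1)$fraction
#' @export
coverage_fraction <- function(benchmark, transcripts, sig_threshold = 1e-10,
                              assembly_id = "assembly",
                              benchmark_id = "benchmark",
                              count_alignments = FALSE) {
  if (is.data.frame(benchmark)) {
    benchmark <- stats::setNames(benchmark$seq, benchmark$id)
  }
  if (length(benchmark) == 0) stop("`benchmark` must be non-empty", call. = FALSE)
  if (inherits(transcripts, "synthetic_assembly")) {
    transcripts <- transcripts$transcripts
  }
  if (nrow(transcripts) == 0) {
    recovered <- rep(FALSE, length(benchmark))
    n_aln <- if (count_alignments) 0L else NA_integer_
  } else {
    frames <- assembly_frames(transcripts)
    recovered <- vapply(benchmark, function(q) {
      has_significant_hit(q, frames, sig_threshold)
    }, logical(1))
    # raw alignment count: one per significant (protein, transcript) pair,
    # computed only on request (the per-protein indicator is the control)
    n_aln <- if (count_alignments) 0L else NA_integer_
    if (count_alignments && any(recovered)) {
      hits <- search_protein_vs_transcripts(benchmark[recovered], transcripts,
                                            sig_threshold)
      n_aln <- nrow(hits)
    }
  }
  out <- tibble::tibble(
    assembly_id = assembly_id,
    benchmark_id = benchmark_id,
    n_benchmark = length(benchmark),
    n_recovered = sum(recovered),
    fraction = sum(recovered) / length(benchmark),
    n_alignments = n_aln,
    sig_threshold = sig_threshold
  )
  attr(out, "per_protein") <- tibble::tibble(
    protein_id = names(benchmark), recovered = unname(recovered)
  )
  class(out) <- c("coverage_report", class(out))
  out
}

#' Completeness comparability gate
#'
#' An assembly passes the gate iff its benchmark recovery fraction is at
#' least `factor` times the smallest fraction among the designated
#' positive-control assemblies (assemblies from species where the target
#' gene was found, establishing what "comparable coverage" looks like).
#'
#' @param fraction Recovery fraction of the assembly under test.
#' @param control_fractions Recovery fractions of the positive controls.
#' @param factor Fraction of the weakest control that must be reached
#'   (default 0.55; see the methods vignette for the rationale).
#' @return Logical, `NA` when no controls are supplied.
#' @export
completeness_gate <- function(fraction, control_fractions, factor = 0.55) {
  if (length(control_fractions) == 0 || all(is.na(control_fractions))) {
    return(NA)
  }
  fraction >= factor * min(control_fractions, na.rm = TRUE)
}
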