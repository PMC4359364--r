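# Diagnostic-feature classification of H3-family variants.
#
# A candidate is laid onto canonical H3 with an ends-free alignment and
# three features are read off: the number of insertion columns inside the
# loop1 window, the state of the three diagnostic fold residues (Q68,
# F84, T118), and the percent identity of the N-terminal tail.  CenH3 is
# called for an extended loop1 plus a majority of substituted diagnostic
# sites plus a divergent tail; H3/H3.3 require a near-identical fold and
# are told apart by the four H3.3 signature residues.

#' Classifier thresholds
#'
#' All decision thresholds of [classify_variant()], overridable per call.
#'
#' @param min_loop1_extension Minimum loop1 insertion columns for CenH3.
#' @param min_diagnostic_subs Minimum number (of 3) of substituted
#'   diagnostic positions for CenH3.
#' @param max_ntail_identity_cenh3 Maximum N-tail percent identity
#'   compatible with CenH3.
#' @param min_fold_identity_h3 Minimum fold percent identity for H3/H3.3.
#' @param min_h33_subs Minimum number (of 4) of H3.3-signature
#'   substitutions to call H3.3 rather than H3.
#' @return A named list of thresholds.
#' @export
classifier_thresholds <- function(min_loop1_extension = 1L,
                                  min_diagnostic_subs = 2L,
                                  max_ntail_identity_cenh3 = 50,
                                  min_fold_identity_h3 = 90,
                                  min_h33_subs = 2L) {
  list(
    min_loop1_extension = min_loop1_extension,
    min_diagnostic_subs = min_diagnostic_subs,
    max_ntail_identity_cenh3 = max_ntail_identity_cenh3,
    min_fold_identity_h3 = min_fold_identity_h3,
    min_h33_subs = min_h33_subs
  )
}

#' Find H3-family candidate proteins in an assembly
#'
#' Translated search of the query panel (canonical H3 plus confirmed
#' CenH3 homologs, mirroring the iterative-search strategy) against all
#' six frames of every transcript.  For each transcript with a
#' significant hit, the open reading frame containing the hit region is
#' extracted as the candidate protein; hits whose aligned region is
#' interrupted by stop codons in every frame are retained but flagged
#' putatively nonfunctional.
#'
#' @param transcripts Assembly tibble (`id`, `seq`) or
#'   `synthetic_assembly`.
#' @param queries Named character vector of query proteins
#'   (default [default_query_panel()]).
#' @param sig_threshold E-value cutoff for candidacy.
#' @return A tibble: `candidate_id`, `transcript_id`, `frame`, `protein`
#'   (extracted ORF), `best_query`, `score`, `evalue`, `nonfunctional`.
#'   Zero rows when the assembly contains no histone-fold homology.
#' @export
find_h3_candidates <- function(transcripts, queries = default_query_panel(),
                               sig_threshold = 1e-10) {
  if (inherits(transcripts, "synthetic_assembly")) {
    transcripts <- transcripts$transcripts
  }
  empty <- tibble::tibble(
    candidate_id = character(), transcript_id = character(),
    frame = integer(), protein = character(), best_query = character(),
    score = numeric(), evalue = numeric(), nonfunctional = logical()
  )
  if (nrow(transcripts) == 0) return(empty)
  hits <- search_protein_vs_transcripts(queries, transcripts, sig_threshold)
  if (nrow(hits) == 0) return(empty)
  best <- hits |>
    dplyr::group_by(.data$subject) |>
    dplyr::slice_min(.data$evalue, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  purrr::map_dfr(seq_len(nrow(best)), function(i) {
    tx <- transcripts$seq[transcripts$id == best$subject[i]][1]
    frame_aa <- frame_translation(tx, best$frame[i])
    orf <- extract_orf(frame_aa, best$s_start[i], best$s_end[i])
    tibble::tibble(
      candidate_id = paste0(best$subject[i], "|", frame_name(best$frame[i])),
      transcript_id = best$subject[i],
      frame = best$frame[i],
      protein = orf$protein,
      best_query = best$query[i],
      score = best$score[i],
      evalue = best$evalue[i],
      nonfunctional = orf$interrupted
    )
  })
}

# Extract the ORF of a frame translation containing the aligned region
# [s_start, s_end] (aa coordinates in the frame).  `interrupted` is TRUE
# when a stop codon falls inside the aligned region itself, i.e. the ORF
# cannot span the homologous segment.
extract_orf <- function(frame_aa, s_start, s_end) {
  aa <- strsplit(frame_aa, "", fixed = TRUE)[[1]]
  stops <- which(aa == "*")
  left <- c(0L, stops[stops < s_start])
  from <- max(left) + 1L
  right <- stops[stops >= s_start]
  to <- if (length(right)) min(right) - 1L else length(aa)
  interrupted <- to < s_end
  if (!interrupted) {
    after <- stops[stops > s_end]
    to <- if (length(after)) min(after) - 1L else length(aa)
  }
  list(protein = paste(aa[from:to], collapse = ""), interrupted = interrupted)
}

#' Count loop1 insertion columns of a candidate
#'
#' Given an ends-free alignment of a candidate to canonical H3, counts
#' candidate insertion columns (H3-gap columns) whose flanking H3
#' coordinates fall inside the loop1 window.  Returns `NA` (an
#' "unaligned" signal, deliberately distinct from 0) when the candidate
#' has no residues aligned within the window at all.
#'
#' @param aln An `aa_alignment` with the candidate as query and canonical
#'   H3 as subject.
#' @param reference An [h3_reference()].
#' @return Integer count of loop1 insertion columns, or `NA_integer_`.
#' @export
measure_loop1_extension <- function(aln, reference = h3_reference()) {
  map <- alignment_map(aln)
  covered <- map$s_pos[!is.na(map$s_pos) & !is.na(map$q_pos)]
  if (!any(covered >= reference$loop1_start & covered <= reference$loop1_end)) {
    return(NA_integer_)
  }
  s_filled <- cumfill(map$s_pos)
  ins <- is.na(map$s_pos) & !is.na(map$q_pos)
  flank_left <- s_filled[ins]
  sum(!is.na(flank_left) &
        flank_left >= reference$loop1_start - 1L &
        flank_left < reference$loop1_end, na.rm = TRUE)
}

# last non-NA value at or before each position
cumfill <- function(x) {
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  out <- rep(NA_integer_, length(x))
  out[idx > 0] <- x[idx[idx > 0]]
  out
}

#' Diagnostic residue states of a candidate
#'
#' For each diagnostic H3 position (Q68, F84, T118) reports whether the
#' aligned candidate residue is `"canonical"` (identical),
#' `"substituted"` (different residue), or `"unaligned"` (gap or outside
#' the aligned range).
#'
#' @inheritParams measure_loop1_extension
#' @return A named character vector, one state per diagnostic position.
#' @export
diagnostic_residue_states <- function(aln, reference = h3_reference()) {
  map <- alignment_map(aln)
  vapply(names(reference$diagnostic_positions), function(p) {
    pos <- as.integer(p)
    row <- map[!is.na(map$s_pos) & map$s_pos == pos, ]
    if (nrow(row) == 0 || is.na(row$q_pos[1])) return("unaligned")
    if (row$q_res[1] == reference$diagnostic_positions[[p]]) "canonical" else "substituted"
  }, "")
}

#' Classify one candidate protein as an H3-family variant
#'
#' Applies the diagnostic decision rule.  With default thresholds:
#' CenH3 requires loop1 extension >= 1 AND >= 2 of 3 diagnostic positions
#' substituted AND N-tail identity < 50% (an absent or unalignable tail
#' counts as divergent); H3 requires fold identity >= 90%, no loop1
#' extension, all diagnostic positions canonical and no H3.3-signature
#' substitutions; H3.3 is as H3 but with the signature substitutions;
#' anything else with significant fold homology is H3-like; candidates
#' whose homologous region is interrupted by stop codons are flagged
#' putatively nonfunctional and never labelled CenH3.
#'
#' @param protein Candidate protein string, or one row of
#'   [find_h3_candidates()] output.
#' @param reference An [h3_reference()].
#' @param thresholds A [classifier_thresholds()] list.
#' @param candidate_id Label for the output.
#' @param nonfunctional Logical flag from candidate extraction.
#' @return A one-row tibble (the histone call): `candidate_id`, `label`
#'   in `{H3, H3.3, CenH3, H3-like, non-histone}`, `loop1_extension`,
#'   `state_68`, `state_84`, `state_118`, `fold_identity`,
#'   `ntail_identity`, `notes`.
#' @examples
#' classify_variant(h3_reference()$seq)$label  # "H3"
#' @export
classify_variant <- function(protein, reference = h3_reference(),
                             thresholds = classifier_thresholds(),
                             candidate_id = "candidate",
                             nonfunctional = FALSE) {
  if (is.data.frame(protein)) {
    row <- protein[1, ]
    candidate_id <- row$candidate_id
    nonfunctional <- isTRUE(row$nonfunctional)
    protein <- row$protein
  }
  # candidates too divergent to align to H3 directly (true CenH3 folds
  # often are) are read off through the best-matching bundled anchor,
  # exactly as in the placement module
  pr <- project_onto_h3(protein, reference)
  ref_aa <- strsplit(reference$seq, "", fixed = TRUE)[[1]]
  fold_idx <- reference$fold_start:reference$fold_end
  tail_idx <- seq_len(reference$fold_start - 1L)
  fold_id <- 100 * sum(pr$columns[fold_idx] == ref_aa[fold_idx]) / length(fold_idx)
  ntail_id <- 100 * sum(pr$columns[tail_idx] == ref_aa[tail_idx]) / length(tail_idx)

  loop_idx <- reference$loop1_start:reference$loop1_end
  loop1 <- length(pr$loop1_inserts)
  if (loop1 == 0L && all(pr$columns[loop_idx] == "-")) loop1 <- NA_integer_

  states <- vapply(names(reference$diagnostic_positions), function(p) {
    res <- pr$columns[as.integer(p)]
    if (res == "-") "unaligned"
    else if (res == reference$diagnostic_positions[[p]]) "canonical"
    else "substituted"
  }, "")
  n_sub <- sum(states == "substituted")
  h33_subs <- sum(vapply(names(reference$h33_positions), function(p) {
    res <- pr$columns[as.integer(p)]
    res != "-" && res != ref_aa[as.integer(p)]
  }, logical(1)))

  fold_covered <- sum(pr$columns[fold_idx] != "-")
  notes <- character(0)

  is_cenh3 <- !is.na(loop1) && loop1 >= thresholds$min_loop1_extension &&
    n_sub >= thresholds$min_diagnostic_subs &&
    (is.na(ntail_id) || ntail_id < thresholds$max_ntail_identity_cenh3)
  is_core_h3 <- fold_id >= thresholds$min_fold_identity_h3 &&
    !is.na(loop1) && loop1 == 0L && all(states == "canonical")

  label <- if (fold_covered == 0) {
    "non-histone"
  } else if (is_cenh3 && !nonfunctional) {
    "CenH3"
  } else if (is_core_h3 && h33_subs < thresholds$min_h33_subs) {
    "H3"
  } else if (is_core_h3) {
    "H3.3"
  } else {
    "H3-like"
  }
  if (nonfunctional) notes <- c(notes, "putatively nonfunctional")
  if (is_cenh3 && nonfunctional) notes <- c(notes, "CenH3-like features but interrupted ORF")

  tibble::tibble(
    candidate_id = candidate_id,
    label = label,
    loop1_extension = loop1,
    state_68 = unname(states[1]),
    state_84 = unname(states[2]),
    state_118 = unname(states[3]),
    fold_identity = fold_id,
    ntail_identity = ntail_id,
    notes = paste(notes, collapse = "; ")
  )
}

#' Find and classify all H3-family variants in an assembly
#'
#' Convenience wrapper chaining [find_h3_candidates()] and
#' [classify_variant()].
#'
#' @inheritParams find_h3_candidates
#' @param thresholds A [classifier_thresholds()] list.
#' @return The histone-call tibble (one row per candidate; zero rows for
#'   assemblies without histone-fold homology), with candidate columns
#'   `transcript_id`, `frame`, `protein`, `evalue` joined on.
#' @export
classify_assembly <- function(transcripts, queries = default_query_panel(),
                              reference = h3_reference(),
                              thresholds = classifier_thresholds(),
                              sig_threshold = 1e-10) {
  candidates <- find_h3_candidates(transcripts, queries, sig_threshold)
  if (nrow(candidates) == 0) {
    return(tibble::tibble(
      candidate_id = character(), label = character(),
      loop1_extension = integer(), state_68 = character(),
      state_84 = character(), state_118 = character(),
      fold_identity = numeric(), ntail_identity = numeric(),
      notes = character(), transcript_id = character(), frame = integer(),
      protein = character(), evalue = numeric()
    ))
  }
  calls <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    classify_variant(candidates[i, ], reference, thresholds)
  })
  dplyr::left_join(
    calls,
    candidates[, c("candidate_id", "transcript_id", "frame", "protein", "evalue")],
    by = "candidate_id"
  )
}
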