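# Bundled reference annotation for the H3 family.
#
# The canonical H3 protein is invariant among insects; all coordinates in
# the package use mature (initiator-Met-cleaved) numbering on this sequence.
# The histone fold spans residues 63-135; loop1 is the insertion-prone
# region between helices alpha1 and alpha2 and is recorded here as the
# fixed window 78-87 so that the diagnostic phenylalanine at 84 lies inside
# it.  The three residues whose loss is diagnostic for CenH3 relative to
# canonical H3 are Q68, F84 and T118.  The generator and the classifier
# share these constants.

H3_CANONICAL <- paste0(
  "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQKSTELLIRKLPFQR",
  "LVREIAQDFKTDLRFQSSAVMALQEACEAYLVGLFEDTNLCAIHAKRVTIMPKDIQLARRIRGERA"
)

.ref_cache <- new.env(parent = emptyenv())

#' Canonical H3 reference annotation
#'
#' Returns the bundled canonical H3 sequence together with the coordinate
#' constants every other module keys on: the histone-fold interval, the
#' loop1 window, the diagnostic positions (Q68, F84, T118 in mature
#' numbering) whose substitution is characteristic of CenH3, and the four
#' residues that distinguish the replication-independent variant H3.3 from
#' canonical H3 (31, 87, 89, 90).
#'
#' @return An object of class `h3_reference`: a list with elements `seq`,
#'   `fold_start`, `fold_end`, `loop1_start`, `loop1_end`,
#'   `diagnostic_positions` (named character, names = positions, values =
#'   canonical residues) and `h33_positions` (named character, values =
#'   the residues expected in H3.3).
#' @examples
#' ref <- h3_reference()
#' substr(ref$seq, 68, 68)  # "Q"
#' @export
h3_reference <- function() {
  ref <- list(
    seq = H3_CANONICAL,
    fold_start = 63L,
    fold_end = 135L,
    loop1_start = 78L,
    loop1_end = 87L,
    diagnostic_positions = c(`68` = "Q", `84` = "F", `118` = "T"),
    h33_positions = c(`31` = "S", `87` = "A", `89` = "I", `90` = "G")
  )
  stopifnot(
    nchar(ref$seq) == 135L,
    substr(ref$seq, 68, 68) == "Q",
    substr(ref$seq, 84, 84) == "F",
    substr(ref$seq, 118, 118) == "T"
  )
  structure(ref, class = "h3_reference")
}

h33_sequence <- function(reference = h3_reference()) {
  aa <- strsplit(reference$seq, "")[[1]]
  pos <- as.integer(names(reference$h33_positions))
  aa[pos] <- unname(reference$h33_positions)
  paste(aa, collapse = "")
}

# Deterministic bundled CenH3-style references.  The host ancestor stands
# for the animal CenH3 family the survey is looking for; the fungal-style
# donor stands for the divergent lineage from which contaminating
# transcripts originate.  Both are built once from canonical H3 with fixed
# internal seeds; fungal CenH3s are far more divergent in the fold, which
# is what makes the clade test decisive.
cenh3_references <- function() {
  if (!is.null(.ref_cache$cenh3)) return(.ref_cache$cenh3)
  refs <- list(
    host_ancestor = make_cenh3_like(n_loop1_insert = 2L, seed = 104729L,
                                    fold_divergence = 0.45),
    fungal_donor = make_cenh3_like(n_loop1_insert = 4L, seed = 224737L,
                                   fold_divergence = 0.60)
  )
  .ref_cache$cenh3 <- refs
  refs
}

# Map a residue position of a make_cenh3_like() product back to canonical
# H3 coordinates (NA for inserted loop1 residues).  Valid because the
# construction is length-preserving outside the single loop1 insertion.
cenh3_anchor_map <- function(n_loop1_insert,
                             insert_after = CENH3_INSERT_AFTER) {
  n_total <- 135L + n_loop1_insert
  map <- integer(n_total)
  map[seq_len(insert_after)] <- seq_len(insert_after)
  map[insert_after + seq_len(n_loop1_insert)] <- NA_integer_
  tail_idx <- (insert_after + n_loop1_insert + 1L):n_total
  map[tail_idx] <- tail_idx - n_loop1_insert
  map
}

#' Default query panel for H3-family homology searches
#'
#' The iterative-search strategy seeds translated searches with canonical
#' H3 plus confirmed CenH3 homologs, so that divergent candidates missed by
#' the H3 query are still recovered.  The bundled panel contains canonical
#' H3, H3.3, the host-type CenH3 reference and the fungal-style CenH3
#' reference.
#'
#' @return A named character vector of protein sequences with attribute
#'   `query_class`, a character vector labelling each query `"h3"` or
#'   `"cenh3"` (used by [read_level_search()] to attribute read hits).
#' @export
default_query_panel <- function() {
  refs <- cenh3_references()
  panel <- c(
    H3 = H3_CANONICAL,
    H3.3 = h33_sequence(),
    CenH3_host = refs$host_ancestor,
    CenH3_fungal = refs$fungal_donor
  )
  attr(panel, "query_class") <- c("h3", "h3", "cenh3", "cenh3")
  panel
}

#' Reference panel for host-versus-contaminant placement
#'
#' Builds the labelled sequence panels used by [placement_verdict()]: a
#' host clade (relatives of the host-type CenH3 reference), a contaminant
#' clade (relatives of the fungal-style reference) and a canonical H3/H3.3
#' outgroup.  Panels are deterministic; members are mild, seeded
#' perturbations of the two bundled ancestors.
#'
#' @param n_refs Number of sequences per panel (>= 3).
#' @param divergence Within-clade divergence (substitutions per site) of
#'   panel members from their ancestor.
#' @return An object of class `reference_panel`: list with named character
#'   vectors `host_refs`, `contaminant_refs`, `outgroup`.
#' @examples
#' panel <- reference_panel()
#' names(panel$host_refs)
#' @export
reference_panel <- function(n_refs = 4L, divergence = 0.08) {
  n_refs <- assert_count(n_refs, "n_refs", min = 3L)
  refs <- cenh3_references()
  key <- paste0("panel_", n_refs, "_", divergence)
  if (!is.null(.ref_cache[[key]])) return(.ref_cache[[key]])
  make_clade <- function(ancestor, prefix, seed0) {
    out <- vapply(seq_len(n_refs), function(i) {
      with_seed(seed0 + i, mutate_protein(ancestor, divergence))
    }, "")
    stats::setNames(out, paste0(prefix, "_", seq_len(n_refs)))
  }
  panel <- structure(list(
    host_refs = make_clade(refs$host_ancestor, "host_cenh3", 7000L),
    contaminant_refs = make_clade(refs$fungal_donor, "fungal_cenh3", 8000L),
    outgroup = c(
      H3_outgroup_1 = H3_CANONICAL,
      H3_outgroup_2 = h33_sequence(),
      H3_outgroup_3 = with_seed(9001L, mutate_protein(H3_CANONICAL, 0.03))
    )
  ), class = "reference_panel")
  .ref_cache[[key]] <- panel
  panel
}
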