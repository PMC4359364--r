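# Host-versus-contaminant attribution by phylogenetic placement.
#
# Candidate CenH3-like proteins are reduced to their histone-fold domain
# (optionally excluding the hypervariable loop1), aligned column-wise onto
# canonical H3 coordinates via the best-matching bundled anchor, and
# placed in a neighbor-joining tree with labelled host and contaminant
# reference panels plus an H3 outgroup.  The consumed decision is a clade
# membership with bootstrap support, not branch lengths.

# Anchor sequences with analytic residue -> H3-column maps.  Candidates
# too divergent to align directly to H3 are anchored through the CenH3
# reference that hits them best (the iterative-search idea again).
anchor_set <- function() {
  refs <- cenh3_references()
  list(
    H3 = list(seq = H3_CANONICAL, map = seq_len(135L)),
    H3.3 = list(seq = h33_sequence(), map = seq_len(135L)),
    CenH3_host = list(seq = refs$host_ancestor, map = cenh3_anchor_map(2L)),
    CenH3_fungal = list(seq = refs$fungal_donor, map = cenh3_anchor_map(4L))
  )
}

# Project a protein onto canonical H3 columns.  Returns a list with
# `columns` (character[135]: the protein residue aligned over each H3
# position, "-" where gapped) and `loop1_inserts` (residues inserted
# within the loop1 window, in order).
project_onto_h3 <- function(protein, reference = h3_reference(),
                            anchors = anchor_set()) {
  scored <- lapply(anchors, function(a) {
    align_global(protein, a$seq, type = "overlap")
  })
  best <- which.max(vapply(scored, function(a) a$score, numeric(1)))
  a <- anchors[[best]]
  map <- alignment_map(scored[[best]])
  cols <- rep("-", 135L)
  anchor_pos_to_h3 <- a$map
  aligned <- !is.na(map$q_pos) & !is.na(map$s_pos)
  h3_pos <- rep(NA_integer_, nrow(map))
  h3_pos[aligned] <- anchor_pos_to_h3[map$s_pos[aligned]]
  ok <- aligned & !is.na(h3_pos)
  cols[h3_pos[ok]] <- map$q_res[ok]
  # candidate residues in insertion columns flanked inside the loop1 window
  s_on_h3 <- rep(NA_integer_, nrow(map))
  s_on_h3[!is.na(map$s_pos)] <- anchor_pos_to_h3[map$s_pos[!is.na(map$s_pos)]]
  filled <- cumfill(s_on_h3)
  ins <- !is.na(map$q_pos) & is.na(h3_pos)
  in_loop <- ins & !is.na(filled) &
    filled >= reference$loop1_start - 1L & filled < reference$loop1_end
  list(columns = cols, loop1_inserts = map$q_res[in_loop])
}

#' Extract the histone-fold domain of a protein
#'
#' Returns the subsequence of `protein` aligned to the canonical H3
#' histone fold (residues `fold_start..fold_end`), anchored through the
#' best-matching bundled reference.  With `exclude_loop1 = TRUE` the
#' loop1 window columns and any candidate insertions within them are
#' removed — the form used for tree building, since loop1 length itself
#' is the diagnostic character and would distort distances.
#'
#' @param protein Protein string with significant fold homology.
#' @param reference An [h3_reference()].
#' @param exclude_loop1 Drop the loop1 window?
#' @return The (ungapped) domain sequence.
#' @export
extract_fold_domain <- function(protein, reference = h3_reference(),
                                exclude_loop1 = FALSE) {
  row <- fold_row(protein, reference, exclude_loop1)
  out <- paste(row[row != "-"], collapse = "")
  if (!nzchar(out)) stop("protein has no alignable histone fold", call. = FALSE)
  out
}

# One gapped alignment row over fold columns (plus loop1 insertions when
# they are not excluded).
fold_row <- function(protein, reference, exclude_loop1) {
  pr <- project_onto_h3(protein, reference)
  fold_idx <- reference$fold_start:reference$fold_end
  loop_idx <- reference$loop1_start:reference$loop1_end
  if (exclude_loop1) {
    pr$columns[setdiff(fold_idx, loop_idx)]
  } else {
    before <- fold_idx[fold_idx <= CENH3_INSERT_AFTER]
    after <- fold_idx[fold_idx > CENH3_INSERT_AFTER]
    c(pr$columns[before], pr$loop1_inserts, pr$columns[after])
  }
}

#' Column-wise fold alignment of a sequence set
#'
#' Reference-anchored multiple alignment of histone-fold domains: every
#' sequence is projected onto canonical H3 columns (loop1 excluded by
#' default), giving an equal-width character matrix ready for
#' [build_tree()].
#'
#' @param proteins Named character vector of protein sequences.
#' @param reference An [h3_reference()].
#' @param exclude_loop1 Drop the loop1 window (default TRUE for trees).
#' @return A character matrix, rows = sequences, columns = fold columns.
#' @export
fold_alignment <- function(proteins, reference = h3_reference(),
                           exclude_loop1 = TRUE) {
  stopifnot(!is.null(names(proteins)))
  fold_idx <- reference$fold_start:reference$fold_end
  loop_idx <- reference$loop1_start:reference$loop1_end
  keep <- if (exclude_loop1) setdiff(fold_idx, loop_idx) else fold_idx
  rows <- t(vapply(proteins, function(p) {
    project_onto_h3(p, reference)$columns[keep]
  }, character(length(keep))))
  rownames(rows) <- names(proteins)
  rows
}

# Poisson-corrected p-distance with pairwise deletion.
poisson_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      p <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0.95
      p <- min(p, 0.95)
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  stats::as.dist(d)
}

#' Neighbor-joining tree with nonparametric bootstrap
#'
#' Builds an NJ tree on Poisson-corrected p-distances from a column-wise
#' protein alignment (columns with more than 50% gaps are dropped first),
#' plus `n_bootstrap` trees from column resampling for clade-support
#' estimation.  Deterministic given `seed`.
#'
#' @param alignment Character matrix (rows = sequences) or named
#'   character vector of equal-length gapped sequences; at least 4
#'   sequences.
#' @param n_bootstrap Number of bootstrap replicates.
#' @param seed RNG seed.
#' @return An object of class `histone_tree`: list with `tree` (an
#'   [ape::phylo]), `boot_trees` (list of phylo), `alignment`,
#'   `n_bootstrap`.
#' @examples
#' aln <- rbind(a = c("A","A","A","A"), b = c("A","A","A","C"),
#'              c = c("G","G","G","G"), d = c("G","G","G","T"))
#' tr <- build_tree(aln, n_bootstrap = 10, seed = 1)
#' @export
build_tree <- function(alignment, n_bootstrap = 100L, seed = 1L) {
  if (!is.matrix(alignment)) {
    stopifnot(!is.null(names(alignment)))
    alignment <- t(vapply(alignment, function(s) strsplit(s, "")[[1]],
                          character(nchar(alignment[[1]]))))
  }
  if (nrow(alignment) < 4L) {
    stop("tree building needs at least 4 sequences", call. = FALSE)
  }
  gap_frac <- colMeans(alignment == "-")
  alignment <- alignment[, gap_frac <= 0.5, drop = FALSE]
  if (ncol(alignment) < 2L) stop("alignment has no usable columns", call. = FALSE)
  main <- ape::nj(poisson_dist(alignment))
  boots <- with_seed(seed, {
    lapply(seq_len(n_bootstrap), function(b) {
      cols <- sample.int(ncol(alignment), replace = TRUE)
      ape::nj(poisson_dist(alignment[, cols, drop = FALSE]))
    })
  })
  structure(list(tree = main, boot_trees = boots, alignment = alignment,
                 n_bootstrap = n_bootstrap),
            class = "histone_tree")
}

#' @export
print.histone_tree <- function(x, ...) {
  cat(sprintf("<histone_tree> %d tips, %d alignment columns, %d bootstrap replicates\n",
              length(x$tree$tip.label), ncol(x$alignment), x$n_bootstrap))
  invisible(x)
}

tips_of_node <- function(tree, node) {
  if (node <= length(tree$tip.label)) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

# Root a tree on the outgroup (falling back to a single outgroup tip
# when the outgroup is not monophyletic).
root_on_outgroup <- function(phy, og) {
  og <- intersect(og, phy$tip.label)
  tryCatch(
    ape::root(phy, outgroup = og, resolve.root = TRUE),
    error = function(e) ape::root(phy, outgroup = og[1], resolve.root = TRUE)
  )
}

# Walk rootward from the candidate tip in a rooted tree.  The first
# clade containing a labelled reference fixes the lineage hypothesis
# (mixed first contact => NA); the walk continues while the growing
# clade stays pure for that lineage, and the largest pure clade's
# members are reported.
walk_lineage <- function(rooted, candidate_id, host, contam) {
  node <- which(rooted$tip.label == candidate_id)
  if (length(node) == 0) return(list(lineage = NA_character_, members = character(0)))
  root_node <- length(rooted$tip.label) + 1L
  lineage <- NULL; members <- character(0)
  repeat {
    parent <- rooted$edge[rooted$edge[, 2] == node, 1]
    if (length(parent) == 0) break
    tips <- tips_of_node(rooted, parent)
    others <- setdiff(tips, candidate_id)
    if (any(others %in% c(host, contam))) {
      pure <- if (all(others %in% contam)) "contaminant"
              else if (all(others %in% host)) "host"
              else NA_character_
      if (is.null(lineage)) {
        if (is.na(pure)) break
        lineage <- pure; members <- others; node <- parent
      } else if (!is.na(pure) && pure == lineage) {
        members <- others; node <- parent
      } else break
    } else {
      node <- parent
    }
    if (node == root_node) break
  }
  list(lineage = if (is.null(lineage)) NA_character_ else lineage,
       members = members)
}

#' Attribute a candidate to host or contaminant lineage
#'
#' Roots the tree on the H3 outgroup and walks rootward from the
#' candidate tip: the first clade containing a labelled reference fixes
#' the lineage hypothesis (a mixed clade leaves the candidate
#' unresolved), and the walk extends while the clade stays pure for that
#' lineage.  Support is the bootstrap percentage of replicates whose own
#' walk assigns the candidate to the same lineage — the assignment
#' itself is bootstrapped, because the candidate's exact attachment
#' point inside a reference radiation is unstable while its lineage
#' membership is the reproducible signal.
#'
#' @param tree A `histone_tree` from [build_tree()] whose alignment
#'   included the candidate, the panel and the outgroup.
#' @param candidate_id Tip label of the candidate.
#' @param panel A [reference_panel()].
#' @param support_threshold Minimum bootstrap percentage (default 70).
#' @return A one-row tibble of class `placement_verdict`: `candidate_id`,
#'   `verdict` in `{host, contaminant, unresolved}`, `support`,
#'   `clade_members`; the rooted tree is attached as attribute `tree`.
#' @export
placement_verdict <- function(tree, candidate_id, panel = reference_panel(),
                              support_threshold = 70) {
  stopifnot(inherits(tree, "histone_tree"))
  phy <- tree$tree
  if (!candidate_id %in% phy$tip.label) {
    stop(sprintf("candidate '%s' not in tree", candidate_id), call. = FALSE)
  }
  og <- names(panel$outgroup)
  host <- names(panel$host_refs)
  contam <- names(panel$contaminant_refs)
  rooted <- root_on_outgroup(phy, og)
  main <- walk_lineage(rooted, candidate_id, host, contam)

  verdict <- "unresolved"; support <- NA_real_
  if (!is.na(main$lineage)) {
    boot_lineages <- vapply(tree$boot_trees, function(bt) {
      walk_lineage(root_on_outgroup(bt, og), candidate_id, host, contam)$lineage
    }, character(1))
    support <- 100 * mean(!is.na(boot_lineages) & boot_lineages == main$lineage)
    verdict <- if (support >= support_threshold) main$lineage else "unresolved"
  }
  out <- tibble::tibble(
    candidate_id = candidate_id,
    verdict = verdict,
    support = support,
    clade_members = paste(main$members, collapse = ",")
  )
  attr(out, "tree") <- rooted
  class(out) <- c("placement_verdict", class(out))
  out
}

#' Place a candidate protein against the bundled panels
#'
#' Convenience wrapper: aligns the candidate with the panel and outgroup
#' ([fold_alignment()], loop1 excluded), builds the bootstrapped NJ tree
#' and returns the [placement_verdict()].
#'
#' @param protein Candidate protein sequence.
#' @param candidate_id Label for the candidate.
#' @param panel A [reference_panel()].
#' @param n_bootstrap,seed Passed to [build_tree()].
#' @param support_threshold Passed to [placement_verdict()].
#' @return A `placement_verdict` tibble (see [placement_verdict()]).
#' @export
place_candidate <- function(protein, candidate_id = "candidate",
                            panel = reference_panel(), n_bootstrap = 100L,
                            seed = 1L, support_threshold = 70) {
  seqs <- c(stats::setNames(protein, candidate_id),
            panel$host_refs, panel$contaminant_refs, panel$outgroup)
  aln <- fold_alignment(seqs, exclude_loop1 = TRUE)
  tr <- build_tree(aln, n_bootstrap = n_bootstrap, seed = seed)
  placement_verdict(tr, candidate_id, panel, support_threshold)
}

#' Write a tree with bootstrap support labels to Newick
#'
#' @param x A `histone_tree` or the tibble returned by
#'   [placement_verdict()] (whose attribute carries the rooted tree).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(x, path) {
  phy <- if (inherits(x, "histone_tree")) x$tree else attr(x, "tree")
  ape::write.tree(phy, file = path)
  invisible(path)
}
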