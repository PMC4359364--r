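# Profile (PSSM) detection of the CenpC motif and the cupin domain.
#
# CenpC, the inner-kinetochore partner of CenH3, carries two conserved
# elements: the short CenpC motif that binds the CenH3 nucleosome, and a
# C-terminal cupin fold.  Both are detected here with position-specific
# score matrices built from seed alignments and scored against a
# permutation null; cupin hits are additionally placed in a clade test,
# because cupin folds occur in many non-kinetochore protein families and
# only the CenpC-type clade is informative.

#' Build a position-specific score matrix from a seed alignment
#'
#' Per-column residue frequencies with additive pseudocounts, expressed
#' as log2-odds against a background distribution (uniform by default).
#'
#' @param seed_alignment Named character vector of aligned sequences
#'   (equal lengths, >= 3 sequences, no all-gap columns).
#' @param pseudocount Additive pseudocount weight per residue.
#' @param background Named numeric of background frequencies over the 20
#'   amino acids (defaults to uniform).
#' @param name Motif name carried in the result.
#' @return An object of class `pssm`: a 20 x width matrix of log2-odds
#'   scores with attributes `background`, `consensus`, `name`.
#' @examples
#' p <- build_profile(c(a = "MKW", b = "MKW", c = "MRW"))
#' attr(p, "consensus")  # "MKW"
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          background = NULL, name = "motif") {
  if (length(seed_alignment) < 3) {
    stop("seed alignment needs >= 3 sequences", call. = FALSE)
  }
  widths <- nchar(seed_alignment)
  if (length(unique(widths)) != 1) {
    stop("ragged seed alignment: sequences differ in length", call. = FALSE)
  }
  w <- widths[[1]]
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA20)
  }
  mat <- matrix(0, nrow = 20, ncol = w, dimnames = list(AA20, NULL))
  chars <- do.call(rbind, strsplit(seed_alignment, "", fixed = TRUE))
  for (j in seq_len(w)) {
    col <- chars[, j]
    col <- col[col %in% AA20]
    if (length(col) == 0) stop("all-gap column in seed alignment", call. = FALSE)
    counts <- table(factor(col, levels = AA20))
    freqs <- (as.numeric(counts) + pseudocount * background) /
      (length(col) + pseudocount)
    mat[, j] <- log2(freqs / background)
  }
  consensus <- paste(rownames(mat)[apply(mat, 2, which.max)], collapse = "")
  structure(mat, class = "pssm", background = background,
            consensus = consensus, name = name)
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> motif '%s', width %d, consensus %s\n",
              attr(x, "name"), ncol(x), attr(x, "consensus")))
  invisible(x)
}

pssm_window_scores <- function(profile, protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  w <- ncol(profile)
  n <- length(aa) - w + 1L
  idx <- match(aa, rownames(profile))  # NA (e.g. X, *) scores 0
  vapply(seq_len(n), function(o) {
    cols <- idx[o:(o + w - 1L)]
    sum(profile[cbind(cols, seq_len(w))], na.rm = TRUE)
  }, numeric(1))
}

#' Scan a protein with a profile
#'
#' Slides the PSSM along the protein, reports the maximum-scoring window
#' and a permutation p-value: the (add-one smoothed) fraction of
#' residue-shuffled copies of the protein whose own best window score
#' reaches the observed one.  The smallest attainable p-value is
#' `1 / (n_null + 1)`.
#'
#' @param profile A [build_profile()] PSSM.
#' @param protein Protein string at least as long as the profile width.
#' @param n_null Number of shuffled null sequences.
#' @param seed RNG seed for the shuffles.
#' @param protein_id Label carried into the result.
#' @return A one-row tibble (class `motif_hit`): `protein_id`, `motif`,
#'   `offset` (0-based), `score` (bits), `pvalue`.
#' @export
scan_profile <- function(profile, protein, n_null = 999L, seed = 1L,
                         protein_id = "protein") {
  stopifnot(inherits(profile, "pssm"))
  if (nchar(protein) < ncol(profile)) {
    stop("protein shorter than profile width", call. = FALSE)
  }
  scores <- pssm_window_scores(profile, protein)
  best <- which.max(scores)
  obs <- scores[best]
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  null_max <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      max(pssm_window_scores(profile, paste(sample(aa), collapse = "")))
    }, numeric(1))
  })
  p <- (1 + sum(null_max >= obs)) / (n_null + 1)
  out <- tibble::tibble(
    protein_id = protein_id,
    motif = attr(profile, "name"),
    offset = best - 1L,
    score = obs,
    pvalue = p
  )
  class(out) <- c("motif_hit", class(out))
  out
}

#' Scan a set of proteins with a profile
#'
#' @param profile A [build_profile()] PSSM.
#' @param proteins Named character vector; entries shorter than the
#'   profile width are skipped.
#' @inheritParams scan_profile
#' @return A tibble of per-protein best hits sorted by ascending p-value.
#' @export
scan_proteome <- function(profile, proteins, n_null = 999L, seed = 1L) {
  stopifnot(!is.null(names(proteins)))
  keep <- nchar(proteins) >= ncol(profile)
  out <- purrr::map_dfr(names(proteins)[keep], function(id) {
    scan_profile(profile, proteins[[id]], n_null = n_null,
                 seed = child_seed(seed, id), protein_id = id)
  })
  dplyr::arrange(out, .data$pvalue)
}

# --- Profile serialization -----------------------------------------------

#' Read or write a PSSM as plain text
#'
#' Format: comment header with motif name, an `alphabet` row, a
#' `background` row, then one whitespace-separated score row per profile
#' column.
#'
#' @param profile A `pssm`.
#' @param path File path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a `pssm`.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# pssm ", attr(profile, "name")),
    paste("alphabet", paste(rownames(profile), collapse = " ")),
    paste("background", paste(signif(attr(profile, "background"), 6), collapse = " "))
  ), con)
  utils::write.table(t(profile), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  name <- sub("^# pssm ", "", lines[1])
  alphabet <- strsplit(sub("^alphabet ", "", lines[2]), " ")[[1]]
  background <- as.numeric(strsplit(sub("^background ", "", lines[3]), " ")[[1]])
  mat <- t(as.matrix(utils::read.table(text = lines[-(1:3)])))
  dimnames(mat) <- list(alphabet, NULL)
  consensus <- paste(alphabet[apply(mat, 2, which.max)], collapse = "")
  structure(mat, class = "pssm",
            background = stats::setNames(background, alphabet),
            consensus = consensus, name = name)
}

# --- Bundled synthetic CenpC fixtures ------------------------------------

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "cenh3scan")
  if (!nzchar(p)) stop("bundled fixture not found: ", file, call. = FALSE)
  p
}

#' Bundled synthetic CenpC-motif and cupin profiles
#'
#' PSSMs built from the bundled *synthetic* seed alignments (constructed
#' in silico to mimic the conservation structure of the real CenpC motif
#' and cupin domain families; they are not curated biological sequences).
#'
#' @param pseudocount Passed to [build_profile()].
#' @return A `pssm`.
#' @export
cenpc_motif_profile <- function(pseudocount = 1) {
  aln <- read_fasta(extdata_path("synthetic_cenpc_motif_seed.fasta"), type = "AA")
  build_profile(stats::setNames(aln$seq, aln$id), pseudocount,
                name = "CenpC_motif")
}

#' @rdname cenpc_motif_profile
#' @export
cupin_profile <- function(pseudocount = 1) {
  aln <- read_fasta(extdata_path("synthetic_cupin_seed.fasta"), type = "AA")
  build_profile(stats::setNames(aln$seq, aln$id), pseudocount, name = "cupin")
}

#' Bundled synthetic cupin reference panel
#'
#' Labelled cupin domains for the clade test distinguishing CenpC-type
#' cupins from other cupin subfamilies: `host_refs` are CenpC-type,
#' `contaminant_refs` are non-CenpC cupins, `outgroup` a third, distant
#' subfamily.  All sequences are synthetic, equal-length and alignable by
#' position.
#'
#' @return A `reference_panel`-shaped list.
#' @export
cupin_panel <- function() {
  seqs <- read_fasta(extdata_path("synthetic_cupin_panel.fasta"), type = "AA")
  v <- stats::setNames(seqs$seq, seqs$id)
  structure(list(
    host_refs = v[grepl("^cenpc_cupin", names(v))],
    contaminant_refs = v[grepl("^other_cupin", names(v))],
    outgroup = v[grepl("^outgroup_cupin", names(v))]
  ), class = "reference_panel")
}

#' Clade test for a cupin hit
#'
#' Places the scanned cupin window with the bundled cupin panel in a
#' bootstrapped NJ tree.  Verdict `"host"` means the cupin groups with
#' CenpC-type cupins (i.e. is consistent with a CenpC architecture).
#'
#' @param cupin_seq The protein window matched by [cupin_profile()]
#'   (same width as the panel sequences).
#' @param candidate_id Label.
#' @param n_bootstrap,seed,support_threshold Tree/test parameters.
#' @return A `placement_verdict` tibble.
#' @export
cupin_clade_verdict <- function(cupin_seq, candidate_id = "cupin_candidate",
                                n_bootstrap = 100L, seed = 1L,
                                support_threshold = 70) {
  panel <- cupin_panel()
  seqs <- c(stats::setNames(cupin_seq, candidate_id),
            panel$host_refs, panel$contaminant_refs, panel$outgroup)
  if (length(unique(nchar(seqs))) != 1) {
    stop("cupin window length must match the panel width", call. = FALSE)
  }
  aln <- t(vapply(seqs, function(s) strsplit(s, "")[[1]],
                  character(nchar(seqs[[1]]))))
  tr <- build_tree(aln, n_bootstrap = n_bootstrap, seed = seed)
  placement_verdict(tr, candidate_id, panel, support_threshold)
}

#' Call the CenpC architecture of one protein
#'
#' Combines the CenpC-motif scan, the cupin scan and (for cupin-only
#' cases) the cupin clade test into one architecture label: a protein
#' with both elements is `"motif+cupin"`; one whose motif has decayed but
#' whose cupin is still recognisably CenpC-type is `"cupin-only"`; a
#' cupin hit whose clade test contradicts a CenpC-type origin does not
#' count.
#'
#' @param motif_hit,cupin_hit One-row tibbles from [scan_profile()].
#' @param cupin_verdict Optional `placement_verdict` for the cupin hit
#'   window (required to accept a cupin whose motif is absent).
#' @param p_threshold Significance threshold on permutation p-values.
#' @return One of `"motif+cupin"`, `"motif-only"`, `"cupin-only"`,
#'   `"none"`.
#' @export
call_cenpc_architecture <- function(motif_hit, cupin_hit,
                                    cupin_verdict = NULL,
                                    p_threshold = 1e-3) {
  has_motif <- nrow(motif_hit) > 0 && any(motif_hit$pvalue <= p_threshold)
  cupin_sig <- nrow(cupin_hit) > 0 && any(cupin_hit$pvalue <= p_threshold)
  cupin_consistent <- is.null(cupin_verdict) ||
    any(cupin_verdict$verdict == "host")
  has_cupin <- cupin_sig && cupin_consistent
  if (has_motif && has_cupin) "motif+cupin"
  else if (has_motif) "motif-only"
  else if (has_cupin) "cupin-only"
  else "none"
}
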