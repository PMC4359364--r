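# Synthetic species assemblies with known ground truth.
#
# The generator emulates what the real surveys consume: a per-species de
# novo transcriptome containing a benchmark gene complement with
# expression-coupled dropout, the core histone repertoire (H3, H3.3,
# optionally a CenH3 built by loop1 insertion + diagnostic substitutions +
# randomised N-tail), optionally a contaminating CenH3 transcript from a
# divergent fungal-style donor, and log-normal expression levels.

# Loop1 insertion point shared by generator and classifier: insertions go
# between H3 positions 82 and 83, inside the loop1 window 78-87.
CENH3_INSERT_AFTER <- 82L

#' Build a CenH3-like protein from canonical H3
#'
#' Constructs a centromeric-histone-like variant by (i) inserting
#' `n_loop1_insert` random residues inside the loop1 window, (ii)
#' replacing the three diagnostic residues (Q68, F84, T118) with
#' non-canonical amino acids, (iii) randomising the N-terminal tail
#' (positions 1 to fold start - 1), and (iv) sprinkling substitutions over
#' the rest of the fold at rate `fold_divergence`.  At the default
#' divergence the histone fold outside these edits stays >= 70% identical
#' to H3.
#'
#' @param h3 Canonical H3 protein (defaults to the bundled reference).
#' @param n_loop1_insert Number of loop1 insertion residues (>= 1).
#' @param seed RNG seed; identical seeds give identical output.
#' @param fold_divergence Substitution rate (per site) applied to fold
#'   residues outside the diagnostic positions.
#' @return A protein string of length `nchar(h3) + n_loop1_insert`.
#' @examples
#' cenh3 <- make_cenh3_like(n_loop1_insert = 2, seed = 1)
#' nchar(cenh3)  # 137
#' @export
make_cenh3_like <- function(h3 = h3_reference()$seq, n_loop1_insert = 2L,
                            seed = 1L, fold_divergence = 0.05) {
  if (!is.numeric(n_loop1_insert) || n_loop1_insert < 1 ||
      n_loop1_insert != floor(n_loop1_insert)) {
    stop("`n_loop1_insert` must be an integer >= 1", call. = FALSE)
  }
  ref <- h3_reference()
  stopifnot(nchar(h3) == nchar(ref$seq))
  with_seed(seed, {
    aa <- strsplit(h3, "", fixed = TRUE)[[1]]
    # randomised N-terminal tail
    tail_len <- ref$fold_start - 1L
    aa[seq_len(tail_len)] <- sample(AA20, tail_len, replace = TRUE)
    # background fold divergence, sparing the diagnostic sites
    diag_pos <- as.integer(names(ref$diagnostic_positions))
    fold_idx <- setdiff(ref$fold_start:ref$fold_end, diag_pos)
    hit <- runif(length(fold_idx)) < 1 - exp(-fold_divergence)
    for (i in fold_idx[hit]) aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
    # diagnostic substitutions: anything but the canonical residue
    for (p in diag_pos) {
      aa[p] <- sample(setdiff(AA20, ref$diagnostic_positions[[as.character(p)]]), 1L)
    }
    insert <- sample(AA20, n_loop1_insert, replace = TRUE)
    paste(c(aa[seq_len(CENH3_INSERT_AFTER)], insert,
            aa[(CENH3_INSERT_AFTER + 1L):length(aa)]), collapse = "")
  })
}

# Species-level host CenH3: a mild, seeded divergence of the bundled host
# ancestor with a freshly randomised N-terminal tail (tails are not
# conserved between lineages, only the fold is).
derive_host_cenh3 <- function(divergence = 0.05) {
  ref <- h3_reference()
  anc <- cenh3_references()$host_ancestor
  aa <- strsplit(mutate_protein(anc, divergence), "", fixed = TRUE)[[1]]
  tail_len <- ref$fold_start - 1L
  aa[seq_len(tail_len)] <- sample(AA20, tail_len, replace = TRUE)
  paste(aa, collapse = "")
}

# Degraded H3-derived variant: heavily eroded fold, no loop1 extension
# (the pea-aphid-style pseudogene-like pattern the classifier must keep
# apart from CenH3).
derive_degraded_h3 <- function(divergence = 0.35) {
  ref <- h3_reference()
  aa <- strsplit(ref$seq, "", fixed = TRUE)[[1]]
  idx <- ref$fold_start:ref$fold_end
  hit <- runif(length(idx)) < 1 - exp(-divergence)
  for (i in idx[hit]) aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
  paste(aa, collapse = "")
}

#' Back-translate a protein with uniform codon choice
#'
#' @param protein Protein string (no gaps).
#' @param seed RNG seed.
#' @return A nucleotide string of length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein, seed = 1L) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), code)
  flat <- unlist(by_aa, use.names = FALSE)
  lens <- lengths(by_aa)
  offs <- stats::setNames(cumsum(lens) - lens, names(by_aa))
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(aa), names(by_aa))
  if (length(bad)) stop("cannot back-translate residue(s): ",
                        paste(bad, collapse = ","), call. = FALSE)
  with_seed(seed, {
    pick <- floor(stats::runif(length(aa)) * lens[aa]) + 1L
    paste(flat[offs[aa] + pick], collapse = "")
  })
}

#' Define a synthetic species scenario
#'
#' A scenario fixes everything about one synthetic species: how many
#' benchmark genes its transcriptome should contain, the per-gene dropout
#' probability (assembly incompleteness; low-expression genes drop out
#' preferentially), whether the species has a CenH3 gene, whether a
#' contaminating CenH3 from a divergent fungal-style donor is co-assembled,
#' and the log-normal expression model.
#'
#' @param species_id Species label.
#' @param n_benchmark_genes Number of benchmark genes (>= 1).
#' @param dropout_prob Per-gene probability of being missing from the
#'   assembly, in `[0, 1]`.
#' @param cenh3_present Does the species genome encode CenH3?
#' @param contaminant_present Is a contaminant CenH3 transcript present?
#' @param contaminant_divergence Substitutions per site applied to the
#'   fungal donor reference to form the contaminant (>= 0).
#' @param degraded_h3_present Emit an additional degraded H3-derived
#'   variant (eroded fold, no loop1 extension)?
#' @param expression_logmean,expression_logsd Log-normal abundance
#'   parameters (natural-log scale).
#' @param seed Integer seed; identical scenarios are byte-identical.
#' @return An object of class `species_scenario`.
#' @examples
#' species_scenario("sp1", dropout_prob = 0.1, seed = 42)
#' @export
species_scenario <- function(species_id = "species1",
                             n_benchmark_genes = 20L,
                             dropout_prob = 0,
                             cenh3_present = TRUE,
                             contaminant_present = FALSE,
                             contaminant_divergence = 0.5,
                             degraded_h3_present = FALSE,
                             expression_logmean = 3,
                             expression_logsd = 1.5,
                             seed = 1L) {
  assert_prob(dropout_prob, "dropout_prob")
  n_benchmark_genes <- assert_count(n_benchmark_genes, "n_benchmark_genes")
  if (contaminant_divergence < 0) {
    stop("`contaminant_divergence` must be >= 0", call. = FALSE)
  }
  structure(list(
    species_id = species_id,
    n_benchmark_genes = n_benchmark_genes,
    dropout_prob = dropout_prob,
    cenh3_present = isTRUE(cenh3_present),
    contaminant_present = isTRUE(contaminant_present),
    contaminant_divergence = contaminant_divergence,
    degraded_h3_present = isTRUE(degraded_h3_present),
    expression_logmean = expression_logmean,
    expression_logsd = expression_logsd,
    seed = as.integer(seed)
  ), class = "species_scenario")
}

#' @export
print.species_scenario <- function(x, ...) {
  cat(sprintf(
    "<species_scenario> %s: %d benchmark genes, dropout %.2f, CenH3 %s%s, seed %d\n",
    x$species_id, x$n_benchmark_genes, x$dropout_prob,
    if (x$cenh3_present) "present" else "absent",
    if (x$contaminant_present) sprintf(", contaminant (div %.2f)",
                                       x$contaminant_divergence) else "",
    x$seed
  ))
  invisible(x)
}

#' Generate a synthetic transcriptome assembly
#'
#' Realises a [species_scenario()] as an assembly with a complete truth
#' table.  Benchmark genes are random proteins (lengths 100-600)
#' back-translated with uniform codon choice; the number emitted is
#' binomial with survival probability `1 - dropout_prob` and the dropped
#' genes are picked preferentially among low-abundance ones.  H3 and H3.3
#' are always emitted; the host CenH3 (if present) survives dropout
#' independently; the contaminant CenH3 (if present) is always emitted.
#' Per-transcript counts are Poisson draws around log-normal abundances.
#'
#' @param scenario A [species_scenario()].
#' @param benchmark_proteins Optional named character vector of benchmark
#'   proteins shared across species (as when one reference proteome
#'   benchmarks a whole survey); defaults to scenario-seeded random
#'   proteins.
#' @return An object of class `synthetic_assembly`: list with
#'   `species_id`, `transcripts` (tibble: `id`, `locus_id`, `isoform_id`,
#'   `seq`, `length`, `count`), `proteins` (named character, all genes,
#'   emitted or not), `truth` (tibble: `gene_id`, `class`, `emitted`,
#'   `contaminant`, `count`), and `benchmark` (the benchmark proteins).
#' @examples
#' asm <- generate_assembly(species_scenario("sp1", n_benchmark_genes = 5, seed = 3))
#' asm$truth
#' @export
generate_assembly <- function(scenario, benchmark_proteins = NULL) {
  stopifnot(inherits(scenario, "species_scenario"))
  with_seed(scenario$seed, {
    n <- scenario$n_benchmark_genes
    if (is.null(benchmark_proteins)) {
      lens <- sample(100:600, n, replace = TRUE)
      benchmark_proteins <- stats::setNames(
        vapply(lens, random_protein, ""),
        sprintf("bench_%03d", seq_len(n))
      )
    } else {
      stopifnot(!is.null(names(benchmark_proteins)))
      n <- length(benchmark_proteins)
    }

    genes <- tibble::tibble(
      gene_id = names(benchmark_proteins),
      class = "benchmark",
      protein = unname(benchmark_proteins),
      contaminant = FALSE
    )
    genes <- dplyr::bind_rows(genes, tibble::tibble(
      gene_id = c("H3", "H3.3"),
      class = c("H3", "H3.3"),
      protein = c(h3_reference()$seq, h33_sequence()),
      contaminant = FALSE
    ))
    if (scenario$cenh3_present) {
      genes <- dplyr::bind_rows(genes, tibble::tibble(
        gene_id = "CenH3", class = "CenH3",
        protein = derive_host_cenh3(), contaminant = FALSE
      ))
    }
    if (scenario$degraded_h3_present) {
      genes <- dplyr::bind_rows(genes, tibble::tibble(
        gene_id = "H3_degraded", class = "H3-like",
        protein = derive_degraded_h3(), contaminant = FALSE
      ))
    }
    if (scenario$contaminant_present) {
      genes <- dplyr::bind_rows(genes, tibble::tibble(
        gene_id = "CenH3_contaminant", class = "CenH3",
        protein = mutate_protein(cenh3_references()$fungal_donor,
                                 scenario$contaminant_divergence),
        contaminant = TRUE
      ))
    }

    genes$abundance <- stats::rlnorm(nrow(genes),
                                     meanlog = scenario$expression_logmean,
                                     sdlog = scenario$expression_logsd)

    # expression-coupled dropout: the number of surviving benchmark genes
    # is Binomial(n, 1 - dropout); the dropped ones are drawn with weight
    # inversely proportional to abundance, so the marginal emitted
    # fraction still follows the binomial law.
    bench_idx <- which(genes$class == "benchmark")
    k_drop <- stats::rbinom(1L, length(bench_idx), scenario$dropout_prob)
    dropped <- if (k_drop > 0) {
      sample(bench_idx, k_drop, prob = 1 / genes$abundance[bench_idx])
    } else integer(0)
    genes$emitted <- TRUE
    genes$emitted[dropped] <- FALSE
    genes$emitted[genes$class %in% c("H3", "H3.3")] <- TRUE
    cen_idx <- which(genes$gene_id == "CenH3")
    if (length(cen_idx)) {
      genes$emitted[cen_idx] <- stats::runif(1) >= scenario$dropout_prob
    }

    genes$count <- ifelse(genes$emitted, stats::rpois(nrow(genes), genes$abundance), 0L)

    emitted <- genes[genes$emitted, ]
    transcripts <- tibble::tibble(
      id = paste0(emitted$gene_id, ".i1"),
      locus_id = emitted$gene_id,
      isoform_id = "i1",
      seq = vapply(seq_len(nrow(emitted)), function(i) {
        back_translate(emitted$protein[i],
                       seed = child_seed(scenario$seed, emitted$gene_id[i]))
      }, ""),
      count = emitted$count
    )
    transcripts$length <- nchar(transcripts$seq)

    structure(list(
      species_id = scenario$species_id,
      scenario = scenario,
      transcripts = transcripts,
      proteins = stats::setNames(genes$protein, genes$gene_id),
      truth = tibble::tibble(
        gene_id = genes$gene_id, class = genes$class,
        emitted = genes$emitted, contaminant = genes$contaminant,
        count = genes$count
      ),
      benchmark = benchmark_proteins
    ), class = "synthetic_assembly")
  })
}

#' @export
print.synthetic_assembly <- function(x, ...) {
  cat(sprintf("<synthetic_assembly> %s: %d transcripts (%d genes in truth)\n",
              x$species_id, nrow(x$transcripts), nrow(x$truth)))
  invisible(x)
}

#' Shred transcripts into fixed-length reads
#'
#' Optional read-level view of an assembly for exercising
#' [read_level_search()] and [assign_counts()]: each transcript yields
#' reads at uniformly random start positions, one read per unit of its
#' `count` (or a fixed number per transcript).
#'
#' @param transcripts Assembly tibble (or `synthetic_assembly`); needs
#'   columns `id`, `seq` and, unless `reads_per_transcript` is given,
#'   `count`.
#' @param read_length Read length in nt; transcripts shorter than this
#'   are skipped.
#' @param reads_per_transcript Optional fixed read number per transcript.
#' @param seed RNG seed.
#' @return A tibble with columns `read_id`, `origin`, `seq`.
#' @export
shred_reads <- function(transcripts, read_length = 100L,
                        reads_per_transcript = NULL, seed = 1L) {
  if (inherits(transcripts, "synthetic_assembly")) {
    transcripts <- transcripts$transcripts
  }
  read_length <- assert_count(read_length, "read_length")
  with_seed(seed, {
    out <- purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
      len <- nchar(transcripts$seq[i])
      if (len < read_length) return(NULL)
      nr <- if (is.null(reads_per_transcript)) {
        as.integer(transcripts$count[i])
      } else as.integer(reads_per_transcript)
      if (is.na(nr) || nr <= 0L) return(NULL)
      starts <- sample.int(len - read_length + 1L, nr, replace = TRUE)
      tibble::tibble(
        origin = transcripts$id[i],
        seq = substring(transcripts$seq[i], starts, starts + read_length - 1L)
      )
    })
    if (nrow(out) == 0) {
      return(tibble::tibble(read_id = character(), origin = character(),
                            seq = character()))
    }
    out$read_id <- sprintf("read_%05d", seq_len(nrow(out)))
    out[, c("read_id", "origin", "seq")]
  })
}

#' Write a synthetic assembly to disk
#'
#' Standard outputs for one synthetic species: transcript FASTA, protein
#' FASTA and a TSV truth table (`gene_id`, `emitted`, `class`,
#' `contaminant`, `count`).  Deterministic given the scenario seed.
#'
#' @param assembly A `synthetic_assembly`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_assembly <- function(assembly, dir) {
  stopifnot(inherits(assembly, "synthetic_assembly"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(assembly$transcripts[, c("id", "seq")],
              file.path(dir, paste0(assembly$species_id, "_transcripts.fasta")),
              type = "DNA")
  write_fasta(assembly$proteins,
              file.path(dir, paste0(assembly$species_id, "_proteins.fasta")),
              type = "AA")
  utils::write.table(
    assembly$truth[, c("gene_id", "emitted", "class", "contaminant", "count")],
    file.path(dir, paste0(assembly$species_id, "_truth.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
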