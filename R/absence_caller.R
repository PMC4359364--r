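# Integrated per-species presence calls.
#
# "Present" needs a classified, non-contaminant candidate.  "Absent" is
# only ever called under controls: the assembly must pass the
# completeness gate (it recovers a benchmark-proteome fraction comparable
# to the positive-control assemblies) and, when reads are available, a
# read-level translated search must find no CenH3-specific fragments.
# Anything else is inconclusive.

#' Pipeline configuration
#'
#' Houses every threshold of the survey in one serialisable list.
#'
#' @param sig_threshold E-value cutoff for assembly-level searches
#'   (default 1e-10).
#' @param read_search_threshold E-value cutoff for the read-level search
#'   (default 1e-5; short translated fragments cannot reach the
#'   assembly-level threshold).
#' @param min_len_coverage Transcript length filter for the completeness
#'   survey (nt).
#' @param min_len_rank Transcript length filter for abundance ranking (nt).
#' @param min_read_length Reads shorter than this cannot support a
#'   read-level negative (default 90 nt).
#' @param support_threshold Bootstrap % needed to accept a clade verdict.
#' @param completeness_factor See [completeness_gate()].
#' @param n_bootstrap Bootstrap replicates for placement trees.
#' @param classifier A [classifier_thresholds()] list.
#' @param seed Master seed; all per-candidate seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sig_threshold = 1e-10,
                            read_search_threshold = 1e-5,
                            min_len_coverage = 250L,
                            min_len_rank = 200L,
                            min_read_length = 90L,
                            support_threshold = 70,
                            completeness_factor = 0.55,
                            n_bootstrap = 100L,
                            classifier = classifier_thresholds(),
                            seed = 1L) {
  stopifnot(sig_threshold > 0, read_search_threshold > 0,
            min_len_coverage > 0, min_len_rank > 0, support_threshold > 0)
  structure(list(
    sig_threshold = sig_threshold,
    read_search_threshold = read_search_threshold,
    min_len_coverage = as.integer(min_len_coverage),
    min_len_rank = as.integer(min_len_rank),
    min_read_length = as.integer(min_read_length),
    support_threshold = support_threshold,
    completeness_factor = completeness_factor,
    n_bootstrap = as.integer(n_bootstrap),
    classifier = classifier,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Translated search of raw reads for H3-family fragments
#'
#' Rules out the possibility that a gene is expressed but unassembled:
#' each read is translated in six frames and searched with the H3-family
#' query panel.  Hits are attributed to H3/H3.3 or to CenH3 by best
#' score; the CenH3-specific count is the quantity an absence call needs
#' to be zero.  Reads shorter than `min_read_length` cannot yield
#' significant translated alignments, so such input is refused with an
#' error of class `cenh3scan_short_reads` — an explicit "insufficient
#' read length" signal, never a silent negative.
#'
#' @param reads Tibble with columns `read_id`, `seq`.
#' @param queries Named query panel with a `query_class` attribute
#'   (see [default_query_panel()]).
#' @param threshold E-value cutoff (default 1e-5).
#' @param min_read_length Minimum usable read length (nt).
#' @return A list of class `read_search`: `hits` (per-read best
#'   attribution), `n_cenh3_specific`, `n_h3_attributable`,
#'   `n_reads_searched`.
#' @export
read_level_search <- function(reads, queries = default_query_panel(),
                              threshold = 1e-5, min_read_length = 90L) {
  stopifnot(is.data.frame(reads))
  qclass <- attr(queries, "query_class")
  if (is.null(qclass)) {
    stop("`queries` needs a `query_class` attribute ('h3'/'cenh3')", call. = FALSE)
  }
  usable <- reads[nchar(reads$seq) >= min_read_length, , drop = FALSE]
  if (nrow(reads) > 0 && nrow(usable) == 0) {
    stop(structure(class = c("cenh3scan_short_reads", "error", "condition"),
                   list(message = sprintf(
                     "insufficient read length: all reads < %d nt, too short for significant translated alignments",
                     min_read_length), call = NULL)))
  }
  empty_hits <- tibble::tibble(read_id = character(), best_query = character(),
                               class = character(), score = numeric(),
                               evalue = numeric())
  if (nrow(usable) == 0) {
    return(structure(list(hits = empty_hits, n_cenh3_specific = 0L,
                          n_h3_attributable = 0L, n_reads_searched = 0L),
                     class = "read_search"))
  }
  as_tx <- tibble::tibble(id = usable$read_id, seq = usable$seq)
  hits <- search_protein_vs_transcripts(queries, as_tx, threshold)
  if (nrow(hits) == 0) {
    return(structure(list(hits = empty_hits, n_cenh3_specific = 0L,
                          n_h3_attributable = 0L,
                          n_reads_searched = nrow(usable)),
                     class = "read_search"))
  }
  class_of <- stats::setNames(qclass, names(queries))
  per_read <- hits |>
    dplyr::group_by(read_id = .data$subject) |>
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$read_id, best_query = .data$query,
                     class = unname(class_of[.data$query]),
                     .data$score, .data$evalue)
  structure(list(
    hits = per_read,
    n_cenh3_specific = sum(per_read$class == "cenh3"),
    n_h3_attributable = sum(per_read$class == "h3"),
    n_reads_searched = nrow(usable)
  ), class = "read_search")
}

#' @export
print.read_search <- function(x, ...) {
  cat(sprintf("<read_search> %d reads searched: %d H3/H3.3-attributable, %d CenH3-specific\n",
              x$n_reads_searched, x$n_h3_attributable, x$n_cenh3_specific))
  invisible(x)
}

#' Integrated presence call for one species
#'
#' Runs the classifier over the assembly, attributes every CenH3-labelled
#' candidate to host or contaminant lineage, computes the completeness
#' control, and combines them: `present` iff at least one non-contaminant
#' CenH3 candidate; `absent` iff there is none, the completeness gate
#' passes, and (if reads are supplied) the read-level search is negative;
#' otherwise `inconclusive`.  The abundance percentile of the CenH3
#' transcript (when present and counts are available) is attached as
#' evidence, not used as a gate.
#'
#' @param assembly A `synthetic_assembly` or assembly tibble (`id`,
#'   `seq`, optional `locus_id`, `isoform_id`, `count`).
#' @param gene Gene surveyed (currently `"CenH3"`).
#' @param config A [pipeline_config()].
#' @param benchmark Benchmark proteome (named character) for the
#'   completeness control; taken from a `synthetic_assembly` when absent.
#' @param control_fractions Recovery fractions of the positive-control
#'   assemblies; without them the gate cannot run and no-candidate
#'   assemblies are forced inconclusive.
#' @param panel A [reference_panel()] for contamination attribution.
#' @param reads Optional read tibble for [read_level_search()].
#' @param species_id Species label (defaults from the assembly).
#' @return A one-row tibble of class `presence_call`: `species_id`,
#'   `gene`, `status`, `n_candidates`, `n_contaminant`,
#'   `coverage_fraction`, `gate_passed`, `cenh3_percentile`,
#'   `read_cenh3_hits`, `notes`; full evidence (histone calls, placement
#'   verdicts, coverage report, read search) in attribute `evidence`.
#' @export
call_presence <- function(assembly, gene = "CenH3",
                          config = pipeline_config(),
                          benchmark = NULL, control_fractions = NULL,
                          panel = reference_panel(), reads = NULL,
                          species_id = NULL) {
  if (inherits(assembly, "synthetic_assembly")) {
    if (is.null(species_id)) species_id <- assembly$species_id
    if (is.null(benchmark)) benchmark <- assembly$benchmark
    transcripts <- assembly$transcripts
  } else {
    transcripts <- assembly
    if (is.null(species_id)) species_id <- "assembly"
  }
  notes <- character(0)

  calls <- classify_assembly(transcripts,
                             reference = h3_reference(),
                             thresholds = config$classifier,
                             sig_threshold = config$sig_threshold)
  cen <- calls[calls$label == "CenH3", , drop = FALSE]
  verdicts <- purrr::map_dfr(seq_len(nrow(cen)), function(i) {
    place_candidate(cen$protein[i], cen$candidate_id[i], panel,
                    n_bootstrap = config$n_bootstrap,
                    seed = child_seed(config$seed, cen$candidate_id[i]),
                    support_threshold = config$support_threshold)
  })
  n_contam <- if (nrow(verdicts)) sum(verdicts$verdict == "contaminant") else 0L
  non_contam <- if (nrow(cen)) {
    cen$candidate_id[!cen$candidate_id %in%
                       verdicts$candidate_id[verdicts$verdict == "contaminant"]]
  } else character(0)

  coverage <- NULL
  gate <- NA
  if (!is.null(benchmark)) {
    filtered <- filter_transcripts(transcripts, min_len = config$min_len_coverage)
    coverage <- coverage_fraction(benchmark, filtered,
                                  sig_threshold = config$sig_threshold,
                                  assembly_id = species_id)
    gate <- completeness_gate(coverage$fraction, control_fractions,
                              config$completeness_factor)
  } else {
    notes <- c(notes, "no benchmark proteome: completeness control unavailable")
  }
  if (is.na(gate)) {
    notes <- c(notes, "no positive controls: completeness gate cannot run")
  }

  read_res <- NULL
  reads_negative <- TRUE
  if (!is.null(reads)) {
    read_res <- tryCatch(
      read_level_search(reads, threshold = config$read_search_threshold,
                        min_read_length = config$min_read_length),
      cenh3scan_short_reads = function(e) {
        notes <<- c(notes, conditionMessage(e))
        NULL
      }
    )
    if (!is.null(read_res)) reads_negative <- read_res$n_cenh3_specific == 0L
  }

  abundance <- NULL
  cen_pct <- NA_real_
  if (!is.null(transcripts$count)) {
    abundance <- normalize_abundance(transcripts, min_rank_len = config$min_len_rank)
    if (length(non_contam)) {
      tx_ids <- cen$transcript_id[cen$candidate_id %in% non_contam]
      hitrows <- match(tx_ids, abundance$id)
      if (any(!is.na(hitrows))) cen_pct <- max(abundance$percentile[stats::na.omit(hitrows)])
    }
  }

  status <- if (length(non_contam) > 0) {
    "present"
  } else if (isTRUE(gate) && reads_negative) {
    "absent"
  } else {
    "inconclusive"
  }
  if (status == "absent" && n_contam > 0) {
    notes <- c(notes, sprintf("%d CenH3-like candidate(s) attributed to contamination", n_contam))
  }
  if (status == "present" && !is.na(cen_pct) && cen_pct < 10) {
    notes <- c(notes, "CenH3 transcript in bottom 10th abundance percentile")
  }

  out <- tibble::tibble(
    species_id = species_id,
    gene = gene,
    status = status,
    n_candidates = nrow(cen),
    n_contaminant = n_contam,
    coverage_fraction = if (is.null(coverage)) NA_real_ else coverage$fraction,
    gate_passed = gate,
    cenh3_percentile = cen_pct,
    read_cenh3_hits = if (is.null(read_res)) NA_integer_ else read_res$n_cenh3_specific,
    notes = paste(notes, collapse = "; ")
  )
  attr(out, "evidence") <- list(
    histone_calls = calls, placement = verdicts, coverage = coverage,
    abundance = abundance, read_search = read_res
  )
  class(out) <- c("presence_call", class(out))
  out
}

#' Survey many species for CenH3 presence/absence
#'
#' Generates (or accepts) one assembly per species, computes the shared
#' benchmark coverage of positive-control assemblies, and produces the
#' per-species presence/absence matrix with all controls attached.  All
#' species in a survey are benchmarked against the same protein set, as
#' when one reference proteome benchmarks every assembly.
#'
#' @param scenarios A list of [species_scenario()]s (synthetic survey) or
#'   of `synthetic_assembly` objects.
#' @param config A [pipeline_config()].
#' @param n_controls Number of internally generated positive-control
#'   species (complete, CenH3-positive) when `control_assemblies` is not
#'   given.
#' @param control_assemblies Optional list of positive-control
#'   assemblies.
#' @param benchmark Optional shared benchmark proteome; defaults to a
#'   seeded random proteome of the first scenario's size.
#' @return An object of class `cenh3_survey`: list with `calls` (the
#'   per-species matrix tibble), `truth` (for synthetic scenarios),
#'   `coverage`, `control_fractions`, `config`, and per-species evidence.
#' @examples
#' \donttest{
#' sc <- lapply(1:2, function(i)
#'   species_scenario(paste0("sp", i), n_benchmark_genes = 5,
#'                    cenh3_present = i == 1, seed = i))
#' sv <- run_survey(sc, config = pipeline_config(seed = 1), n_controls = 1)
#' sv$calls
#' }
#' @export
run_survey <- function(scenarios, config = pipeline_config(),
                       n_controls = 3L, control_assemblies = NULL,
                       benchmark = NULL) {
  if (length(scenarios) == 0) {
    return(structure(list(
      calls = tibble::tibble(species_id = character(), gene = character(),
                             status = character()),
      truth = tibble::tibble(), coverage = tibble::tibble(),
      control_fractions = numeric(0), config = config, evidence = list()
    ), class = "cenh3_survey"))
  }
  is_scenario <- vapply(scenarios, inherits, TRUE, what = "species_scenario")
  if (is.null(benchmark)) {
    n_bench <- if (any(is_scenario)) {
      scenarios[[which(is_scenario)[1]]]$n_benchmark_genes
    } else {
      length(scenarios[[1]]$benchmark)
    }
    benchmark <- with_seed(child_seed(config$seed, "benchmark"), {
      lens <- sample(100:600, n_bench, replace = TRUE)
      stats::setNames(vapply(lens, random_protein, ""),
                      sprintf("bench_%03d", seq_len(n_bench)))
    })
  }
  assemblies <- lapply(scenarios, function(s) {
    if (inherits(s, "species_scenario")) generate_assembly(s, benchmark) else s
  })

  if (is.null(control_assemblies)) {
    control_assemblies <- lapply(seq_len(n_controls), function(i) {
      generate_assembly(
        species_scenario(paste0("control_", i), n_benchmark_genes = length(benchmark),
                         dropout_prob = 0, cenh3_present = TRUE,
                         seed = child_seed(config$seed, paste0("control", i))),
        benchmark
      )
    })
  }
  control_fractions <- vapply(control_assemblies, function(a) {
    tx <- filter_transcripts(a, min_len = config$min_len_coverage)
    coverage_fraction(benchmark, tx, sig_threshold = config$sig_threshold,
                      assembly_id = if (inherits(a, "synthetic_assembly")) a$species_id else "control")$fraction
  }, numeric(1))

  results <- lapply(assemblies, function(a) {
    call_presence(a, gene = "CenH3", config = config, benchmark = benchmark,
                  control_fractions = control_fractions)
  })
  calls <- dplyr::bind_rows(results)
  truth <- purrr::map_dfr(assemblies, function(a) {
    if (!inherits(a, "synthetic_assembly")) return(NULL)
    host_cen <- a$truth[a$truth$class == "CenH3" & !a$truth$contaminant, ]
    tibble::tibble(
      species_id = a$species_id,
      cenh3_in_genome = nrow(host_cen) > 0,
      cenh3_emitted = nrow(host_cen) > 0 && any(host_cen$emitted),
      contaminant_emitted = any(a$truth$contaminant & a$truth$emitted),
      dropout_prob = a$scenario$dropout_prob
    )
  })
  coverage <- dplyr::bind_rows(lapply(results, function(r) {
    cov <- attr(r, "evidence")$coverage
    if (is.null(cov)) return(NULL)
    tibble::as_tibble(cov)
  }))
  structure(list(
    calls = calls, truth = truth, coverage = coverage,
    control_fractions = control_fractions, config = config,
    evidence = lapply(results, attr, "evidence")
  ), class = "cenh3_survey")
}

#' @export
print.cenh3_survey <- function(x, ...) {
  cat(sprintf("<cenh3_survey> %d species\n", nrow(x$calls)))
  print(table(x$calls$status))
  invisible(x)
}

#' Write survey outputs as TSV
#'
#' Writes the presence/absence matrix and the coverage report.
#'
#' @param survey A `cenh3_survey`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(survey$calls, file.path(dir, "presence_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(survey$coverage)) {
    utils::write.table(survey$coverage, file.path(dir, "coverage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
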