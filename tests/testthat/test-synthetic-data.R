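test_that("make_cenh3_like builds the diagnostic construction deterministically", {
  ref <- h3_reference()
  out <- make_cenh3_like(n_loop1_insert = 2, seed = 1)
  expect_equal(nchar(out), 137)
  expect_identical(out, make_cenh3_like(n_loop1_insert = 2, seed = 1))
  expect_error(make_cenh3_like(n_loop1_insert = 0), ">= 1")

  # re-aligned to H3, the insertion shows up as loop1 gap columns
  for (k in c(1, 2, 3)) {
    cen <- make_cenh3_like(n_loop1_insert = k, seed = 5 + k)
    aln <- align_global(cen, ref$seq, type = "overlap")
    expect_equal(measure_loop1_extension(aln, ref), k)
    # diagnostic positions are never the canonical Q/F/T
    states <- diagnostic_residue_states(aln, ref)
    expect_true(all(states == "substituted"))
  }
})

test_that("cenh3-like folds stay recognisably H3-derived outside the edits", {
  ref <- h3_reference()
  cen <- make_cenh3_like(n_loop1_insert = 2, seed = 3)
  aln <- align_global(cen, ref$seq, type = "overlap")
  map <- alignment_map(aln)
  edited <- c(as.integer(names(ref$diagnostic_positions)),
              ref$loop1_start:ref$loop1_end)
  fold_cols <- map[!is.na(map$s_pos) & map$s_pos >= ref$fold_start &
                     !map$s_pos %in% edited & !is.na(map$q_pos), ]
  expect_gte(100 * mean(fold_cols$q_res == fold_cols$s_res), 70)
})

test_that("assembly generation honours dropout edge cases and records truth", {
  asm0 <- generate_assembly(species_scenario("s", n_benchmark_genes = 6,
                                             dropout_prob = 0, seed = 2))
  expect_true(all(asm0$truth$emitted))
  expect_setequal(asm0$transcripts$locus_id, asm0$truth$gene_id)

  asm1 <- generate_assembly(species_scenario("s", n_benchmark_genes = 6,
                                             dropout_prob = 1,
                                             cenh3_present = TRUE, seed = 2))
  tr <- asm1$truth
  expect_false(tr$emitted[tr$gene_id == "CenH3"])
  expect_equal(tr$class[tr$gene_id == "CenH3"], "CenH3")
  # H3/H3.3 always emitted; every emitted transcript has a truth entry
  expect_true(all(tr$emitted[tr$class %in% c("H3", "H3.3")]))
  expect_true(all(asm1$transcripts$locus_id %in% tr$gene_id))
  expect_true(all(asm1$truth$count >= 0))
})

test_that("identical scenarios give byte-identical assemblies", {
  sc <- species_scenario("s", n_benchmark_genes = 8, dropout_prob = 0.4,
                         contaminant_present = TRUE, seed = 77)
  expect_identical(generate_assembly(sc), generate_assembly(sc))
})

test_that("emitted benchmark fraction follows the binomial law", {
  n <- 120; d <- 0.3; seeds <- 1:50
  fr <- vapply(seeds, function(s) {
    asm <- generate_assembly(species_scenario("s", n_benchmark_genes = n,
                                              dropout_prob = d, seed = s))
    tr <- asm$truth[asm$truth$class == "benchmark", ]
    mean(tr$emitted)
  }, numeric(1))
  se <- sqrt(d * (1 - d) / (n * length(seeds)))
  expect_lt(abs(mean(fr) - (1 - d)), 3 * se + 1e-9)
})

test_that("contaminant transcripts derive from the fungal donor", {
  asm <- generate_assembly(species_scenario("s", n_benchmark_genes = 4,
                                            cenh3_present = FALSE,
                                            contaminant_present = TRUE,
                                            contaminant_divergence = 0.3,
                                            seed = 5))
  tr <- asm$truth
  expect_true(tr$contaminant[tr$gene_id == "CenH3_contaminant"])
  donor <- cenh3scan:::cenh3_references()$fungal_donor
  contam <- asm$proteins[["CenH3_contaminant"]]
  expect_equal(nchar(contam), nchar(donor))
  pdiff <- mean(strsplit(contam, "")[[1]] != strsplit(donor, "")[[1]])
  expect_lt(pdiff, 1 - exp(-0.3) + 0.15)
})

test_that("the read shredder tiles transcripts proportionally to counts", {
  asm <- generate_assembly(species_scenario("s", n_benchmark_genes = 4, seed = 8))
  reads <- shred_reads(asm, read_length = 100, seed = 1)
  expect_true(all(nchar(reads$seq) == 100))
  expect_identical(reads, shred_reads(asm, read_length = 100, seed = 1))
  per_tx <- table(reads$origin)
  counts <- stats::setNames(asm$transcripts$count, asm$transcripts$id)
  for (id in names(per_tx)) expect_equal(unname(per_tx[[id]]), unname(counts[[id]]))
})

test_that("assemblies round-trip to FASTA and TSV on disk", {
  asm <- generate_assembly(species_scenario("disk", n_benchmark_genes = 3, seed = 4))
  dir <- withr::local_tempdir()
  write_assembly(asm, dir)
  fa <- read_fasta(file.path(dir, "disk_transcripts.fasta"), type = "DNA")
  expect_equal(fa$seq, asm$transcripts$seq)
  truth <- utils::read.delim(file.path(dir, "disk_truth.tsv"))
  expect_equal(truth$gene_id, asm$truth$gene_id)
})
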