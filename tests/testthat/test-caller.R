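test_that("read-level search attributes fragments and refuses short reads", {
  asm <- generate_assembly(species_scenario("s", n_benchmark_genes = 3, seed = 51))
  cen_tx <- asm$transcripts[asm$transcripts$locus_id == "CenH3", ]
  h3_tx <- asm$transcripts[asm$transcripts$locus_id %in% c("H3", "H3.3"), ]

  cen_reads <- shred_reads(cen_tx, read_length = 100, reads_per_transcript = 15, seed = 1)
  res_cen <- read_level_search(cen_reads)
  expect_gt(res_cen$n_cenh3_specific, 0)

  h3_reads <- shred_reads(h3_tx, read_length = 100, reads_per_transcript = 15, seed = 2)
  res_h3 <- read_level_search(h3_reads)
  expect_equal(res_h3$n_cenh3_specific, 0)
  expect_gt(res_h3$n_h3_attributable, 0)

  short <- shred_reads(cen_tx, read_length = 50, reads_per_transcript = 5, seed = 3)
  expect_error(read_level_search(short), "insufficient read length",
               class = "cenh3scan_short_reads")
})

test_that("presence calls integrate candidates, gate and contamination", {
  cfg <- pipeline_config(seed = 2)
  # planted CenH3, complete assembly -> present
  asm_p <- generate_assembly(species_scenario("pos", n_benchmark_genes = 8, seed = 61))
  call_p <- call_presence(asm_p, config = cfg, control_fractions = c(1, 1))
  expect_equal(call_p$status, "present")
  expect_gte(call_p$n_candidates, 1)

  # no CenH3, complete, controls available -> absent
  asm_a <- generate_assembly(species_scenario("neg", n_benchmark_genes = 8,
                                              cenh3_present = FALSE, seed = 62))
  call_a <- call_presence(asm_a, config = cfg, control_fractions = c(1, 1))
  expect_equal(call_a$status, "absent")
  expect_true(call_a$gate_passed)

  # no CenH3 and a gutted assembly -> the gate forces inconclusive
  asm_i <- generate_assembly(species_scenario("bad", n_benchmark_genes = 8,
                                              cenh3_present = FALSE,
                                              dropout_prob = 0.9, seed = 63))
  call_i <- call_presence(asm_i, config = cfg, control_fractions = c(1, 1))
  expect_equal(call_i$status, "inconclusive")

  # contaminant-only CenH3 -> absent, with contamination evidence attached
  asm_c <- generate_assembly(species_scenario("contam", n_benchmark_genes = 8,
                                              cenh3_present = FALSE,
                                              contaminant_present = TRUE,
                                              contaminant_divergence = 0.5,
                                              seed = 64))
  call_c <- call_presence(asm_c, config = cfg, control_fractions = c(1, 1))
  expect_equal(call_c$status, "absent")
  expect_equal(call_c$n_contaminant, 1)
  expect_match(call_c$notes, "contamination")
  ev <- attr(call_c, "evidence")
  expect_equal(ev$placement$verdict, "contaminant")
})

test_that("missing positive controls force inconclusive on empty assemblies", {
  asm <- generate_assembly(species_scenario("neg", n_benchmark_genes = 6,
                                            cenh3_present = FALSE, seed = 65))
  call <- call_presence(asm, control_fractions = NULL)
  expect_equal(call$status, "inconclusive")
  expect_match(call$notes, "positive controls")
})

test_that("a small survey reproduces the generator truth matrix", {
  scens <- lapply(1:6, function(i) {
    species_scenario(sprintf("sp%02d", i), n_benchmark_genes = 8,
                     cenh3_present = i <= 3, seed = 700 + i)
  })
  sv <- run_survey(scens, config = pipeline_config(seed = 3), n_controls = 2)
  truth <- sv$truth
  expected <- ifelse(truth$cenh3_emitted, "present", "absent")
  expect_equal(sv$calls$status, expected)
  expect_equal(glance(sv)$accuracy, 1)
  expect_equal(glance(sv)$n_false_absent, 0)
  # determinism: identical configuration, identical output
  sv2 <- run_survey(scens, config = pipeline_config(seed = 3), n_controls = 2)
  expect_identical(sv$calls, sv2$calls)
  # tidy/autoplot interfaces
  expect_s3_class(tidy(sv), "tbl_df")
  expect_s3_class(autoplot(sv), "ggplot")
})

test_that("an empty species list gives an empty matrix", {
  sv <- run_survey(list())
  expect_equal(nrow(sv$calls), 0)
})

test_that("survey outputs serialise to TSV", {
  scens <- list(species_scenario("solo", n_benchmark_genes = 5, seed = 81))
  sv <- run_survey(scens, config = pipeline_config(seed = 4), n_controls = 1)
  dir <- withr::local_tempdir()
  write_survey(sv, dir)
  mat <- utils::read.delim(file.path(dir, "presence_matrix.tsv"))
  expect_equal(mat$species_id, "solo")
  expect_true(mat$status %in% c("present", "absent", "inconclusive"))
})
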