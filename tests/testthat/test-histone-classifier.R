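ref <- h3_reference()

test_that("reference sequences classify as themselves", {
  expect_equal(classify_variant(ref$seq)$label, "H3")
  h33 <- cenh3scan:::h33_sequence()
  expect_equal(classify_variant(h33)$label, "H3.3")
  call <- classify_variant(ref$seq)
  expect_equal(call$loop1_extension, 0L)
  expect_equal(call$fold_identity, 100)
  expect_true(all(c(call$state_68, call$state_84, call$state_118) == "canonical"))
})

test_that("generated CenH3 variants are always called CenH3", {
  for (s in c(1, 12, 123)) {
    cen <- make_cenh3_like(n_loop1_insert = 2, seed = s)
    expect_equal(classify_variant(cen)$label, "CenH3")
  }
  host <- cenh3scan:::cenh3_references()$host_ancestor
  expect_equal(classify_variant(host)$label, "CenH3")
  fungal <- cenh3scan:::cenh3_references()$fungal_donor
  expect_equal(classify_variant(fungal)$label, "CenH3")
})

test_that("degraded H3-derived variants are H3-like, never CenH3", {
  for (s in 1:5) {
    set.seed(s)
    d <- cenh3scan:::derive_degraded_h3()
    lab <- classify_variant(d)$label
    expect_equal(lab, "H3-like")
  }
})

test_that("single-site and truncation edge cases are read correctly", {
  aa <- strsplit(ref$seq, "")[[1]]
  aa[118] <- "A"
  aln <- align_global(paste(aa, collapse = ""), ref$seq, type = "overlap")
  expect_equal(unname(diagnostic_residue_states(aln, ref)),
               c("canonical", "canonical", "substituted"))
  # truncated before loop1: unaligned signal, not zero
  aln_tr <- align_global(substr(ref$seq, 1, 70), ref$seq, type = "overlap")
  expect_true(is.na(measure_loop1_extension(aln_tr, ref)))
  # H3 against itself has no loop1 extension
  expect_equal(measure_loop1_extension(align_global(ref$seq, ref$seq), ref), 0L)
})

test_that("candidate discovery recovers exactly the histone repertoire", {
  asm <- generate_assembly(species_scenario("s", n_benchmark_genes = 4, seed = 31))
  cands <- find_h3_candidates(asm)
  expect_setequal(cands$transcript_id, c("H3.i1", "H3.3.i1", "CenH3.i1"))
  # an assembly without histones yields no candidates
  set.seed(2)
  decoys <- toy_assembly(stats::setNames(
    replicate(5, random_aa_string(150, alphabet = cenh3scan:::AA20)),
    paste0("d", 1:5)
  ))
  expect_equal(nrow(find_h3_candidates(decoys)), 0)
})

test_that("stop-interrupted CenH3 transcripts are flagged and never CenH3", {
  cen <- make_cenh3_like(n_loop1_insert = 2, seed = 9)
  nt <- back_translate(cen, seed = 1)
  # plant a stop codon in the middle of the fold (candidate position ~100)
  substr(nt, 301, 303) <- "TAA"
  asm <- tibble::tibble(id = "cen_stop", seq = nt)
  calls <- classify_assembly(asm)
  expect_equal(nrow(calls), 1)
  expect_match(calls$notes, "nonfunctional")
  expect_false(calls$label == "CenH3")
})

test_that("loop1 insertions never turn an H3 into H3.3", {
  for (k in 1:3) {
    s <- paste0(substr(ref$seq, 1, 82), strrep("G", k), substr(ref$seq, 83, 135))
    expect_false(classify_variant(s)$label %in% c("H3.3", "H3"))
  }
})

test_that("every candidate receives exactly one label", {
  asm <- generate_assembly(species_scenario("s", n_benchmark_genes = 3,
                                            contaminant_present = TRUE,
                                            degraded_h3_present = TRUE,
                                            seed = 41))
  calls <- classify_assembly(asm)
  expect_true(all(calls$label %in% c("H3", "H3.3", "CenH3", "H3-like", "non-histone")))
  expect_equal(anyDuplicated(calls$candidate_id), 0)
})
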