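test_that("six-frame translation follows the standard code and keeps stops", {
  expect_equal(unname(translate_six_frames("ATGGCC")[["+1"]]), "MA")
  expect_equal(unname(translate_six_frames("ATGTAAGCC")[["+1"]]), "M*A")
  # codons containing N become X, not dropped
  expect_equal(unname(translate_six_frames("ATGNCC")[["+1"]]), "MX")
  expect_error(translate_six_frames("AT"), "length >= 3")
})

test_that("forward frames of the reverse complement equal reverse frames", {
  set.seed(11)
  for (len in c(300, 301, 302)) {
    s <- random_aa_string(len)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(translate_six_frames(rc)[["+1"]], translate_six_frames(s)[["-1"]])
    expect_equal(translate_six_frames(rc)[["-1"]], translate_six_frames(s)[["+1"]])
  }
})

test_that("all six frames match an independent translator (seqinr)", {
  skip_if_not_installed("seqinr")
  set.seed(7)
  s <- random_aa_string(300)
  fr <- translate_six_frames(s)
  sc <- strsplit(s, "")[[1]]
  for (f in 0:2) {
    expect_equal(unname(fr[[paste0("+", f + 1)]]),
                 paste(seqinr::translate(sc, frame = f, sens = "F"), collapse = ""))
    expect_equal(unname(fr[[as.character(-(f + 1))]]),
                 paste(seqinr::translate(sc, frame = f, sens = "R"), collapse = ""))
  }
})

test_that("global alignment is exact: self-identity, symmetry, errors", {
  x <- "MKVLAEQRKDFW"
  expect_equal(align_global(x, x)$pident, 100)
  set.seed(3)
  a <- random_aa_string(20, alphabet = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  b <- random_aa_string(15, alphabet = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  expect_equal(align_global(a, b)$score, align_global(b, a)$score)
  expect_error(align_global("", "A"), "non-empty")
})

test_that("alignment column map is strictly increasing outside gaps", {
  aln <- align_global("MKKACDEFGHIK", "ACDEFGHI", type = "overlap")
  map <- alignment_map(aln)
  expect_true(all(diff(stats::na.omit(map$q_pos)) > 0))
  expect_true(all(diff(stats::na.omit(map$s_pos)) > 0))
  expect_equal(nrow(map), nchar(aln$q_aln))
})

test_that("global score equals exhaustive path enumeration on short pairs", {
  set.seed(42)
  for (rep in 1:25) {
    la <- sample(1:5, 1); lb <- sample(1:5, 1)
    a <- random_aa_string(la); b <- random_aa_string(lb)
    expect_equal(align_global(a, b)$score,
                 enumerate_align_score(a, b, blosum62_raw),
                 info = paste(a, b))
  }
})

test_that("translated search finds planted sequences and rejects noise", {
  set.seed(5)
  prot <- random_aa_string(120, alphabet = cenh3scan:::AA20)
  decoys <- stats::setNames(
    replicate(20, random_aa_string(120, alphabet = cenh3scan:::AA20)),
    paste0("decoy", 1:20)
  )
  tx <- toy_assembly(c(stats::setNames(prot, "planted"), decoys))
  hits <- search_protein_vs_transcripts(prot, tx)
  expect_equal(hits$subject, "planted")
  expect_equal(hits$pident, 100)
  # hits come back sorted by E-value and at most one per transcript
  expect_false(any(duplicated(hits$subject)))

  # planted homolog at ~60% identity among decoys: exactly one significant hit
  aa <- strsplit(prot, "")[[1]]
  mut <- sample(length(aa), round(0.4 * length(aa)))
  for (i in mut) aa[i] <- sample(setdiff(cenh3scan:::AA20, aa[i]), 1)
  homolog <- paste(aa, collapse = "")
  hits2 <- search_protein_vs_transcripts(homolog, tx)
  expect_equal(hits2$subject, "planted")

  # a query with no common composition yields nothing at 1e-10
  hits3 <- search_protein_vs_transcripts(strrep("W", 50), tx)
  expect_equal(nrow(hits3), 0)
})

test_that("hits are invariant to reverse-complementing a transcript", {
  set.seed(9)
  prot <- random_aa_string(90, alphabet = cenh3scan:::AA20)
  tx <- toy_assembly(stats::setNames(prot, "fwd"))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx$seq[1])))
  tx_rc <- tibble::tibble(id = "rev", seq = rc)
  h1 <- search_protein_vs_transcripts(prot, tx)
  h2 <- search_protein_vs_transcripts(prot, tx_rc)
  expect_equal(h1$score, h2$score)
  expect_equal(h1$frame, -h2$frame)
})

test_that("E-values decrease in score, scale with database size, and error on bad input", {
  e1 <- evalue_of(100, 135, 3e4)
  expect_lt(e1, evalue_of(50, 135, 3e4))
  expect_equal(evalue_of(100, 135, 6e4) / e1, 2)
  expect_error(evalue_of(10, 0, 100), "positive")
  expect_error(evalue_of(10, 100, -1), "positive")
})

test_that("calibrated E-values are honest on null searches", {
  # 100 random searches: the mean number of hits with E < 1 should be
  # about 1 per search (within a factor of 3)
  set.seed(21)
  n_hits <- vapply(1:100, function(i) {
    q <- random_aa_string(100, alphabet = cenh3scan:::AA20)
    tx <- tibble::tibble(
      id = paste0("t", 1:10),
      seq = replicate(10, random_aa_string(300))
    )
    nrow(search_protein_vs_transcripts(q, tx, sig_threshold = 1))
  }, numeric(1))
  expect_gt(mean(n_hits), 1 / 3)
  expect_lt(mean(n_hits), 3)
})
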