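test_that("profile construction matches hand-computed frequencies", {
  aln <- c(a = "AR", b = "AR", c = "AN", d = "AR", e = "AN")
  p <- build_profile(aln, pseudocount = 1)
  # column 1: A in 5/5; freq = (5 + 1/20) / 6; background 1/20
  expect_equal(unname(p["A", 1]), log2(((5 + 0.05) / 6) / 0.05))
  # column 2: R 3/5, N 2/5
  expect_equal(unname(p["R", 2]), log2(((3 + 0.05) / 6) / 0.05))
  expect_equal(unname(p["N", 2]), log2(((2 + 0.05) / 6) / 0.05))
  expect_equal(attr(p, "consensus"), "AR")
  expect_error(build_profile(c(a = "AR", b = "ARN", c = "AR")), "ragged")
  expect_error(build_profile(c(a = "AR", b = "AR")), ">= 3")
})

test_that("degenerate profiles behave at the limits", {
  # one repeated sequence, zero pseudocount: unit probability per column
  p0 <- build_profile(c(a = "MKW", b = "MKW", c = "MKW"), pseudocount = 0)
  expect_equal(unname(p0["M", 1]), log2(20))
  expect_equal(sum(p0[, 1] > -Inf), 1)
  # huge pseudocount washes everything to 0 bits
  set.seed(3)
  aln <- stats::setNames(replicate(6, random_aa_string(10, cenh3scan:::AA20)),
                         letters[1:6])
  pbig <- build_profile(aln, pseudocount = 1e6)
  expect_true(all(abs(pbig) < 0.01))
})

test_that("the consensus outscores any single-substitution variant", {
  p <- cenpc_motif_profile()
  cons <- attr(p, "consensus")
  s_cons <- max(cenh3scan:::pssm_window_scores(p, cons))
  set.seed(5)
  for (i in sample(nchar(cons), 6)) {
    aa <- strsplit(cons, "")[[1]]
    aa[i] <- sample(setdiff(cenh3scan:::AA20, aa[i]), 1)
    expect_lte(max(cenh3scan:::pssm_window_scores(p, paste(aa, collapse = ""))),
               s_cons)
  }
})

test_that("scanning finds planted motifs at the right offset with small p", {
  p <- cenpc_motif_profile()
  cons <- attr(p, "consensus")
  set.seed(11)
  host <- random_aa_string(150, cenh3scan:::AA20)
  planted <- paste0(substr(host, 1, 60), cons, substr(host, 61, 150))
  hit <- scan_profile(p, planted, n_null = 199, seed = 1)
  expect_equal(hit$offset, 60)
  expect_lte(hit$pvalue, 0.01)
  expect_error(scan_profile(p, "MKV"), "shorter")

  # among decoys, the planted protein has the smallest p-value
  prots <- c(stats::setNames(planted, "planted"),
             stats::setNames(replicate(10, random_aa_string(170, cenh3scan:::AA20)),
                             paste0("d", 1:10)))
  res <- scan_proteome(p, prots, n_null = 199, seed = 2)
  expect_equal(res$protein_id[1], "planted")
})

test_that("permutation p-values are honest under the null", {
  p <- cenpc_motif_profile()
  set.seed(13)
  pv <- vapply(1:30, function(i) {
    scan_profile(p, random_aa_string(120, cenh3scan:::AA20),
                 n_null = 99, seed = i)$pvalue
  }, numeric(1))
  expect_gt(mean(pv), 0.25)  # roughly uniform, certainly not enriched
  expect_true(all(pv > 0 & pv <= 1))
})

test_that("profiles round-trip through the text serialisation", {
  p <- cupin_profile()
  f <- withr::local_tempfile(fileext = ".pssm")
  write_profile(p, f)
  q <- read_profile(f)
  expect_equal(unclass(p), unclass(q), ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(attr(q, "name"), "cupin")
})

test_that("architecture calls combine motif, cupin and the clade test", {
  motif <- cenpc_motif_profile(); cupin <- cupin_profile()
  cons_m <- attr(motif, "consensus"); cons_c <- attr(cupin, "consensus")
  set.seed(17)
  pad <- function(...) paste0(...)
  both <- pad(random_aa_string(40, cenh3scan:::AA20), cons_m,
              random_aa_string(30, cenh3scan:::AA20), cons_c)
  cupin_only <- pad(random_aa_string(40, cenh3scan:::AA20),
                    paste(sample(strsplit(cons_m, "")[[1]]), collapse = ""),
                    random_aa_string(30, cenh3scan:::AA20), cons_c)
  neither <- random_aa_string(150, cenh3scan:::AA20)

  hit <- function(seq) list(
    m = scan_profile(motif, seq, n_null = 999, seed = 3),
    c = scan_profile(cupin, seq, n_null = 999, seed = 4)
  )
  h1 <- hit(both)
  win1 <- substr(both, h1$c$offset + 1, h1$c$offset + ncol(cupin))
  v1 <- cupin_clade_verdict(win1, seed = 5)
  expect_equal(call_cenpc_architecture(h1$m, h1$c, v1), "motif+cupin")

  h2 <- hit(cupin_only)
  win2 <- substr(cupin_only, h2$c$offset + 1, h2$c$offset + ncol(cupin))
  v2 <- cupin_clade_verdict(win2, seed = 6)
  expect_equal(v2$verdict, "host")  # CenpC-type cupin clade
  expect_equal(call_cenpc_architecture(h2$m, h2$c, v2), "cupin-only")

  h3 <- hit(neither)
  expect_equal(call_cenpc_architecture(h3$m, h3$c), "none")

  # a cupin that clusters with non-CenpC cupins does not count
  other <- cupin_panel()$contaminant_refs[[1]]
  seq_other <- pad(random_aa_string(40, cenh3scan:::AA20), other)
  h4 <- hit(seq_other)
  if (h4$c$pvalue <= 1e-3) {
    win4 <- substr(seq_other, h4$c$offset + 1, h4$c$offset + ncol(cupin))
    v4 <- cupin_clade_verdict(win4, seed = 7)
    expect_false(call_cenpc_architecture(h4$m, h4$c, v4) %in%
                   c("cupin-only", "motif+cupin"))
  }
})
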