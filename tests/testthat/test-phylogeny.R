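ref <- h3_reference()

test_that("fold-domain extraction respects coordinates and loop1 exclusion", {
  fold <- extract_fold_domain(ref$seq, exclude_loop1 = FALSE)
  expect_equal(fold, substr(ref$seq, ref$fold_start, ref$fold_end))
  no_loop <- extract_fold_domain(ref$seq, exclude_loop1 = TRUE)
  loop_len <- ref$loop1_end - ref$loop1_start + 1
  expect_equal(nchar(no_loop), nchar(fold) - loop_len)

  # generated CenH3 with a 3-residue insert: excluding loop1 removes the
  # window and the insert; including it keeps both
  cen <- make_cenh3_like(n_loop1_insert = 3, seed = 2)
  with_ins <- extract_fold_domain(cen, exclude_loop1 = FALSE)
  without <- extract_fold_domain(cen, exclude_loop1 = TRUE)
  expect_equal(nchar(without), nchar(fold) - loop_len)
  expect_equal(nchar(with_ins) - nchar(without), loop_len + 3)
  expect_error(extract_fold_domain(strrep("W", 40)), "histone fold")
})

test_that("neighbor joining recovers a known 4-taxon topology", {
  # 60 columns: sites 1-20 unite (a,b), 21-40 unite (c,d)
  col <- function(pair1, pair2) c(a = pair1, b = pair1, c = pair2, d = pair2)
  m <- cbind(
    matrix(rep(col("A", "C"), 20), nrow = 4),
    matrix(rep(col("G", "T"), 20), nrow = 4),
    matrix(rep(c(a = "A", b = "C", c = "G", d = "T"), 20), nrow = 4)
  )
  rownames(m) <- letters[1:4]
  tr <- build_tree(m, n_bootstrap = 50, seed = 1)
  # the ab|cd split must be present
  pp <- ape::prop.part(tr$tree)
  labs <- attr(pp, "labels")
  sides <- lapply(pp, function(ix) sort(labs[ix]))
  expect_true(any(vapply(sides, function(s)
    identical(s, c("a", "b")) || identical(s, c("c", "d")), logical(1))))
  expect_error(build_tree(m[1:3, ]), "at least 4")
})

test_that("duplicate sequences form a zero-length cherry", {
  m <- rbind(a = strsplit(strrep("ARND", 10), "")[[1]],
             b = strsplit(strrep("ARND", 10), "")[[1]],
             c = strsplit(strrep("GHIL", 10), "")[[1]],
             d = strsplit(strrep("WYVK", 10), "")[[1]])
  tr <- build_tree(m, n_bootstrap = 10, seed = 1)$tree
  i <- which(tr$tip.label == "a"); j <- which(tr$tip.label == "b")
  dmat <- ape::cophenetic.phylo(tr)
  expect_lt(dmat["a", "b"], 1e-9)
})

test_that("placement attributes true lineage members with strong support", {
  panel <- reference_panel()
  # an exact copy of a contaminant reference is attributed to contamination
  v <- place_candidate(panel$contaminant_refs[[1]], "copy", seed = 4)
  expect_equal(v$verdict, "contaminant")
  expect_gte(v$support, 95)
  # a freshly derived host CenH3 goes to the host clade
  set.seed(8)
  host <- cenh3scan:::derive_host_cenh3()
  vh <- place_candidate(host, "host_cand", seed = 5)
  expect_equal(vh$verdict, "host")
  expect_gte(vh$support, 70)
  expect_error(placement_verdict(build_tree(
    fold_alignment(c(panel$host_refs, panel$outgroup)), 10, 1), "ghost", panel),
    "not in tree")
})

test_that("H3-proximal variants are left unresolved, not attributed", {
  # an H3-derived variant (the pea-aphid-like case) clusters with the
  # outgroup and must not be assigned to either lineage
  set.seed(19)
  nearby <- cenh3scan:::mutate_protein(ref$seq, 0.15)
  v <- place_candidate(nearby, "h3_variant", seed = 6)
  expect_equal(v$verdict, "unresolved")
})

test_that("verdicts are invariant to sequence order and panel label swaps", {
  panel <- reference_panel()
  cand <- panel$contaminant_refs[[2]]
  seqs <- c(cand = cand, panel$host_refs, panel$contaminant_refs, panel$outgroup)
  aln <- fold_alignment(seqs)
  t1 <- build_tree(aln, n_bootstrap = 60, seed = 9)
  v1 <- placement_verdict(t1, "cand", panel)
  perm <- aln[rev(seq_len(nrow(aln))), ]
  t2 <- build_tree(perm, n_bootstrap = 60, seed = 9)
  v2 <- placement_verdict(t2, "cand", panel)
  expect_equal(v1$verdict, v2$verdict)
  # relabelling within a panel does not change the verdict class
  panel2 <- panel
  names(panel2$contaminant_refs) <- rev(names(panel2$contaminant_refs))
  seqs2 <- c(cand = cand, panel2$host_refs, panel2$contaminant_refs, panel2$outgroup)
  v3 <- placement_verdict(build_tree(fold_alignment(seqs2), 60, 9), "cand", panel2)
  expect_equal(v1$verdict, v3$verdict)
})

test_that("trees serialise to newick", {
  panel <- reference_panel()
  tr <- build_tree(fold_alignment(c(panel$host_refs, panel$outgroup)), 10, 1)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tr$tree$tip.label)
})
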