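# Regenerates the bundled synthetic CenpC fixtures under inst/extdata.
# These sequences are synthetic: they mimic the conservation structure of
# the CenpC-motif and cupin-domain families (a short strongly conserved
# motif; equal-length cupin domains falling into distinct subfamilies)
# without being curated biological sequences.  Deterministic; run from the
# repository root with: Rscript tools/make_synthetic_fixtures.R

aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

mutate_seq <- function(seq, rate) {
  aa <- strsplit(seq, "")[[1]]
  hit <- runif(length(aa)) < 1 - exp(-rate)
  for (i in which(hit)) aa[i] <- sample(setdiff(aa20, aa[i]), 1L)
  paste(aa, collapse = "")
}

write_fa <- function(seqs, path) {
  con <- file(path, "w")
  for (n in names(seqs)) {
    writeLines(paste0(">", n), con)
    writeLines(substring(seqs[[n]], seq(1, nchar(seqs[[n]]), 60),
                         pmin(seq(1, nchar(seqs[[n]]), 60) + 59, nchar(seqs[[n]]))), con)
  }
  close(con)
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
set.seed(20260921)

# CenpC-motif seed alignment: 24 columns, 6 sequences, mild variation
motif_consensus <- "WTRRVSEFLEDPQVRGNIKWHEDG"
motif_seed <- setNames(
  c(motif_consensus,
    vapply(1:5, function(i) mutate_seq(motif_consensus, 0.12), "")),
  paste0("cenpc_motif_seed_", 1:6)
)
write_fa(motif_seed, "inst/extdata/synthetic_cenpc_motif_seed.fasta")

# Cupin domain: 100 columns; three subfamilies as sister clades with
# positive stem lengths (each subfamily ancestor diverges from a common
# deep ancestor), so distance-based placement of a subfamily member is
# stable.
cupin_deep <- paste(sample(aa20, 100, replace = TRUE), collapse = "")
cupin_cenpc <- mutate_seq(cupin_deep, 0.35)
cupin_other <- mutate_seq(cupin_deep, 0.35)
cupin_out <- mutate_seq(cupin_deep, 0.8)

cupin_seed <- setNames(
  c(cupin_cenpc, vapply(1:5, function(i) mutate_seq(cupin_cenpc, 0.07), "")),
  paste0("cupin_seed_", 1:6)
)
write_fa(cupin_seed, "inst/extdata/synthetic_cupin_seed.fasta")

panel <- c(
  setNames(vapply(1:4, function(i) mutate_seq(cupin_cenpc, 0.07), ""),
           paste0("cenpc_cupin_", 1:4)),
  setNames(vapply(1:4, function(i) mutate_seq(cupin_other, 0.07), ""),
           paste0("other_cupin_", 1:4)),
  setNames(vapply(1:3, function(i) mutate_seq(cupin_out, 0.07), ""),
           paste0("outgroup_cupin_", 1:3))
)
write_fa(panel, "inst/extdata/synthetic_cupin_panel.fasta")

cat("fixtures written to inst/extdata\n")
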