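# Independent oracles and small fixture builders shared across tests.

# Exhaustive enumeration of all global alignments with affine gaps
# (gap of length k costs open + k * ext; end gaps penalised), tracking the
# previous move so gap opening is charged correctly.  Deliberately
# recursive path enumeration, not dynamic programming.
enumerate_align_score <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      best <- max(best, mat[A[i], B[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(A)) {
      cost <- if (prev == "D") ext else open + ext
      best <- max(best, -cost + rec(i + 1L, j, "D"))
    }
    if (j <= length(B)) {
      cost <- if (prev == "I") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1L, "I"))
    }
    best
  }
  rec(1L, 1L, "S")
}

# Independent Gotoh three-state dynamic program (global, affine, end gaps
# penalised) - second oracle for lengths where path enumeration is
# impractical.
gotoh_align_score <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, m + 1, n + 1)
  M[1, 1] <- 0
  for (i in 2:(m + 1)) Ix[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(n + 1)) Iy[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- s + max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[m + 1, n + 1], Ix[m + 1, n + 1], Iy[m + 1, n + 1])
}

random_aa_string <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

blosum62_raw <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# tiny assembly with known content
toy_assembly <- function(proteins, seed = 1) {
  tibble::tibble(
    id = names(proteins),
    locus_id = names(proteins),
    isoform_id = "i1",
    seq = vapply(seq_along(proteins), function(i) {
      back_translate(proteins[[i]], seed = seed + i)
    }, "")
  )
}
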