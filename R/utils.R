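# Internal helpers shared across modules.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  All seeded operations in the package go
# through this so that user-level RNG state is never clobbered.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct 31-bit child seed from a parent seed and a stream tag.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 1103L + h * 12979L) %% 2147483629)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

random_protein <- function(length) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

# Substitute residues i.i.d. at an expected per-site rate (substitutions per
# site); multiple hits collapse via 1 - exp(-rate).  Length-preserving.
mutate_protein <- function(seq, rate) {
  stopifnot(rate >= 0)
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  p_hit <- 1 - exp(-rate)
  hit <- runif(length(aa)) < p_hit
  if (any(hit)) {
    aa[hit] <- vapply(aa[hit], function(a) sample(setdiff(AA20, a), 1L), "")
  }
  paste(aa, collapse = "")
}

#' Read or write FASTA files as tibbles
#'
#' Thin wrappers around the Biostrings FASTA readers/writers that move
#' between on-disk FASTA and the two-column tibbles (`id`, `seq`) the rest
#' of the package works with.  Identifiers are truncated at the first
#' whitespace on read; sequences are wrapped at 60 characters on write.
#'
#' @param path File path.
#' @param type `"DNA"` or `"AA"`.
#' @param x A data frame with columns `id` and `seq`, or a named character
#'   vector of sequences.
#' @return `read_fasta()` returns a tibble with columns `id` and `seq`;
#'   `write_fasta()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' write_fasta(c(tx1 = "ATGGCC"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- switch(type,
    DNA = Biostrings::readDNAStringSet(path),
    AA  = Biostrings::readAAStringSet(path)
  )
  ids <- sub("\\s.*$", "", names(set))
  tibble::tibble(id = ids, seq = unname(as.character(set)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (is.data.frame(x)) {
    seqs <- stats::setNames(x$seq, x$id)
  } else {
    seqs <- x
  }
  set <- switch(type,
    DNA = Biostrings::DNAStringSet(seqs),
    AA  = Biostrings::AAStringSet(seqs)
  )
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
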