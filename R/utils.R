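`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement character sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that keeps
#' plain character vectors as the working currency of the package.
#'
#' @param x Character vector of DNA sequences (IUPAC letters allowed).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute k random positions of a sequence with a different base.
mutate_seq <- function(seq, positions = NULL, k = length(positions)) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (is.null(positions)) positions <- sample(length(chars), k)
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b, USE.NAMES = FALSE)
}

# Parse "chrom:pos" locus identifiers.
locus_id <- function(chrom, pos) paste0(chrom, ":", pos)

split_locus_id <- function(id) {
  parts <- regmatches(id, regexpr(":[0-9]+$", id))
  data.frame(chrom = sub(":[0-9]+$", "", id),
             pos = as.integer(sub(":", "", parts)),
             stringsAsFactors = FALSE)
}

signif3 <- function(x) signif(x, 3)

as_dnastringset <- function(reference) {
  if (inherits(reference, "me_reference")) return(reference$sequences)
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (is.character(reference)) {
    out <- Biostrings::DNAStringSet(reference)
    if (is.null(names(out))) names(out) <- paste0("chr", seq_along(out))
    return(out)
  }
  stop("cannot interpret 'reference' as a set of chromosome sequences")
}
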