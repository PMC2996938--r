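#' Primer and adapter oligonucleotides of the assay
#'
#' The assay reads the junctions of a target retrotransposon subfamily with a
#' subfamily-specific sequencing primer, after enriching fragment libraries
#' with a subfamily-specific biotinylated amplification primer. These
#' accessors expose the oligonucleotide sequences used throughout the
#' package: by the library simulator (which plants their binding sites inside
#' synthetic elements), by the read quality screen (adapter contamination),
#' and by the primer-binding-site scanner.
#'
#' `me_amp_primer()` is the element-specific 3' 20 nt of the amplification
#' primer ALUBP2; `me_seq_primer()` is the sequencing primer ALUSPv2;
#' `me_motif()` is the element sequence expected at the start of every
#' junction read (the printed motif is 15 nt even though a junction read
#' carries 16 nt of element sequence; the 16th base is not part of the
#' screened motif).
#'
#' @return A character string (or named character vector for
#'   `oligo_screen_set()`).
#' @name oligos
NULL

#' @rdname oligos
#' @export
me_seq_primer <- function() "CCCAAAGTGCTGGGATTACAGGCGTGA"

#' @rdname oligos
#' @export
me_amp_primer <- function() "GCCCAGGCCGGACTGCGGAC"

#' @rdname oligos
#' @export
me_motif <- function() "GCCACCGCGCCCGGC"

#' Oligonucleotide set screened for adapter contamination
#'
#' Reads are screened against the library-construction oligonucleotides and
#' their reverse complements. The element-specific 3' 20 nt of the
#' amplification primer is excluded from screening, because genuine junction
#' reads legitimately contain element sequence; only the universal
#' (adapter-derived) segments are treated as contamination.
#'
#' @return Named character vector of sequences to screen (reverse complements
#'   included).
#' @export
oligo_screen_set <- function() {
  fwd <- c(
    CPEA1Xa = "CTCGGCATTCCTGCTGAACCGCTCTTCCGATCT",
    ALUBP2_universal = "ACACTCTTTCCCTACACGACGCTCTTCCGATCT",
    PEP2 = "CAAGCAGAAGACGGCATACGAGATCGGTCTCGGCATTCCTGCTGAACCGCTCTTCCGATCT"
  )
  rev <- revcomp(fwd)
  names(rev) <- paste0(names(fwd), "_rc")
  c(fwd, rev)
}

# 16 nt of element sequence read at the start of every junction read:
# the printed motif plus the 16th base of the element 5' end.
junction_prefix <- function() paste0(me_motif(), "C")

# Fixed body filler of the synthetic element consensus. Arbitrary but
# constant, so that references built from the same parameters are identical.
element_body <- local({
  body <- NULL
  function() {
    if (is.null(body)) {
      body <<- with_seed(101L, list(a = random_dna(197), b = random_dna(30)))
    }
    body
  }
})

#' Synthetic target element consensus
#'
#' Builds the consensus sequence of the simulated target subfamily. Reading
#' the element 5' to 3' it contains, at fixed offsets: the reverse complement
#' of the 16 nt junction prefix (positions 1-16, so that junction reads start
#' with the expected element motif), the sequencing primer binding site
#' (positions 17-43), a fixed filler body, the amplification primer binding
#' site (positions 241-260, placing the two binding-site starts 224 bp apart
#' on the forward reference strand for a plus-strand element), a short 3'
#' segment, and a poly-A tail. Both primers bind the reference minus strand
#' for a plus-strand element, so that sequencing proceeds across the 5'
#' junction into the upstream genomic flank.
#'
#' @param polya_len Poly-A tail length in nt (affects realism only; junction
#'   geometry is independent of it).
#' @return A character string.
#' @export
element_consensus <- function(polya_len = 20) {
  body <- element_body()
  paste0(
    revcomp(junction_prefix()),     #   1-16
    revcomp(me_seq_primer()),       #  17-43 sequencing PBS
    body$a,                         #  44-240
    revcomp(me_amp_primer()),       # 241-260 amplification PBS
    body$b,                         # 261-290
    strrep("A", polya_len)
  )
}

# Offsets (1-based, within the element) of planted features.
element_layout <- function() {
  list(
    junction = c(1L, 16L),
    seq_pbs = c(17L, 43L),
    seq_pbs_3p10 = c(17L, 26L),   # 3' 10 bp of the minus-strand sequencing PBS
    amp_pbs = c(241L, 260L),
    amp_pbs_3p10 = c(241L, 250L),
    length = 290L
  )
}
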