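#' Build a synthetic reference genome with planted mobile elements
#'
#' Generates random background chromosomes and plants three kinds of
#' features, non-overlapping and with generous flanking margins:
#'
#' * *target* elements: copies of [element_consensus()] carrying perfect
#'   amplification and sequencing primer binding sites (PBS). These emulate
#'   reference insertions of the assayed subfamily.
#' * *decoy* elements: copies of the consensus degraded with substitutions,
#'   including at least one mismatch in the 3' 10 bp of each PBS and
#'   `decoy_motif_divergence` substitutions in the 16 nt junction region.
#'   These emulate the background of older related elements that amplify
#'   only sporadically and must be excluded from the putatively fixed set.
#' * *segmental duplications*: for `n_duplication` randomly chosen target
#'   elements, the `dup_block_len` bp of genomic flank adjacent to the
#'   element's 5' junction is copied (at `dup_identity` identity) to a
#'   distant location. Read pairs from such loci cannot be mapped uniquely,
#'   which is the mechanism behind duplication-driven false negatives.
#'
#' Placement divides each chromosome into equal slots, one per feature, and
#' draws a position inside each slot leaving `margin` bp on either side, so
#' fragment windows never run off a chromosome or into a neighbour.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_target,n_decoy,n_duplication Feature counts.
#' @param n_polymorphic_known Number of target loci to designate as "known
#'   polymorphic" (the exclusion list consulted when selecting putatively
#'   fixed loci, standing in for a catalogue of known polymorphisms).
#' @param seed Integer seed; identical parameters and seed give a
#'   byte-identical reference.
#' @param target_positions Optional data frame (`chrom`, `start`, `strand`)
#'   fixing target element placement exactly (tests and worked examples);
#'   requires `n_decoy = 0` and `n_duplication = 0`.
#' @param polya_len,tsd_len Poly-A tail and target-site-duplication lengths
#'   recorded for realism; junction geometry does not depend on them.
#' @param decoy_motif_divergence Substitutions planted in the junction region
#'   of each decoy. At the default 3 the motif remains detectable (emulating
#'   older but still recognisable elements); at 6 or more it is not, which
#'   exercises the motif-detection failure path.
#' @param dup_block_len,dup_identity Length and identity of duplicated flank
#'   blocks.
#' @param margin Clearance in bp kept around every planted feature.
#' @return An object of class `me_reference`: a list with `sequences`
#'   ([Biostrings::DNAStringSet]), `me_track` (data frame of planted
#'   elements with 1-based closed coordinates, strand, family label, junction
#'   anchor and expected junction-endpoint identifier), `duplicated_blocks`,
#'   `polymorphic_known` (locus identifiers) and `params`.
#' @export
make_reference <- function(chrom_lengths = c(chr1 = 200000L),
                           n_target = 10, n_decoy = 0, n_duplication = 0,
                           n_polymorphic_known = 0,
                           seed = 1,
                           target_positions = NULL,
                           polya_len = 20, tsd_len = 15,
                           decoy_motif_divergence = 3,
                           dup_block_len = 600, dup_identity = 0.995,
                           margin = 800) {
  chrom_lengths <- unlist(chrom_lengths)  # tolerate YAML-style named lists
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (n_duplication > n_target)
    stop("n_duplication must not exceed n_target (each duplicated block is anchored to a target element)")
  if (n_polymorphic_known > n_target)
    stop("n_polymorphic_known must not exceed n_target")
  consensus <- element_consensus(polya_len)
  elem_w <- nchar(consensus)
  layout <- element_layout()

  with_seed(seed, {
    seqs <- vapply(chrom_lengths, random_dna, character(1))

    if (!is.null(target_positions)) {
      if (n_decoy > 0 || n_duplication > 0)
        stop("explicit target_positions require n_decoy = 0 and n_duplication = 0")
      stopifnot(nrow(target_positions) == n_target)
      items <- data.frame(chrom = target_positions$chrom,
                          start = as.integer(target_positions$start),
                          type = "target",
                          strand = target_positions$strand,
                          stringsAsFactors = FALSE)
    } else {
      n_items <- n_target + n_decoy + n_duplication
      if (n_items == 0) {
        items <- data.frame(chrom = character(0), start = integer(0),
                            type = character(0), strand = character(0))
      } else {
        # feature counts per chromosome, proportional to length
        frac <- chrom_lengths / sum(chrom_lengths)
        n_c <- floor(frac * n_items)
        rem <- n_items - sum(n_c)
        if (rem > 0) {
          ord <- order(frac * n_items - n_c, decreasing = TRUE)
          n_c[ord[seq_len(rem)]] <- n_c[ord[seq_len(rem)]] + 1
        }
        need <- max(elem_w, if (n_duplication > 0) dup_block_len else 0L) +
          2 * margin
        types <- sample(rep(c("target", "decoy", "dup_copy"),
                            c(n_target, n_decoy, n_duplication)))
        rows <- list(); k <- 0
        for (ci in seq_along(chrom_lengths)) {
          if (n_c[ci] == 0) next
          w <- chrom_lengths[ci] %/% n_c[ci]
          if (w < need)
            stop(sprintf(paste0("infeasible packing: chromosome %s needs slots of ",
                                ">= %d bp for %d features but can offer only %d bp; ",
                                "reduce feature counts or margin, or lengthen the chromosome"),
                         names(chrom_lengths)[ci], need, n_c[ci], w))
          for (si in seq_len(n_c[ci])) {
            k <- k + 1
            ty <- types[k]
            fw <- if (ty == "dup_copy") dup_block_len else elem_w
            lo <- (si - 1) * w + 1 + margin
            hi <- si * w - margin - fw + 1
            rows[[k]] <- data.frame(chrom = names(chrom_lengths)[ci],
                                    start = as.integer(sample(lo:hi, 1)),
                                    type = ty,
                                    strand = sample(c("+", "-"), 1),
                                    stringsAsFactors = FALSE)
          }
        }
        items <- do.call(rbind, rows)
      }
    }

    elems <- items[items$type != "dup_copy", , drop = FALSE]
    copies <- items[items$type == "dup_copy", , drop = FALSE]

    # plant element sequences
    track <- NULL
    if (nrow(elems) > 0) {
      seq_list <- character(nrow(elems))
      for (i in seq_len(nrow(elems))) {
        es <- if (elems$type[i] == "decoy") {
          decoy_sequence(consensus, layout, decoy_motif_divergence)
        } else consensus
        seq_list[i] <- if (elems$strand[i] == "+") es else revcomp(es)
      }
      end <- elems$start + elem_w - 1L
      bad <- end > chrom_lengths[elems$chrom] | elems$start < 1
      if (any(bad))
        stop("infeasible packing: a planted element extends beyond its chromosome")
      for (i in seq_len(nrow(elems))) {
        substr(seqs[elems$chrom[i]], elems$start[i], end[i]) <- seq_list[i]
      }
      anchor <- ifelse(elems$strand == "+", elems$start - 1L, end)
      endpoint <- ifelse(elems$strand == "+", elems$start - 20L, end + 20L)
      track <- data.frame(
        chrom = elems$chrom, start = elems$start, end = end,
        strand = elems$strand,
        family = ifelse(elems$type == "target", "AluYb-like", "AluS-like"),
        anchor = as.integer(anchor), endpoint = as.integer(endpoint),
        locus_id = locus_id(elems$chrom, endpoint),
        stringsAsFactors = FALSE
      )
    } else {
      track <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          family = character(0), anchor = integer(0),
                          endpoint = integer(0), locus_id = character(0),
                          stringsAsFactors = FALSE)
    }

    # duplicated flank blocks: source = flank adjacent to a target 5' junction
    dup <- data.frame(chrom_src = character(0), src_start = integer(0),
                      src_end = integer(0), chrom_copy = character(0),
                      copy_start = integer(0), copy_end = integer(0),
                      identity = numeric(0), locus_id = character(0),
                      stringsAsFactors = FALSE)
    if (nrow(copies) > 0) {
      tgt <- track[track$family == "AluYb-like", , drop = FALSE]
      linked <- sample(nrow(tgt), nrow(copies))
      n_sub <- max(1L, round((1 - dup_identity) * dup_block_len))
      # divergence between the two copies is confined to the 100 bp of the
      # block adjacent to the element, so the far-flank region that read
      # pairs sample is copied exactly (mapping there is always ambiguous)
      mut_zone_len <- min(100L, dup_block_len)
      if (n_sub > mut_zone_len)
        stop("dup_identity too low: copy divergence does not fit the ",
             "element-adjacent mutation zone")
      rows <- list()
      for (i in seq_len(nrow(copies))) {
        t <- tgt[linked[i], ]
        if (t$strand == "+") {
          ss <- t$start - dup_block_len; se <- t$start - 1L
          zone <- (dup_block_len - mut_zone_len + 1L):dup_block_len
        } else {
          ss <- t$end + 1L; se <- t$end + dup_block_len
          zone <- 1:mut_zone_len
        }
        block <- substr(seqs[t$chrom], ss, se)
        block <- mutate_seq(block, positions = sample(zone, n_sub))
        cs <- copies$start[i]; ce <- cs + dup_block_len - 1L
        substr(seqs[copies$chrom[i]], cs, ce) <- block
        rows[[i]] <- data.frame(chrom_src = t$chrom, src_start = as.integer(ss),
                                src_end = as.integer(se),
                                chrom_copy = copies$chrom[i],
                                copy_start = as.integer(cs),
                                copy_end = as.integer(ce),
                                identity = 1 - n_sub / dup_block_len,
                                locus_id = t$locus_id,
                                stringsAsFactors = FALSE)
      }
      dup <- do.call(rbind, rows)
    }

    poly_known <- character(0)
    if (n_polymorphic_known > 0) {
      ids <- track$locus_id[track$family == "AluYb-like"]
      poly_known <- sort(sample(ids, n_polymorphic_known))
    }

    structure(list(
      sequences = Biostrings::DNAStringSet(seqs),
      me_track = track,
      duplicated_blocks = dup,
      polymorphic_known = poly_known,
      params = list(chrom_lengths = chrom_lengths, n_target = n_target,
                    n_decoy = n_decoy, n_duplication = n_duplication,
                    n_polymorphic_known = n_polymorphic_known, seed = seed,
                    polya_len = polya_len, tsd_len = tsd_len,
                    decoy_motif_divergence = decoy_motif_divergence,
                    dup_block_len = dup_block_len, dup_identity = dup_identity,
                    margin = margin)
    ), class = "me_reference")
  })
}

# Degrade the consensus into an older-family decoy: substitutions in the
# junction region, exactly one in the 3' 10 bp of each PBS, and a few in the
# body. Scores against the primers stay near (but at or above) the scan
# thresholds while the 3'-mismatch rule always disqualifies decoys from the
# putatively fixed set.
decoy_sequence <- function(consensus, layout, motif_divergence) {
  s <- consensus
  if (motif_divergence > 0) {
    pos <- sample(layout$junction[1]:layout$junction[2], motif_divergence)
    s <- mutate_seq(s, positions = pos)
  }
  s <- mutate_seq(s, positions = sample(layout$seq_pbs_3p10[1]:layout$seq_pbs_3p10[2], 1))
  s <- mutate_seq(s, positions = sample(layout$amp_pbs_3p10[1]:layout$amp_pbs_3p10[2], 1))
  body <- setdiff(44:240, layout$amp_pbs[1]:layout$amp_pbs[2])
  mutate_seq(s, positions = sample(body, 5))
}

#' @export
print.me_reference <- function(x, ...) {
  cat("Synthetic reference:", length(x$sequences), "chromosome(s),",
      sum(Biostrings::width(x$sequences)), "bp\n")
  cat("  target elements:    ", sum(x$me_track$family == "AluYb-like"), "\n")
  cat("  decoy elements:     ", sum(x$me_track$family == "AluS-like"), "\n")
  cat("  duplicated blocks:  ", nrow(x$duplicated_blocks), "\n")
  cat("  known polymorphic:  ", length(x$polymorphic_known), "\n")
  invisible(x)
}

#' Write a synthetic reference to FASTA / BED-like track files
#'
#' The element track is written as 6-column BED (0-based half-open
#' coordinates, name = family label).
#'
#' @param ref An `me_reference`.
#' @param fasta,track Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_reference <- function(ref, fasta = NULL, track = NULL) {
  stopifnot(inherits(ref, "me_reference"))
  if (!is.null(fasta)) Biostrings::writeXStringSet(ref$sequences, fasta)
  if (!is.null(track)) {
    bed <- data.frame(chrom = ref$me_track$chrom,
                      start = ref$me_track$start - 1L,
                      end = ref$me_track$end,
                      name = ref$me_track$family,
                      score = 0L,
                      strand = ref$me_track$strand)
    utils::write.table(bed, track, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(fasta = fasta, track = track))
}

#' Read an element annotation track from a BED-like TSV
#'
#' Accepts the 6-column BED written by [write_reference()] (0-based
#' half-open) and returns the 1-based closed representation used internally,
#' with junction anchors and expected endpoint identifiers derived from
#' strand.
#'
#' @param path Path to a 6-column BED-like TSV.
#' @return Data frame in `me_track` layout.
#' @export
read_track_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"),
                           stringsAsFactors = FALSE)
  start <- bed$start + 1L
  anchor <- ifelse(bed$strand == "+", start - 1L, bed$end)
  endpoint <- ifelse(bed$strand == "+", start - 20L, bed$end + 20L)
  data.frame(chrom = bed$chrom, start = start, end = bed$end,
             strand = bed$strand, family = bed$name,
             anchor = as.integer(anchor), endpoint = as.integer(endpoint),
             locus_id = locus_id(bed$chrom, endpoint),
             stringsAsFactors = FALSE)
}
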