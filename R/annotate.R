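#' Scan a reference for primer binding sites
#'
#' Ungapped local alignment of a primer against both strands of every
#' chromosome. Every offset at which the full primer footprint fits is
#' scored (match/mismatch only; the legacy nucleotide scores +1/-3 by
#' default, with gaps forbidden outright) and the best-scoring contiguous
#' segment on that diagonal is reported when it reaches `min_score`. The
#' scan is exhaustive over offsets, which is a superset of word-seeded
#' search and identical to it at any threshold reachable by a
#' `word_size`-length exact seed; `word_size` is accepted for interface
#' compatibility and documentation.
#'
#' For a minus-strand site the primer matches the reverse complement of
#' the plus strand; reported `start`/`end` are always plus-strand 1-based
#' closed footprint coordinates. `mm_3p10` counts mismatches to the primer
#' over its 3'-terminal 10 bases (the extension-critical window);
#' `prim3_pos` is the plus-strand coordinate of the primer's 3' end.
#'
#' @param reference Reference accepted by [toy_map()].
#' @param primer_seq Primer sequence (5' to 3').
#' @param match,mismatch Alignment scores.
#' @param min_score Minimum reported segment score.
#' @param word_size Seed length of the equivalent word-seeded search.
#' @param role Label attached to the sites (`"SEQUENCING"` or
#'   `"AMPLIFICATION"`).
#' @return Data frame: `chrom`, `start`, `end`, `strand`, `score`,
#'   `seg_from`, `seg_to` (the scoring segment), `mm_3p10`, `mm_total`,
#'   `prim3_pos`, `role`.
#' @export
scan_pbs <- function(reference, primer_seq, match = 1, mismatch = -3,
                     min_score = 16, word_size = 7,
                     role = c("SEQUENCING", "AMPLIFICATION")) {
  role <- match.arg(role)
  if (nchar(primer_seq) < word_size)
    stop("primer shorter than word_size")
  seqs <- as.character(as_dnastringset(reference))
  m <- nchar(primer_seq)
  rc <- revcomp(primer_seq)
  out <- list()
  for (ch in names(seqs)) {
    # plus strand: primer 3' end at the footprint's right; window = last 10
    hp <- .scan_ungapped_cpp(seqs[[ch]], primer_seq, match, mismatch,
                             min_score, m - 10L, m - 1L)
    if (nrow(hp)) {
      hp$chrom <- ch; hp$strand <- "+"
      hp$prim3_pos <- hp$pos + m - 1L
      out[[length(out) + 1]] <- hp
    }
    # minus strand: scan the reverse complement; its first 10 pattern
    # offsets are the primer's 3'-terminal bases
    hm <- .scan_ungapped_cpp(seqs[[ch]], rc, match, mismatch,
                             min_score, 0L, 9L)
    if (nrow(hm)) {
      hm$chrom <- ch; hm$strand <- "-"
      hm$prim3_pos <- hm$pos
      out[[length(out) + 1]] <- hm
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), seg_from = integer(0),
                      seg_to = integer(0), mm_3p10 = integer(0),
                      mm_total = integer(0), prim3_pos = integer(0),
                      role = character(0), stringsAsFactors = FALSE))
  h <- do.call(rbind, out)
  data.frame(chrom = h$chrom, start = h$pos, end = h$pos + m - 1L,
             strand = h$strand, score = h$score, seg_from = h$seg_from,
             seg_to = h$seg_to, mm_3p10 = h$mm_window, mm_total = h$mm_total,
             prim3_pos = h$prim3_pos, role = role, stringsAsFactors = FALSE)
}

# Junction endpoint of the 36-nt read a sequencing PBS would generate:
# the read extends from the base after the primer's 3' end.
pbs_read_endpoint <- function(sites, read_len = 36) {
  ifelse(sites$strand == "+", sites$prim3_pos + read_len,
         sites$prim3_pos - read_len)
}

#' Link primer binding sites to an element annotation track
#'
#' Each site is annotated with the track element containing it (if any) and
#' with the junction endpoint of the sequencing read it would generate, for
#' matching against called loci.
#'
#' @param sites Data frame from [scan_pbs()].
#' @param me_track Element track (the `me_track` of an `me_reference`, or
#'   [read_track_bed()] output).
#' @param read_len Sequencing read length.
#' @return `sites` with added columns `family` (`NA` when the site is not
#'   inside an annotated element), `element_start`, `element_end`,
#'   `predicted_endpoint`.
#' @export
link_pbs_to_track <- function(sites, me_track, read_len = 36) {
  sites$family <- NA_character_
  sites$element_start <- NA_integer_
  sites$element_end <- NA_integer_
  for (i in seq_len(nrow(sites))) {
    hit <- which(me_track$chrom == sites$chrom[i] &
                   me_track$start <= sites$start[i] &
                   me_track$end >= sites$end[i])
    if (length(hit)) {
      hit <- hit[1]
      sites$family[i] <- me_track$family[hit]
      sites$element_start[i] <- me_track$start[hit]
      sites$element_end[i] <- me_track$end[hit]
    }
  }
  sites$predicted_endpoint <- as.integer(pbs_read_endpoint(sites, read_len))
  sites
}

#' Classify called loci against annotated primer binding sites
#'
#' Every called locus receives exactly one class: `KNOWN_TARGET` when a
#' linked sequencing PBS inside a target-subfamily element predicts the
#' locus position (within `position_tol` bp), `NONSPECIFIC` when the linked
#' element belongs to another family (sporadic amplification of old
#' elements with degenerate primer sites), and `NOVEL` otherwise (the
#' insertion is absent from the reference).
#'
#' @param loci Called loci (the `loci` element of [call_loci()] output).
#' @param annotated_sites Output of [link_pbs_to_track()] for the
#'   sequencing primer.
#' @param target_family Track family label of the assayed subfamily.
#' @param position_tol Matching tolerance in bp.
#' @return `loci` with an added `class` column.
#' @export
classify_loci <- function(loci, annotated_sites, target_family = "AluYb-like",
                          position_tol = 3) {
  cls <- rep("NOVEL", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    sel <- which(annotated_sites$chrom == loci$chrom[i] &
                   abs(annotated_sites$predicted_endpoint - loci$pos[i]) <= position_tol)
    if (!length(sel)) next
    sel <- sel[which.min(abs(annotated_sites$predicted_endpoint[sel] - loci$pos[i]))]
    fam <- annotated_sites$family[sel]
    cls[i] <- if (is.na(fam)) "NOVEL"
      else if (fam == target_family) "KNOWN_TARGET"
      else "NONSPECIFIC"
  }
  loci$class <- cls
  loci
}

#' Criteria for putatively fixed, retrievable reference loci
#'
#' A reference element is putatively fixed and retrievable when both primer
#' binding sites are present with scores at or above the thresholds, their
#' plus-strand start positions are separated by `spacing` within
#' `spacing_tol` (inclusive bounds), both sites share an orientation, the
#' sequencing PBS lies 3' (downstream, in the orientation of the sites) of
#' the amplification PBS, neither site has a mismatch to its primer in the
#' 3' 10 bp, and the locus is not on the known-polymorphic list.
#'
#' The score thresholds are raw ungapped-alignment scores under the +1/-3
#' scoring used by [scan_pbs()] and are calibrated by the user for any
#' other scoring scheme.
#'
#' @param amp_min,seq_min Minimum amplification / sequencing PBS scores.
#' @param spacing,spacing_tol Required start-position separation (bp).
#' @param max_3p_mismatch Maximum mismatches in either 3' 10 bp window.
#' @param read_len Sequencing read length (for the locus identifier).
#' @return Parameter list.
#' @export
fixed_locus_params <- function(amp_min = 16, seq_min = 23,
                               spacing = 224, spacing_tol = 15,
                               max_3p_mismatch = 0, read_len = 36) {
  stopifnot(spacing_tol >= 0)
  list(amp_min = amp_min, seq_min = seq_min, spacing = spacing,
       spacing_tol = spacing_tol, max_3p_mismatch = max_3p_mismatch,
       read_len = read_len)
}

#' Select putatively fixed, retrievable loci
#'
#' @param amp_sites,seq_sites [scan_pbs()] output for the amplification and
#'   sequencing primers.
#' @param params A [fixed_locus_params()] list.
#' @param polymorphic_known Character vector of known-polymorphic locus
#'   identifiers (`"chrom:pos"`), excluded from the result (matched within
#'   `position_tol` bp).
#' @param position_tol Tolerance for the polymorphic-list exclusion.
#' @return Data frame of selected loci: `locus_id`, `chrom`, `pos` (the
#'   predicted junction endpoint), `strand`, `amp_start`, `seq_start`,
#'   `separation`.
#' @export
select_fixed_loci <- function(amp_sites, seq_sites,
                              params = fixed_locus_params(),
                              polymorphic_known = character(0),
                              position_tol = 3) {
  amp <- amp_sites[amp_sites$score >= params$amp_min &
                     amp_sites$mm_3p10 <= params$max_3p_mismatch, , drop = FALSE]
  seqs <- seq_sites[seq_sites$score >= params$seq_min &
                      seq_sites$mm_3p10 <= params$max_3p_mismatch, , drop = FALSE]
  lo <- params$spacing - params$spacing_tol
  hi <- params$spacing + params$spacing_tol
  rows <- list()
  for (i in seq_len(nrow(seqs))) {
    cand <- which(amp$chrom == seqs$chrom[i] & amp$strand == seqs$strand[i])
    if (!length(cand)) next
    sep <- abs(amp$start[cand] - seqs$start[i])
    downstream <- if (seqs$strand[i] == "+") seqs$start[i] > amp$start[cand]
      else seqs$start[i] < amp$start[cand]
    ok <- which(sep >= lo & sep <= hi & downstream)
    if (!length(ok)) next
    j <- cand[ok[which.min(sep[ok])]]
    ep <- as.integer(pbs_read_endpoint(seqs[i, , drop = FALSE], params$read_len))
    rows[[length(rows) + 1]] <- data.frame(
      locus_id = locus_id(seqs$chrom[i], ep), chrom = seqs$chrom[i], pos = ep,
      strand = seqs$strand[i], amp_start = amp$start[j],
      seq_start = seqs$start[i], separation = abs(amp$start[j] - seqs$start[i]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(locus_id = character(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      amp_start = integer(0), seq_start = integer(0),
                      separation = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if (length(polymorphic_known)) {
    known <- split_locus_id(polymorphic_known)
    drop <- vapply(seq_len(nrow(out)), function(i) {
      any(known$chrom == out$chrom[i] & abs(known$pos - out$pos[i]) <= position_tol)
    }, logical(1))
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Flag loci whose upstream flank is segmentally duplicated
#'
#' Tests whether the `window` bp of genomic flank adjacent to a locus's
#' junction (upstream of the insertion, i.e. the sequence its read pairs
#' are drawn from) has a near-identical copy elsewhere in the genome. Read
#' pairs from such loci do not map to a unique position and are eliminated
#' by the mapping-quality filter, so these loci are systematic false
#' negatives. Detection is by exact seeding (`seed_len`-mers every
#' `seed_stride` bp, both orientations) followed by full-window ungapped
#' comparison; identity is matching bases over the window.
#'
#' @param reference Reference accepted by [toy_map()].
#' @param chrom,pos Locus identifier coordinates (junction endpoint).
#' @param strand Insertion strand: the flank window is `[pos - window + 1,
#'   pos]` for `"+"` insertions and `[pos, pos + window - 1]` for `"-"`.
#' @param window Flank window length in bp.
#' @param min_identity Minimum identity of a duplicate copy.
#' @param seed_len,seed_stride Seeding parameters.
#' @return Logical: is there a duplicate copy elsewhere?
#' @export
flag_upstream_duplication <- function(reference, chrom, pos, strand = "+",
                                      window = 500, min_identity = 0.99,
                                      seed_len = 31, seed_stride = 16) {
  seqs <- as_dnastringset(reference)
  L <- Biostrings::width(seqs)[match(chrom, names(seqs))]
  from <- if (strand == "+") pos - window + 1L else pos
  to <- from + window - 1L
  if (from < 1 || to > L)
    stop("fewer than 'window' bases of flank exist for this locus")
  w <- as.character(Biostrings::subseq(seqs[[chrom]], from, to))
  max_mm <- floor((1 - min_identity) * window)
  offs <- seq(1L, window - seed_len + 1L, by = seed_stride)

  for (orient in c("fwd", "rc")) {
    q <- if (orient == "fwd") w else revcomp(w)
    for (ch in names(seqs)) {
      subject <- seqs[[ch]]
      cand <- integer(0)
      for (o in offs) {
        seed <- Biostrings::DNAString(substr(q, o, o + seed_len - 1L))
        m <- Biostrings::matchPattern(seed, subject)
        if (length(m)) cand <- c(cand, Biostrings::start(m) - o + 1L)
      }
      cand <- unique(cand)
      cand <- cand[cand >= 1 & cand + window - 1L <= length(subject)]
      if (orient == "fwd" && ch == chrom) {
        cand <- cand[abs(cand - from) >= window]  # exclude the window itself
      }
      if (!length(cand)) next
      for (p in cand) {
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(q), subject,
                                          starting.at = p, with.indels = FALSE)
        if (mm <= max_mm) return(TRUE)
      }
    }
  }
  FALSE
}

#' Compare two locus lists with positional tolerance
#'
#' Greedy nearest-match pairing: candidate pairs within `tol` bp on the
#' same chromosome are matched in order of increasing distance, each locus
#' at most once.
#'
#' @param list_a,list_b Data frames with `chrom` and `pos` columns.
#' @param tol Maximum match distance in bp.
#' @return List with `matched` (data frame of row indices `ia`, `ib` and
#'   `distance`), `n_matched`, `unmatched_a`, `unmatched_b` (row indices).
#' @export
compare_locus_lists <- function(list_a, list_b, tol = 50) {
  cand <- list()
  for (i in seq_len(nrow(list_a))) {
    sel <- which(list_b$chrom == list_a$chrom[i] &
                   abs(list_b$pos - list_a$pos[i]) <= tol)
    if (length(sel))
      cand[[length(cand) + 1]] <- data.frame(
        ia = i, ib = sel, distance = abs(list_b$pos[sel] - list_a$pos[i]))
  }
  matched <- data.frame(ia = integer(0), ib = integer(0), distance = integer(0))
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$distance, cand$ia, cand$ib), , drop = FALSE]
    used_a <- logical(nrow(list_a)); used_b <- logical(nrow(list_b))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (!used_a[cand$ia[r]] && !used_b[cand$ib[r]]) {
        keep[r] <- TRUE
        used_a[cand$ia[r]] <- TRUE
        used_b[cand$ib[r]] <- TRUE
      }
    }
    matched <- cand[keep, , drop = FALSE]
    rownames(matched) <- NULL
  }
  list(matched = matched, n_matched = nrow(matched),
       unmatched_a = setdiff(seq_len(nrow(list_a)), matched$ia),
       unmatched_b = setdiff(seq_len(nrow(list_b)), matched$ib))
}
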