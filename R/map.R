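#' Map reads end-to-end against a small reference
#'
#' A hermetic substitution-only aligner for desk-scale references: reports
#' every end-to-end placement of each read (both strands) with at most
#' `max_mismatch` substitutions, found by exact k-mer seeding with
#' `max_mismatch + 1` disjoint seeds per read (pigeonhole guarantees no
#' placement within the edit bound is missed). Mapping quality follows the
#' convention that only zero versus non-zero matters downstream: a unique
#' best-scoring placement gets quality 37, tied best placements get 0.
#'
#' @param reads Character vector of read sequences.
#' @param reference An `me_reference`, [Biostrings::DNAStringSet] or named
#'   character vector of chromosomes.
#' @param max_mismatch Maximum substitutions (edit bound), default 3.
#' @return Data frame with one row per alignment: `read` (index into
#'   `reads`), `chrom`, `pos` (1-based leftmost), `strand`, `mismatches`,
#'   `is_best` (ties at the read's best score), `n_best` (number of tied
#'   best placements for the read) and `mapq` (37 or 0, on best rows).
#' @export
toy_map <- function(reads, reference, max_mismatch = 3) {
  seqs <- as.character(as_dnastringset(reference))
  empty <- data.frame(read = integer(0), chrom = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0),
                      is_best = logical(0), n_best = integer(0),
                      mapq = integer(0), stringsAsFactors = FALSE)
  if (length(reads) == 0) return(empty)
  lens <- nchar(reads)
  out <- list()
  for (len in sort(unique(lens))) {
    sel <- which(lens == len)
    k <- max(1L, len %/% (max_mismatch + 1L))
    h <- .toymap_batch(reads[sel], unname(seqs), k, max_mismatch)
    if (nrow(h) == 0) next
    h$read <- sel[h$read]
    h$chrom <- names(seqs)[h$ref]
    h$ref <- NULL
    out[[length(out) + 1]] <- h
  }
  if (!length(out)) return(empty)
  hits <- do.call(rbind, out)
  best_mm <- stats::ave(hits$mismatches, hits$read, FUN = min)
  hits$is_best <- hits$mismatches == best_mm
  nb <- stats::ave(as.integer(hits$is_best), hits$read, FUN = sum)
  hits$n_best <- as.integer(nb)
  hits$mapq <- ifelse(hits$is_best, ifelse(hits$n_best == 1, 37L, 0L), NA_integer_)
  hits[order(hits$read, -hits$is_best, hits$chrom, hits$pos), c(
    "read", "chrom", "pos", "strand", "mismatches", "is_best", "n_best", "mapq")]
}

# One chosen placement per read: any best-score row, plus uniqueness info.
# Reads without alignments are absent from the result.
best_placements <- function(hits) {
  b <- hits[hits$is_best, , drop = FALSE]
  first <- !duplicated(b$read)
  b[first, , drop = FALSE]
}

# Reference bases consumed by a CIGAR string (M, D, N, =, X operations).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (!length(ops)) return(NA_integer_)
    w <- as.integer(sub("[MIDNSHP=X]", "", ops))
    type <- sub("[0-9]+", "", ops)
    sum(w[type %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

softclip_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+S", cg))[[1]]
    if (!length(ops)) return(0L)
    sum(as.integer(sub("S", "", ops)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Pair-level mapping filters
#'
#' Applies the pair filters to a table of paired alignments: a pair is kept
#' only when it is properly paired (both mates mapped to the same
#' chromosome on opposite strands, oriented toward each other, with outer
#' distance inside the insert window), neither mate has mapping quality 0,
#' and neither mate aligned with more than `max_edit` mismatched or
#' unmatched bases. The first violated condition, in that order, is
#' reported as the reason.
#'
#' @param align Data frame with per-mate columns `j_mapped`, `j_chrom`,
#'   `j_pos`, `j_strand`, `j_ref_width`, `j_mapq`, `j_edit` and the same
#'   with prefix `f_`. An optional logical `properly_paired` column (e.g.
#'   from SAM flags) overrides the geometric proper-pair check.
#' @param insert_min,insert_max Accepted outer-distance window between the
#'   outermost mapped bases of the two mates.
#' @param max_edit Maximum per-mate edit distance (substituted plus
#'   inserted/deleted/clipped bases).
#' @return Data frame with `keep` (logical) and `reason` (one of `OK`,
#'   `NOT_PROPER`, `MAPQ_ZERO`, `EDIT_GT3`).
#' @export
filter_pair <- function(align, insert_min = 100, insert_max = 1000,
                        max_edit = 3) {
  n <- nrow(align)
  if (n == 0) return(data.frame(keep = logical(0), reason = character(0)))
  if ("properly_paired" %in% names(align)) {
    proper <- align$properly_paired %in% TRUE
  } else {
    both <- align$j_mapped %in% TRUE & align$f_mapped %in% TRUE
    proper <- rep(FALSE, n)
    idx <- which(both & align$j_chrom == align$f_chrom &
                   align$j_strand != align$f_strand)
    if (length(idx)) {
      jfwd <- align$j_strand[idx] == "+"
      fw_pos <- ifelse(jfwd, align$j_pos[idx], align$f_pos[idx])
      rv_pos <- ifelse(jfwd, align$f_pos[idx], align$j_pos[idx])
      rv_w <- ifelse(jfwd, align$f_ref_width[idx], align$j_ref_width[idx])
      outer <- rv_pos + rv_w - fw_pos
      proper[idx] <- fw_pos <= rv_pos & outer >= insert_min & outer <= insert_max
    }
  }
  reason <- rep("OK", n)
  reason[which(align$j_edit > max_edit | align$f_edit > max_edit)] <- "EDIT_GT3"
  reason[which(align$j_mapq == 0 | align$f_mapq == 0)] <- "MAPQ_ZERO"
  reason[!proper] <- "NOT_PROPER"
  data.frame(keep = reason == "OK", reason = reason, stringsAsFactors = FALSE)
}

#' Map read pairs with the dual intact/trimmed junction scheme
#'
#' Junction reads are mapped twice: intact (all 36 nt, of which the first
#' 16 nt are expected element sequence) and with those 16 nt trimmed off.
#' The flank read (index already trimmed) is mapped once. A pair whose
#' intact mapping passes all filters represents an element present in the
#' reference and the trimmed mapping is ignored as redundant; a pair that
#' passes only when trimmed is evidence of an insertion absent from the
#' reference. When a mate has several tied-best placements, the combination
#' forming a proper pair is preferred (its mapping quality stays 0, so such
#' pairs are still discarded, with `MAPQ_ZERO` as the reason).
#'
#' @param pairs Data frame of usable pairs from [demux_stream()]: `id`,
#'   `sample`, `junction` (36 nt), `flank` (30 nt), `experiment`.
#' @param reference Reference accepted by [toy_map()].
#' @param trim_len Leading element bases trimmed in the second pass.
#' @param max_mismatch Per-read substitution bound for the toy mapper.
#' @param insert_min,insert_max,max_edit Passed to [filter_pair()].
#' @return Data frame, one row per input pair: identity columns, `mode`
#'   (`INTACT`, `TRIMMED` or `NA`), `keep`, `reason`, and the junction/flank
#'   placement columns used downstream (`j_chrom`, `j_pos`, `j_strand`,
#'   `j_cigar`, `j_mapq`, `j_edit`, and `f_` equivalents).
#' @export
map_read_pairs <- function(pairs, reference, trim_len = 16, max_mismatch = 3,
                           insert_min = 100, insert_max = 1000, max_edit = 3) {
  n <- nrow(pairs)
  jh <- toy_map(pairs$junction, reference, max_mismatch)
  fh <- toy_map(pairs$flank, reference, max_mismatch)
  intact <- pair_alignment_table(n, jh, fh, nchar(pairs$junction), nchar(pairs$flank),
                                 insert_min, insert_max)
  vi <- filter_pair(intact, insert_min, insert_max, max_edit)

  res <- intact
  res$mode <- ifelse(vi$keep, "INTACT", NA_character_)
  res$keep <- vi$keep
  res$reason <- vi$reason

  redo <- which(!vi$keep)
  if (length(redo)) {
    trimmed_seq <- substring(pairs$junction[redo], trim_len + 1)
    th <- toy_map(trimmed_seq, reference, max_mismatch)
    fh_sub <- fh[fh$read %in% redo, , drop = FALSE]
    fh_sub$read <- match(fh_sub$read, redo)
    tr <- pair_alignment_table(length(redo), th, fh_sub, nchar(trimmed_seq),
                               nchar(pairs$flank[redo]), insert_min, insert_max)
    vt <- filter_pair(tr, insert_min, insert_max, max_edit)
    ok <- which(vt$keep)
    if (length(ok)) {
      cols <- grep("^[jf]_", names(res), value = TRUE)
      res[redo[ok], cols] <- tr[ok, cols]
      res$mode[redo[ok]] <- "TRIMMED"
      res$keep[redo[ok]] <- TRUE
      res$reason[redo[ok]] <- "OK"
    }
    # report the more informative of the two failure reasons
    still <- which(!vt$keep)
    if (length(still)) {
      use_tr <- !intact$j_mapped[redo[still]] & tr$j_mapped[still]
      res$reason[redo[still][use_tr]] <- vt$reason[still][use_tr]
    }
  }
  cbind(pairs[, intersect(c("id", "sample", "experiment"), names(pairs)),
              drop = FALSE], res)
}

# Assemble one PairAlignment row per pair from per-read hit tables,
# preferring tied-best placement combinations that form a proper pair.
pair_alignment_table <- function(n, jh, fh, j_len, f_len,
                                 insert_min, insert_max) {
  out <- data.frame(
    j_mapped = rep(FALSE, n), j_chrom = NA_character_, j_pos = NA_integer_,
    j_strand = NA_character_, j_cigar = NA_character_, j_ref_width = NA_integer_,
    j_mapq = NA_integer_, j_edit = NA_integer_,
    f_mapped = rep(FALSE, n), f_chrom = NA_character_, f_pos = NA_integer_,
    f_strand = NA_character_, f_cigar = NA_character_, f_ref_width = NA_integer_,
    f_mapq = NA_integer_, f_edit = NA_integer_,
    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  j_len <- rep_len(j_len, n); f_len <- rep_len(f_len, n)

  jb <- jh[jh$is_best, , drop = FALSE]
  fb <- fh[fh$is_best, , drop = FALSE]
  fill <- function(out, side, rows, reads, len) {
    p <- paste0(side, "_")
    out[[paste0(p, "mapped")]][reads] <- TRUE
    out[[paste0(p, "chrom")]][reads] <- rows$chrom
    out[[paste0(p, "pos")]][reads] <- rows$pos
    out[[paste0(p, "strand")]][reads] <- rows$strand
    out[[paste0(p, "cigar")]][reads] <- paste0(len[reads], "M")
    out[[paste0(p, "ref_width")]][reads] <- len[reads]
    out[[paste0(p, "mapq")]][reads] <- rows$mapq
    out[[paste0(p, "edit")]][reads] <- rows$mismatches
    out
  }
  j1 <- jb[!duplicated(jb$read), , drop = FALSE]
  f1 <- fb[!duplicated(fb$read), , drop = FALSE]
  out <- fill(out, "j", j1, j1$read, j_len)
  out <- fill(out, "f", f1, f1$read, f_len)

  # multi-best mates: look for a combination that pairs properly
  multi <- union(j1$read[j1$n_best > 1], f1$read[f1$n_best > 1])
  for (r in multi) {
    jr <- jb[jb$read == r, , drop = FALSE]
    fr <- fb[fb$read == r, , drop = FALSE]
    if (nrow(jr) == 0 || nrow(fr) == 0) next
    found <- FALSE
    for (a in seq_len(nrow(jr))) {
      for (b in seq_len(nrow(fr))) {
        if (jr$chrom[a] != fr$chrom[b] || jr$strand[a] == fr$strand[b]) next
        if (jr$strand[a] == "+") {
          fw_pos <- jr$pos[a]; rv_pos <- fr$pos[b]; rv_w <- f_len[r]
        } else {
          fw_pos <- fr$pos[b]; rv_pos <- jr$pos[a]; rv_w <- j_len[r]
        }
        outer <- rv_pos + rv_w - fw_pos
        if (fw_pos <= rv_pos && outer >= insert_min && outer <= insert_max) {
          out <- fill(out, "j", jr[a, ], r, j_len)
          out <- fill(out, "f", fr[b, ], r, f_len)
          found <- TRUE; break
        }
      }
      if (found) break
    }
  }
  out
}

#' Ingest externally produced paired alignments from SAM
#'
#' Reads headerful SAM (one paired file, or separate junction and flank
#' files) and yields the pair-alignment table that [filter_pair()] and
#' [junction_endpoint()] consume, tagged with the mapping mode. Pairs are
#' joined by read name; the proper-pair call is taken from the aligner's
#' flags (properly mapped pairs have flag values 99/147 or 83/163). Edit
#' distance is the `NM` tag plus soft-clipped bases (mismatched plus
#' unmatched); records without `NM` get the number of clipped bases only.
#' Records with a missing mate are counted and dropped.
#'
#' @param junction_sam Path to SAM with junction-read alignments, or a
#'   paired SAM containing both mates (then `flank_sam = NULL`; mates are
#'   told apart by the first/second-in-pair flag bits).
#' @param flank_sam Optional path to SAM with flank-read alignments.
#' @param mode Mapping mode tag for these alignments (`"INTACT"` or
#'   `"TRIMMED"`).
#' @return List with `alignments` (pair table; one row per read name) and
#'   `n_dropped` (records without a usable mate).
#' @export
ingest_sam <- function(junction_sam, flank_sam = NULL,
                       mode = c("INTACT", "TRIMMED")) {
  mode <- match.arg(mode)
  read_side <- function(path) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "strand", "mapq", "cigar"),
      tag = "NM")
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    data.frame(qname = x$qname, flag = x$flag,
               chrom = as.character(x$rname), pos = x$pos,
               strand = as.character(x$strand), mapq = x$mapq,
               cigar = x$cigar, nm = x$tag$NM %||% rep(NA_integer_, length(x$qname)),
               stringsAsFactors = FALSE)
  }
  if (is.null(flank_sam)) {
    all <- read_side(junction_sam)
    first <- bitwAnd(all$flag, 64L) > 0
    j <- all[first, , drop = FALSE]
    f <- all[!first, , drop = FALSE]
  } else {
    j <- read_side(junction_sam)
    f <- read_side(flank_sam)
  }
  common <- intersect(j$qname, f$qname)
  n_dropped <- (nrow(j) - length(common)) + (nrow(f) - length(common))
  j <- j[match(common, j$qname), , drop = FALSE]
  f <- f[match(common, f$qname), , drop = FALSE]

  side_cols <- function(x, pfx) {
    mapped <- bitwAnd(x$flag, 4L) == 0
    edit <- ifelse(is.na(x$nm), 0L, x$nm) + softclip_width(x$cigar)
    d <- data.frame(mapped = mapped, chrom = x$chrom, pos = x$pos,
                    strand = ifelse(mapped, x$strand, NA_character_),
                    cigar = x$cigar, ref_width = cigar_ref_width(x$cigar),
                    mapq = x$mapq, edit = as.integer(edit),
                    stringsAsFactors = FALSE)
    names(d) <- paste0(pfx, "_", names(d))
    d
  }
  proper <- (j$flag %in% c(99L, 83L) & f$flag %in% c(147L, 163L)) |
    (j$flag %in% c(147L, 163L) & f$flag %in% c(99L, 83L))
  align <- cbind(data.frame(id = common, stringsAsFactors = FALSE),
                 side_cols(j, "j"), side_cols(f, "f"))
  align$properly_paired <- proper
  align$mode <- rep(mode, length(common))
  list(alignments = align, n_dropped = n_dropped)
}
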