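#' Junction endpoint of a mapped junction read
#'
#' The reference coordinate aligned to the junction read's final sequenced
#' base is the locus identifier: it lies about 20 bp past the element's 5'
#' junction in the genomic flank, so it exists in the reference even when
#' the insertion does not, and it is identical whether the pair mapped
#' intact or with the 16 nt of element sequence trimmed (the trimmed read
#' ends at the same reference base). For a forward-strand alignment this is
#' `pos + (reference bases consumed by the CIGAR) - 1`; for a
#' reverse-strand alignment the final sequenced base is the leftmost
#' reference coordinate, `pos`.
#'
#' @param align Pair-alignment data frame (from [map_read_pairs()] or
#'   [ingest_sam()]) with columns `j_chrom`, `j_pos`, `j_strand`, `j_cigar`.
#' @return Data frame `chrom`, `pos` (endpoint), plus `mode`, `sample`,
#'   `experiment` and `id` columns carried through when present.
#' @export
junction_endpoint <- function(align) {
  w <- cigar_ref_width(align$j_cigar)
  if (any(!is.na(w) & w == 0))
    stop("junction CIGAR consumes zero reference bases")
  pos <- ifelse(align$j_strand == "+", align$j_pos + w - 1L, align$j_pos)
  out <- data.frame(chrom = align$j_chrom, pos = as.integer(pos),
                    stringsAsFactors = FALSE)
  for (col in intersect(c("mode", "sample", "experiment", "id"), names(align)))
    out[[col]] <- align[[col]]
  out
}

#' Group junction endpoints into candidate loci
#'
#' Endpoints sharing an exact position form a group. Endpoints positioned
#' singly (groups of size 1) within `merge_tol` bp of a larger group are
#' rare mapping/sequencing artifacts and are absorbed into the most
#' numerous neighbouring group; when two neighbours are equally numerous
#' the nearer wins, and at equal distance the lower coordinate wins. Only
#' singletons are merged: two multi-read groups within the tolerance remain
#' distinct. Support is conserved exactly.
#'
#' @param endpoints Data frame with `chrom` and `pos` (plus any carried
#'   columns).
#' @param merge_tol Maximum merge distance in bp.
#' @return The input with an added `group_pos` column (the group's position
#'   identifier, i.e. the position of its largest exact-position stack).
#' @export
group_endpoints <- function(endpoints, merge_tol = 3) {
  endpoints$group_pos <- endpoints$pos
  if (nrow(endpoints) == 0) return(endpoints)
  for (ch in unique(endpoints$chrom)) {
    sel <- endpoints$chrom == ch
    tab <- table(endpoints$pos[sel])
    pos <- as.integer(names(tab))
    cnt <- as.integer(tab)
    singles <- pos[cnt == 1]
    big_pos <- pos[cnt > 1]
    big_cnt <- cnt[cnt > 1]
    if (!length(singles) || !length(big_pos)) next
    for (p in singles) {
      d <- abs(big_pos - p)
      cand <- which(d <= merge_tol & d > 0)
      if (!length(cand)) next
      cand <- cand[order(-big_cnt[cand], d[cand], big_pos[cand])]
      target <- big_pos[cand[1]]
      endpoints$group_pos[sel & endpoints$pos == p] <- target
    }
  }
  endpoints
}

#' Parameters of the element-motif check on junction reads
#'
#' A junction read is taken to contain element sequence when its leading
#' segment matches the expected motif at `exact_len` bases (identity over
#' the first `exact_len` bases of the motif) or reaches a local-alignment
#' score of at least `score_min` against the motif under the given costs
#' (gaps effectively forbidden by the default gap costs).
#'
#' The expected motif is printed as 15 nt although junction reads carry
#' 16 nt of element sequence; the mismatch is deliberate and the motif is
#' configurable.
#'
#' @param motif Expected element motif.
#' @param exact_len Leading bases compared for the identity criterion.
#' @param score_min Local-alignment score threshold.
#' @param match,mismatch,gap_open,gap_ext Alignment costs.
#' @return Parameter list.
#' @export
me_motif_params <- function(motif = me_motif(), exact_len = 10,
                            score_min = 45, match = 5, mismatch = -4,
                            gap_open = 64, gap_ext = 8) {
  stopifnot(exact_len > 0, score_min > 0)
  list(motif = motif, exact_len = exact_len, score_min = score_min,
       match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext)
}

#' Detect element sequence at the start of junction reads
#'
#' @param seq Character vector of junction-read leading segments (16 nt).
#' @param params A [me_motif_params()] list.
#' @return Logical vector.
#' @export
detect_me_sequence <- function(seq, params = me_motif_params()) {
  if (length(seq) == 0) return(logical(0))
  exact <- substr(seq, 1, params$exact_len) ==
    substr(params$motif, 1, params$exact_len)
  out <- exact
  rest <- which(!exact)
  if (length(rest)) {
    sc <- .sw_score_batch(seq[rest], params$motif, params$match,
                          params$mismatch, params$gap_open, params$gap_ext)
    out[rest] <- sc >= params$score_min
  }
  out
}

#' Call insertion loci from grouped junction endpoints
#'
#' Groups are retained as insertion loci when they are supported by at
#' least `min_support` read pairs (summed over all samples and
#' experiments) and at least `min_me_fraction` of the supporting junction
#' reads contain detectable element sequence (both bounds inclusive).
#' Groups failing the motif rule are likely non-element artifacts; weakly
#' supported groups are unreliable.
#'
#' @param grouped Data frame from [group_endpoints()] with columns `chrom`,
#'   `group_pos`, `sample`, `experiment`, `mode` and logical `me_detected`.
#' @param min_support Minimum total read-pair support.
#' @param min_me_fraction Minimum fraction of motif-positive junction
#'   reads.
#' @return List with `loci` (data frame: `locus_id`, `chrom`, `pos`,
#'   `total_support`, `me_fraction`, `modes`) and `support` (long data
#'   frame: `locus_id`, `experiment`, `sample`, `n`). Only retained loci
#'   appear.
#' @export
call_loci <- function(grouped, min_support = 10, min_me_fraction = 0.5) {
  empty <- list(
    loci = data.frame(locus_id = character(0), chrom = character(0),
                      pos = integer(0), total_support = integer(0),
                      me_fraction = numeric(0), modes = character(0),
                      stringsAsFactors = FALSE),
    support = data.frame(locus_id = character(0), experiment = character(0),
                         sample = character(0), n = integer(0),
                         stringsAsFactors = FALSE))
  if (nrow(grouped) == 0) return(empty)
  if (!"experiment" %in% names(grouped)) grouped$experiment <- "exp1"
  key <- locus_id(grouped$chrom, grouped$group_pos)
  agg <- stats::aggregate(
    list(total_support = rep(1L, nrow(grouped)),
         me_positive = as.integer(grouped$me_detected)),
    by = list(locus_id = key), FUN = sum)
  modes <- tapply(grouped$mode, key, function(m)
    paste(sort(unique(m)), collapse = ","))
  agg$me_fraction <- agg$me_positive / agg$total_support
  keep <- agg$total_support >= min_support & agg$me_fraction >= min_me_fraction
  agg <- agg[keep, , drop = FALSE]
  if (nrow(agg) == 0) return(empty)
  cp <- split_locus_id(agg$locus_id)
  loci <- data.frame(locus_id = agg$locus_id, chrom = cp$chrom, pos = cp$pos,
                     total_support = agg$total_support,
                     me_fraction = agg$me_fraction,
                     modes = unname(modes[agg$locus_id]),
                     stringsAsFactors = FALSE)
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  rownames(loci) <- NULL
  sup <- grouped[key %in% loci$locus_id, , drop = FALSE]
  skey <- locus_id(sup$chrom, sup$group_pos)
  support <- stats::aggregate(list(n = rep(1L, nrow(sup))),
                              by = list(locus_id = skey,
                                        experiment = sup$experiment,
                                        sample = sup$sample), FUN = sum)
  list(loci = loci, support = support)
}

#' Presence/absence genotype matrix from called loci
#'
#' The assay yields dominant presence/absence calls: a sample is called
#' positive at a locus when its supporting read-pair count (summed over
#' experiments) reaches `min_pairs_per_sample`. Any supporting read pair
#' counts as evidence at the default threshold of 1; raising the threshold
#' trades sensitivity against spurious support.
#'
#' @param called Output of [call_loci()].
#' @param min_pairs_per_sample Minimum pairs for a positive call.
#' @param samples Optional sample universe for the matrix columns (samples
#'   with no supporting pairs anywhere still get a column of zeroes).
#' @return List with `presence` (loci x samples 0/1 integer matrix) and
#'   `counts` (matching support-count matrix).
#' @export
genotype_matrix <- function(called, min_pairs_per_sample = 1, samples = NULL) {
  sup <- called$support
  samples <- samples %||% sort(unique(sup$sample))
  loci <- called$loci$locus_id
  counts <- matrix(0L, nrow = length(loci), ncol = length(samples),
                   dimnames = list(loci, samples))
  if (nrow(sup)) {
    agg <- stats::aggregate(list(n = sup$n),
                            by = list(locus_id = sup$locus_id,
                                      sample = sup$sample), FUN = sum)
    counts[cbind(match(agg$locus_id, loci), match(agg$sample, samples))] <-
      as.integer(agg$n)
  }
  presence <- (counts >= min_pairs_per_sample) + 0L
  list(presence = presence, counts = counts)
}

#' Write called loci and genotypes as TSV
#'
#' Tabular outputs use a commented header naming columns and coordinate
#' conventions (locus positions are 1-based junction-endpoint
#' coordinates).
#'
#' @param called Output of [call_loci()].
#' @param genotypes Output of [genotype_matrix()].
#' @param loci_tsv,genotypes_tsv Output paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_locus_tsv <- function(called, genotypes = NULL, loci_tsv = NULL,
                            genotypes_tsv = NULL) {
  if (!is.null(loci_tsv)) {
    con <- file(loci_tsv, "w")
    writeLines(paste0("# insertion loci; pos = 1-based reference coordinate ",
                      "of the junction read's final base"), con)
    utils::write.table(called$loci, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  if (!is.null(genotypes_tsv) && !is.null(genotypes)) {
    con <- file(genotypes_tsv, "w")
    writeLines("# presence(0/1) and supporting read-pair count per locus x sample", con)
    df <- data.frame(locus_id = rownames(genotypes$presence),
                     genotypes$presence, check.names = FALSE)
    cn <- colnames(genotypes$counts)
    for (s in cn) df[[paste0(s, "_pairs")]] <- genotypes$counts[, s]
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(c(loci = loci_tsv, genotypes = genotypes_tsv))
}
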