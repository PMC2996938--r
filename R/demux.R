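#' Assign sample indexes to flank reads
#'
#' The first 5 nt of each genomic flank read carry the sample index. An
#' exact match to a valid index wins outright; otherwise a unique valid
#' index at Hamming distance 1 is assigned (single-mismatch error
#' correction); a read 5-mer at distance 1 from two or more valid indexes,
#' or at distance greater than 1 from all of them, is left unassigned.
#' 'N' counts as a mismatch. On assignment the first 6 nt (index plus the
#' ligated 'T') are trimmed from the flank read.
#'
#' @param flank_seq Character vector of flank read sequences (>= 6 nt).
#' @param valid_indexes Character vector of distinct 5-nt indexes.
#' @return Data frame with one row per read: `index` (assigned index or
#'   `NA`), `distance` (0 or 1 when assigned), `trimmed` (flank sequence
#'   with index + 'T' removed; `NA` when unassigned).
#' @export
assign_index <- function(flank_seq, valid_indexes) {
  valid_indexes <- unname(valid_indexes)
  if (length(valid_indexes) == 0) stop("the set of valid indexes is empty")
  if (any(nchar(valid_indexes) != 5)) stop("valid indexes must all be 5 nt")
  if (anyDuplicated(valid_indexes)) stop("valid indexes must be distinct")
  if (length(flank_seq) && any(nchar(flank_seq) < 6))
    stop("flank reads must be at least 6 nt (index + 'T')")

  obs <- substr(flank_seq, 1, 5)
  assigned <- ifelse(obs %in% valid_indexes, obs, NA_character_)
  distance <- ifelse(is.na(assigned), NA_integer_, 0L)

  todo <- unique(obs[is.na(assigned)])
  if (length(todo)) {
    # distance of each unseen 5-mer to every valid index
    corr <- vapply(todo, function(o) {
      d <- hamming(rep(o, length(valid_indexes)), valid_indexes)
      hits <- which(d == 1)
      if (length(hits) == 1) valid_indexes[hits] else NA_character_
    }, character(1))
    hit <- is.na(assigned) & obs %in% todo[!is.na(corr)]
    assigned[hit] <- corr[obs[hit]]
    distance[hit] <- 1L
  }
  data.frame(index = assigned, distance = distance,
             trimmed = ifelse(is.na(assigned), NA_character_,
                              substring(flank_seq, 7)),
             stringsAsFactors = FALSE)
}

#' Default scoring for the adapter-contamination screen
#'
#' Ungapped local alignment with match +5 / mismatch -4; a score above 60
#' then corresponds to roughly 13 or more consecutive matching bases.
#'
#' @param match,mismatch Base-level scores.
#' @param threshold Score above which a read is flagged as contaminated.
#' @return A list of scoring parameters.
#' @export
qc_scoring <- function(match = 5, mismatch = -4, threshold = 60) {
  list(match = match, mismatch = mismatch, threshold = threshold)
}

#' Screen reads for the three quality defects
#'
#' A read is flagged as unusable when it (a) is low complexity (more than
#' 85% a single base), (b) has more than two 'N' base calls, or (c) carries
#' library-oligonucleotide sequence (best ungapped local alignment score
#' against any screened oligo or its reverse complement above the
#' threshold).
#'
#' @param seq Character vector of read sequences.
#' @param oligos Sequences to screen against (default [oligo_screen_set()];
#'   reverse complements must be included explicitly, as the default does).
#' @param scoring A [qc_scoring()] list.
#' @param max_base_fraction Low-complexity threshold (fraction of one base).
#' @param max_n Maximum tolerated 'N' calls.
#' @return Data frame of logicals: `low_complexity`, `excess_n`,
#'   `adapter_contaminated`, `usable`.
#' @export
classify_read_quality <- function(seq, oligos = oligo_screen_set(),
                                  scoring = qc_scoring(),
                                  max_base_fraction = 0.85, max_n = 2) {
  if (length(seq) == 0)
    return(data.frame(low_complexity = logical(0), excess_n = logical(0),
                      adapter_contaminated = logical(0), usable = logical(0)))
  if (any(nchar(seq) == 0)) stop("empty read sequence")
  ds <- Biostrings::DNAStringSet(seq)
  freq <- Biostrings::letterFrequency(ds, c("A", "C", "G", "T", "N"))
  low <- apply(freq[, c("A", "C", "G", "T"), drop = FALSE], 1, max) /
    Biostrings::width(ds) > max_base_fraction
  ns <- freq[, "N"] > max_n
  sc <- .ungapped_max_scores(seq, unname(oligos), scoring$match, scoring$mismatch)
  ad <- sc > scoring$threshold
  data.frame(low_complexity = low, excess_n = ns, adapter_contaminated = ad,
             usable = !(low | ns | ad), row.names = NULL)
}

#' Demultiplex a stream of read pairs and screen their quality
#'
#' Every input pair lands in exactly one bucket: a per-sample usable
#' bucket, `unassigned_index`, or `failed_qc`. Index assignment is judged
#' first (mirroring the pipeline order); quality is nevertheless evaluated
#' for every pair so that the accounting counters (total, high-quality,
#' per-rule defect counts, index-valid) are computed over the full input. A
#' pair failing several rules is counted once, under the first failing rule
#' in the order (a) low complexity, (b) excess 'N', (c) adapter.
#'
#' The ligated 'T' at position 6 of the flank read is trimmed but not
#' validated; non-'T' bases there are tallied in a diagnostic counter only.
#'
#' @param pairs Data frame with columns `id`, `junction`, `flank` (e.g. from
#'   [read_pair_fastq()] or a simulated library's `$pairs`).
#' @param index_table Named character vector sample -> index, or a data
#'   frame with columns `sample` and `index`.
#' @param oligos,scoring Passed to [classify_read_quality()].
#' @param read_len Declared read length; a record of any other length stops
#'   with an error (re-running on already-trimmed output is thereby
#'   rejected, never silently re-trimmed).
#' @param experiment Experiment label attached to the output pairs.
#' @return List with `pairs` (usable pairs: `id`, `sample`, `junction`,
#'   `flank` trimmed to 30 nt, `experiment`), `counters` (named list:
#'   `total`, `high_quality`, `rule_a`, `rule_b`, `rule_c`, `index_valid`,
#'   `usable`, `non_t_position6`), and `buckets` (per-pair bucket label).
#' @export
demux_stream <- function(pairs, index_table, oligos = oligo_screen_set(),
                         scoring = qc_scoring(), read_len = 36,
                         experiment = "exp1") {
  if (is.data.frame(index_table)) {
    valid <- stats::setNames(index_table$index, index_table$sample)
  } else valid <- index_table
  n <- nrow(pairs)
  if (n > 0) {
    badlen <- which(nchar(pairs$junction) != read_len | nchar(pairs$flank) != read_len)
    if (length(badlen))
      stop("record ", badlen[1], " (id '", pairs$id[badlen[1]], "') has reads of ",
           "unexpected length; input may already be trimmed")
  }

  if (n == 0) {
    counters <- list(total = 0L, high_quality = 0L, rule_a = 0L, rule_b = 0L,
                     rule_c = 0L, index_valid = 0L, usable = 0L,
                     non_t_position6 = 0L)
    return(list(pairs = data.frame(id = character(0), sample = character(0),
                                   junction = character(0), flank = character(0),
                                   experiment = character(0),
                                   stringsAsFactors = FALSE),
                counters = counters, buckets = character(0)))
  }

  asg <- assign_index(pairs$flank, unname(valid))
  sample <- names(valid)[match(asg$index, valid)]

  qj <- classify_read_quality(pairs$junction, oligos, scoring)
  qf <- classify_read_quality(pairs$flank, oligos, scoring)
  rule_a <- qj$low_complexity | qf$low_complexity
  rule_b <- !rule_a & (qj$excess_n | qf$excess_n)
  rule_c <- !rule_a & !rule_b & (qj$adapter_contaminated | qf$adapter_contaminated)
  hq <- qj$usable & qf$usable

  bucket <- ifelse(is.na(asg$index), "unassigned_index",
                   ifelse(!hq, "failed_qc", sample))
  keep <- !is.na(asg$index) & hq

  counters <- list(
    total = n,
    high_quality = sum(hq),
    rule_a = sum(rule_a),
    rule_b = sum(rule_b),
    rule_c = sum(rule_c),
    index_valid = sum(hq & !is.na(asg$index)),
    usable = sum(keep),
    non_t_position6 = sum(substr(pairs$flank, 6, 6) != "T")
  )

  out <- data.frame(id = pairs$id[keep], sample = sample[keep],
                    junction = pairs$junction[keep],
                    flank = asg$trimmed[keep],
                    experiment = experiment,
                    stringsAsFactors = FALSE)
  list(pairs = out, counters = counters, buckets = bucket)
}
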