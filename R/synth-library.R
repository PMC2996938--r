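#' Describe an indexed, pooled sequencing library
#'
#' Captures the design of one sequencing experiment: which samples are
#' pooled, their 5-nt indexes and intended proportions, sequencing depth,
#' per-locus coverage overdispersion, the fragment size-selection window and
#' the per-base error rate.
#'
#' The coverage model is negative binomial per locus and sample with
#' variance equal to `dispersion` times the mean; amplified fragment
#' libraries show per-locus count variances at least an order of magnitude
#' above the Poisson expectation, which a Poisson model cannot reproduce.
#' `dispersion = 1` recovers Poisson coverage.
#'
#' @param indexes Named character vector, sample label -> 5-nt index. All
#'   indexes must be distinct.
#' @param proportions Named numeric pooling proportions summing to 1
#'   (default: equal).
#' @param total_pairs Expected total read pairs emitted by the experiment.
#' @param dispersion Variance-to-mean ratio of per-locus pair counts (>= 1).
#' @param error_rate Independent per-base substitution error rate.
#' @param frag_min,frag_max Fragment size-selection window in bp (gel
#'   excision window).
#' @param experiment Experiment label carried through to locus support
#'   tables.
#' @param individuals Named character vector, sample label -> cohort
#'   individual (default: sample labels are individual labels; replication
#'   designs point two samples at the same individual).
#' @param pairs_per_locus Optional exact pair count emitted per carried
#'   locus and sample (overrides the coverage model; used for worked
#'   examples and tests).
#' @param nonspecific_rate Expected number of pairs per decoy element
#'   (summed over samples) emitted by sporadic non-specific amplification.
#' @param corrupt Named list of fractions of pairs to corrupt:
#'   `low_complexity`, `excess_n`, `adapter`, `bad_index` (defaults 0).
#' @param phred_char Constant base-quality character written to FASTQ.
#' @param seed Integer seed.
#' @return A `library_design` list.
#' @export
library_design <- function(indexes,
                           proportions = NULL,
                           total_pairs = 10000,
                           dispersion = 10,
                           error_rate = 0.001,
                           frag_min = 650, frag_max = 700,
                           experiment = "exp1",
                           individuals = NULL,
                           pairs_per_locus = NULL,
                           nonspecific_rate = 0,
                           corrupt = list(),
                           phred_char = "I",
                           seed = 1) {
  indexes <- unlist(indexes)  # tolerate YAML-style named lists
  if (!is.null(proportions)) proportions <- unlist(proportions)
  if (!is.null(individuals)) individuals <- unlist(individuals)
  if (is.null(names(indexes))) stop("indexes must be a named vector (sample -> index)")
  if (any(nchar(indexes) != 5)) stop("all indexes must be 5 nt")
  if (anyDuplicated(indexes)) stop("indexes must be distinct")
  if (is.null(proportions)) {
    proportions <- stats::setNames(rep(1 / length(indexes), length(indexes)),
                                   names(indexes))
  }
  if (is.null(names(proportions))) names(proportions) <- names(indexes)
  proportions <- proportions[names(indexes)]
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("pooling proportions must sum to 1")
  if (dispersion < 1) stop("dispersion (variance/mean) must be >= 1")
  if (is.null(individuals)) {
    individuals <- stats::setNames(names(indexes), names(indexes))
  }
  corrupt <- utils::modifyList(
    list(low_complexity = 0, excess_n = 0, adapter = 0, bad_index = 0), corrupt)
  structure(list(indexes = indexes, proportions = proportions,
                 total_pairs = total_pairs, dispersion = dispersion,
                 error_rate = error_rate, frag_min = frag_min,
                 frag_max = frag_max, experiment = experiment,
                 individuals = individuals,
                 pairs_per_locus = pairs_per_locus,
                 nonspecific_rate = nonspecific_rate,
                 corrupt = corrupt, phred_char = phred_char, seed = seed),
            class = "library_design")
}

#' Simulate an indexed pooled paired-read library
#'
#' Emulates the wet-lab protocol downstream of the cohort: for every locus a
#' sample carries, an overdispersed number of fragments is drawn; each
#' fragment has a length drawn uniformly in the size-selection window and
#' yields one read pair. The junction read (36 nt) starts with 16 nt of
#' element sequence adjacent to the 5' junction and continues across the
#' junction into 20 nt of genomic flank, strand-correctly. The flank read
#' (36 nt) is the sample's 5-nt index, the ligated 'T', and 30 nt of genomic
#' sequence from the fragment's far end. Independent per-base substitution
#' errors are applied at the configured rate.
#'
#' Heterozygous carriers emit at half the homozygous mean (one of two
#' chromosome copies carries the junction); non-carriers emit nothing.
#'
#' @param ref An `me_reference`.
#' @param cohort An `me_cohort` simulated on `ref`.
#' @param design A [library_design()]. Every sample's individual must exist
#'   in the cohort.
#' @return Object of class `me_library`: list with `pairs` (data frame:
#'   `id`, `junction`, `flank`), `truth` (per-pair source sample, locus and
#'   intended junction endpoint, plus corruption category), `counts` (locus
#'   x sample matrix of emitted pair counts), `loci` (locus table used),
#'   `design`, and `experiment`.
#' @export
simulate_library <- function(ref, cohort, design) {
  stopifnot(inherits(ref, "me_reference"), inherits(cohort, "me_cohort"),
            inherits(design, "library_design"))
  samples <- names(design$indexes)
  indiv <- design$individuals[samples]
  missing <- setdiff(indiv, cohort$individuals)
  if (length(missing))
    stop("sample(s) mapped to individuals absent from the cohort: ",
         paste(missing, collapse = ", "))

  loci <- cohort$loci
  g <- cohort$genotypes[indiv, , drop = FALSE]  # samples x loci (copies)
  rownames(g) <- samples

  # sporadic non-specific amplification of decoy elements
  decoys <- ref$me_track[ref$me_track$family == "AluS-like", , drop = FALSE]
  if (design$nonspecific_rate > 0 && nrow(decoys) > 0) {
    dl <- data.frame(locus_id = decoys$locus_id, chrom = decoys$chrom,
                     strand = decoys$strand, anchor = decoys$anchor,
                     endpoint = decoys$endpoint, in_reference = TRUE,
                     class = "nonspecific", allele_freq = NA_real_,
                     tsd_len = NA_integer_, polya_len = NA_integer_,
                     stringsAsFactors = FALSE)
    loci <- rbind(loci, dl[, names(loci)])
    g <- cbind(g, matrix(2L, nrow = length(samples), ncol = nrow(dl),
                         dimnames = list(samples, dl$locus_id)))
  }

  seqs <- as.character(ref$sequences)
  chrom_lengths <- nchar(seqs)

  with_seed(design$seed, {
    counts <- draw_pair_counts(loci, g, design)
    n_total <- sum(counts)

    # expand to one row per pair
    idx <- which(counts > 0, arr.ind = TRUE)
    per <- counts[counts > 0]
    li <- rep(idx[, 1], per)
    si <- rep(idx[, 2], per)
    n <- length(li)
    stopifnot(n == n_total)

    frag_len <- if (design$frag_max > design$frag_min)
      sample(design$frag_min:design$frag_max, n, replace = TRUE)
    else rep(design$frag_min, n)

    chrom <- loci$chrom[li]
    strand <- loci$strand[li]
    anchor <- loci$anchor[li]

    # junction reads: constant per locus (before errors)
    jprefix <- junction_prefix_for(loci, seqs)
    jflank <- junction_flank_for(loci, seqs)
    junction <- paste0(jprefix, jflank)[li]

    # flank reads: genomic 30-mer at the fragment's far end
    plus <- strand == "+"
    gstart <- ifelse(plus, anchor + 261L - frag_len, anchor + frag_len - 289L)
    gend <- gstart + 29L
    if (any(gstart < 1) || any(gend > chrom_lengths[chrom]))
      stop("fragment window extends beyond a chromosome; increase placement margins ",
           "or reduce frag_max")
    genomic <- substring(seqs[chrom], gstart, gend)
    if (any(!plus)) genomic[!plus] <- revcomp(genomic[!plus])
    flank <- paste0(design$indexes[colnames(counts)][si], "T", genomic)

    if (design$error_rate > 0) {
      junction <- apply_base_errors(junction, design$error_rate)
      flank <- apply_base_errors(flank, design$error_rate)
    }

    category <- rep("ok", n)
    cr <- design$corrupt
    if (any(unlist(cr) > 0) && n > 0) {
      pool <- sample(n)  # disjoint corruption targets
      take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
      k <- round(cr$low_complexity * n)
      if (k > 0) { i <- take(k); junction[i] <- strrep("A", 36); category[i] <- "low_complexity" }
      k <- round(cr$excess_n * n)
      if (k > 0) {
        i <- take(k)
        for (p in c(10, 20, 30)) substr(junction[i], p, p) <- "N"
        category[i] <- "excess_n"
      }
      k <- round(cr$adapter * n)
      if (k > 0) {
        i <- take(k)
        ad <- substr(oligo_screen_set()[["PEP2"]], 1, 20)
        substr(junction[i], 9, 28) <- ad
        category[i] <- "adapter"
      }
      k <- round(cr$bad_index * n)
      if (k > 0) {
        i <- take(k)
        bad <- unassignable_index(design$indexes)
        substr(flank[i], 1, 5) <- bad
        category[i] <- "bad_index"
      }
    }

    ids <- sprintf("mep%07d", seq_len(n))
    truth <- data.frame(id = ids, sample = colnames(counts)[si],
                        locus_id = rownames(counts)[li],
                        endpoint = loci$endpoint[li],
                        chrom = chrom, category = category,
                        stringsAsFactors = FALSE)
    pairs <- data.frame(id = ids, junction = junction, flank = flank,
                        stringsAsFactors = FALSE)
    structure(list(pairs = pairs, truth = truth, counts = counts,
                   loci = loci, design = design,
                   experiment = design$experiment),
              class = "me_library")
  })
}

# Per-(locus, sample) emitted pair counts. Negative binomial with mean
# proportional to pooling proportion and genotype dosage, variance =
# dispersion x mean; exact counts if the design overrides the model.
draw_pair_counts <- function(loci, g, design) {
  samples <- rownames(g)
  n_loci <- nrow(loci)
  counts <- matrix(0L, nrow = n_loci, ncol = length(samples),
                   dimnames = list(loci$locus_id, samples))
  nonspec <- loci$class == "nonspecific"
  for (s in seq_along(samples)) {
    dose <- ifelse(nonspec, 0, g[s, loci$locus_id] / 2)
    if (!is.null(design$pairs_per_locus)) {
      counts[, s] <- as.integer(ifelse(dose > 0, design$pairs_per_locus, 0L))
    } else {
      w <- sum(dose)
      if (w > 0) {
        mu <- design$total_pairs * design$proportions[[samples[s]]] * dose / w
        pos <- which(mu > 0)
        counts[pos, s] <- if (design$dispersion > 1) {
          size <- mu[pos] / (design$dispersion - 1)
          as.integer(stats::rnbinom(length(pos), size = size, mu = mu[pos]))
        } else {
          as.integer(stats::rpois(length(pos), mu[pos]))
        }
      }
    }
    if (any(nonspec) && design$nonspecific_rate > 0) {
      lam <- design$nonspecific_rate * design$proportions[[samples[s]]]
      counts[nonspec, s] <- as.integer(stats::rpois(sum(nonspec), lam))
    }
  }
  counts
}

# 16 nt of element sequence leading every junction read of a locus, taken
# from the reference for reference loci (decoys thus carry their divergence)
# and from the consensus for novel insertions.
junction_prefix_for <- function(loci, seqs) {
  out <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (!loci$in_reference[i]) { out[i] <- junction_prefix(); next }
    a <- loci$anchor[i]
    out[i] <- if (loci$strand[i] == "+")
      revcomp(substr(seqs[[loci$chrom[i]]], a + 1, a + 16))
    else substr(seqs[[loci$chrom[i]]], a - 15, a)
  }
  out
}

# 20 nt of genomic flank crossing the 5' junction, strand-correct.
junction_flank_for <- function(loci, seqs) {
  out <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    a <- loci$anchor[i]
    out[i] <- if (loci$strand[i] == "+")
      revcomp(substr(seqs[[loci$chrom[i]]], a - 19, a))
    else substr(seqs[[loci$chrom[i]]], a + 1, a + 20)
  }
  out
}

apply_base_errors <- function(reads, rate) {
  w <- nchar(reads)
  n_err <- stats::rbinom(length(reads), w, rate)
  hit <- which(n_err > 0)
  for (i in hit) reads[i] <- mutate_seq(reads[i], k = n_err[i])
  reads
}

# A 5-mer at Hamming distance >= 2 from every valid index (guaranteed
# unassignable even under single-mismatch correction).
unassignable_index <- function(indexes) {
  repeat {
    cand <- random_dna(5)
    if (all(hamming(rep(cand, length(indexes)), unname(indexes)) >= 2))
      return(cand)
  }
}

#' @export
print.me_library <- function(x, ...) {
  cat("Simulated library '", x$experiment, "': ", nrow(x$pairs),
      " read pairs, ", ncol(x$counts), " sample(s), ",
      nrow(x$counts), " loci\n", sep = "")
  invisible(x)
}

#' Write / read simulated libraries as FASTQ
#'
#' `write_library_fastq()` writes the junction reads and flank reads of a
#' simulated library to two FASTQ files (shared pair IDs with `/1` and `/2`
#' suffixes, constant base qualities), the per-pair truth table as TSV, and
#' the design parameters as a YAML sidecar. `read_pair_fastq()` reads any
#' such pair of lockstep FASTQ files back into the data frame layout that
#' [demux_stream()] consumes.
#'
#' @param lib An `me_library`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return `write_library_fastq()`: invisibly, the paths written.
#'   `read_pair_fastq()`: a data frame with columns `id`, `junction`,
#'   `flank`.
#' @export
write_library_fastq <- function(lib, dir, prefix = lib$experiment) {
  stopifnot(inherits(lib, "me_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jp <- file.path(dir, paste0(prefix, "_junction.fastq"))
  fp <- file.path(dir, paste0(prefix, "_flank.fastq"))
  q <- function(seqs) Biostrings::BStringSet(strrep(lib$design$phred_char, nchar(seqs)))
  j <- Biostrings::DNAStringSet(lib$pairs$junction)
  names(j) <- paste0(lib$pairs$id, "/1")
  Biostrings::writeXStringSet(j, jp, format = "fastq", qualities = q(lib$pairs$junction))
  f <- Biostrings::DNAStringSet(lib$pairs$flank)
  names(f) <- paste0(lib$pairs$id, "/2")
  Biostrings::writeXStringSet(f, fp, format = "fastq", qualities = q(lib$pairs$flank))
  tp <- file.path(dir, paste0(prefix, "_truth.tsv"))
  utils::write.table(lib$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  yp <- file.path(dir, paste0(prefix, "_design.yaml"))
  d <- lib$design
  d$indexes <- as.list(d$indexes); d$proportions <- as.list(d$proportions)
  d$individuals <- as.list(d$individuals)
  yaml::write_yaml(unclass(d), yp)
  invisible(c(junction = jp, flank = fp, truth = tp, design = yp))
}

#' @rdname write_library_fastq
#' @param junction_fastq,flank_fastq Paths to the two lockstep FASTQ files.
#' @export
read_pair_fastq <- function(junction_fastq, flank_fastq) {
  j <- Biostrings::readDNAStringSet(junction_fastq, format = "fastq")
  f <- Biostrings::readDNAStringSet(flank_fastq, format = "fastq")
  if (length(j) != length(f))
    stop("junction and flank FASTQ files have different record counts")
  jid <- sub("/1$", "", sub(" .*", "", names(j)))
  fid <- sub("/2$", "", sub(" .*", "", names(f)))
  bad <- which(jid != fid)
  if (length(bad))
    stop("read pair files out of lockstep at record ", bad[1],
         ": '", jid[bad[1]], "' vs '", fid[bad[1]], "'")
  data.frame(id = jid, junction = as.character(j), flank = as.character(f),
             stringsAsFactors = FALSE)
}
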