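#' Evaluation statistics for targeted insertion scanning
#'
#' These functions implement the summary statistics used to evaluate the
#' assay. They return raw (unrounded) values; reports round rates to 3
#' significant figures and sensitivity to 1 decimal for display.
#'
#' @name metrics
NULL

#' Observed versus expected index proportions in a pooled library
#'
#' @param counts Named numeric vector of assigned read-pair counts per
#'   sample/index.
#' @param expected Intended pooling fractions (either proportions summing
#'   to 1 or percentages summing to 100), in the same order or with the
#'   same names.
#' @return Data frame (`sample`, `count`, `expected_pct`, `observed_pct`,
#'   `observed_pct_display`) with attribute `mean_abs_dev`, the mean
#'   absolute deviation in percentage points.
#' @export
index_proportions <- function(counts, expected) {
  stopifnot(length(counts) == length(expected))
  if (!is.null(names(expected)) && !is.null(names(counts)))
    expected <- expected[names(counts)]
  exp_pct <- if (abs(sum(expected) - 1) < 1e-6) 100 * expected else expected
  obs_pct <- 100 * counts / sum(counts)
  out <- data.frame(sample = names(counts) %||% seq_along(counts),
                    count = as.numeric(counts),
                    expected_pct = as.numeric(exp_pct),
                    observed_pct = as.numeric(obs_pct),
                    observed_pct_display = signif3(as.numeric(obs_pct)),
                    stringsAsFactors = FALSE)
  attr(out, "mean_abs_dev") <- mean(abs(out$observed_pct - out$expected_pct))
  out
}

#' False negative rate among putatively fixed loci
#'
#' @param n_missed Loci with no positive call in the sample.
#' @param n_total Putatively fixed loci assayed.
#' @return Percentage (raw; display at 3 significant figures).
#' @export
false_negative_rate <- function(n_missed, n_total) {
  stopifnot(n_missed >= 0, n_total > 0)
  100 * n_missed / n_total
}

#' Sensitivity adjusted for loci that are not truly fixed
#'
#' Of the putatively fixed loci missed in a sample, some are systematic
#' misses (flanks in duplicated regions; junctions lacking detectable
#' element sequence) and the remainder are only putative false negatives:
#' confirmatory genotyping shows that most of those are genuinely absent
#' insertions. The adjusted false-negative estimate is
#' `n_dup + n_no_motif + pcr_confirm_rate * n_putative_residual` (the
#' product kept unrounded), and sensitivity is the complement over
#' `n_total`.
#'
#' @param n_dup Misses in segmentally duplicated regions.
#' @param n_no_motif Misses lacking the element motif in the junction read.
#' @param n_putative_residual Remaining putative false-negative loci.
#' @param pcr_confirm_rate Fraction of residual misses confirmed as real
#'   false negatives by independent genotyping (in `[0, 1]`).
#' @param n_total Putatively fixed loci assayed.
#' @return List with `fn_estimate` and `sensitivity` (percent; display at
#'   1 decimal).
#' @export
adjusted_sensitivity <- function(n_dup, n_no_motif, n_putative_residual,
                                 pcr_confirm_rate, n_total) {
  stopifnot(pcr_confirm_rate >= 0, pcr_confirm_rate <= 1, n_total > 0)
  fn <- n_dup + n_no_motif + pcr_confirm_rate * n_putative_residual
  list(fn_estimate = fn, sensitivity = 100 * (n_total - fn) / n_total)
}

#' Specificity from confirmatory genotyping of positive calls
#'
#' @param n_false_pos Positive calls contradicted by confirmation.
#' @param n_pos_checked Positive calls checked.
#' @return Percentage.
#' @export
specificity <- function(n_false_pos, n_pos_checked) {
  stopifnot(n_pos_checked > 0, n_false_pos >= 0, n_false_pos <= n_pos_checked)
  100 * (1 - n_false_pos / n_pos_checked)
}

#' Replication failure rate between technical replicates
#'
#' The average, over the two replicates, of the fraction of loci (positive
#' in either replicate) that each replicate missed:
#' `100 * (miss_a + miss_b) / (2 * n_union)`. Symmetric in the two
#' replicates.
#'
#' @param n_union Loci positive in either replicate.
#' @param miss_a,miss_b Loci missed by each replicate.
#' @return Percentage (raw; display at 3 significant figures).
#' @export
replication_failure_rate <- function(n_union, miss_a, miss_b) {
  stopifnot(n_union > 0, miss_a >= 0, miss_b >= 0,
            miss_a <= n_union, miss_b <= n_union)
  100 * (miss_a + miss_b) / (2 * n_union)
}

#' Per-locus coverage overdispersion
#'
#' Amplified fragment libraries show per-locus read-pair count variances
#' well above the Poisson expectation (variance equal to the mean); the
#' variance-to-mean ratio quantifies that overdispersion.
#'
#' @param counts Per-locus read-pair counts for one sample.
#' @return List with `mean`, `variance` (unbiased) and `ratio`
#'   (variance/mean).
#' @export
coverage_dispersion <- function(counts) {
  m <- mean(counts)
  v <- stats::var(counts)
  list(mean = m, variance = v, ratio = if (m > 0) v / m else NA_real_)
}

#' Additive locus accounting across annotation classes
#'
#' @param n_known_target Loci annotated as reference elements of the target
#'   subfamily.
#' @param n_nonspecific Loci annotated as elements of other families.
#' @param n_novel Loci absent from the reference.
#' @return List with `total` (all identified loci) and
#'   `target_subfamily_total` (known target plus novel, the loci attributed
#'   to the assayed subfamily).
#' @export
locus_class_totals <- function(n_known_target, n_nonspecific, n_novel) {
  list(total = n_known_target + n_nonspecific + n_novel,
       target_subfamily_total = n_known_target + n_novel)
}

#' Score called genotypes against simulation truth
#'
#' Builds the per-(locus, sample) confusion matrix of a called
#' presence/absence matrix against the simulated cohort: a cell is truth
#' positive when the individual carries at least one copy of the
#' insertion. Called loci are matched to truth loci by position (within
#' `tol` bp, same chromosome); called loci matching no truth locus count
#' as false positives in every sample where they are called present.
#' Sporadic non-specific (decoy) emissions are not insertion genotypes and
#' are excluded from the truth universe.
#'
#' @param genotypes Output of [genotype_matrix()].
#' @param cohort The simulated `me_cohort`.
#' @param libraries A list of `me_library` objects (to map samples to
#'   individuals).
#' @param tol Locus matching tolerance in bp.
#' @return List with `per_sample` (data frame: sample, TP, FP, FN, TN,
#'   sensitivity, specificity, fdr) and `overall` (the same, pooled).
#' @export
evaluate_against_truth <- function(genotypes, cohort, libraries, tol = 3) {
  if (inherits(libraries, "me_library")) libraries <- list(libraries)
  sample_to_ind <- do.call(c, lapply(libraries, function(l) l$design$individuals))
  sample_to_ind <- sample_to_ind[!duplicated(names(sample_to_ind))]

  truth_loci <- cohort$loci
  called <- split_locus_id(rownames(genotypes$presence))
  match_idx <- rep(NA_integer_, nrow(called))
  for (i in seq_len(nrow(called))) {
    sel <- which(truth_loci$chrom == called$chrom[i] &
                   abs(truth_loci$endpoint - called$pos[i]) <= tol)
    if (length(sel))
      match_idx[i] <- sel[which.min(abs(truth_loci$endpoint[sel] - called$pos[i]))]
  }

  # called loci explained by sporadic non-specific amplification of decoy
  # elements (real reference elements, not insertion genotypes) leave the
  # evaluation universe entirely
  nonspec <- do.call(rbind, lapply(libraries, function(l) {
    if (is.null(l$loci)) return(NULL)
    l$loci[l$loci$class == "nonspecific", c("chrom", "endpoint")]
  }))
  excluded <- rep(FALSE, nrow(called))
  if (!is.null(nonspec) && nrow(nonspec)) {
    for (i in which(is.na(match_idx))) {
      excluded[i] <- any(nonspec$chrom == called$chrom[i] &
                           abs(nonspec$endpoint - called$pos[i]) <= tol)
    }
  }

  samples <- colnames(genotypes$presence)
  per <- lapply(samples, function(s) {
    ind <- sample_to_ind[[s]] %||% s
    truth_pos <- cohort$genotypes[ind, ] > 0
    called_pos_truth <- rep(FALSE, nrow(truth_loci))
    hit <- !is.na(match_idx)
    called_pos_truth[match_idx[hit]] <- genotypes$presence[hit, s] > 0
    tp <- sum(truth_pos & called_pos_truth)
    fn <- sum(truth_pos & !called_pos_truth)
    tn <- sum(!truth_pos & !called_pos_truth)
    fp <- sum(!truth_pos & called_pos_truth) +
      sum(genotypes$presence[!hit & !excluded, s] > 0)  # outside the truth set
    data.frame(sample = s, TP = tp, FP = fp, FN = fn, TN = tn,
               sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
               fdr = if (tp + fp > 0) 100 * fp / (tp + fp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  tot <- colSums(per[, c("TP", "FP", "FN", "TN")])
  overall <- data.frame(
    sample = "overall", TP = tot["TP"], FP = tot["FP"], FN = tot["FN"],
    TN = tot["TN"],
    sensitivity = 100 * tot["TP"] / (tot["TP"] + tot["FN"]),
    specificity = 100 * tot["TN"] / (tot["TN"] + tot["FP"]),
    fdr = if (tot["TP"] + tot["FP"] > 0)
      100 * tot["FP"] / (tot["TP"] + tot["FP"]) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_sample = per, overall = overall)
}
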