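#' Simulate insertion genotypes for a cohort of individuals
#'
#' Assigns every assayable locus to one of three classes and draws per-locus
#' copy-number genotypes (0, 1 or 2):
#'
#' * *fixed*: reference target elements present in two copies in everyone
#'   (the class used to estimate false-negative rates);
#' * *polymorphic*: segregating insertions; copies drawn binomially
#'   (Hardy-Weinberg) at an allele frequency drawn per locus from
#'   `allele_freq`;
#' * *singleton*: insertions carried, in one copy, by exactly one individual
#'   (rare, de novo or non-germline insertions).
#'
#' Reference target elements are split into fixed and polymorphic by
#' `fixed_fraction`. `n_novel` additional loci absent from the reference are
#' placed in unoccupied sequence (these are detected through the trimmed
#' junction-mapping path); a fraction `singleton_rate` of them are
#' singletons, the rest polymorphic.
#'
#' @param ref An `me_reference` from [make_reference()].
#' @param n_individuals Number of individuals (labelled `A`, `B`, ... unless
#'   `individuals` is given).
#' @param fixed_fraction Fraction of reference target loci that are fixed.
#' @param allele_freq Allele frequency for polymorphic loci: a single number
#'   or a range `c(lo, hi)` sampled uniformly per locus. Must lie in [0, 1].
#' @param singleton_rate Fraction of novel loci that are singletons.
#' @param n_novel Number of non-reference insertion loci.
#' @param individuals Optional character vector of sample labels.
#' @param novel_margin Minimum clearance (bp) between a novel insertion site
#'   and any planted feature or chromosome end.
#' @param seed Integer seed.
#' @return An object of class `me_cohort`: list with `individuals`, `loci`
#'   (data frame: locus identifier, position, strand, class, whether present
#'   in the reference, allele frequency, TSD and poly-A lengths) and
#'   `genotypes` (individuals x loci integer matrix of copy numbers).
#' @export
simulate_cohort <- function(ref, n_individuals,
                            fixed_fraction = 1,
                            allele_freq = c(0.1, 0.9),
                            singleton_rate = 0,
                            n_novel = 0,
                            individuals = NULL,
                            novel_margin = 800,
                            seed = 1) {
  stopifnot(inherits(ref, "me_reference"))
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (any(allele_freq < 0) || any(allele_freq > 1))
    stop("allele frequencies must lie in [0, 1]")
  if (fixed_fraction < 0 || fixed_fraction > 1)
    stop("fixed_fraction must lie in [0, 1]")
  if (singleton_rate < 0 || singleton_rate > 1)
    stop("singleton_rate must lie in [0, 1]")
  if (is.null(individuals)) {
    individuals <- make.unique(rep(LETTERS, length.out = n_individuals), sep = "")
  }
  stopifnot(length(individuals) == n_individuals)

  tgt <- ref$me_track[ref$me_track$family == "AluYb-like", , drop = FALSE]
  chrom_lengths <- ref$params$chrom_lengths

  with_seed(seed, {
    n_ref <- nrow(tgt)
    n_fixed <- round(fixed_fraction * n_ref)
    fixed_idx <- if (n_ref > 0) sort(sample(n_ref, n_fixed)) else integer(0)
    ref_class <- rep("polymorphic", n_ref)
    ref_class[fixed_idx] <- "fixed"

    loci <- data.frame(
      locus_id = tgt$locus_id, chrom = tgt$chrom, strand = tgt$strand,
      anchor = tgt$anchor, endpoint = tgt$endpoint,
      in_reference = TRUE, class = ref_class,
      stringsAsFactors = FALSE
    )

    if (n_novel > 0) {
      novel <- place_novel_loci(ref, n_novel, novel_margin)
      n_single <- round(singleton_rate * n_novel)
      cls <- rep("polymorphic", n_novel)
      if (n_single > 0) cls[sample(n_novel, n_single)] <- "singleton"
      novel$in_reference <- FALSE
      novel$class <- cls
      loci <- rbind(loci, novel[, names(loci)])
    }

    n_loci <- nrow(loci)
    freq <- rep(NA_real_, n_loci)
    poly <- loci$class == "polymorphic"
    if (any(poly)) {
      freq[poly] <- if (length(allele_freq) == 1) allele_freq else
        stats::runif(sum(poly), allele_freq[1], allele_freq[2])
    }
    loci$allele_freq <- freq
    loci$tsd_len <- ref$params$tsd_len
    loci$polya_len <- ref$params$polya_len

    g <- matrix(0L, nrow = n_individuals, ncol = n_loci,
                dimnames = list(individuals, loci$locus_id))
    for (j in seq_len(n_loci)) {
      g[, j] <- switch(loci$class[j],
        fixed = rep(2L, n_individuals),
        polymorphic = as.integer(stats::rbinom(n_individuals, 2, freq[j])),
        singleton = { v <- integer(n_individuals)
                      v[sample(n_individuals, 1)] <- 1L
                      v })
    }

    structure(list(individuals = individuals, loci = loci, genotypes = g,
                   params = list(fixed_fraction = fixed_fraction,
                                 allele_freq = allele_freq,
                                 singleton_rate = singleton_rate,
                                 n_novel = n_novel, seed = seed)),
              class = "me_cohort")
  })
}

# Draw positions for non-reference insertions, keeping clear of planted
# elements, duplicated blocks, chromosome ends and each other.
place_novel_loci <- function(ref, n_novel, margin) {
  chrom_lengths <- ref$params$chrom_lengths
  occupied <- list()
  add_iv <- function(ch, lo, hi) occupied[[length(occupied) + 1]] <<- c(match(ch, names(chrom_lengths)), lo, hi)
  tr <- ref$me_track
  for (i in seq_len(nrow(tr))) add_iv(tr$chrom[i], tr$start[i] - margin, tr$end[i] + margin)
  db <- ref$duplicated_blocks
  for (i in seq_len(nrow(db))) {
    add_iv(db$chrom_src[i], db$src_start[i] - margin, db$src_end[i] + margin)
    add_iv(db$chrom_copy[i], db$copy_start[i] - margin, db$copy_end[i] + margin)
  }
  occ <- if (length(occupied)) do.call(rbind, occupied) else matrix(numeric(0), ncol = 3)

  out <- vector("list", n_novel)
  placed <- matrix(numeric(0), ncol = 2)  # chrom idx, pos
  tries <- 0
  for (k in seq_len(n_novel)) {
    repeat {
      tries <- tries + 1
      if (tries > 1000 * n_novel)
        stop("could not place novel insertion loci; reference too crowded for n_novel requested")
      ci <- sample(length(chrom_lengths), 1, prob = chrom_lengths)
      p <- sample(seq(margin + 1L, chrom_lengths[ci] - margin), 1)
      clash <- (nrow(occ) > 0 && any(occ[, 1] == ci & p >= occ[, 2] & p <= occ[, 3])) ||
        (nrow(placed) > 0 && any(placed[, 1] == ci & abs(placed[, 2] - p) < margin))
      if (!clash) break
    }
    placed <- rbind(placed, c(ci, p))
    strand <- sample(c("+", "-"), 1)
    ch <- names(chrom_lengths)[ci]
    endpoint <- if (strand == "+") p - 19L else p + 20L
    out[[k]] <- data.frame(locus_id = locus_id(ch, endpoint), chrom = ch,
                           strand = strand, anchor = as.integer(p),
                           endpoint = as.integer(endpoint),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.me_cohort <- function(x, ...) {
  cat("Simulated cohort:", length(x$individuals), "individual(s),",
      nrow(x$loci), "insertion loci\n")
  print(table(x$loci$class))
  invisible(x)
}
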