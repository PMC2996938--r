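#' Default pipeline configuration
#'
#' A single nested list drives the whole pipeline. Every analysis threshold
#' defaults to the value the method was designed around: single-mismatch
#' index correction, the three quality rules (85% one base, more than two
#' 'N's, oligo alignment score over 60), pair filters (proper orientation,
#' no zero mapping quality, at most 3 mismatched/unmatched bases), junction
#' endpoint merging within 3 bp, minimum locus support of 10 pairs, a 50%
#' junction-motif fraction, and the putatively-fixed-locus criteria
#' (224 +/- 15 bp primer spacing, clean 3' ends). The configuration
#' round-trips through YAML unchanged.
#'
#' @param ... Named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return Configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = NULL,
    experiment = "exp1",
    simulate = NULL,
    inputs = list(junction_fastq = NULL, flank_fastq = NULL,
                  reference_fasta = NULL, track_bed = NULL,
                  index_table = NULL),
    qc = list(match = 5, mismatch = -4, threshold = 60,
              max_base_fraction = 0.85, max_n = 2),
    demux = list(read_len = 36L),
    map = list(trim_len = 16L, max_mismatch = 3L, insert_min = 100L,
               insert_max = 1000L, max_edit = 3L),
    motif = list(exact_len = 10L, score_min = 45, match = 5, mismatch = -4,
                 gap_open = 64, gap_ext = 8),
    call = list(merge_tol = 3L, min_support = 10L, min_me_fraction = 0.5,
                min_pairs_per_sample = 1L),
    annotate = list(target_family = "AluYb-like", position_tol = 3L,
                    pbs_match = 1, pbs_mismatch = -3,
                    seq_min = 23, amp_min = 16,
                    spacing = 224L, spacing_tol = 15L, max_3p_mismatch = 0L)
  )
  merge_config(cfg, list(...))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[nm] <- override[nm]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> demultiplex/QC -> dual-mode mapping
#' and pair filtering -> junction-endpoint locus calling -> annotation ->
#' metrics, from a single configuration. Identical configuration and seed
#' give identical outputs. When `config$outdir` is set, the locus list,
#' genotype matrix and a JSON manifest are written there.
#'
#' Inputs are either simulated in place (set `config$simulate`; see
#' Details) or read from files named under `config$inputs`. Pre-built
#' objects can also be passed directly, which is how the stages compose in
#' scripts and tests.
#'
#' `config$simulate` is a list with elements `reference` (arguments for
#' [make_reference()]), `cohort` (arguments for [simulate_cohort()]) and
#' `design` (arguments for [library_design()]); the global `config$seed`
#' seeds any of them that do not set their own.
#'
#' @param config Configuration from [default_config()].
#' @param reference,cohort,library Optional pre-built objects overriding
#'   `config$simulate` / `config$inputs`.
#' @return Object of class `me_manifest`: list with `counters`
#'   (stage-by-stage read-pair accounting), `called` (loci and support),
#'   `genotypes`, `classes` (annotation class per locus), `metrics`
#'   (index-proportion report, coverage dispersion, and truth-based
#'   evaluation when simulating), `config`, and output `paths`.
#' @export
run_all <- function(config = default_config(), reference = NULL,
                    cohort = NULL, library = NULL) {
  cfg <- config
  truth_available <- FALSE

  if (!is.null(library)) {
    lib <- library
    ref <- reference
    truth_available <- !is.null(cohort)
  } else if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    ref_args <- sim$reference %||% list()
    if (is.null(ref_args$seed)) ref_args$seed <- cfg$seed
    ref <- reference %||% do.call(make_reference, ref_args)
    coh_args <- sim$cohort %||% list(n_individuals = 1)
    if (is.null(coh_args$seed)) coh_args$seed <- cfg$seed + 1L
    coh_args <- c(list(ref = ref), coh_args)
    cohort <- do.call(simulate_cohort, coh_args)
    des_args <- sim$design
    if (is.null(des_args$seed)) des_args$seed <- cfg$seed + 2L
    if (is.null(des_args$experiment)) des_args$experiment <- cfg$experiment
    design <- do.call(library_design, des_args)
    lib <- simulate_library(ref, cohort, design)
    truth_available <- TRUE
  } else {
    inp <- cfg$inputs
    if (is.null(inp$junction_fastq) || is.null(inp$flank_fastq) ||
        is.null(inp$reference_fasta) || is.null(inp$index_table))
      stop("config error: either 'simulate' or all of inputs$junction_fastq, ",
           "inputs$flank_fastq, inputs$reference_fasta, inputs$index_table ",
           "must be provided")
    for (p in unlist(inp)) if (!is.null(p) && !file.exists(p))
      stop("config error: input file does not exist: ", p)
    pairs <- read_pair_fastq(inp$junction_fastq, inp$flank_fastq)
    sequences <- Biostrings::readDNAStringSet(inp$reference_fasta)
    names(sequences) <- sub(" .*", "", names(sequences))
    track <- if (!is.null(inp$track_bed)) read_track_bed(inp$track_bed)
    idx <- utils::read.table(inp$index_table, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    ref <- list(sequences = sequences, me_track = track,
                polymorphic_known = character(0))
    class(ref) <- "me_reference"
    lib <- list(pairs = pairs,
                design = list(indexes = stats::setNames(idx$index, idx$sample),
                              proportions = NULL),
                experiment = cfg$experiment)
  }
  if (!is.null(cfg$outdir))
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  # demultiplex + quality screen
  scoring <- qc_scoring(cfg$qc$match, cfg$qc$mismatch, cfg$qc$threshold)
  dm <- demux_stream(lib$pairs, lib$design$indexes, scoring = scoring,
                     read_len = cfg$demux$read_len,
                     experiment = lib$experiment %||% cfg$experiment)

  # dual-mode mapping and pair filters
  mapped <- map_read_pairs(dm$pairs, ref,
                           trim_len = cfg$map$trim_len,
                           max_mismatch = cfg$map$max_mismatch,
                           insert_min = cfg$map$insert_min,
                           insert_max = cfg$map$insert_max,
                           max_edit = cfg$map$max_edit)
  kept <- mapped[mapped$keep, , drop = FALSE]

  # junction motif detection on the leading element segment
  mp <- me_motif_params(exact_len = cfg$motif$exact_len,
                        score_min = cfg$motif$score_min,
                        match = cfg$motif$match, mismatch = cfg$motif$mismatch,
                        gap_open = cfg$motif$gap_open,
                        gap_ext = cfg$motif$gap_ext)
  jfirst <- substr(dm$pairs$junction[mapped$keep], 1, cfg$map$trim_len)
  me_det <- detect_me_sequence(jfirst, mp)

  # locus calling
  ep <- junction_endpoint(kept)
  ep$me_detected <- me_det
  grouped <- group_endpoints(ep, merge_tol = cfg$call$merge_tol)
  called <- call_loci(grouped, min_support = cfg$call$min_support,
                      min_me_fraction = cfg$call$min_me_fraction)
  genotypes <- genotype_matrix(called,
                               min_pairs_per_sample = cfg$call$min_pairs_per_sample,
                               samples = names(lib$design$indexes))

  # annotation
  classes <- NULL
  fixed <- NULL
  if (!is.null(ref$me_track)) {
    seq_sites <- scan_pbs(ref, me_seq_primer(), cfg$annotate$pbs_match,
                          cfg$annotate$pbs_mismatch, cfg$annotate$seq_min,
                          role = "SEQUENCING")
    seq_sites <- link_pbs_to_track(seq_sites, ref$me_track)
    classes <- classify_loci(called$loci, seq_sites,
                             target_family = cfg$annotate$target_family,
                             position_tol = cfg$annotate$position_tol)
    amp_sites <- scan_pbs(ref, me_amp_primer(), cfg$annotate$pbs_match,
                          cfg$annotate$pbs_mismatch, cfg$annotate$amp_min,
                          role = "AMPLIFICATION")
    fixed <- select_fixed_loci(
      amp_sites, seq_sites,
      fixed_locus_params(amp_min = cfg$annotate$amp_min,
                         seq_min = cfg$annotate$seq_min,
                         spacing = cfg$annotate$spacing,
                         spacing_tol = cfg$annotate$spacing_tol,
                         max_3p_mismatch = cfg$annotate$max_3p_mismatch),
      polymorphic_known = ref$polymorphic_known %||% character(0),
      position_tol = cfg$annotate$position_tol)
  }

  # accounting
  counters <- c(dm$counters, list(
    mapped_ok = sum(mapped$keep),
    motif_positive = sum_usable_motif(dm, mapped, cfg, mp),
    final_support = sum(called$loci$total_support)))

  # metrics
  met <- list()
  sample_counts <- table(factor(dm$pairs$sample,
                                levels = names(lib$design$indexes)))
  if (!is.null(lib$design$proportions)) {
    met$index_proportions <- index_proportions(
      stats::setNames(as.numeric(sample_counts), names(sample_counts)),
      lib$design$proportions)
  }
  if (ncol(genotypes$counts) > 0 && nrow(genotypes$counts) > 1) {
    met$coverage_dispersion <- lapply(
      stats::setNames(colnames(genotypes$counts), colnames(genotypes$counts)),
      function(s) coverage_dispersion(genotypes$counts[, s]))
  }
  if (truth_available) {
    met$evaluation <- evaluate_against_truth(genotypes, cohort, lib,
                                             tol = cfg$annotate$position_tol)
  }

  manifest <- structure(list(
    counters = counters, called = called, genotypes = genotypes,
    classes = classes, fixed_loci = fixed, metrics = met,
    reasons = table(mapped$reason),
    config = cfg, paths = NULL), class = "me_manifest")

  if (!is.null(cfg$outdir)) {
    lp <- file.path(cfg$outdir, "loci.tsv")
    gp <- file.path(cfg$outdir, "genotypes.tsv")
    write_locus_tsv(called, genotypes, lp, gp)
    mp_path <- file.path(cfg$outdir, "manifest.json")
    jsonlite::write_json(list(counters = counters,
                              n_loci = nrow(called$loci),
                              reasons = as.list(manifest$reasons),
                              config = cfg),
                         mp_path, auto_unbox = TRUE, null = "null", digits = NA)
    manifest$paths <- c(loci = lp, genotypes = gp, manifest = mp_path)
  }
  manifest
}

# usable pairs whose junction read carries detectable element sequence
sum_usable_motif <- function(dm, mapped, cfg, mp) {
  if (nrow(dm$pairs) == 0) return(0L)
  jf <- substr(dm$pairs$junction, 1, cfg$map$trim_len)
  sum(detect_me_sequence(jf, mp))
}

#' Read-pair accounting table
#'
#' Summarises the filter cascade in the layout used to report sequencing
#' yield: total pairs, pairs with both reads of high quality, the three
#' quality-defect rows (mutually exclusive, in rule order), high-quality
#' pairs with a valid index, those whose junction read carries the element
#' motif, and pairs supporting a locus in the final results, each with its
#' percentage of the total.
#'
#' @param manifest An `me_manifest` from [run_all()].
#' @return Data frame with `row`, `n` and `pct` columns.
#' @export
report_table1 <- function(manifest) {
  ct <- manifest$counters
  rows <- c("Total read pairs",
            "Both reads of high quality (not a, b or c)",
            "(a) Either read is > 85% one base",
            "(b) Either read has > 2 'N' base calls",
            "(c) Oligo sequence detected in either read",
            "Both reads high quality, index valid",
            "Junction read has element motif; high quality; index valid",
            "Supports an insertion locus in the final results")
  n <- c(ct$total, ct$high_quality, ct$rule_a, ct$rule_b, ct$rule_c,
         ct$index_valid, ct$motif_positive, ct$final_support)
  pct <- if (ct$total > 0) 100 * n / ct$total else rep(0, length(n))
  data.frame(row = rows, n = as.integer(n), pct = signif3(pct),
             stringsAsFactors = FALSE)
}

#' @export
print.me_manifest <- function(x, ...) {
  cat("Pipeline manifest\n")
  print(report_table1(x))
  cat("\nLoci called:", nrow(x$called$loci), "\n")
  if (!is.null(x$classes) && nrow(x$classes))
    print(table(x$classes$class))
  invisible(x)
}
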