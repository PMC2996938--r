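# Shared fixtures and independent oracle implementations. Fixtures are
# cached per test run so multiple files can reuse the same small simulation.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

paper_indexes <- c(A = "ACCAT", B = "TATTC", C = "GGTTA", D = "CGCTA",
                   D2 = "TTGAT")

# small reference + cohort + library exercising every locus class
small_scenario <- function() {
  fixture("small_scenario", function() {
    ref <- make_reference(c(chr1 = 300000L), n_target = 10, n_decoy = 5,
                          n_duplication = 2, n_polymorphic_known = 2,
                          seed = 11)
    cohort <- simulate_cohort(ref, 3, fixed_fraction = 0.8, allele_freq = 0.5,
                              singleton_rate = 0.5, n_novel = 4, seed = 5)
    design <- library_design(c(A = "ACCAT", B = "TATTC", C = "GGTTA"),
                             total_pairs = 1500, error_rate = 0.001,
                             nonspecific_rate = 40, seed = 2)
    lib <- simulate_library(ref, cohort, design)
    dm <- demux_stream(lib$pairs, design$indexes)
    mapped <- map_read_pairs(dm$pairs, ref)
    list(ref = ref, cohort = cohort, design = design, lib = lib,
         dm = dm, mapped = mapped)
  })
}

# brute-force end-to-end aligner: all offsets, both strands, <= mm subs
brute_map <- function(read, seqs, max_mismatch = 3) {
  out <- list()
  for (ori in c("+", "-")) {
    q <- if (ori == "+") read else revcomp(read)
    qc <- strsplit(q, "")[[1]]
    len <- length(qc)
    for (ch in names(seqs)) {
      sc <- strsplit(seqs[[ch]], "")[[1]]
      if (length(sc) < len) next
      for (p in seq_len(length(sc) - len + 1)) {
        mm <- sum(qc != sc[p:(p + len - 1)])
        if (mm <= max_mismatch)
          out[[length(out) + 1]] <- data.frame(chrom = ch, pos = p,
                                               strand = ori, mismatches = mm,
                                               stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0), pos = integer(0),
                                      strand = character(0),
                                      mismatches = integer(0)))
  do.call(rbind, out)
}

# brute-force endpoint grouping: exact stacks, then absorb singletons into
# the most numerous neighbour within tol (nearer wins ties, then lower pos)
brute_group <- function(pos, tol = 3) {
  tab <- table(pos)
  p <- as.integer(names(tab)); n <- as.integer(tab)
  group <- stats::setNames(p, p)
  for (i in which(n == 1)) {
    d <- abs(p - p[i])
    cand <- which(d <= tol & d > 0 & n > 1)
    if (!length(cand)) next
    cand <- cand[order(-n[cand], d[cand], p[cand])]
    group[as.character(p[i])] <- p[cand[1]]
  }
  unname(group[as.character(pos)])
}

# all-offsets ungapped scan oracle (vectorised Kadane over the footprint)
brute_scan <- function(subject, pattern, match = 1, mismatch = -3,
                       min_score = 16) {
  sc <- strsplit(subject, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  m <- length(pc); n <- length(sc)
  if (n < m) return(data.frame(pos = integer(0), score = numeric(0)))
  n_off <- n - m + 1
  run <- numeric(n_off); best <- numeric(n_off)
  for (j in seq_len(m)) {
    s <- ifelse(sc[j:(j + n_off - 1)] == pc[j], match, mismatch)
    run <- pmax(run + s, 0)
    best <- pmax(best, run)
  }
  keep <- best >= min_score
  data.frame(pos = which(keep), score = best[keep])
}

random_read <- function(n, len = 36) {
  vapply(seq_len(n), function(i) random_dna(len), character(1))
}

random_dna <- function(n) mescan:::random_dna(n)
hamming <- function(a, b) mescan:::hamming(a, b)

with_seed_dna <- function(seed, len) {
  mescan:::with_seed(seed, mescan:::random_dna(len))
}

with_seed_list <- function(seed, f) mescan:::with_seed(seed, f())
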