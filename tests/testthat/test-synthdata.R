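test_that("make_reference plants the requested features deterministically", {
  ref <- make_reference(c(chr1 = 100000L), n_target = 10, n_decoy = 0,
                        n_duplication = 0, seed = 7)
  expect_equal(sum(ref$me_track$family == "AluYb-like"), 10)
  expect_equal(nrow(ref$duplicated_blocks), 0)

  ref2 <- make_reference(c(chr1 = 100000L), n_target = 10, n_decoy = 0,
                         n_duplication = 0, seed = 7)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_reference(ref, fasta = f1); write_reference(ref2, fasta = f2)
  expect_identical(readLines(f1), readLines(f2))

  # every element interval lies within its chromosome
  expect_true(all(ref$me_track$start >= 1))
  expect_true(all(ref$me_track$end <= 100000L))
})

test_that("target elements carry exact primer binding sites at fixed offsets", {
  ref <- make_reference(c(chr1 = 60000L), n_target = 3, seed = 4)
  lay <- mescan:::element_layout()
  for (i in seq_len(3)) {
    tr <- ref$me_track[i, ]
    es <- as.character(Biostrings::subseq(ref$sequences[[tr$chrom]],
                                          tr$start, tr$end))
    if (tr$strand == "-") es <- revcomp(es)
    expect_identical(substr(es, lay$seq_pbs[1], lay$seq_pbs[2]),
                     revcomp(me_seq_primer()))
    expect_identical(substr(es, lay$amp_pbs[1], lay$amp_pbs[2]),
                     revcomp(me_amp_primer()))
  }
})

test_that("every decoy has >= 1 mismatch in the 3' 10 bp of its sequencing PBS", {
  ref <- make_reference(c(chr1 = 200000L), n_target = 2, n_decoy = 8, seed = 9)
  lay <- mescan:::element_layout()
  dec <- ref$me_track[ref$me_track$family == "AluS-like", ]
  expect_equal(nrow(dec), 8)
  expected <- substr(revcomp(me_seq_primer()), 1,
                     lay$seq_pbs_3p10[2] - lay$seq_pbs_3p10[1] + 1)
  for (i in seq_len(nrow(dec))) {
    es <- as.character(Biostrings::subseq(ref$sequences[[dec$chrom[i]]],
                                          dec$start[i], dec$end[i]))
    if (dec$strand[i] == "-") es <- revcomp(es)
    observed <- substr(es, lay$seq_pbs_3p10[1], lay$seq_pbs_3p10[2])
    expect_gte(hamming(observed, expected), 1)
  }
})

test_that("infeasible packing fails with an explicit constraint error", {
  expect_error(make_reference(c(chr1 = 5000L), n_target = 10, seed = 1),
               "infeasible packing")
})

test_that("cohort genotypes follow the configured locus classes", {
  ref <- make_reference(c(chr1 = 100000L), n_target = 10, seed = 3)
  co <- simulate_cohort(ref, 4, fixed_fraction = 1, seed = 2)
  expect_true(all(co$genotypes == 2L))

  co2 <- simulate_cohort(ref, 4, fixed_fraction = 1, singleton_rate = 1,
                         n_novel = 1, seed = 8)
  single <- co2$loci$locus_id[co2$loci$class == "singleton"]
  expect_length(single, 1)
  expect_equal(sum(co2$genotypes[, single] > 0), 1)

  expect_error(simulate_cohort(ref, 4, allele_freq = 1.2, fixed_fraction = 0),
               "frequencies")
})

test_that("polymorphic carrier fraction matches the binomial expectation", {
  ref <- make_reference(c(chr1 = 1200000L), n_target = 1000, seed = 6,
                        margin = 300)
  co <- simulate_cohort(ref, 1, fixed_fraction = 0, allele_freq = 0.5, seed = 1)
  carrier <- mean(co$genotypes[1, ] > 0)
  p <- 0.75  # P(>=1 copy) at f = 0.5
  expect_lt(abs(carrier - p), 3 * sqrt(p * (1 - p) / 1000))
})

test_that("library conservation: emitted pairs equal the truth counts exactly", {
  sc <- small_scenario()
  expect_identical(nrow(sc$lib$pairs), sum(sc$lib$counts))
  # per-sample conservation
  per_sample <- table(sc$lib$truth$sample)
  expect_equal(as.integer(per_sample[colnames(sc$lib$counts)]),
               unname(colSums(sc$lib$counts)))
})

test_that("error-free homozygous locus yields one identical junction 36-mer", {
  ref <- make_reference(c(chr1 = 50000L), n_target = 1, seed = 12)
  co <- simulate_cohort(ref, 1, fixed_fraction = 1, seed = 1)
  de <- library_design(c(A = "ACCAT"), proportions = c(A = 1), error_rate = 0,
                       pairs_per_locus = 10, seed = 3)
  lib <- simulate_library(ref, co, de)
  expect_equal(nrow(lib$pairs), 10)
  expect_length(unique(lib$pairs$junction), 1)
  expect_equal(nchar(lib$pairs$junction[1]), 36)
  expect_true(startsWith(lib$pairs$junction[1], me_motif()))
  # flank reads: index + T + 30 nt genomic
  expect_true(all(substr(lib$pairs$flank, 1, 6) == "ACCATT"))
  expect_true(all(nchar(lib$pairs$flank) == 36))
})

test_that("sample absent from the cohort is an error", {
  ref <- make_reference(c(chr1 = 50000L), n_target = 1, seed = 12)
  co <- simulate_cohort(ref, 1, individuals = "A", seed = 1)
  de <- library_design(c(Z = "ACCAT"), proportions = c(Z = 1))
  expect_error(simulate_library(ref, co, de), "absent from the cohort")
})

test_that("negative binomial coverage reproduces the configured overdispersion", {
  ref <- make_reference(c(chr1 = 700000L), n_target = 500, seed = 15,
                        margin = 500)
  co <- simulate_cohort(ref, 1, fixed_fraction = 1, seed = 1)
  de <- library_design(c(A = "ACCAT"), proportions = c(A = 1),
                       total_pairs = 15000, dispersion = 10, error_rate = 0,
                       seed = 4)
  lib <- simulate_library(ref, co, de)
  disp <- coverage_dispersion(lib$counts[, "A"])
  expect_gte(disp$ratio, 5)
})

test_that("mirrored references give mirrored junction reads (strand correctness)", {
  L <- 50000L
  rA <- make_reference(c(chr1 = L), n_target = 1, seed = 8,
                       target_positions = data.frame(chrom = "chr1",
                                                     start = 20000L,
                                                     strand = "+"))
  elen <- nchar(element_consensus())
  rB <- make_reference(c(chr1 = L), n_target = 1, seed = 8,
                       target_positions = data.frame(chrom = "chr1",
                                                     start = L - (20000L + elen - 1L) + 1L,
                                                     strand = "-"))
  rB$sequences <- Biostrings::reverseComplement(rA$sequences)
  names(rB$sequences) <- "chr1"
  cA <- simulate_cohort(rA, 1, seed = 2)
  cB <- simulate_cohort(rB, 1, seed = 2)
  de <- library_design(c(A = "ACCAT"), proportions = c(A = 1), error_rate = 0,
                       pairs_per_locus = 15, seed = 6)
  lA <- simulate_library(rA, cA, de)
  lB <- simulate_library(rB, cB, de)
  expect_identical(sort(lA$pairs$junction), sort(lB$pairs$junction))
})

test_that("library FASTQ output is deterministic and round-trips", {
  ref <- make_reference(c(chr1 = 50000L), n_target = 2, seed = 5)
  co <- simulate_cohort(ref, 2, seed = 7)
  de <- library_design(c(A = "ACCAT", B = "TATTC"), total_pairs = 100, seed = 9)
  lib <- simulate_library(ref, co, de)
  d1 <- file.path(tempdir(), "lib1"); d2 <- file.path(tempdir(), "lib2")
  p1 <- write_library_fastq(lib, d1)
  p2 <- write_library_fastq(simulate_library(ref, co, de), d2)
  expect_identical(readLines(p1[["junction"]]), readLines(p2[["junction"]]))
  expect_identical(readLines(p1[["flank"]]), readLines(p2[["flank"]]))
  back <- read_pair_fastq(p1[["junction"]], p1[["flank"]])
  expect_identical(back$junction, lib$pairs$junction)
  expect_identical(back$flank, lib$pairs$flank)
})
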