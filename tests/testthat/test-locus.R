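test_that("junction endpoint accounts for strand and CIGAR reference span", {
  al <- data.frame(j_chrom = "chr1",
                   j_pos = c(1001L, 1001L, 1017L, 5000L),
                   j_strand = c("+", "+", "+", "-"),
                   j_cigar = c("36M", "10M2D26M", "20M", "36M"),
                   stringsAsFactors = FALSE)
  ep <- junction_endpoint(al)
  expect_equal(ep$pos, c(1036L, 1038L, 1036L, 5000L))
  expect_error(junction_endpoint(data.frame(j_chrom = "c", j_pos = 1L,
                                            j_strand = "+", j_cigar = "36I")),
               "zero reference bases")
})

test_that("intact and trimmed mappings of the same fragment share an endpoint", {
  sc <- small_scenario()
  kept <- sc$mapped[sc$mapped$keep, ]
  ep <- junction_endpoint(kept)
  truth <- sc$lib$truth[match(kept$id, sc$lib$truth$id), ]
  clean <- truth$category == "ok"
  # simulated truth records the intended endpoint for every pair;
  # both modes must recover it
  agree <- ep$pos == truth$endpoint
  expect_gt(mean(agree[clean]), 0.99)  # rare read errors can shift an endpoint
  for (md in c("INTACT", "TRIMMED")) {
    sel <- clean & kept$mode == md
    expect_gt(sum(sel), 0)
    expect_gt(mean(agree[sel]), 0.99)
  }
})

test_that("endpoint grouping merges lone neighbours into the largest stack", {
  ep <- data.frame(chrom = "chr1", pos = c(rep(1036L, 50), 1037L))
  g <- group_endpoints(ep)
  expect_true(all(g$group_pos == 1036L))

  # distance 4 exceeds the tolerance
  ep2 <- data.frame(chrom = "chr1", pos = c(rep(1036L, 50), rep(1040L, 50)))
  g2 <- group_endpoints(ep2)
  expect_equal(sort(unique(g2$group_pos)), c(1036L, 1040L))

  # gap of exactly 3 merges
  ep3 <- data.frame(chrom = "chr1", pos = c(rep(1036L, 5), 1039L))
  expect_true(all(group_endpoints(ep3)$group_pos == 1036L))

  # equidistant between equal groups: lower coordinate wins
  ep4 <- data.frame(chrom = "chr1", pos = c(rep(1036L, 50), 1039L, rep(1042L, 50)))
  g4 <- group_endpoints(ep4)
  expect_equal(g4$group_pos[51], 1036L)

  # two adjacent multi-read groups stay distinct
  ep5 <- data.frame(chrom = "chr1", pos = c(rep(1036L, 5), rep(1038L, 5)))
  expect_equal(sort(unique(group_endpoints(ep5)$group_pos)), c(1036L, 1038L))
})

test_that("grouping equals the brute-force absorb procedure on random inputs", {
  for (trial in 1:20) {
    pos <- mescan:::with_seed(trial + 100, {
      centers <- sample(1000:2000, 30)
      n <- sample(c(1, 1, 1, 3, 8, 20), 30, replace = TRUE)
      unlist(mapply(function(c, k) c + sample(-2:2, k, replace = TRUE),
                    centers, n))
    })
    ep <- data.frame(chrom = "chr1", pos = as.integer(pos))
    got <- group_endpoints(ep)$group_pos
    want <- brute_group(pos)
    expect_equal(got, want, info = paste("trial", trial))
  }
  # support is conserved and never moves farther than the tolerance
  pos <- mescan:::with_seed(7, sample(1:50, 2000, replace = TRUE))
  g <- group_endpoints(data.frame(chrom = "c", pos = pos), merge_tol = 3)
  expect_equal(length(g$group_pos), 2000)
  expect_true(all(abs(g$group_pos - g$pos) <= 3))
})

test_that("element motif detection matches the exact and score criteria", {
  motif <- me_motif()
  params <- me_motif_params()
  read16 <- paste0(motif, "A")
  expect_true(detect_me_sequence(read16))
  expect_equal(mescan:::.sw_score_batch(motif, motif, 5, -4, 64, 8), 75)

  # two substitutions: 13 x 5 - 2 x 4 = 57 >= 45
  mut2 <- motif
  substr(mut2, 3, 3) <- "T"; substr(mut2, 8, 8) <- "A"
  expect_equal(mescan:::.sw_score_batch(mut2, motif, 5, -4, 64, 8), 57)
  expect_true(detect_me_sequence(paste0(mut2, "A")))

  # identity over the first 10 bases qualifies regardless of the tail
  head10 <- paste0(substr(motif, 1, 10), "TTTTTT")
  expect_true(detect_me_sequence(head10))
})

test_that("score path agrees with a full Smith-Waterman oracle on random 16-mers", {
  reads <- mescan:::with_seed(55, random_read(1000, 16))
  params <- me_motif_params()
  got_scores <- mescan:::.sw_score_batch(reads, params$motif, 5, -4, 64, 8)
  mat <- Biostrings::nucleotideSubstitutionMatrix(5, -4)
  oracle <- vapply(reads, function(r) {
    Biostrings::pairwiseAlignment(Biostrings::DNAString(r),
                                  Biostrings::DNAString(params$motif),
                                  type = "local", substitutionMatrix = mat,
                                  gapOpening = 64, gapExtension = 8,
                                  scoreOnly = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(got_scores, oracle)
  # a uniformly random 16-mer essentially never reaches the threshold
  expect_lt(mean(oracle >= params$score_min), 0.01)
  expect_equal(detect_me_sequence(reads, params),
               substr(reads, 1, 10) == substr(params$motif, 1, 10) |
                 oracle >= params$score_min)
})

test_that("locus calling applies inclusive support and motif-fraction bounds", {
  mk <- function(n, n_pos) {
    data.frame(chrom = "chr1", pos = 500L, group_pos = 500L,
               sample = "A", experiment = "e1", mode = "INTACT",
               me_detected = rep(c(TRUE, FALSE), c(n_pos, n - n_pos)))
  }
  expect_equal(nrow(call_loci(mk(9, 9))$loci), 0)    # support 9 -> dropped
  expect_equal(nrow(call_loci(mk(10, 10))$loci), 1)  # support 10 -> kept
  expect_equal(nrow(call_loci(mk(10, 4))$loci), 0)   # 40% motif -> dropped
  expect_equal(nrow(call_loci(mk(10, 5))$loci), 1)   # 50% motif -> kept
  out <- call_loci(mk(10, 5))
  expect_equal(out$loci$total_support, 10L)
  expect_equal(out$loci$me_fraction, 0.5)
})

test_that("support is summed across samples and experiments before the bound", {
  g <- data.frame(chrom = "chr1", pos = 700L, group_pos = 700L,
                  sample = rep(c("A", "B"), c(6, 4)),
                  experiment = rep(c("e1", "e2"), 5),
                  mode = "INTACT", me_detected = TRUE)
  out <- call_loci(g)
  expect_equal(nrow(out$loci), 1)
  expect_equal(sum(out$support$n), 10L)
  expect_equal(nrow(out$support), 4)  # (experiment, sample) breakdown
})

test_that("genotype matrix thresholds per-sample support", {
  g <- data.frame(chrom = "chr1", pos = c(rep(900L, 12), 900L),
                  group_pos = 900L,
                  sample = rep(c("A", "B"), c(12, 1)),
                  experiment = "e1", mode = "INTACT", me_detected = TRUE)
  called <- call_loci(g)
  gm1 <- genotype_matrix(called, min_pairs_per_sample = 1,
                         samples = c("A", "B", "C"))
  expect_equal(unname(gm1$presence[1, ]), c(1L, 1L, 0L))
  gm2 <- genotype_matrix(called, min_pairs_per_sample = 2,
                         samples = c("A", "B", "C"))
  expect_equal(unname(gm2$presence[1, ]), c(1L, 0L, 0L))
  expect_equal(unname(gm2$counts[1, ]), c(12L, 1L, 0L))
})

test_that("called genotypes match simulated truth where coverage permits", {
  sc <- small_scenario()
  kept <- sc$mapped[sc$mapped$keep, ]
  ep <- junction_endpoint(kept)
  ep$me_detected <- detect_me_sequence(substr(sc$dm$pairs$junction[sc$mapped$keep], 1, 16))
  called <- call_loci(group_endpoints(ep))
  gm <- genotype_matrix(called, samples = names(sc$design$indexes))
  ev <- evaluate_against_truth(gm, sc$cohort, sc$lib)
  # emitted coverage >= 1 pair and not in a duplicated block -> called
  dupids <- sc$ref$duplicated_blocks$locus_id
  loci_ok <- setdiff(rownames(sc$lib$counts), dupids)
  loci_ok <- intersect(loci_ok, sc$cohort$loci$locus_id)
  big <- sc$lib$counts[loci_ok, ] >= 10
  pres <- matrix(0L, nrow = length(loci_ok), ncol = ncol(gm$presence),
                 dimnames = list(loci_ok, colnames(gm$presence)))
  hit <- intersect(rownames(gm$presence), loci_ok)
  pres[hit, ] <- gm$presence[hit, ]
  expect_true(all(pres[big] == 1L))
})
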