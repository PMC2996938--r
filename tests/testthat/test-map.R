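test_that("toy_map equals the brute-force all-offset scan on a small reference", {
  seqs <- with_seed_list(31, function() c(chrA = random_dna(2000),
                                          chrB = random_dna(1500)))
  reads <- mescan:::with_seed(32, {
    r <- character(0)
    # planted reads with 0..4 substitutions, both strands, plus random ones
    for (i in 1:12) {
      ch <- sample(names(seqs), 1)
      p <- sample(nchar(seqs[[ch]]) - 35, 1)
      rd <- substr(seqs[[ch]], p, p + 35)
      k <- sample(0:4, 1)
      if (k > 0) rd <- mescan:::mutate_seq(rd, k = k)
      if (sample(c(TRUE, FALSE), 1)) rd <- revcomp(rd)
      r <- c(r, rd)
    }
    c(r, random_read(5))
  })
  hits <- toy_map(reads, seqs, max_mismatch = 3)
  for (i in seq_along(reads)) {
    got <- hits[hits$read == i, c("chrom", "pos", "strand", "mismatches")]
    want <- brute_map(reads[i], seqs, 3)
    got <- got[order(got$chrom, got$pos, got$strand), ]
    want <- want[order(want$chrom, want$pos, want$strand), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("read", i))
  }
})

test_that("toy_map agrees with Biostrings matchPattern on a 50 kb reference", {
  seqs <- with_seed_list(41, function() c(chr1 = random_dna(50000)))
  subject <- Biostrings::DNAString(seqs[["chr1"]])
  reads <- mescan:::with_seed(42, {
    p <- sample(49000, 40)
    r <- substring(seqs[["chr1"]], p, p + 29)
    r <- vapply(r, function(x) mescan:::mutate_seq(x, k = sample(0:3, 1)),
                character(1), USE.NAMES = FALSE)
    r
  })
  hits <- toy_map(reads, seqs, max_mismatch = 3)
  for (i in seq_along(reads)) {
    fwd <- Biostrings::matchPattern(reads[i], subject, max.mismatch = 3)
    rev <- Biostrings::matchPattern(revcomp(reads[i]), subject, max.mismatch = 3)
    want <- sort(c(Biostrings::start(fwd), Biostrings::start(rev)))
    got <- sort(hits$pos[hits$read == i])
    expect_equal(got, want, info = paste("read", i))
  }
})

test_that("unique hits get positive mapping quality, ties get zero", {
  base <- with_seed_dna(51, 3000)
  dupseg <- substr(base, 101, 200)
  seqs <- c(chr1 = paste0(base, dupseg, with_seed_dna(52, 500)))
  unique_read <- substr(base, 501, 536)
  dup_read <- substr(base, 120, 155)      # inside the duplicated segment
  hits <- toy_map(c(unique_read, dup_read), seqs)
  h1 <- hits[hits$read == 1 & hits$is_best, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$mapq, 37L)
  expect_equal(h1$mismatches, 0L)
  h2 <- hits[hits$read == 2 & hits$is_best, ]
  expect_equal(nrow(h2), 2)
  expect_true(all(h2$mapq == 0L))
  # 4 substitutions exceed the edit bound
  broken <- mescan:::with_seed(53, mescan:::mutate_seq(unique_read, k = 4))
  expect_equal(nrow(toy_map(broken, seqs)), 0)
})

test_that("pair filters report the first violated condition", {
  row <- function(...) {
    d <- data.frame(j_mapped = TRUE, j_chrom = "c", j_pos = 500L,
                    j_strand = "-", j_ref_width = 36L, j_mapq = 37L,
                    j_edit = 0L,
                    f_mapped = TRUE, f_chrom = "c", f_pos = 101L,
                    f_strand = "+", f_ref_width = 30L, f_mapq = 37L,
                    f_edit = 1L, stringsAsFactors = FALSE)
    for (nm in names(list(...))) d[[nm]] <- list(...)[[nm]]
    d
  }
  v <- filter_pair(row())
  expect_equal(v$reason, "OK"); expect_true(v$keep)
  expect_equal(filter_pair(row(f_mapq = 0L))$reason, "MAPQ_ZERO")
  expect_equal(filter_pair(row(j_mapq = 0L))$reason, "MAPQ_ZERO")
  expect_equal(filter_pair(row(j_edit = 4L))$reason, "EDIT_GT3")
  expect_equal(filter_pair(row(f_strand = "-"))$reason, "NOT_PROPER")
  expect_equal(filter_pair(row(f_mapped = FALSE))$reason, "NOT_PROPER")
  # outside the insert window
  expect_equal(filter_pair(row(f_pos = 10000L))$reason, "NOT_PROPER")
  # unmapped beats mapq zero in the reporting order
  expect_equal(filter_pair(row(f_mapped = FALSE, j_mapq = 0L))$reason,
               "NOT_PROPER")
})

test_that("reference-present loci map intact; novel insertions map only trimmed", {
  sc <- small_scenario()
  truth <- sc$lib$truth
  mapped <- sc$mapped
  loci <- sc$lib$loci
  novel <- loci$locus_id[!loci$in_reference]
  refl <- loci$locus_id[loci$in_reference & loci$class != "nonspecific"]
  dupids <- sc$ref$duplicated_blocks$locus_id
  refl <- setdiff(refl, dupids)
  m_ref <- mapped$mode[mapped$id %in% truth$id[truth$locus_id %in% refl &
                                                 truth$category == "ok"]]
  m_nov <- mapped$mode[mapped$id %in% truth$id[truth$locus_id %in% novel &
                                                 truth$category == "ok"]]
  expect_true(all(m_ref == "INTACT"))
  expect_gt(length(m_nov), 0)
  expect_true(all(m_nov == "TRIMMED"))
})

test_that("pairs from duplicated flank blocks are rejected with MAPQ_ZERO", {
  sc <- small_scenario()
  dupids <- sc$ref$duplicated_blocks$locus_id
  dup_pairs <- sc$lib$truth$id[sc$lib$truth$locus_id %in% dupids]
  reasons <- sc$mapped$reason[match(dup_pairs, sc$mapped$id)]
  reasons <- reasons[!is.na(reasons)]
  expect_gt(length(reasons), 0)
  expect_true(all(reasons == "MAPQ_ZERO"))
})

test_that("error-free pairs from unique regions all pass the filters", {
  ref <- make_reference(c(chr1 = 100000L), n_target = 8, seed = 33)
  co <- simulate_cohort(ref, 2, seed = 1)
  de <- library_design(c(A = "ACCAT", B = "TATTC"), total_pairs = 400,
                       error_rate = 0, seed = 2)
  lib <- simulate_library(ref, co, de)
  dm <- demux_stream(lib$pairs, de$indexes)
  mapped <- map_read_pairs(dm$pairs, ref)
  expect_true(all(mapped$keep))
  expect_true(all(mapped$reason == "OK"))
})

test_that("SAM ingestion joins mates and derives proper-pair state from flags", {
  rec <- function(qname, flag, pos, cigar, mpos, nm, len) {
    paste(qname, flag, "chr1", pos, 37, cigar, "=", mpos, 0,
          strrep("A", len), strrep("I", len), paste0("NM:i:", nm), sep = "\t")
  }
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:10000",
    # proper pair, junction reverse (flags 83/163)
    rec("p1", 83, 1001, "36M", 701, 1, 36),
    rec("p1", 163, 701, "30M", 1001, 0, 30),
    # proper pair, junction forward (flags 99/147)
    rec("p2", 99, 2001, "36M", 2301, 0, 36),
    rec("p2", 147, 2301, "30M", 2001, 0, 30),
    # both forward: not proper (flags 97/145)
    rec("p3", 97, 3001, "36M", 3301, 0, 36),
    rec("p3", 145, 3301, "30M", 3001, 0, 30),
    # soft clip contributes to the edit distance
    rec("p4", 99, 4001, "30M6S", 4301, 0, 36),
    rec("p4", 147, 4301, "30M", 4001, 0, 30),
    # missing mate: dropped
    rec("p5", 99, 5001, "36M", 5301, 0, 36))
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  res <- ingest_sam(path, mode = "INTACT")
  al <- res$alignments
  expect_equal(res$n_dropped, 1)
  expect_equal(sort(al$id), c("p1", "p2", "p3", "p4"))
  expect_equal(al$properly_paired[match(c("p1", "p2", "p3"), al$id)],
               c(TRUE, TRUE, FALSE))
  expect_equal(al$j_edit[al$id == "p4"], 6L)
  expect_equal(al$j_edit[al$id == "p1"], 1L)
  v <- filter_pair(al)
  expect_equal(v$reason[match(c("p1", "p2", "p3", "p4"), al$id)],
               c("OK", "OK", "NOT_PROPER", "EDIT_GT3"))
})
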