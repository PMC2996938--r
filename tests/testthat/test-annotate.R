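test_that("PBS scan finds planted sites with exact 3'-window accounting", {
  primer <- me_seq_primer()
  bg <- with_seed_dna(61, 4000)
  # plant the primer verbatim (plus strand) at 1001
  subject <- bg
  substr(subject, 1001, 1000 + nchar(primer)) <- primer
  sites <- scan_pbs(c(chr1 = subject), primer, min_score = 23)
  hit <- sites[sites$start == 1001 & sites$strand == "+", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$score, nchar(primer))
  expect_equal(hit$mm_3p10, 0L)

  # one substitution at 3' position 5 (5th base from the primer's 3' end)
  mut <- primer
  p5 <- nchar(primer) - 4
  substr(mut, p5, p5) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, p5, p5))[1]
  subject2 <- bg
  substr(subject2, 2001, 2000 + nchar(primer)) <- mut
  sites2 <- scan_pbs(c(chr1 = subject2), primer, min_score = 20)
  hit2 <- sites2[sites2$start == 2001, ]
  expect_equal(nrow(hit2), 1)
  expect_equal(hit2$mm_3p10, 1L)

  # minus-strand planting is found with mirrored coordinates
  subject3 <- bg
  substr(subject3, 3001, 3000 + nchar(primer)) <- revcomp(primer)
  sites3 <- scan_pbs(c(chr1 = subject3), primer, min_score = 23)
  hit3 <- sites3[sites3$start == 3001, ]
  expect_equal(hit3$strand, "-")
  expect_equal(hit3$prim3_pos, 3001L)
})

test_that("PBS scan equals the all-offsets scoring oracle", {
  for (trial in 1:3) {
    subject <- with_seed_dna(70 + trial, 20000)
    # plant degraded copies so there is something above threshold
    subject <- mescan:::with_seed(80 + trial, {
      s <- subject
      for (p in sample(19000, 5)) {
        pr <- mescan:::mutate_seq(me_seq_primer(), k = sample(0:3, 1))
        if (sample(c(TRUE, FALSE), 1)) pr <- revcomp(pr)
        substr(s, p, p + nchar(pr) - 1) <- pr
      }
      s
    })
    got <- scan_pbs(c(c1 = subject), me_seq_primer(), min_score = 16)
    want_f <- brute_scan(subject, me_seq_primer(), min_score = 16)
    want_r <- brute_scan(subject, revcomp(me_seq_primer()), min_score = 16)
    expect_equal(got$start[got$strand == "+"], want_f$pos)
    expect_equal(got$score[got$strand == "+"], want_f$score)
    expect_equal(got$start[got$strand == "-"], want_r$pos)
    expect_equal(got$score[got$strand == "-"], want_r$score)
  }
})

test_that("PBS scan is symmetric under reverse complementation of the reference", {
  sc <- small_scenario()
  seqs <- as.character(sc$ref$sequences)
  L <- nchar(seqs[["chr1"]])
  fwd <- scan_pbs(sc$ref, me_seq_primer(), min_score = 23)
  rcref <- c(chr1 = revcomp(seqs[["chr1"]]))
  rev <- scan_pbs(rcref, me_seq_primer(), min_score = 23)
  mirror_start <- L - fwd$end + 1L
  expect_setequal(paste(rev$start, rev$strand),
                  paste(mirror_start, ifelse(fwd$strand == "+", "-", "+")))
})

test_that("sites link to containing elements and predict the locus endpoint", {
  sc <- small_scenario()
  sites <- scan_pbs(sc$ref, me_seq_primer(), min_score = 23)
  sites <- link_pbs_to_track(sites, sc$ref$me_track)
  expect_true(all(!is.na(sites$family)))
  tgt <- sites[sites$family == "AluYb-like", ]
  # predicted endpoints equal the planted locus identifiers
  expect_setequal(
    mescan:::locus_id(tgt$chrom, tgt$predicted_endpoint),
    sc$ref$me_track$locus_id[sc$ref$me_track$family == "AluYb-like"])
  # a site in unannotated sequence stays unlinked
  bare <- with_seed_dna(66, 2000)
  substr(bare, 501, 500 + nchar(me_seq_primer())) <- me_seq_primer()
  s2 <- scan_pbs(c(chr1 = bare), me_seq_primer(), min_score = 23)
  s2 <- link_pbs_to_track(s2, sc$ref$me_track[0, ])
  expect_true(all(is.na(s2$family)))
})

test_that("loci classify exhaustively into known target / non-specific / novel", {
  sc <- small_scenario()
  kept <- sc$mapped[sc$mapped$keep, ]
  ep <- junction_endpoint(kept)
  ep$me_detected <- detect_me_sequence(substr(sc$dm$pairs$junction[sc$mapped$keep], 1, 16))
  called <- call_loci(group_endpoints(ep))
  sites <- link_pbs_to_track(scan_pbs(sc$ref, me_seq_primer(), min_score = 23),
                             sc$ref$me_track)
  cl <- classify_loci(called$loci, sites)
  expect_true(all(cl$class %in% c("KNOWN_TARGET", "NONSPECIFIC", "NOVEL")))
  truth <- sc$lib$loci
  key <- match(cl$locus_id, truth$locus_id)
  expect_true(all(cl$class[truth$class[key] == "nonspecific"] == "NONSPECIFIC"))
  expect_true(all(cl$class[!truth$in_reference[key]] == "NOVEL"))
  expect_true(all(cl$class[truth$in_reference[key] &
                             truth$class[key] != "nonspecific"] == "KNOWN_TARGET"))
})

test_that("fixed-locus selection recovers exactly the clean planted targets", {
  sc <- small_scenario()
  seq_sites <- scan_pbs(sc$ref, me_seq_primer(), min_score = 23)
  amp_sites <- scan_pbs(sc$ref, me_amp_primer(), min_score = 16,
                        role = "AMPLIFICATION")
  fx <- select_fixed_loci(amp_sites, seq_sites,
                          polymorphic_known = sc$ref$polymorphic_known)
  want <- setdiff(
    sc$ref$me_track$locus_id[sc$ref$me_track$family == "AluYb-like"],
    sc$ref$polymorphic_known)
  expect_setequal(fx$locus_id, want)
})

test_that("fixed-locus criteria enforce spacing, order and clean 3' ends", {
  site <- function(start, strand = "-", mm = 0L, score = 27, chrom = "chr1") {
    data.frame(chrom = chrom, start = start, end = start + 26L,
               strand = strand, score = score, seg_from = start,
               seg_to = start + 26L, mm_3p10 = mm, mm_total = mm,
               prim3_pos = if (strand == "-") start else start + 26L,
               role = "SEQUENCING", stringsAsFactors = FALSE)
  }
  amp <- function(start, strand = "-", mm = 0L, score = 20) {
    s <- site(start, strand, mm, score); s$role <- "AMPLIFICATION"; s
  }
  p <- fixed_locus_params()
  # separation 224 within [209, 239]: selected
  expect_equal(nrow(select_fixed_loci(amp(1224), site(1000), p)), 1)
  # boundary: 239 selected, 240 excluded
  expect_equal(nrow(select_fixed_loci(amp(1239), site(1000), p)), 1)
  expect_equal(nrow(select_fixed_loci(amp(1240), site(1000), p)), 0)
  expect_equal(nrow(select_fixed_loci(amp(1209), site(1000), p)), 1)
  expect_equal(nrow(select_fixed_loci(amp(1208), site(1000), p)), 0)
  # wrong order for a minus-strand pair: seq must be at the lower coordinate
  expect_equal(nrow(select_fixed_loci(amp(1000), site(1224), p)), 0)
  # plus-strand pair: seq downstream = higher coordinate
  expect_equal(nrow(select_fixed_loci(amp(1000, "+"), site(1224, "+"), p)), 1)
  expect_equal(nrow(select_fixed_loci(amp(1224, "+"), site(1000, "+"), p)), 0)
  # opposite orientations never pair
  expect_equal(nrow(select_fixed_loci(amp(1224, "+"), site(1000, "-"), p)), 0)
  # one mismatch in the sequencing PBS 3' 10 bp: excluded
  expect_equal(nrow(select_fixed_loci(amp(1224), site(1000, mm = 1L), p)), 0)
  # below a score threshold: excluded
  expect_equal(nrow(select_fixed_loci(amp(1224, score = 15), site(1000), p)), 0)
  # on the known-polymorphic list: excluded
  sel <- select_fixed_loci(amp(1224), site(1000), p)
  expect_equal(nrow(select_fixed_loci(amp(1224), site(1000), p,
                                      polymorphic_known = sel$locus_id)), 0)
})

test_that("upstream duplication flag separates duplicated from unique loci", {
  sc <- small_scenario()
  dupids <- sc$ref$duplicated_blocks$locus_id
  tr <- sc$ref$me_track[sc$ref$me_track$family == "AluYb-like", ]
  for (i in seq_len(nrow(tr))) {
    got <- flag_upstream_duplication(sc$ref, tr$chrom[i], tr$endpoint[i],
                                     tr$strand[i])
    expect_identical(got, tr$locus_id[i] %in% dupids, label = tr$locus_id[i])
  }
})

test_that("duplication flag respects the identity threshold", {
  base <- with_seed_dna(88, 6000)
  win <- substr(base, 1001, 1500)
  # a 98%-identical copy (10 substitutions in 500 bp) must not trigger at 0.99
  copy98 <- mescan:::with_seed(89, mescan:::mutate_seq(win, k = 10))
  copy995 <- mescan:::with_seed(90, mescan:::mutate_seq(win, k = 2))
  s98 <- paste0(base, copy98); s995 <- paste0(base, copy995)
  expect_false(flag_upstream_duplication(c(chr1 = s98), "chr1", 1500L, "+"))
  expect_true(flag_upstream_duplication(c(chr1 = s995), "chr1", 1500L, "+"))
  expect_false(flag_upstream_duplication(c(chr1 = base), "chr1", 1500L, "+"))
  expect_error(flag_upstream_duplication(c(chr1 = base), "chr1", 400L, "+"),
               "fewer than")
})

test_that("locus list comparison pairs greedily within the tolerance", {
  a <- data.frame(chrom = "chr1", pos = c(100L, 500L, 900L))
  expect_equal(compare_locus_lists(a, a)$n_matched, 3)

  b <- data.frame(chrom = "chr1", pos = c(150L, 551L, 900L))
  cmp <- compare_locus_lists(a, b, tol = 50)
  expect_equal(cmp$n_matched, 2)  # offset 50 matches, 51 does not
  expect_equal(cmp$unmatched_a, 2L)
  expect_equal(cmp$unmatched_b, 2L)

  disjoint <- data.frame(chrom = "chr1", pos = c(5000L, 6000L))
  expect_equal(compare_locus_lists(a, disjoint)$n_matched, 0)

  # each locus matched at most once
  many_b <- data.frame(chrom = "chr1", pos = c(98L, 99L, 101L))
  cmp2 <- compare_locus_lists(data.frame(chrom = "chr1", pos = 100L), many_b)
  expect_equal(cmp2$n_matched, 1)
})
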