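test_that("SNP calling scans columns with determined unequal bases", {
  expect_equal(nrow(call_snps(pairwise_alignment("ACGT", "ACGT"))), 0L)
  aln <- pairwise_alignment("AC-GT", "ATAGT")
  sn <- call_snps(aln)
  expect_equal(nrow(sn), 1L)
  expect_equal(sn$column, 2L)
  expect_equal(c(sn$base_a, sn$base_b), c("C", "T"))
  expect_equal(c(sn$pos_a, sn$pos_b), c(1L, 1L))
  # ambiguity columns are skipped and counted separately
  aln2 <- pairwise_alignment("ANGT", "ACGA")
  sn2 <- call_snps(aln2)
  expect_equal(nrow(sn2), 1L)                  # only the T/A column
  expect_equal(attr(sn2, "ambiguous_columns"), 1L)
})

test_that("column classes account for every alignment column", {
  for (seed in c(41, 42, 43)) {
    pair <- simulate_pair(small_cfg(seed = seed))
    aln <- pair$truth$alignment
    cls <- table(column_classes(aln))
    expect_equal(sum(cls), alignment_ncol(aln))
    expect_equal(unname(cls[["snp"]]), nrow(call_snps(aln)))
  }
})

test_that("indel events are maximal per-row gap runs", {
  aln <- pairwise_alignment("AC-GT", "ATAGT")
  ind <- call_indels(aln)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$carrier, "a")
  expect_equal(ind$length, 1L)
  expect_equal(ind$indel_seq, "A")
  # two runs in the same row separated by matches stay distinct
  row_a <- paste0("ACGTACGTAC", strrep("-", 10), "GTT", strrep("-", 2), "ACGT")
  row_b <- paste0("ACGTACGTAC", "GTCCAAGTCC", "GTT", "AA", "ACGT")
  ind2 <- call_indels(pairwise_alignment(row_a, row_b))
  expect_equal(nrow(ind2), 2L)
  expect_equal(sort(ind2$length), c(2L, 10L))
  expect_false(any(ind2$complex))
})

test_that("abutting opposite-row gap runs are two events flagged complex", {
  aln <- pairwise_alignment("ACGTAC--GGTACGTA", "ACGT--ACGGTACGTA")
  ind <- call_indels(aln)
  expect_equal(nrow(ind), 2L)
  expect_setequal(ind$carrier, c("a", "b"))
  expect_true(all(ind$complex))
})

test_that("indel flanks come from the non-gap row with sufficient width", {
  seq_a <- paste0(strrep("C", 30), strrep("G", 30))
  seq_b <- paste0(strrep("C", 30), "ATATATAT", strrep("G", 30))
  aln <- pairwise_alignment(paste0(strrep("C", 30), strrep("-", 8),
                                   strrep("G", 30)), seq_b)
  ind <- call_indels(aln)
  expect_equal(ind$indel_seq, "ATATATAT")
  expect_equal(ind$flank_left, strrep("C", 20))
  expect_equal(ind$flank_right, strrep("G", 20))
  # flank widened to the indel length when longer than the default
  long <- strrep("ACGTT", 6)                   # 30 bp insertion
  aln2 <- pairwise_alignment(
    paste0(strrep("C", 40), strrep("-", 30), strrep("G", 40)),
    paste0(strrep("C", 40), long, strrep("G", 40)))
  expect_equal(nchar(call_indels(aln2)$flank_left), 30L)
})

test_that("indel classification follows the polyN > SSR > other order", {
  # boundary case: 2 inserted + 3 left + 2 right = 7 -> polyN
  expect_equal(classify_indel("AA", "CGTAAA", "AACGT"), "polyN")
  # run of 6 through the locus stays below the sevenfold threshold, but the
  # duplicated "AA" motif still matches the adjacent-copy (SSR) rule
  expect_equal(classify_indel("AA", "CGTAA", "AACGT"), "SSR_or_inversion")
  # short run with no adjacent copy falls through to other
  expect_equal(classify_indel("AA", "CGTA", "CCGT"), "other")
  # one adjacent repetition of a multi-nucleotide motif -> SSR
  expect_equal(classify_indel("ATAT", "CCGGCCGG", "ATATCCGG"),
               "SSR_or_inversion")
  expect_equal(classify_indel("ATGC", "CCGGATGC", "CCGGCCGG"),
               "SSR_or_inversion")
  # adjacent reverse complement counts as SSR/inversion class
  expect_equal(classify_indel("AAGG", "TTCCCCTT", "CACACACA"),
               "SSR_or_inversion")
  expect_equal(classify_indel("GTCAG", "CCCC", "TTTT"), "other")
  # homopolymer indel that is also a trivial tandem: polyN wins
  expect_equal(classify_indel("AAAA", "CGAAAA", "CCGG"), "polyN")
  expect_error(classify_indel(""), "empty")
})

test_that("classification agrees with the brute-force oracle on 1000 events", {
  ev <- random_events(1000, seed = 99)
  got <- vapply(seq_len(nrow(ev)), function(i)
    classify_indel(ev$indel_seq[i], ev$flank_left[i], ev$flank_right[i]),
    character(1L))
  want <- vapply(seq_len(nrow(ev)), function(i)
    brute_classify(ev$indel_seq[i], ev$flank_left[i], ev$flank_right[i]),
    character(1L))
  expect_identical(got, want)
})

test_that("planted inversions are recovered at their planted coordinates", {
  cfg <- small_cfg(seed = 51, inversion_count = 2)
  pair <- simulate_pair(cfg)
  inv <- detect_inversions(pair$truth$alignment)
  expect_equal(nrow(inv), 2L)
  expect_setequal(inv$start_a, pair$truth$inversions$pos)
  expect_equal(inv$length, rep(cfg$inversion_length, 2L))
  expect_true(all(inv$identity == 1))
  # no long mismatch run -> no inversion calls
  pair2 <- simulate_pair(small_cfg(seed = 52))
  expect_equal(nrow(detect_inversions(pair2$truth$alignment)), 0L)
})

test_that("non-palindromic planted inversions carry a FALSE palindrome flag", {
  # a perfectly palindromic inversion is sequence-identical to the original
  # and therefore invisible; the flag marks near-threshold candidates
  pair <- simulate_pair(small_cfg(seed = 53, inversion_count = 1))
  inv <- detect_inversions(pair$truth$alignment)
  expect_equal(nrow(inv), 1L)
  expect_false(any(inv$palindromic))
})

test_that("per-class indel AT distributions summarise correctly", {
  ev <- data.frame(indel_seq = c("AT", "AAAA", "GGGG"),
                   length = c(2L, 4L, 4L),
                   klass = c("other", "polyN", "polyN"),
                   stringsAsFactors = FALSE)
  prof <- indel_at_profiles(ev, baseline = 0.6)
  expect_equal(prof$per_event$at, c(1, 1, 0))
  s <- prof$summary
  expect_equal(s$mean[s$klass == "polyN"], 0.5)
  expect_equal(s$median[s$klass == "polyN"], 0.5)
  expect_equal(s$n[s$klass == "SSR_or_inversion"], 0L)
  expect_equal(prof$baseline, 0.6)
})

test_that("simulated indel AT bias is recovered from the events", {
  set.seed(7)
  n <- 200
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "T", "G", "C"), 10, TRUE,
                 prob = c(0.4, 0.4, 0.1, 0.1)), collapse = ""),
    character(1L))
  ev <- data.frame(indel_seq = seqs, length = 10L, klass = "other",
                   stringsAsFactors = FALSE)
  prof <- indel_at_profiles(ev)
  expect_lt(abs(prof$summary$mean[prof$summary$klass == "other"] - 0.8), 0.05)
})

test_that("SNP neighbourhood AT windows exclude the site and flag truncation", {
  cons <- structure(list(bases = paste0("TTTTT", "R", "AAAAA"),
                         at_content = 10 / 10, column_map = 1:11),
                    class = "consensus_sequence")
  snp <- data.frame(column = 6L)
  prof <- snp_neighborhood_at(cons, snp, radii = c(5, 10))
  expect_equal(unname(prof$at[1, "r5"]), 1.0)
  expect_false(prof$truncated[1, "r5"])
  expect_true(prof$truncated[1, "r10"])        # window clipped at both ends
  cons2 <- structure(list(bases = paste0("GGGGG", "R", "CCCCC"),
                          at_content = 0, column_map = 1:11),
                     class = "consensus_sequence")
  prof2 <- snp_neighborhood_at(cons2, snp, radii = 5)
  expect_equal(unname(prof2$at[1, "r5"]), 0.0)
  expect_error(snp_neighborhood_at(cons, snp, radii = c(0, 5)), "positive")
})

test_that("neighbourhood AT at a large radius matches a direct recount", {
  pair <- simulate_pair(small_cfg(seed = 61))
  aln <- pair$truth$alignment
  cons <- consensus(aln)
  snps <- call_snps(aln)
  prof <- snp_neighborhood_at(cons, snps, radii = 100)
  ch <- strsplit(cons$bases, "")[[1L]]
  for (i in sample.int(nrow(snps), min(10, nrow(snps)))) {
    p <- snps$column[i]
    idx <- setdiff(max(1, p - 100):min(length(ch), p + 100), p)
    w <- ch[idx]
    at <- sum(w %in% c("A", "T", "W")) + 0.5 * sum(w %in% c("R", "Y", "K", "M"))
    det <- sum(w %in% c("A", "C", "G", "T", "W", "S", "R", "Y", "K", "M"))
    expect_equal(unname(prof$at[i, 1L]), at / det)
  }
})
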