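test_that("region slices follow the left-closed right-open column rule", {
  set.seed(71)
  a <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  aln <- pairwise_alignment(a, a)
  reg <- data.frame(name = "r", kind = "spacer", start = 100L, end = 250L)
  sub <- region_slice(aln, reg)
  expect_equal(alignment_ncol(sub), 150L)      # no gaps: width = length
  # a 6-column insertion in B inside the region widens the slice by 6
  row_a <- paste0(substr(a, 1, 200), strrep("-", 6), substr(a, 201, 400))
  row_b <- paste0(substr(a, 1, 200), "GGCCAA", substr(a, 201, 400))
  aln2 <- pairwise_alignment(row_a, row_b)
  sub2 <- region_slice(aln2, reg)
  expect_equal(alignment_ncol(sub2), 156L)
  # an insertion immediately before the region start is excluded
  reg3 <- data.frame(name = "r3", kind = "spacer", start = 200L, end = 250L)
  sub3 <- region_slice(aln2, reg3)
  expect_equal(alignment_ncol(sub3), 50L)
  expect_error(region_slice(aln, data.frame(name = "x", start = 390L,
                                            end = 420L)), "outside")
})

test_that("region statistics follow the PIC and p-distance definitions", {
  # identical slice
  s <- strrep("ACGT", 30)
  reg <- data.frame(name = "id", kind = "spacer", start = 0L, end = 120L)
  st <- compute_region_stats(region_slice(pairwise_alignment(s, s), reg), reg)
  expect_equal(st$snps, 0L); expect_equal(st$indels, 0L)
  expect_equal(st$p_distance, 0)
  # 2 SNPs over 100 gap-free columns plus one 5-column indel:
  # p = 0.02, pics = 3
  set.seed(72)
  base <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  ch <- strsplit(base, "")[[1L]]
  swap <- function(x) c(A = "G", C = "T", G = "A", T = "C")[[x]]
  chb <- ch; chb[10] <- swap(ch[10]); chb[60] <- swap(ch[60])
  row_a <- paste0(paste(ch, collapse = ""), strrep("-", 5))
  row_b <- paste0(paste(chb, collapse = ""), "AATTC")
  aln <- pairwise_alignment(row_a, row_b)
  reg2 <- data.frame(name = "x", kind = "spacer", start = 0L, end = 100L)
  st2 <- compute_region_stats(region_slice(aln, reg2), reg2)
  expect_equal(st2$snps, 2L)
  expect_equal(st2$indels, 1L)
  expect_equal(st2$pics, 3L)
  expect_equal(st2$p_distance, 0.02)
  expect_equal(st2$aligned_length, 105L)
  # all-gap slice: p-distance is missing, not zero
  aln3 <- pairwise_alignment(strrep("-", 10), strrep("A", 10))
  st3 <- compute_region_stats(aln3, data.frame(name = "g", kind = "spacer"))
  expect_true(is.na(st3$p_distance))
})

test_that("region p-distances match a brute-force recount", {
  pair <- simulate_pair(small_cfg(seed = 73))
  aln <- pair$truth$alignment
  regions <- extract_noncoding_regions(pair$genome_a, dedupe_ir = FALSE)
  stats <- region_stats_table(aln, regions)
  ca <- strsplit(aln$row_a, "")[[1L]]
  cb <- strsplit(aln$row_b, "")[[1L]]
  poscols <- which(!is.na(aln$col_to_pos_a))
  la <- length(poscols)
  set.seed(74)
  for (i in sample.int(nrow(stats), min(50, nrow(stats)))) {
    reg <- regions[regions$name == stats$name[i], ]
    if (reg$end > la) next
    cols <- poscols[reg$start + 1L]:(if (reg$end < la)
      poscols[reg$end + 1L] - 1L else length(ca))
    xa <- ca[cols]; xb <- cb[cols]
    det <- xa %in% c("A", "C", "G", "T") & xb %in% c("A", "C", "G", "T")
    p_brute <- if (sum(det) > 0) sum(xa[det] != xb[det]) / sum(det) else NA
    expect_equal(stats$p_distance[i], p_brute)
  }
})

test_that("per-region SNP totals never exceed the whole-genome count", {
  pair <- simulate_pair(small_cfg(seed = 75))
  aln <- pair$truth$alignment
  stats <- region_stats_table(aln, extract_noncoding_regions(pair$genome_a))
  expect_lte(sum(stats$snps), nrow(call_snps(aln)))
})

test_that("ranking sorts, breaks ties deterministically and permutes", {
  one <- data.frame(name = "only", kind = "spacer", aligned_length = 100L,
                    snps = 1L, indels = 0L, inversions = 0L, pics = 1L,
                    p_distance = 0.01, stringsAsFactors = FALSE)
  expect_equal(rank_regions(one, "p_distance")$rank, 1L)
  st <- data.frame(name = c("b", "a", "c", "d"), kind = "spacer",
                   aligned_length = c(100L, 100L, 200L, 100L),
                   snps = c(2L, 2L, 2L, 1L), indels = c(1L, 2L, 2L, 0L),
                   inversions = 0L, pics = c(3L, 4L, 4L, 1L),
                   p_distance = c(0.02, 0.02, 0.02, 0.01),
                   stringsAsFactors = FALSE)
  r <- rank_regions(st, "p_distance")
  # ties on p: higher pics first; pics tie: longer first; then name
  expect_equal(r$name, c("c", "a", "b", "d"))
  expect_setequal(r$name, st$name)             # permutation, nothing lost
  expect_equal(rank_regions(st, "pics", top_n = 2)$name, c("c", "a"))
  expect_error(rank_regions(st[0, ], "pics"), "empty")
})

test_that("whole-genome summary matches the per-pair definitions", {
  s <- strrep("ACGTTGCA", 100)
  self <- whole_genome_summary(pairwise_alignment(s, s))
  expect_equal(self$p_distance, 0)
  expect_equal(self$length_difference, 0L)
  pair <- simulate_pair(small_cfg(seed = 76))
  aln <- pair$truth$alignment
  summ <- whole_genome_summary(aln)
  expect_equal(summ$snps, nrow(pair$truth$snps))
  expect_equal(summ$aligned_length, alignment_ncol(aln))
  expect_equal(summ$length_difference,
               abs(nchar(pair$genome_a$sequence) -
                     nchar(pair$genome_b$sequence)))
})

test_that("sliding windows tile the consensus and conserve counts", {
  # mutation-free pair: all-zero track
  s <- strrep("ACGT", 300)
  aln0 <- pairwise_alignment(s, s)
  w0 <- sliding_windows(consensus(aln0), call_variants(aln0), window = 500)
  expect_equal(sum(w0$snp_count), 0L)
  expect_equal(sum(w0$indel_count), 0L)
  expect_equal(w0$end[nrow(w0)], 1200L)
  expect_true(w0$short[nrow(w0)])              # 200 bp final slot flagged
  # direct placement: SNPs at consensus positions 10 and 600
  set.seed(77)
  ch <- sample(c("A", "C", "G", "T"), 1000, TRUE)
  chb <- ch
  chb[10] <- c(A = "G", C = "T", G = "A", T = "C")[[ch[10]]]
  chb[600] <- c(A = "G", C = "T", G = "A", T = "C")[[ch[600]]]
  aln1 <- pairwise_alignment(paste(ch, collapse = ""),
                             paste(chb, collapse = ""))
  w1 <- sliding_windows(consensus(aln1), call_variants(aln1), window = 500)
  expect_equal(w1$snp_count, c(1L, 1L))
  expect_equal(sliding_windows(consensus(aln0), call_variants(aln0),
                               window = 500)$at_content[1],
               at_content(substr(s, 1, 500)))
  expect_error(sliding_windows(consensus(aln0), call_variants(aln0),
                               window = 0), "window")
  # all-A window
  alnA <- pairwise_alignment(strrep("A", 500), strrep("A", 500))
  expect_equal(sliding_windows(consensus(alnA),
                               call_variants(alnA))$at_content, 1.0)
})
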