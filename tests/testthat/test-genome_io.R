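test_that("GenBank parsing resolves joins, complements and duplicate names", {
  path <- toy_genbank(tempfile(fileext = ".gb"))
  g <- read_annotated_genome(path)
  expect_s3_class(g, "annotated_genome")
  expect_equal(g$id, "TOY1")
  expect_equal(nchar(g$sequence), 1000L)
  expect_true(g$circular)
  # 5 features, duplicate geneA suffixed -> 5 unique names
  expect_setequal(unique(g$features$name),
                  c("geneA", "trnX", "geneB", "geneC", "geneA_2"))
  # 1-based inclusive converted to 0-based half-open
  a <- g$features[g$features$name == "geneA", ]
  expect_equal(c(a$start, a$end), c(10L, 100L))
  tr <- g$features[g$features$name == "trnX", ]
  expect_equal(tr$strand, "-")
  expect_equal(c(tr$start, tr$end), c(150L, 222L))
  b <- g$features[g$features$name == "geneB", ]
  expect_equal(nrow(b), 2L)                 # two-exon gene -> 2 intervals
  expect_equal(b$start, c(300L, 500L))
  expect_equal(b$end, c(400L, 640L))
})

test_that("GenBank write -> read round trip preserves sequence and features", {
  g <- simulate_genome(small_cfg(seed = 4))
  path <- tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_annotated_genome(path)
  expect_equal(g2$sequence, g$sequence)
  expect_equal(g2$id, g$id)
  f1 <- g$features[order(g$features$name, g$features$part),
                   c("name", "kind", "strand", "start", "end")]
  f2 <- g2$features[order(g2$features$name, g2$features$part),
                    c("name", "kind", "strand", "start", "end")]
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f2, f1)
  # write again: byte-identical record
  path2 <- tempfile(fileext = ".gb")
  write_genbank(g2, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("malformed records are rejected with informative errors", {
  expect_error(read_annotated_genome(tempfile()), "no such file")
  p <- tempfile()
  writeLines(c("LOCUS       X 10 bp", "FEATURES", "     gene            1..5",
               '                     /gene="g"'), p)
  expect_error(read_annotated_genome(p), "without sequence")
  expect_error(annotated_genome("x", "ACGT", data.frame(
    name = "g", kind = "gene", strand = "+", start = 2L, end = 9L)),
    "outside the sequence")
  expect_error(annotated_genome("x", ""), "empty sequence")
})

test_that("gc_content follows the determined-bases definition", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATGCN"), 0.5)       # N excluded both sides
  expect_equal(gc_content("atgc"), 0.5)
  expect_error(gc_content(""), "empty")
  # complementarity of the two measures on ambiguity-free sequence
  s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  expect_equal(gc_content(s) + at_content(s), 1.0)
})

test_that("quadripartite detection recovers a planted IR pair exactly", {
  cfg <- sim_config(genome_length = 40000, ir_length = 7000,
                    ssc_length = 4800, n_genes = 10, n_trnas = 5, seed = 9)
  g <- simulate_genome(cfg)
  gq <- g
  gq$features <- gq$features[gq$features$kind != "IR", , drop = FALSE]
  q <- detect_quadripartite(gq, min_ir_len = 5000)
  lsc_len <- 40000 - 2 * 7000 - 4800
  expect_false(q$from_annotation)
  expect_equal(q$ir_length, 7000L)
  expect_equal(q$ira, c(lsc_len, lsc_len + 7000L))
  expect_equal(q$irb, c(40000L - 7000L, 40000L))
  expect_equal(q$ir_identity, 1.0)
  # tiling invariant: lsc + ssc + 2 ir = genome length
  expect_equal((q$lsc[2] - q$lsc[1]) + (q$ssc[2] - q$ssc[1]) +
                 2 * q$ir_length, 40000L)
  # annotated IRs take precedence
  qa <- detect_quadripartite(g)
  expect_true(qa$from_annotation)
  expect_equal(qa$ir_length, 7000L)
})

test_that("random sequence has no detectable IR", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 50000, TRUE), collapse = "")
  g <- annotated_genome("rand", s)
  expect_error(detect_quadripartite(g, min_ir_len = 10000),
               class = "plastscan_structure_not_found")
})

test_that("spacer extraction applies the length filter and naming rule", {
  mk <- function(b_start) {
    annotated_genome("t", strrep("ACGT", 150), data.frame(
      name = c("geneA", "geneB"), kind = "gene", strand = "+",
      start = c(0L, b_start), end = c(100L, 500L)), circular = FALSE)
  }
  # 50 bp candidate dropped by the min_len = 100 filter
  r1 <- extract_noncoding_regions(mk(150L), dedupe_ir = FALSE)
  expect_equal(nrow(r1), 0L)
  # 120 bp spacer retained, named left-right, boundaries abut the features
  r2 <- extract_noncoding_regions(mk(220L), dedupe_ir = FALSE)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$name, "geneA-geneB")
  expect_equal(c(r2$start, r2$end), c(100L, 220L))
  expect_equal(r2$kind, "spacer")
})

test_that("the trnK intron is split at matK into 5' and 3' parts", {
  g <- simulate_genome(small_cfg(seed = 2))
  reg <- extract_noncoding_regions(g, dedupe_ir = FALSE)
  tk <- reg[grepl("trnK intron", reg$name), ]
  expect_setequal(tk$name, c("trnK intron 5p", "trnK intron 3p"))
  matk <- g$features[g$features$name == "matK", ]
  tkf <- g$features[g$features$name == "trnK", ]
  expect_equal(tk$end[tk$name == "trnK intron 5p"], matk$start)
  expect_equal(tk$start[tk$name == "trnK intron 3p"], matk$end)
  expect_equal(tk$start[tk$name == "trnK intron 5p"], min(tkf$end))
  # without the split, one whole intron
  reg2 <- extract_noncoding_regions(g, split_trnK = FALSE, dedupe_ir = FALSE)
  expect_true("trnK intron" %in% reg2$name)
  expect_false(any(grepl("intron 5p", reg2$name)))
})

test_that("regions partition the noncoding space without overlap", {
  g <- simulate_genome(small_cfg(seed = 6))
  reg <- extract_noncoding_regions(g, min_len = 1, dedupe_ir = FALSE)
  len <- nchar(g$sequence)
  cov <- integer(len)
  for (i in seq_len(nrow(reg))) {
    idx <- (seq(reg$start[i], reg$end[i] - 1L) %% len) + 1L
    cov[idx] <- cov[idx] + 1L
  }
  expect_true(all(cov <= 1L))                  # no two regions overlap
  ft <- g$features[g$features$kind %in% c("gene", "tRNA", "rRNA"), ]
  for (i in seq_len(nrow(ft))) {
    cov[(ft$start[i] + 1L):ft$end[i]] <- cov[(ft$start[i] + 1L):ft$end[i]] + 1L
  }
  # spacers + feature spans cover everything except introns (inside spans)
  expect_true(mean(cov >= 1L) > 0.99)
})

test_that("IR duplicate regions are flagged as copies", {
  cfg <- sim_config(genome_length = 40000, ir_length = 7000,
                    ssc_length = 4800, n_genes = 10, n_trnas = 5, seed = 3)
  g <- simulate_genome(cfg)
  reg <- extract_noncoding_regions(g)
  dup <- reg[!is.na(reg$copy_of), ]
  expect_gte(nrow(dup), 1L)
  # the flagged copy is reverse-complement-identical to its original
  for (i in seq_len(nrow(dup))) {
    orig <- reg[reg$name == dup$copy_of[i], ]
    expect_equal(region_sequence(g, orig),
                 rc(region_sequence(g, dup[i, ])))
  }
})
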