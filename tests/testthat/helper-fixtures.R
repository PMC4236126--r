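# Shared fixtures: a compact simulation configuration and a hand-written
# toy GenBank record with hand-computed coordinates.

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# mid-size configuration for aligner recovery properties (large enough
# that a 2% relative deviation spans at least one whole variant count)
mid_cfg <- function(seed = 1, ...) {
  sim_config(genome_length = 60000, ir_length = 10000, ssc_length = 7200,
             n_genes = 16, n_trnas = 8, seed = seed, ...)
}

small_cfg <- function(seed = 1, ...) {
  sim_config(genome_length = 24000, ir_length = 3200, ssc_length = 2600,
             n_genes = 6, n_trnas = 3, seed = seed, ...)
}

# 5 features: 2 single-interval genes, 1 tRNA, one 2-exon gene, and a second
# copy of geneA (exercises name de-duplication). GenBank is 1-based
# inclusive: geneA 11..100 -> [10,100); trnX complement(151..222) ->
# [150,222) strand -; geneB join(301..400,501..640) -> [300,400)+[500,640);
# geneC 701..820 -> [700,820); geneA (copy) 901..960 -> [900,960).
toy_genbank <- function(path) {
  seq <- paste(rep("acgtacgtac", 100), collapse = "")   # 1000 bp
  lines <- c(
    "LOCUS       TOY1             1000 bp    DNA     circular PLN 01-JAN-2026",
    "DEFINITION  toy record.",
    "ACCESSION   TOY1",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "     gene            11..100",
    '                     /gene="geneA"',
    "     tRNA            complement(151..222)",
    '                     /gene="trnX"',
    "     gene            join(301..400,501..640)",
    '                     /gene="geneB"',
    "     gene            701..820",
    '                     /gene="geneC"',
    "     gene            901..960",
    '                     /gene="geneA"',
    "ORIGIN",
    vapply(seq(1L, 1000L, 60L), function(st) {
      chunk <- substr(seq, st, min(st + 59L, 1000L))
      groups <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      sprintf("%9d %s", st, paste(groups, collapse = " "))
    }, character(1L)),
    "//")
  writeLines(lines, path)
  path
}

# independent brute-force indel classifier used as an oracle: operates on
# the full local context string with explicit scans, no shared code with
# classify_indel()
brute_classify <- function(indel_seq, left, right, min_polyn = 7) {
  ctx <- strsplit(paste0(left, indel_seq, right), "")[[1L]]
  s <- nchar(left) + 1L
  e <- nchar(left) + nchar(indel_seq)
  if (length(unique(ctx[s:e])) == 1L) {
    b <- ctx[s]
    i <- s; while (i > 1L && ctx[i - 1L] == b) i <- i - 1L
    j <- e; while (j < length(ctx) && ctx[j + 1L] == b) j <- j + 1L
    if (j - i + 1L >= min_polyn) return("polyN")
  }
  n <- nchar(indel_seq)
  if (n >= 2L) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(indel_seq)))
    up <- if (nchar(left) >= n) substr(left, nchar(left) - n + 1L,
                                       nchar(left)) else NA
    dn <- if (nchar(right) >= n) substr(right, 1L, n) else NA
    for (x in c(up, dn)) {
      if (!is.na(x) && (x == indel_seq || x == rc)) return("SSR_or_inversion")
    }
  }
  "other"
}

# random indel-event generator biased to produce all three classes
random_events <- function(n, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(len) paste(sample(bases, len, TRUE), collapse = "")
  out <- lapply(seq_len(n), function(i) {
    style <- sample(c("free", "homopolymer", "tandem"), 1L)
    if (style == "homopolymer") {
      b <- sample(bases, 1L)
      indel <- strrep(b, sample(1:4, 1L))
      left <- paste0(rand_seq(15), strrep(b, sample(0:6, 1L)))
      right <- paste0(strrep(b, sample(0:6, 1L)), rand_seq(15))
    } else if (style == "tandem") {
      indel <- rand_seq(sample(2:6, 1L))
      if (runif(1) < 0.5) {
        left <- paste0(rand_seq(14), indel); right <- rand_seq(20)
      } else {
        left <- rand_seq(20); right <- paste0(indel, rand_seq(14))
      }
    } else {
      indel <- rand_seq(sample(1:8, 1L))
      left <- rand_seq(20); right <- rand_seq(20)
    }
    data.frame(indel_seq = indel, flank_left = left, flank_right = right,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# insertion point on genome A of a called indel with carrier "a"
insertion_point_a <- function(aln, col_start) {
  if (col_start == 1L) return(0L)
  prev <- aln$col_to_pos_a[seq_len(col_start - 1L)]
  prev <- prev[!is.na(prev)]
  if (length(prev) == 0L) 0L else prev[length(prev)] + 1L
}

# planted vs called indel comparison key: (A-position, length, ins/del)
called_indel_keys <- function(aln, ind) {
  vapply(seq_len(nrow(ind)), function(i) {
    if (ind$carrier[i] == "b") {
      sprintf("del:%d:%d", aln$col_to_pos_a[ind$col_start[i]], ind$length[i])
    } else {
      sprintf("ins:%d:%d", insertion_point_a(aln, ind$col_start[i]),
              ind$length[i])
    }
  }, character(1L))
}

planted_indel_keys <- function(truth) {
  if (nrow(truth$indels) == 0L) return(character(0))
  sprintf("%s:%d:%d", truth$indels$type, truth$indels$pos,
          truth$indels$length)
}
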