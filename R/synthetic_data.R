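# Synthetic circular quadripartite genome pairs with a known edit script.
#
# The generator emulates the statistical structure the analysis assumes:
# a ~160 kb circular genome at GC ~0.37 with a quadripartite layout
# (LSC / IRa / SSC / IRb, the IRs exact reverse-complement copies), gene /
# tRNA / rRNA annotations including one trnK/matK nesting and multi-exon
# genes, planted homopolymer tracts as substrate for the polyN indel
# process, and low pairwise divergence with AT-biased SNP placement and
# three mutational indel classes.

#' Simulation configuration
#'
#' @param genome_length total genome size in bp.
#' @param gc target GC fraction.
#' @param n_genes,n_trnas numbers of genes and tRNAs to lay out.
#' @param ir_length inverted-repeat length (each copy).
#' @param ssc_length small single-copy segment length.
#' @param snp_rate per-site substitution probability between the pair.
#' @param at_bias probability that a SNP is placed inside a high-AT window
#'   (+-10 bp window with AT >= 0.8) rather than uniformly.
#' @param indel_rate_polyn,indel_rate_ssr,indel_rate_other per-kb event
#'   rates of the three indel classes.
#' @param indel_mean_len mean length (geometric law) of class-"other" indels.
#' @param homopolymer_density planted homopolymer tracts (length 7-15) per bp.
#' @param inversion_count,inversion_length planted inversions.
#' @param seed RNG seed (integer).
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(genome_length = 160000, gc = 0.366,
                       n_genes = 60, n_trnas = 22,
                       ir_length = 26000, ssc_length = 19200,
                       snp_rate = 0.0015, at_bias = 0.7,
                       indel_rate_polyn = 0.3, indel_rate_ssr = 0.2,
                       indel_rate_other = 0.55, indel_mean_len = 4,
                       homopolymer_density = 1 / 2000,
                       inversion_count = 0, inversion_length = 30,
                       seed = 1) {
  cfg <- list(genome_length = as.integer(genome_length), gc = gc,
              n_genes = as.integer(n_genes), n_trnas = as.integer(n_trnas),
              ir_length = as.integer(ir_length),
              ssc_length = as.integer(ssc_length),
              snp_rate = snp_rate, at_bias = at_bias,
              indel_rate_polyn = indel_rate_polyn,
              indel_rate_ssr = indel_rate_ssr,
              indel_rate_other = indel_rate_other,
              indel_mean_len = indel_mean_len,
              homopolymer_density = homopolymer_density,
              inversion_count = as.integer(inversion_count),
              inversion_length = as.integer(inversion_length),
              seed = as.integer(seed))
  if (cfg$gc <= 0 || cfg$gc >= 1) stop("sim_config: gc must be in (0,1)")
  rates <- c(cfg$snp_rate, cfg$indel_rate_polyn, cfg$indel_rate_ssr,
             cfg$indel_rate_other, cfg$homopolymer_density)
  if (any(rates < 0)) stop("sim_config: rates must be >= 0")
  if (cfg$at_bias < 0 || cfg$at_bias > 1) stop("sim_config: at_bias in [0,1]")
  if (2L * cfg$ir_length + cfg$ssc_length >= cfg$genome_length) {
    stop("sim_config: IR pair plus SSC does not fit in the genome")
  }
  structure(cfg, class = "sim_config")
}

# lay out features with random sizes inside [from, to); returns rows placed
layout_features <- function(from, to, n_genes, n_trnas, start_index) {
  rows <- list()
  cur <- from
  gi <- 0L; ti <- 0L
  while ((gi < n_genes || ti < n_trnas) && cur < to - 700L) {
    cur <- cur + sample(120:500, 1L)           # spacer before the feature
    if (ti < n_trnas && (gi >= n_genes || runif(1) < 0.3)) {
      len <- 72L
      if (cur + len >= to) break
      ti <- ti + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("trn%02d", start_index + ti), kind = "tRNA",
        strand = sample(c("+", "-"), 1L), start = cur, end = cur + len,
        part = 1L, stringsAsFactors = FALSE)
      cur <- cur + len
    } else if (gi < n_genes) {
      gi <- gi + 1L
      nm <- sprintf("gene%02d", start_index + gi)
      strand <- sample(c("+", "-"), 1L)
      if (runif(1) < 0.25) {                   # two-exon gene with intron
        e1 <- sample(100:350, 1L); intr <- sample(350:900, 1L)
        e2 <- sample(150:600, 1L)
        if (cur + e1 + intr + e2 >= to) break
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, kind = "gene", strand = strand,
          start = c(cur, cur + e1 + intr),
          end = c(cur + e1, cur + e1 + intr + e2),
          part = 1:2, stringsAsFactors = FALSE)
        cur <- cur + e1 + intr + e2
      } else {
        len <- sample(300:1800, 1L)
        if (cur + len >= to) break
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, kind = "gene", strand = strand, start = cur,
          end = cur + len, part = 1L, stringsAsFactors = FALSE)
        cur <- cur + len
      }
    }
  }
  list(rows = rows, genes_placed = gi, trnas_placed = ti)
}

#' Simulate an annotated quadripartite genome
#'
#' Seeded and reproducible: the same configuration yields a byte-identical
#' genome. Base composition matches \code{cfg$gc} within about half a
#' percent; the IR pair is planted as exact reverse-complement copies (and
#' annotated, kind "IR"); one trnK/matK nesting is always included so the
#' trnK intron split rule is exercised; homopolymer tracts of 7-15 bp are
#' planted at \code{cfg$homopolymer_density} as substrate for polyN indels.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return an \code{\link{annotated_genome}}.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$genome_length
  gc <- cfg$gc
  ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  lsc_len <- L - 2L * cfg$ir_length - cfg$ssc_length
  ira <- c(lsc_len, lsc_len + cfg$ir_length)
  ssc <- c(ira[2L], ira[2L] + cfg$ssc_length)
  irb <- c(ssc[2L], L)

  # homopolymer tracts (before IR mirroring so both copies stay identical)
  n_hp <- round(L * cfg$homopolymer_density)
  if (n_hp > 0L) {
    hp_pos <- sample.int(L - 20L, n_hp)
    for (p in hp_pos) {
      len <- sample(7:15, 1L)
      ch[p:(p + len - 1L)] <- sample(c("A", "T"), 1L)
    }
  }
  # IRb = exact reverse complement of IRa
  ira_seq <- paste(ch[(ira[1L] + 1L):ira[2L]], collapse = "")
  ch[(irb[1L] + 1L):irb[2L]] <- seq_chars(revcomp(ira_seq))
  # break reverse-complement pairing just outside the repeat boundaries so
  # the planted repeat is the maximal one (a base is never its own
  # complement, so copying the partner base always breaks pairing)
  # (the other flank pairs beyond the sequence end and needs no break)
  ch[ssc[2L]] <- ch[ira[2L] + 1L]              # last SSC base vs first base after IRa
  ch[ssc[2L] - 1L] <- ch[ira[2L] + 2L]

  rows <- list()
  # trnK/matK nesting at the start of the LSC (always present)
  rows[[1L]] <- data.frame(name = "trnK", kind = "tRNA", strand = "+",
                           start = c(1000L, 2950L), end = c(1037L, 2987L),
                           part = 1:2, stringsAsFactors = FALSE)
  rows[[2L]] <- data.frame(name = "matK", kind = "gene", strand = "+",
                           start = 1300L, end = 2800L, part = 1L,
                           stringsAsFactors = FALSE)
  # genes and tRNAs across the LSC, remainder into the SSC
  lsc_fill <- layout_features(3200L, lsc_len, cfg$n_genes, cfg$n_trnas, 0L)
  rows <- c(rows, lsc_fill$rows)
  rem_g <- cfg$n_genes - lsc_fill$genes_placed
  rem_t <- cfg$n_trnas - lsc_fill$trnas_placed
  if (rem_g > 0L || rem_t > 0L) {
    ssc_fill <- layout_features(ssc[1L] + 200L, ssc[2L] - 200L, rem_g, rem_t,
                                cfg$n_genes)
    rows <- c(rows, ssc_fill$rows)
    if (ssc_fill$genes_placed < rem_g || ssc_fill$trnas_placed < rem_t) {
      stop("sim_config: requested features exceed the genome layout capacity")
    }
  }
  # rRNA pair inside IRa, mirrored into IRb
  if (cfg$ir_length >= 6000L) {
    ir_rna <- data.frame(name = c("rrnL", "rrnS"), kind = "rRNA",
                         strand = "+",
                         start = ira[1L] + c(1000L, 4200L),
                         end = ira[1L] + c(3800L, 5700L), part = 1L,
                         stringsAsFactors = FALSE)
    mirror <- ir_rna
    mirror$name <- paste0(ir_rna$name, "_2")
    mirror$strand <- "-"
    off_s <- ir_rna$start - ira[1L]; off_e <- ir_rna$end - ira[1L]
    mirror$start <- irb[1L] + (cfg$ir_length - off_e)
    mirror$end <- irb[1L] + (cfg$ir_length - off_s)
    rows <- c(rows, list(ir_rna, mirror))
  }
  # annotate the IRs themselves
  rows <- c(rows, list(data.frame(
    name = c("IRa", "IRb"), kind = "IR", strand = "+",
    start = c(ira[1L], irb[1L]), end = c(ira[2L], irb[2L]), part = 1L,
    stringsAsFactors = FALSE)))

  annotated_genome(id = sprintf("SIM%dA", cfg$seed),
                   sequence = paste(ch, collapse = ""),
                   features = do.call(rbind, rows), circular = TRUE,
                   source = NA_character_)
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Mutate a genome into a diverged partner with a known edit script
#'
#' Plants SNPs (count ~ Binomial(length, snp_rate); with probability
#' \code{at_bias} a SNP goes uniformly into a position whose +-10 bp window
#' has AT >= 0.8, else uniformly), the three indel classes (polyN: +-1 base
#' at a planted homopolymer of >= 7; SSR: gain or loss of one tandem copy of
#' a 2-6 bp motif adjacent to an existing copy; other: random-sequence
#' insertions / deletions of geometric length), and optional inversions.
#' Edits never overlap (rejection sampling); the true pairwise alignment is
#' built directly from the edit script, so applying the script to genome A
#' reproduces genome B exactly.
#'
#' @param genome an \code{annotated_genome} (genome A).
#' @param cfg the \code{\link{sim_config}} (rates and seed).
#' @return list: \code{genome_b} (\code{annotated_genome} with coordinates
#'   lifted through the edit script), \code{truth} of class
#'   \code{ground_truth} with fields snps, indels, inversions (planted
#'   edits, 0-based A coordinates), alignment (the true
#'   \code{pairwise_alignment}).
#' @export
mutate_genome <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  s <- genome$sequence
  L <- nchar(s)
  ch <- seq_chars(s)

  occupied <- logical(L)
  rejections <- 0L
  reserve <- function(from0, to0, margin = 1L) {
    idx <- max(1L, from0 + 1L - margin):min(L, to0 + margin)
    if (any(occupied[idx])) return(FALSE)
    occupied[idx] <<- TRUE
    TRUE
  }
  too_many <- function() {
    rejections <<- rejections + 1L
    if (rejections > 1000L) {
      stop("mutate_genome: > 1000 placement rejections; rates too high ",
           "for the genome length")
    }
  }

  # high-AT windows (+-10 bp, AT >= 0.8) for biased SNP placement
  at01 <- as.integer(ch %in% c("A", "T"))
  cs <- c(0L, cumsum(at01))
  centers <- 11:(L - 10L)
  roll <- cs[centers + 11L] - cs[centers - 10L]
  hot <- centers[roll >= ceiling(0.8 * 21)]

  snps <- list()
  n_snp <- rbinom(1L, L, cfg$snp_rate)
  for (i in seq_len(n_snp)) {
    repeat {
      pos1 <- if (length(hot) > 0L && runif(1) < cfg$at_bias)
        hot[sample.int(length(hot), 1L)] else sample.int(L, 1L)
      if (is_acgt(ch[pos1]) && reserve(pos1 - 1L, pos1 - 1L)) break
      too_many()
    }
    from <- ch[pos1]
    to <- sample(setdiff(c("A", "C", "G", "T"), from), 1L)
    snps[[length(snps) + 1L]] <- data.frame(pos = pos1 - 1L, from = from,
                                            to = to, stringsAsFactors = FALSE)
  }

  indels <- list()
  # polyN: +-1 base at planted homopolymer runs >= 7
  n_pn <- rpois(1L, cfg$indel_rate_polyn * L / 1000)
  if (n_pn > 0L) {
    r <- rle(ch)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    cand <- which(r$lengths >= 7L & r$values %in% c("A", "C", "G", "T"))
    cand <- cand[sample.int(length(cand))]
    placed <- 0L
    for (ci in cand) {
      if (placed >= n_pn) break
      rs <- starts[ci]; re <- ends[ci]
      if (!reserve(rs - 1L, re - 1L)) { too_many(); next }
      ins <- runif(1) < 0.5
      indels[[length(indels) + 1L]] <- data.frame(
        pos = rs - 1L, length = 1L, type = if (ins) "ins" else "del",
        class = "polyN", seq = r$values[ci], stringsAsFactors = FALSE)
      placed <- placed + 1L
    }
  }
  # SSR: gain/loss of one tandem copy of a 2-6 bp motif
  n_ssr <- rpois(1L, cfg$indel_rate_ssr * L / 1000)
  for (i in seq_len(n_ssr)) {
    repeat {
      p1 <- sample.int(L - 20L, 1L)            # 1-based motif start
      m <- sample(2:6, 1L)
      motif <- substr(s, p1, p1 + m - 1L)
      mc <- seq_chars(motif)
      if (all(is_acgt(mc)) && !all(mc == mc[1L]) &&
          reserve(p1 - 1L, p1 + 2L * m - 2L)) break
      too_many()
    }
    nxt <- substr(s, p1 + m, p1 + 2L * m - 1L)
    if (identical(nxt, motif)) {               # tandem exists: delete a copy
      indels[[length(indels) + 1L]] <- data.frame(
        pos = p1 + m - 1L, length = m, type = "del", class = "SSR",
        seq = motif, stringsAsFactors = FALSE)
    } else {                                   # duplicate the motif
      indels[[length(indels) + 1L]] <- data.frame(
        pos = p1 + m - 1L, length = m, type = "ins", class = "SSR",
        seq = motif, stringsAsFactors = FALSE)
    }
  }
  # other: random-sequence insertions / deletions of geometric length
  n_ot <- rpois(1L, cfg$indel_rate_other * L / 1000)
  base_prob <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  for (i in seq_len(n_ot)) {
    len <- rgeom(1L, 1 / cfg$indel_mean_len) + 1L
    del <- runif(1) < 0.5
    repeat {
      p1 <- sample.int(L - len - 10L, 1L)
      seg <- if (del) substr(s, p1, p1 + len - 1L) else
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                     prob = base_prob), collapse = "")
      sc <- seq_chars(seg)
      if ((len == 1L || !all(sc == sc[1L])) && all(is_acgt(sc)) &&
          reserve(p1 - 1L, p1 + len - 2L)) break
      too_many()
    }
    indels[[length(indels) + 1L]] <- data.frame(
      pos = p1 - 1L, length = len, type = if (del) "del" else "ins",
      class = "other", seq = seg, stringsAsFactors = FALSE)
  }
  # inversions: reverse-complement a block; placements whose boundary base
  # self-pairs are rejected so the planted coordinates are recoverable
  inversions <- list()
  for (i in seq_len(cfg$inversion_count)) {
    l <- cfg$inversion_length
    repeat {
      p1 <- sample.int(L - l - 10L, 1L)
      blk <- substr(s, p1, p1 + l - 1L)
      bc <- seq_chars(blk)
      boundary_mismatch <- bc[1L] != comp_base[[bc[l]]]
      if (all(is_acgt(bc)) && boundary_mismatch &&
          !identical(blk, revcomp(blk)) && reserve(p1 - 1L, p1 + l - 2L)) break
      too_many()
    }
    inversions[[length(inversions) + 1L]] <- data.frame(
      pos = p1 - 1L, length = l, stringsAsFactors = FALSE)
  }

  snps <- if (length(snps)) do.call(rbind, snps) else
    data.frame(pos = integer(), from = character(), to = character(),
               stringsAsFactors = FALSE)
  indels <- if (length(indels)) do.call(rbind, indels) else
    data.frame(pos = integer(), length = integer(), type = character(),
               class = character(), seq = character(), stringsAsFactors = FALSE)
  inversions <- if (length(inversions)) do.call(rbind, inversions) else
    data.frame(pos = integer(), length = integer(), stringsAsFactors = FALSE)

  # ---- apply the edit script and build the true alignment ----
  ev <- rbind(
    if (nrow(snps)) data.frame(pos = snps$pos, kind = "snp",
                               len = 1L, seq = snps$to),
    if (nrow(indels)) data.frame(pos = indels$pos, kind = indels$type,
                                 len = indels$length, seq = indels$seq),
    if (nrow(inversions)) data.frame(pos = inversions$pos, kind = "inv",
                                     len = inversions$length, seq = NA))
  pa <- character(0); pb <- character(0)
  cur <- 0L
  if (!is.null(ev) && nrow(ev) > 0L) {
    ev <- ev[order(ev$pos), , drop = FALSE]
    for (j in seq_len(nrow(ev))) {
      e <- ev[j, ]
      if (e$pos > cur) {
        seg <- substr(s, cur + 1L, e$pos)
        pa <- c(pa, seg); pb <- c(pb, seg)
      }
      if (e$kind == "snp") {
        pa <- c(pa, substr(s, e$pos + 1L, e$pos + 1L)); pb <- c(pb, e$seq)
        cur <- e$pos + 1L
      } else if (e$kind == "del") {            # B lacks these A bases
        pa <- c(pa, substr(s, e$pos + 1L, e$pos + e$len))
        pb <- c(pb, strrep("-", e$len))
        cur <- e$pos + e$len
      } else if (e$kind == "ins") {            # B gains seq before A[pos]
        pa <- c(pa, strrep("-", e$len)); pb <- c(pb, e$seq)
        cur <- e$pos
      } else {                                 # inversion
        seg <- substr(s, e$pos + 1L, e$pos + e$len)
        pa <- c(pa, seg); pb <- c(pb, revcomp(seg))
        cur <- e$pos + e$len
      }
    }
  }
  if (cur < L) {
    seg <- substr(s, cur + 1L, L)
    pa <- c(pa, seg); pb <- c(pb, seg)
  }
  aln <- pairwise_alignment(paste(pa, collapse = ""), paste(pb, collapse = ""),
                            id_a = genome$id,
                            id_b = sub("A$", "B", genome$id),
                            drop_all_gap = FALSE)

  # lift feature coordinates from A to B through the alignment
  cols_a <- which(!is.na(aln$col_to_pos_a))
  pb_map <- aln$col_to_pos_b
  ft <- genome$features
  lift_start <- function(x) {                  # first B base at or after col
    cl <- cols_a[x + 1L]
    nn <- which(!is.na(pb_map[cl:length(pb_map)]))[1L]
    pb_map[cl + nn - 1L]
  }
  lift_end <- function(x) {                    # B position after last base
    cl <- cols_a[x]                            # column of A base x-1
    nn <- which(!is.na(pb_map[1:cl]))
    pb_map[nn[length(nn)]] + 1L
  }
  ftb <- ft
  ftb$start <- vapply(ft$start, lift_start, integer(1L))
  ftb$end <- vapply(ft$end, lift_end, integer(1L))
  ftb <- ftb[ftb$start < ftb$end, , drop = FALSE]
  genome_b <- annotated_genome(id = sub("A$", "B", genome$id),
                               sequence = ungap(aln$row_b), features = ftb,
                               circular = genome$circular)

  truth <- structure(list(snps = snps, indels = indels,
                          inversions = inversions, alignment = aln,
                          rejections = rejections),
                     class = "ground_truth")
  list(genome_b = genome_b, truth = truth)
}

#' Simulate a full genome pair
#'
#' Convenience wrapper: \code{\link{simulate_genome}} then
#' \code{\link{mutate_genome}}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list: genome_a, genome_b, truth.
#' @export
simulate_pair <- function(cfg) {
  a <- simulate_genome(cfg)
  mb <- mutate_genome(a, cfg)
  list(genome_a = a, genome_b = mb$genome_b, truth = mb$truth)
}

#' Write a simulated pair with its ground truth
#'
#' Writes GenBank flat files for both genomes, the true alignment as
#' two-record gapped FASTA, and a JSON manifest of the planted edit script.
#'
#' @param pair output of \code{\link{simulate_pair}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_ground_truth <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pa <- file.path(dir, "genome_a.gb")
  pb <- file.path(dir, "genome_b.gb")
  pt <- file.path(dir, "truth_alignment.fasta")
  pj <- file.path(dir, "ground_truth.json")
  write_genbank(pair$genome_a, pa)
  write_genbank(pair$genome_b, pb)
  write_alignment(pair$truth$alignment, pt)
  jsonlite::write_json(list(snps = pair$truth$snps,
                            indels = pair$truth$indels,
                            inversions = pair$truth$inversions),
                       pj, dataframe = "rows", auto_unbox = TRUE)
  invisible(c(genome_a = pa, genome_b = pb, alignment = pt, manifest = pj))
}
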