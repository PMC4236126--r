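# Per-region and whole-genome variability statistics, rankings and
# sliding-window tracks.

#' Slice an alignment to a genomic region
#'
#' The region interval lives on genome A (the first alignment row). The
#' slice covers columns [col(start), col(end)) where col maps ungapped
#' A-positions to alignment columns -- so insertion columns of B inside the
#' region are included, insertions immediately before the region start are
#' not (left-closed/right-open convention).
#'
#' @param aln a \code{pairwise_alignment}.
#' @param region one row of a \code{genomic_regions} table (fields start,
#'   end; end beyond the genome length, i.e. an origin-spanning region, is
#'   rejected here -- rotate the alignment instead).
#' @return a \code{pairwise_alignment} over the slice, with attribute
#'   \code{col_offset} (0-based first column of the slice).
#' @export
region_slice <- function(aln, region) {
  la <- sum(!is.na(aln$col_to_pos_a))
  if (region$start < 0L || region$end > la || region$start >= region$end) {
    stop("region '", region$name %||% "?", "' [", region$start, ",",
         region$end, ") outside genome A [0,", la, ")")
  }
  poscols <- which(!is.na(aln$col_to_pos_a))     # column of each A position
  c0 <- poscols[region$start + 1L]
  c1 <- if (region$end < la) poscols[region$end + 1L] else
    alignment_ncol(aln) + 1L
  sub <- pairwise_alignment(substr(aln$row_a, c0, c1 - 1L),
                            substr(aln$row_b, c0, c1 - 1L),
                            id_a = aln$id_a, id_b = aln$id_b,
                            drop_all_gap = FALSE)
  attr(sub, "col_offset") <- c0 - 1L
  sub
}

#' Variability statistics of one region
#'
#' PICs (potentially informative characters) = SNPs + indel events +
#' inversions. The p-distance is SNPs divided by the number of columns with
#' no gap in either row and no ambiguity code (indel and ambiguous positions
#' are not counted); it is reported as NA when that denominator is zero.
#'
#' @param sub a region slice (\code{\link{region_slice}}).
#' @param region the region row the slice came from.
#' @return one-row data.frame: name, kind, aligned_length, snps, indels,
#'   inversions, pics, p_distance, contains_homopolymer, complex_indels.
#' @export
compute_region_stats <- function(sub, region) {
  vs <- call_variants(sub)
  cls <- column_classes(sub)
  denom <- sum(cls == "identical" | cls == "snp")
  nsnp <- nrow(vs$snps)
  nind <- nrow(vs$indels)
  ninv <- nrow(vs$inversions)
  seq_a <- ungap(sub$row_a)
  hp <- if (nchar(seq_a) > 0L)
    find_homopolymers(seq_a, min_len = 8, bases = c("A", "C", "G", "T")) else
      data.frame()
  data.frame(name = region$name, kind = region$kind %||% NA_character_,
             aligned_length = alignment_ncol(sub),
             snps = nsnp, indels = nind, inversions = ninv,
             pics = nsnp + nind + ninv,
             p_distance = if (denom > 0L) nsnp / denom else NA_real_,
             contains_homopolymer = nrow(hp) > 0L,
             complex_indels = any(vs$indels$complex),
             stringsAsFactors = FALSE)
}

#' Statistics for every region of a table
#'
#' Regions flagged as IR duplicates (\code{copy_of} set) are skipped so each
#' unique region is counted once; origin-spanning regions are skipped with a
#' warning.
#'
#' @param aln a \code{pairwise_alignment} (row a = the reference the regions
#'   are annotated on).
#' @param regions a \code{genomic_regions} table.
#' @return data.frame of class \code{region_stats}, one row per region.
#' @export
region_stats_table <- function(aln, regions) {
  la <- sum(!is.na(aln$col_to_pos_a))
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    if (!is.na(reg$copy_of)) next
    if (reg$end > la) {
      warning("region '", reg$name, "' spans the origin; skipped ",
              "(rotate the linearisation to analyse it)")
      next
    }
    rows[[length(rows) + 1L]] <-
      compute_region_stats(region_slice(aln, reg), reg)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("region_stats", "data.frame")
  out
}

#' Rank regions by variability
#'
#' Descending sort on \code{key}; ties broken by the other key (descending),
#' then aligned length (descending), then name (ascending).
#'
#' @param stats a \code{region_stats} table.
#' @param key "p_distance" or "pics".
#' @param top_n number of rows to keep (default 30).
#' @return the top rows with a \code{rank} column prepended.
#' @export
rank_regions <- function(stats, key = c("p_distance", "pics"), top_n = 30) {
  key <- match.arg(key)
  if (nrow(stats) == 0L) stop("rank_regions: empty statistics table")
  other <- if (key == "p_distance") "pics" else "p_distance"
  o <- order(-xtfrm(stats[[key]]), -xtfrm(stats[[other]]),
             -stats$aligned_length, stats$name)
  out <- stats[o, , drop = FALSE]
  out <- head(out, top_n)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Whole-genome pair summary
#'
#' @param aln a \code{pairwise_alignment}.
#' @return one-row data.frame mirroring a per-pair sequence statistics
#'   table: p_distance over all gap-free unambiguous columns,
#'   aligned_length, length_difference, snps, indels.
#' @export
whole_genome_summary <- function(aln) {
  vs <- call_variants(aln)
  cls <- column_classes(aln)
  denom <- sum(cls == "identical" | cls == "snp")
  la <- sum(!is.na(aln$col_to_pos_a)); lb <- sum(!is.na(aln$col_to_pos_b))
  data.frame(id_a = aln$id_a, id_b = aln$id_b,
             p_distance = if (denom > 0L) nrow(vs$snps) / denom else NA_real_,
             aligned_length = alignment_ncol(aln),
             length_difference = abs(la - lb),
             snps = nrow(vs$snps), indels = nrow(vs$indels),
             stringsAsFactors = FALSE)
}

#' Sliding-window variability track
#'
#' Non-overlapping windows ("slots") of \code{window} consensus bases; the
#' final short window is kept and flagged. SNPs are assigned by consensus
#' position, an indel to the window containing its first column. Relative AT
#' is window AT divided by the whole-consensus AT.
#'
#' @param cons a \code{consensus_sequence}.
#' @param vs a \code{variant_set} from the same alignment.
#' @param window slot size in consensus bases (default 500).
#' @return data.frame of class \code{window_track}: start (0-based on
#'   consensus), end, snp_count, indel_count, at_content,
#'   at_relative_to_genome, short.
#' @export
sliding_windows <- function(cons, vs, window = 500) {
  if (window < 1L) stop("sliding_windows: window must be >= 1")
  n <- nchar(cons$bases)
  starts <- seq(0L, n - 1L, by = window)
  ends <- pmin(starts + window, n)
  wof <- function(pos1) pmin(findInterval(pos1 - 1L, starts), length(starts))
  snp_w <- if (nrow(vs$snps) > 0L) tabulate(wof(vs$snps$column),
                                            length(starts)) else
    integer(length(starts))
  ind_w <- if (nrow(vs$indels) > 0L) tabulate(wof(vs$indels$col_start),
                                              length(starts)) else
    integer(length(starts))
  at <- vapply(seq_along(starts), function(i) {
    s <- substr(cons$bases, starts[i] + 1L, ends[i])
    tryCatch(at_content(s), error = function(e) NA_real_)
  }, numeric(1L))
  out <- data.frame(start = starts, end = ends, snp_count = snp_w,
                    indel_count = ind_w, at_content = at,
                    at_relative_to_genome = at / cons$at_content,
                    short = (ends - starts) < window)
  class(out) <- c("window_track", "data.frame")
  out
}
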