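# Pairwise alignment of near-identical genomes: anchor-chained built-in
# aligner, gapped-FASTA ingestion, column/position maps, consensus.

#' Construct a pairwise alignment object
#'
#' @param row_a,row_b equal-length gapped strings over A/C/G/T/N/IUPAC/-.
#' @param id_a,id_b genome identifiers.
#' @param drop_all_gap remove columns gapped in both rows (logged count kept
#'   in the \code{dropped_columns} field); such columns carry no pairwise
#'   information.
#' @return object of class \code{pairwise_alignment} with fields
#'   \code{row_a}, \code{row_b}, \code{id_a}, \code{id_b},
#'   \code{col_to_pos_a}, \code{col_to_pos_b} (0-based ungapped position per
#'   column, NA at gaps).
#' @export
pairwise_alignment <- function(row_a, row_b, id_a = "A", id_b = "B",
                               drop_all_gap = TRUE) {
  row_a <- toupper(row_a); row_b <- toupper(row_b)
  if (nchar(row_a) != nchar(row_b)) {
    stop("alignment rows have unequal lengths (", nchar(row_a), " vs ",
         nchar(row_b), ")")
  }
  ca <- seq_chars(row_a); cb <- seq_chars(row_b)
  dropped <- 0L
  both_gap <- ca == "-" & cb == "-"
  if (any(both_gap)) {
    if (!drop_all_gap) stop("columns gapped in both rows are not allowed")
    dropped <- sum(both_gap)
    ca <- ca[!both_gap]; cb <- cb[!both_gap]
    row_a <- paste(ca, collapse = ""); row_b <- paste(cb, collapse = "")
  }
  pos_a <- cumsum(ca != "-") - 1L; pos_a[ca == "-"] <- NA_integer_
  pos_b <- cumsum(cb != "-") - 1L; pos_b[cb == "-"] <- NA_integer_
  structure(list(row_a = row_a, row_b = row_b, id_a = id_a, id_b = id_b,
                 col_to_pos_a = pos_a, col_to_pos_b = pos_b,
                 dropped_columns = dropped),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s / %s: %d columns (%d / %d bp ungapped)\n",
              x$id_a, x$id_b, nchar(x$row_a),
              sum(!is.na(x$col_to_pos_a)), sum(!is.na(x$col_to_pos_b))))
  invisible(x)
}

#' Number of columns of a pairwise alignment
#' @param aln a \code{pairwise_alignment}.
#' @return integer column count.
#' @export
alignment_ncol <- function(aln) nchar(aln$row_a)

#' Ungapped sequences of an alignment
#' @param aln a \code{pairwise_alignment}.
#' @return named character vector of the two input sequences.
#' @export
alignment_sequences <- function(aln) {
  setNames(c(ungap(aln$row_a), ungap(aln$row_b)), c(aln$id_a, aln$id_b))
}

#' Load a two-record gapped FASTA alignment
#'
#' @param path FASTA with exactly two equal-length gapped records.
#' @return a \code{pairwise_alignment}; columns gapped in both rows are
#'   removed and counted in \code{dropped_columns}.
#' @export
load_alignment <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2L) {
    stop("'", path, "': expected exactly 2 records, found ", length(recs))
  }
  if (Biostrings::width(recs)[1L] != Biostrings::width(recs)[2L]) {
    stop("'", path, "': records have unequal gapped lengths")
  }
  ids <- sub("\\s.*", "", names(recs))
  aln <- pairwise_alignment(as.character(recs[[1L]]), as.character(recs[[2L]]),
                            id_a = ids[1L], id_b = ids[2L])
  if (aln$dropped_columns > 0L) {
    message("load_alignment: removed ", aln$dropped_columns,
            " columns gapped in both rows")
  }
  aln
}

#' Write an alignment as two-record gapped FASTA
#' @param aln a \code{pairwise_alignment}.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(c(aln$row_a, aln$row_b),
                                    c(aln$id_a, aln$id_b))), path)
  invisible(path)
}

#' Write the alignment column map as TSV (column, pos_a, pos_b)
#' @param aln a \code{pairwise_alignment}.
#' @param path output file.
#' @export
write_column_map <- function(aln, path) {
  write.table(data.frame(column = seq_len(alignment_ncol(aln)),
                         pos_a = aln$col_to_pos_a, pos_b = aln$col_to_pos_b),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- built-in anchor-chained aligner ----

# longest strictly increasing subsequence (indices), patience method;
# tail values kept in a preallocated vector so each step is O(log n)
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tvals <- integer(n); tidx <- integer(n); len <- 0L
  prev <- integer(n)
  for (i in seq_len(n)) {
    xi <- x[i]
    lo <- 1L; hi <- len                        # first tail >= xi
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      if (tvals[mid] < xi) lo <- mid + 1L else hi <- mid - 1L
    }
    j <- lo
    prev[i] <- if (j > 1L) tidx[j - 1L] else 0L
    tvals[j] <- xi; tidx[j] <- i
    if (j > len) len <- j
  }
  out <- integer(len); i <- tidx[len]; pos <- len
  while (i > 0L) { out[pos] <- i; pos <- pos - 1L; i <- prev[i] }
  out
}

unique_kmer_positions <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(list(kmers = character(0), pos = integer(0)))
  km <- substring(s, seq_len(n), seq_len(n) + k - 1L)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  list(kmers = km[!dup], pos = which(!dup) - 1L)   # 0-based
}

global_align_segment <- function(sa, sb) {
  if (nchar(sa) == 0L && nchar(sb) == 0L) return(c("", ""))
  if (nchar(sa) == 0L) return(c(strrep("-", nchar(sb)), sb))
  if (nchar(sb) == 0L) return(c(sa, strrep("-", nchar(sa))))
  la <- nchar(sa); lb <- nchar(sb)
  if (la == lb) {
    # equal lengths with few mismatches: the gapless alignment is optimal
    # (any length-preserving gapped alternative pays two gap openings >= 10,
    # recovering at most 2 per mismatch)
    d <- sum(seq_chars(sa) != seq_chars(sb))
    if (d <= 4L) return(c(sa, sb))
  } else {
    # mismatch-free single indel: longest common prefix + suffix cover the
    # shorter segment, the optimal alignment is one gap run between them
    ca <- seq_chars(sa); cb <- seq_chars(sb)
    n <- min(la, lb)
    pre <- which(ca[seq_len(n)] != cb[seq_len(n)])
    p <- if (length(pre) == 0L) n else pre[1L] - 1L
    suf <- which(rev(ca)[seq_len(n)] != rev(cb)[seq_len(n)])
    s <- if (length(suf) == 0L) n else suf[1L] - 1L
    s <- min(s, n - p)
    if (p + s == n) {
      gap <- strrep("-", abs(la - lb))
      if (la < lb) {
        return(c(paste0(substr(sa, 1L, p), gap, substr(sa, p + 1L, la)), sb))
      } else {
        return(c(sa, paste0(substr(sb, 1L, p), gap, substr(sb, p + 1L, lb))))
      }
    }
  }
  if (nchar(sa) > 20000L || nchar(sb) > 20000L) {
    stop("align_pair: unanchored segment of ", max(nchar(sa), nchar(sb)),
         " bp; sequences too divergent for the built-in aligner, ",
         "supply an external alignment")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 4, gapExtension = 1)
  c(as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)))
}

#' Align two near-identical genomes
#'
#' Built-in aligner for low-divergence pairs (p up to about 1 percent):
#' collects unique shared k-mers as anchors, chains the longest collinear
#' subset, aligns each inter-anchor segment globally (match +1, mismatch -1,
#' gap open -4, gap extend -1) and concatenates. Circular inputs whose
#' deposits start at different origins are rotated to a shared anchor before
#' alignment. The result always satisfies the round-trip invariant: removing
#' gaps from each row reproduces the input sequences exactly.
#'
#' @param a,b \code{annotated_genome} objects (or plain DNA strings).
#' @param k anchor k-mer size.
#' @param band maximum segment length difference treated as alignable
#'   (guards the dynamic-programming step).
#' @return a \code{pairwise_alignment}; field \code{rotation_b} records any
#'   rotation applied to b (bp, 0 if none).
#' @export
align_pair <- function(a, b, k = 21, band = 200) {
  sa <- if (inherits(a, "annotated_genome")) a$sequence else toupper(a)
  sb <- if (inherits(b, "annotated_genome")) b$sequence else toupper(b)
  id_a <- if (inherits(a, "annotated_genome")) a$id else "A"
  id_b <- if (inherits(b, "annotated_genome")) b$id else "B"
  if (nchar(sa) == 0L || nchar(sb) == 0L) stop("align_pair: empty sequence")

  chain_anchors <- function(sa, sb) {
    ua <- unique_kmer_positions(sa, k)
    ub <- unique_kmer_positions(sb, k)
    m <- match(ua$kmers, ub$kmers)
    keep <- !is.na(m)
    pa <- ua$pos[keep]; pb <- ub$pos[m[keep]]
    o <- order(pa); pa <- pa[o]; pb <- pb[o]
    sel <- lis_indices(pb)
    pa <- pa[sel]; pb <- pb[sel]
    # enforce non-overlapping anchors along both sequences
    keep <- logical(length(pa))
    last_a <- -k; last_b <- -k
    for (i in seq_along(pa)) {
      if (pa[i] >= last_a + k && pb[i] >= last_b + k) {
        keep[i] <- TRUE; last_a <- pa[i]; last_b <- pb[i]
      }
    }
    list(pa = pa[keep], pb = pb[keep])
  }

  # circular deposits may start at different origins; a nonzero modal
  # k-mer offset reveals the rotation, which must not become terminal gaps
  rotation_b <- 0L
  ua <- unique_kmer_positions(sa, k); ub <- unique_kmer_positions(sb, k)
  m <- match(ua$kmers, ub$kmers)
  hit <- which(!is.na(m))
  if (length(hit) > 0L) {
    d <- (ub$pos[m[hit]] - ua$pos[hit]) %% nchar(sb)
    tab <- table(d)
    d_star <- as.integer(names(tab)[which.max(tab)])
    if (d_star > band && nchar(sb) - d_star > band &&
        max(tab) >= 0.3 * length(hit)) {
      sb <- paste0(substr(sb, d_star + 1L, nchar(sb)),
                   substr(sb, 1L, d_star))
      rotation_b <- d_star
    }
  }
  anchors <- chain_anchors(sa, sb)
  coverage <- length(anchors$pa) * k / min(nchar(sa), nchar(sb))
  if (coverage < 0.5) {
    stop("align_pair: anchor coverage ", sprintf("%.1f%%", 100 * coverage),
         " is below 50%; sequences too divergent for the built-in aligner, ",
         "use an external aligner and load_alignment()")
  }

  pa <- anchors$pa; pb <- anchors$pb
  # merge consecutive anchors on the same diagonal into blocks
  newblk <- c(TRUE, !(diff(pa) == diff(pb) & diff(pa) <= k))
  blk <- cumsum(newblk)
  bs_a <- tapply(pa, blk, min); be_a <- tapply(pa, blk, max) + k
  bs_b <- tapply(pb, blk, min); be_b <- tapply(pb, blk, max) + k

  parts_a <- character(0); parts_b <- character(0)
  prev_a <- 0L; prev_b <- 0L
  for (i in seq_along(bs_a)) {
    seg <- global_align_segment(substr(sa, prev_a + 1L, bs_a[i]),
                                substr(sb, prev_b + 1L, bs_b[i]))
    parts_a <- c(parts_a, seg[1L], substr(sa, bs_a[i] + 1L, be_a[i]))
    parts_b <- c(parts_b, seg[2L], substr(sb, bs_b[i] + 1L, be_b[i]))
    prev_a <- be_a[i]; prev_b <- be_b[i]
  }
  seg <- global_align_segment(substr(sa, prev_a + 1L, nchar(sa)),
                              substr(sb, prev_b + 1L, nchar(sb)))
  parts_a <- c(parts_a, seg[1L]); parts_b <- c(parts_b, seg[2L])

  aln <- pairwise_alignment(paste(parts_a, collapse = ""),
                            paste(parts_b, collapse = ""),
                            id_a = id_a, id_b = id_b, drop_all_gap = TRUE)
  if (!identical(ungap(aln$row_a), sa) || !identical(ungap(aln$row_b), sb)) {
    stop("align_pair: internal error, round-trip invariant violated")
  }
  aln$rotation_b <- rotation_b
  aln
}

# ---- consensus ----

iupac_merge_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      bases <- names(Biostrings::IUPAC_CODE_MAP)
      m <- matrix(NA_character_, length(bases), length(bases),
                  dimnames = list(bases, bases))
      for (x in bases) for (y in bases) {
        u <- sort(unique(seq_chars(paste0(Biostrings::IUPAC_CODE_MAP[[x]],
                                          Biostrings::IUPAC_CODE_MAP[[y]]))))
        m[x, y] <- names(which(Biostrings::IUPAC_CODE_MAP ==
                                 paste(u, collapse = "")))[1L]
      }
      tab <<- m
    }
    tab
  }
})

#' Consensus sequence of a pairwise alignment
#'
#' One consensus base per alignment column (no column dropped): the common
#' base where the rows agree, the IUPAC ambiguity code of the two bases at a
#' substitution column, and the present base where one row is gapped.
#'
#' @param aln a \code{pairwise_alignment}.
#' @return object of class \code{consensus_sequence}: \code{bases} (string,
#'   length = alignment columns), \code{at_content}, \code{column_map}.
#' @export
consensus <- function(aln) {
  ca <- seq_chars(aln$row_a); cb <- seq_chars(aln$row_b)
  out <- ca
  out[ca == "-"] <- cb[ca == "-"]
  diffs <- which(ca != cb & ca != "-" & cb != "-")
  if (length(diffs) > 0L) {
    tab <- iupac_merge_table()
    nn <- ca[diffs] == "N" | cb[diffs] == "N"
    out[diffs[nn]] <- "N"
    dd <- diffs[!nn]
    out[dd] <- tab[cbind(ca[dd], cb[dd])]
  }
  bases <- paste(out, collapse = "")
  atc <- tryCatch(at_content(bases), error = function(e) NA_real_)
  structure(list(bases = bases, at_content = atc,
                 column_map = seq_along(out)),
            class = "consensus_sequence")
}
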