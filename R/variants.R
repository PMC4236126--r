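# Variant calling from a pairwise alignment: SNPs, indel events (maximal
# gap runs in one row), inversions, indel mutational classes and AT-content
# context statistics.

#' Classify every alignment column
#'
#' @param aln a \code{pairwise_alignment}.
#' @return factor over columns with levels identical, snp, ambiguous, gap.
#'   Ambiguous columns (N or IUPAC codes with both rows non-gap and the rows
#'   differing or undetermined) are excluded from SNP calling and from the
#'   p-distance denominator.
#' @export
column_classes <- function(aln) {
  ca <- seq_chars(aln$row_a); cb <- seq_chars(aln$row_b)
  cls <- rep("identical", length(ca))
  gap <- ca == "-" | cb == "-"
  cls[gap] <- "gap"
  det <- !gap & is_acgt(ca) & is_acgt(cb)
  cls[det & ca != cb] <- "snp"
  cls[!gap & !det] <- "ambiguous"
  factor(cls, levels = c("identical", "snp", "ambiguous", "gap"))
}

#' Call single-nucleotide polymorphisms
#'
#' One SNP per column where both rows carry determined, unequal A/C/G/T
#' bases. Columns with N or ambiguity codes are skipped and available as the
#' \code{ambiguous_columns} attribute.
#'
#' @param aln a \code{pairwise_alignment}.
#' @return data.frame: column (1-based), pos_a, pos_b (0-based ungapped),
#'   base_a, base_b.
#' @export
call_snps <- function(aln) {
  cls <- column_classes(aln)
  idx <- which(cls == "snp")
  ca <- seq_chars(aln$row_a); cb <- seq_chars(aln$row_b)
  out <- data.frame(column = idx,
                    pos_a = aln$col_to_pos_a[idx],
                    pos_b = aln$col_to_pos_b[idx],
                    base_a = ca[idx], base_b = cb[idx],
                    stringsAsFactors = FALSE)
  attr(out, "ambiguous_columns") <- sum(cls == "ambiguous")
  out
}

#' Call indel events
#'
#' An indel event is one maximal run of contiguous gap characters within one
#' row. Runs in different rows separated by at least one non-gap column are
#' distinct events; abutting runs in opposite rows are reported as two
#' events flagged \code{complex}. \code{indel_seq} and the flanks come from
#' the non-gap row; flank width is \code{max(flank, length)} so the
#' adjacent-copy test of \code{\link{classify_indels}} always has enough
#' context.
#'
#' @param aln a \code{pairwise_alignment}.
#' @param flank minimum flank context width (bp, default 20).
#' @return data.frame: col_start, col_end (1-based inclusive column
#'   interval), carrier ("a"/"b" = row holding the gap), pos (0-based
#'   position of the event on the non-gap row), length, indel_seq,
#'   flank_left, flank_right, complex.
#' @export
call_indels <- function(aln, flank = 20) {
  ca <- seq_chars(aln$row_a); cb <- seq_chars(aln$row_b)
  seqs <- alignment_sequences(aln)
  events <- list()
  for (carrier in c("a", "b")) {
    gapmask <- if (carrier == "a") ca == "-" else cb == "-"
    if (!any(gapmask)) next
    r <- rle(gapmask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    other_seq <- if (carrier == "a") seqs[[2L]] else seqs[[1L]]
    other_map <- if (carrier == "a") aln$col_to_pos_b else aln$col_to_pos_a
    for (ri in runs) {
      cs <- starts[ri]; ce <- ends[ri]
      p <- other_map[cs]                       # 0-based on the non-gap row
      len <- ce - cs + 1L
      w <- max(flank, len)
      events[[length(events) + 1L]] <- data.frame(
        col_start = cs, col_end = ce, carrier = carrier, pos = p,
        length = len,
        indel_seq = substr(other_seq, p + 1L, p + len),
        flank_left = substr(other_seq, max(1L, p - w + 1L), p),
        flank_right = substr(other_seq, p + len + 1L, p + len + w),
        stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0L) {
    out <- data.frame(col_start = integer(), col_end = integer(),
                      carrier = character(), pos = integer(),
                      length = integer(), indel_seq = character(),
                      flank_left = character(), flank_right = character(),
                      complex = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, events)
  out <- out[order(out$col_start), , drop = FALSE]
  n <- nrow(out)
  complex <- rep(FALSE, n)
  if (n > 1L) {
    abut <- out$col_start[-1L] == out$col_end[-n] + 1L &
      out$carrier[-1L] != out$carrier[-n]
    complex[-1L][abut] <- TRUE
    complex[-n][abut] <- TRUE
  }
  out$complex <- complex
  rownames(out) <- NULL
  out
}

# length of the homopolymer run of base `b` through the indel locus:
# indel length plus same-base extension into both flanks
homopolymer_run_through <- function(indel_seq, flank_left, flank_right) {
  b <- substr(indel_seq, 1L, 1L)
  run <- nchar(indel_seq)
  lc <- seq_chars(flank_left)
  for (x in rev(lc)) { if (x == b) run <- run + 1L else break }
  rc <- seq_chars(flank_right)
  for (x in rc) { if (x == b) run <- run + 1L else break }
  run
}

#' Classify one indel event
#'
#' Decision order (first match wins):
#' \enumerate{
#'   \item \code{polyN} -- the indel is a homopolymer and the maximal
#'     single-base run through the locus (indel plus same-base extension
#'     into both flanks) is at least 7 bp ("repeated at least sevenfold");
#'   \item \code{SSR_or_inversion} -- the indel (length >= 2) equals the
#'     immediately adjacent upstream or downstream substring of equal length
#'     (gain/loss of one tandem copy of a motif), or equals the reverse
#'     complement of such an adjacent substring (inverted repeat);
#'   \item \code{other} -- anything else.
#' }
#'
#' @param indel_seq inserted/deleted bases (from the non-gap row).
#' @param flank_left,flank_right context on the non-gap row.
#' @param min_polyn minimal total homopolymer run for class polyN.
#' @return one of "polyN", "SSR_or_inversion", "other".
#' @export
classify_indel <- function(indel_seq, flank_left = "", flank_right = "",
                           min_polyn = 7) {
  if (is.na(indel_seq) || nchar(indel_seq) == 0L) {
    stop("classify_indel: empty indel sequence")
  }
  ch <- seq_chars(indel_seq)
  if (all(ch == ch[1L]) &&
      homopolymer_run_through(indel_seq, flank_left, flank_right) >= min_polyn) {
    return("polyN")
  }
  len <- nchar(indel_seq)
  if (len >= 2L) {
    up <- substr(flank_left, nchar(flank_left) - len + 1L, nchar(flank_left))
    down <- substr(flank_right, 1L, len)
    rc <- revcomp(indel_seq)
    if ((nchar(up) == len && (up == indel_seq || up == rc)) ||
        (nchar(down) == len && (down == indel_seq || down == rc))) {
      return("SSR_or_inversion")
    }
  }
  "other"
}

#' Classify a table of indel events
#' @param events output of \code{\link{call_indels}}.
#' @param min_polyn minimal total homopolymer run for class polyN.
#' @return the table with a \code{klass} column added.
#' @export
classify_indels <- function(events, min_polyn = 7) {
  events$klass <- vapply(seq_len(nrow(events)), function(i) {
    classify_indel(events$indel_seq[i], events$flank_left[i],
                   events$flank_right[i], min_polyn = min_polyn)
  }, character(1L))
  events
}

#' Detect inversions in a pairwise alignment
#'
#' Candidate blocks are maximal runs of mismatching columns (runs separated
#' by fewer than \code{min_inv_len} matching columns are merged, since an
#' inverted block typically contains coincidental matches). A candidate is
#' an inversion when one row's block sequence aligns to the reverse
#' complement of the other row's at \code{min_identity} or better.
#'
#' @param aln a \code{pairwise_alignment}.
#' @param min_inv_len minimal mismatch-run length to seed a candidate.
#' @param min_identity reverse-complement identity threshold (default 0.95).
#' @return data.frame: start_a, end_a, start_b, end_b (0-based half-open
#'   ungapped intervals), length, identity, palindromic.
#' @export
detect_inversions <- function(aln, min_inv_len = 10, min_identity = 0.95) {
  ca <- seq_chars(aln$row_a); cb <- seq_chars(aln$row_b)
  mism <- ca != cb & ca != "-" & cb != "-"
  empty <- data.frame(start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer(),
                      length = integer(), identity = numeric(),
                      palindromic = logical(), stringsAsFactors = FALSE)
  if (!any(mism)) return(empty)
  r <- rle(mism)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 1L)
  cs <- starts[runs]; ce <- ends[runs]
  # merge runs separated by short match runs
  merged <- list(); mcs <- cs[1L]; mce <- ce[1L]
  for (i in seq_along(cs)[-1L]) {
    if (cs[i] - mce - 1L < min_inv_len) mce <- ce[i]
    else { merged[[length(merged) + 1L]] <- c(mcs, mce); mcs <- cs[i]; mce <- ce[i] }
  }
  merged[[length(merged) + 1L]] <- c(mcs, mce)
  out <- list()
  for (m in merged) {
    if (m[2L] - m[1L] + 1L < min_inv_len) next
    sa <- paste(ca[m[1L]:m[2L]], collapse = "")
    sb <- paste(cb[m[1L]:m[2L]], collapse = "")
    if (grepl("-", sa, fixed = TRUE) || grepl("-", sb, fixed = TRUE)) next
    ident <- mean(seq_chars(sa) == seq_chars(revcomp(sb)))
    if (ident >= min_identity) {
      out[[length(out) + 1L]] <- data.frame(
        start_a = aln$col_to_pos_a[m[1L]], end_a = aln$col_to_pos_a[m[2L]] + 1L,
        start_b = aln$col_to_pos_b[m[1L]], end_b = aln$col_to_pos_b[m[2L]] + 1L,
        length = nchar(sa), identity = ident,
        palindromic = identical(sa, revcomp(sa)), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' AT-content distributions of indels per mutational class
#'
#' @param events classified indel table (\code{\link{classify_indels}}).
#' @param baseline overall AT content to compare against (e.g. the consensus
#'   AT content).
#' @return list: \code{per_event} (event AT contents with class),
#'   \code{summary} (min/q1/median/mean/q3/max and n per class),
#'   \code{baseline}.
#' @export
indel_at_profiles <- function(events, baseline = NA_real_) {
  at <- vapply(events$indel_seq, function(s) {
    ch <- seq_chars(s)
    det <- sum(is_acgt(ch))
    if (det == 0L) return(NA_real_)
    sum(ch == "A" | ch == "T") / det
  }, numeric(1L), USE.NAMES = FALSE)
  per_event <- data.frame(klass = events$klass, length = events$length,
                          at = at, stringsAsFactors = FALSE)
  classes <- c("polyN", "SSR_or_inversion", "other")
  summ <- do.call(rbind, lapply(classes, function(k) {
    x <- at[events$klass == k & !is.na(at)]
    if (length(x) == 0L) {
      return(data.frame(klass = k, n = 0L, min = NA_real_, q1 = NA_real_,
                        median = NA_real_, mean = NA_real_, q3 = NA_real_,
                        max = NA_real_))
    }
    q <- quantile(x, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(klass = k, n = length(x), min = q[1L], q1 = q[2L],
               median = q[3L], mean = mean(x), q3 = q[4L], max = q[5L])
  }))
  list(per_event = per_event, summary = summ, baseline = baseline)
}

#' AT content of the neighbourhood of each SNP
#'
#' For each SNP and radius r, the AT content of the 2r consensus bases
#' flanking (and excluding) the SNP column. Windows truncated at sequence
#' ends are flagged, not padded.
#'
#' @param cons a \code{consensus_sequence}.
#' @param snps output of \code{\link{call_snps}}.
#' @param radii window half-widths in bp.
#' @return object of class \code{snp_neighborhood_profile}: \code{at}
#'   (SNP x radius matrix), \code{truncated} (logical matrix), \code{radii},
#'   \code{genome_at} baseline.
#' @export
snp_neighborhood_at <- function(cons, snps, radii = c(1:10, 20, 50, 100)) {
  if (any(radii <= 0)) stop("snp_neighborhood_at: radius must be positive")
  ch <- seq_chars(cons$bases)
  n <- length(ch)
  # AT over determined bases, via cumulative counts
  is_at <- as.integer(ch %in% c("A", "T", "W"))
  is_det <- as.integer(ch %in% c("A", "C", "G", "T", "W", "S", "R", "Y",
                                 "K", "M"))
  # count two-base ambiguity codes as half AT where appropriate:
  # W (A/T) fully AT, S (G/C) zero, others (R,Y,K,M) half
  half <- as.integer(ch %in% c("R", "Y", "K", "M")) * 0.5
  at_w <- is_at + half
  cs_at <- c(0, cumsum(at_w)); cs_det <- c(0, cumsum(is_det))
  pos <- snps$column                          # consensus index = column index
  m_at <- matrix(NA_real_, length(pos), length(radii),
                 dimnames = list(NULL, paste0("r", radii)))
  m_tr <- matrix(FALSE, length(pos), length(radii),
                 dimnames = list(NULL, paste0("r", radii)))
  for (j in seq_along(radii)) {
    r <- radii[j]
    lo <- pmax(1L, pos - r); hi <- pmin(n, pos + r)
    trunc <- (pos - r < 1L) | (pos + r > n)
    att <- (cs_at[hi + 1L] - cs_at[lo]) - at_w[pos]
    det <- (cs_det[hi + 1L] - cs_det[lo]) - is_det[pos]
    m_at[, j] <- ifelse(det > 0, att / det, NA_real_)
    m_tr[, j] <- trunc
  }
  structure(list(at = m_at, truncated = m_tr, radii = radii,
                 genome_at = cons$at_content),
            class = "snp_neighborhood_profile")
}

#' Call the full variant set of an alignment
#' @param aln a \code{pairwise_alignment}.
#' @param flank flank context width for indel classification.
#' @param min_inv_len minimal inversion seed length.
#' @return list of class \code{variant_set}: snps, indels (classified),
#'   inversions, ambiguous_columns.
#' @export
call_variants <- function(aln, flank = 20, min_inv_len = 10) {
  snps <- call_snps(aln)
  indels <- classify_indels(call_indels(aln, flank = flank))
  inv <- detect_inversions(aln, min_inv_len = min_inv_len)
  structure(list(snps = snps, indels = indels, inversions = inv,
                 ambiguous_columns = attr(snps, "ambiguous_columns")),
            class = "variant_set")
}

#' Write variants as a VCF-like TSV and BED tracks
#'
#' TSV columns: CHROM (genome a id), POS (1-based pos_a), REF, ALT, TYPE,
#' CLASS, LENGTH. BED tracks (0-based half-open) are written alongside with
#' suffixes .snps.bed, .indels.bed, .inversions.bed.
#'
#' @param vs a \code{variant_set}.
#' @param aln the alignment the variants came from.
#' @param path output TSV path.
#' @export
write_variants <- function(vs, aln, path) {
  sn <- vs$snps; ind <- vs$indels; inv <- vs$inversions
  rows <- list()
  if (nrow(sn) > 0L) {
    rows[[1L]] <- data.frame(CHROM = aln$id_a, POS = sn$pos_a + 1L,
                             REF = sn$base_a, ALT = sn$base_b, TYPE = "SNP",
                             CLASS = ".", LENGTH = 1L)
  }
  if (nrow(ind) > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      CHROM = aln$id_a,
      POS = ifelse(is.na(aln$col_to_pos_a[ind$col_start]),
                   aln$col_to_pos_b[ind$col_start],
                   aln$col_to_pos_a[ind$col_start]) + 1L,
      REF = ".", ALT = ind$indel_seq,
      TYPE = ifelse(ind$carrier == "a", "INS_B", "DEL_B"),
      CLASS = ind$klass, LENGTH = ind$length)
  }
  if (nrow(inv) > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      CHROM = aln$id_a, POS = inv$start_a + 1L, REF = ".", ALT = ".",
      TYPE = "INV", CLASS = ".", LENGTH = inv$length)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(CHROM = character(), POS = integer(), REF = character(),
               ALT = character(), TYPE = character(), CLASS = character(),
               LENGTH = integer())
  tab <- tab[order(tab$POS), , drop = FALSE]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  base <- tools::file_path_sans_ext(path)
  if (nrow(sn) > 0L) {
    write.table(data.frame(aln$id_a, sn$pos_a, sn$pos_a + 1L, "SNP"),
                paste0(base, ".snps.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
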