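# Marker selection: amplicon-size window plus microsatellite screening.
#
# The heuristic models Sanger-style sequencing of PCR amplicons: a read is
# reliable up to (and through) the first long homopolymer it crosses, after
# which slippage corrupts the trace. One such stretch can be bridged by a
# second read from the opposite end; two or more separated stretches leave
# an interval no two reads can cover.

#' Find homopolymer loci
#'
#' Maximal single-base runs of at least \code{min_len} bases, restricted to
#' \code{bases}. The default length threshold 8 encodes "larger than seven
#' nucleotides".
#'
#' @param seq DNA string.
#' @param min_len minimal run length (default 8).
#' @param bases which bases count (default A and T, the polyA/T
#'   microsatellites relevant to read slippage).
#' @return data.frame: base, start (0-based), length.
#' @export
find_homopolymers <- function(seq, min_len = 8, bases = c("A", "T")) {
  if (nchar(seq) == 0L) stop("find_homopolymers: empty sequence")
  ch <- seq_chars(toupper(seq))
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_len & r$values %in% bases
  data.frame(base = r$values[keep], start = starts[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

#' Select sequencing markers from a ranked region table
#'
#' Candidates are regions whose length plus \code{pad} (allowance for
#' primer sites flanking the region) falls inside the amplifiable window
#' [\code{size_min}, \code{size_max}]. Homopolymer loci (any base, length >=
#' \code{hp_min_len}) then determine the verdict: none -> recommended (one
#' read suffices when the amplicon is at most \code{read_len}); exactly one
#' -> conditional, two reads meeting at the stretch; two or more -> a greedy
#' two-read coverage check (forward read reliable through the first
#' stretch, reverse read through the last) decides whether the stretches
#' can all be covered -- if not, the region is dismissed.
#'
#' @param ranked ranked region table (\code{\link{rank_regions}}) with at
#'   least columns name and aligned_length (or length).
#' @param sequences named character vector of region sequences (names
#'   matching \code{ranked$name}).
#' @param size_min,size_max amplicon size window in bp (default 900--1300).
#' @param pad primer-site allowance added to the region length (default 150).
#' @param read_len reliable single-read length in bases (default 1000, the
#'   upper end of the stated 800--1000 range).
#' @param hp_min_len homopolymer length threshold (default 8).
#' @return data.frame of class \code{marker_candidates}: name, rank, length,
#'   amplicon, n_homopolymers, reads_required ("1"/"2"/">2"), verdict
#'   (recommended/conditional/dismissed), reason.
#' @export
select_markers <- function(ranked, sequences, size_min = 900, size_max = 1300,
                           pad = 150, read_len = 1000, hp_min_len = 8) {
  rows <- list()
  for (i in seq_len(nrow(ranked))) {
    nm <- ranked$name[i]
    s <- sequences[[nm]]
    if (is.null(s) || is.na(s)) next
    len <- nchar(s)
    amplicon <- len + pad
    if (amplicon < size_min || amplicon > size_max) next
    hp <- find_homopolymers(s, min_len = hp_min_len,
                            bases = c("A", "C", "G", "T"))
    nh <- nrow(hp)
    if (nh == 0L) {
      reads <- if (amplicon <= read_len) "1" else "2"
      verdict <- "recommended"
      reason <- if (reads == "1")
        "no homopolymer stretch; single primer read covers the amplicon" else
        "no homopolymer stretch; two opposing reads cover the amplicon"
    } else if (nh == 1L) {
      reads <- "2"; verdict <- "conditional"
      reason <- "one homopolymer stretch; two reads meeting at it required"
    } else {
      # forward read reliable over [0, end of first stretch), reverse read
      # over [start of last stretch, len); coverage fails iff a gap remains
      first_end <- min(hp$start + hp$length)
      last_start <- max(hp$start)
      covered <- first_end >= last_start &&
        first_end <= read_len && (len - last_start) <= read_len
      if (covered) {
        reads <- "2"; verdict <- "conditional"
        reason <- "multiple overlapping homopolymer stretches; two reads suffice"
      } else {
        reads <- ">2"; verdict <- "dismissed"
        reason <- sprintf(paste0("%d separated homopolymer stretches; two ",
                                 "reads cannot cover all intervals between ",
                                 "them"), nh)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, rank = ranked$rank[i] %||% i, length = len,
      amplicon = amplicon, n_homopolymers = nh, reads_required = reads,
      verdict = verdict, reason = reason, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), rank = integer(), length = integer(),
               amplicon = integer(), n_homopolymers = integer(),
               reads_required = character(), verdict = character(),
               reason = character(), stringsAsFactors = FALSE)
  class(out) <- c("marker_candidates", "data.frame")
  out
}
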