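# Annotated genome container, GenBank flat-file I/O, quadripartite structure
# detection and noncoding-region (intron/spacer) extraction.
#
# Coordinates are 0-based half-open everywhere inside the package; the
# GenBank convention (1-based inclusive, join/complement locations) is
# converted at the I/O boundary.

# ---- AnnotatedGenome ----

#' Construct an annotated genome
#'
#' @param id accession-like identifier.
#' @param sequence DNA string (A/C/G/T/N plus IUPAC ambiguity codes);
#'   uppercased on input.
#' @param features data.frame with columns \code{name}, \code{kind} (one of
#'   gene/tRNA/rRNA/exon/intron/IR), \code{strand} ("+"/"-"), \code{start},
#'   \code{end} (0-based half-open) and optionally \code{part} (interval
#'   index within a multi-interval feature). Rows sharing a \code{name} are
#'   the ordered intervals of one feature (e.g. exons of one gene).
#' @param circular logical; plastomes are circular.
#' @param source optional file path the record came from.
#' @return object of class \code{annotated_genome}.
#' @export
annotated_genome <- function(id, sequence, features = NULL, circular = TRUE,
                             source = NA_character_) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  if (len == 0L) stop("genome '", id, "': empty sequence")
  if (is.null(features)) {
    features <- data.frame(name = character(), kind = character(),
                           strand = character(), start = integer(),
                           end = integer(), part = integer(),
                           stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!"part" %in% names(features)) features$part <- 1L
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- features$start >= features$end
  if (any(bad)) {
    stop("feature '", features$name[which(bad)[1L]], "': start >= end")
  }
  out <- features$start < 0L | features$end > len
  if (any(out)) {
    stop("feature '", features$name[which(out)[1L]],
         "' lies outside the sequence [0,", len, ")")
  }
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(id = id, sequence = sequence, circular = circular,
                 features = features, source = source),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp, %s, %d features, GC %.1f%%\n",
              x$id, nchar(x$sequence),
              if (x$circular) "circular" else "linear",
              length(unique(x$features$name)),
              100 * gc_content(x$sequence)))
  invisible(x)
}

genome_length <- function(g) nchar(g$sequence)

# substring with wrap-around for circular coordinates (end may exceed length)
circular_substr <- function(seq, start, end) {
  len <- nchar(seq)
  if (end <= len) return(substr(seq, start + 1L, end))
  paste0(substr(seq, start + 1L, len), substr(seq, 1L, end - len))
}

# ---- base composition ----

#' GC content of a DNA sequence
#'
#' Fraction (G+C)/(A+C+G+T). Ambiguity codes, N and gaps are excluded from
#' both numerator and denominator, so \code{gc_content(s) + at_content(s)}
#' is exactly 1 for any sequence with at least one determined base.
#'
#' @param seq DNA string.
#' @return fraction in [0, 1].
#' @export
gc_content <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop("gc_content: empty sequence")
  }
  ch <- seq_chars(toupper(seq))
  gc <- sum(ch == "G" | ch == "C")
  acgt <- gc + sum(ch == "A" | ch == "T")
  if (acgt == 0L) stop("gc_content: no determined A/C/G/T bases")
  gc / acgt
}

#' @rdname gc_content
#' @export
at_content <- function(seq) 1 - gc_content(seq)

# ---- GenBank flat file I/O ----

parse_gb_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  iv <- t(vapply(parts, function(p) {
    p <- gsub("complement\\(|\\)", "", p)  # rare per-part complement
    nums <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    nums
  }, integer(2L)))
  # 1-based inclusive -> 0-based half-open
  data.frame(start = iv[, 1L] - 1L, end = iv[, 2L], strand = strand,
             stringsAsFactors = FALSE)
}

#' Read an annotated genome record
#'
#' Parses a GenBank flat file (LOCUS/FEATURES/ORIGIN) or a plain FASTA plus a
#' tab-separated feature table (columns name, kind, strand, start, end,
#' part). \code{join(...)} and \code{complement(...)} locations are resolved
#' into multi-interval stranded features; all coordinates are converted to
#' 0-based half-open.
#'
#' @param path input file.
#' @param format "genbank" or "fasta+table".
#' @param feature_table for \code{format = "fasta+table"}, path to the TSV
#'   feature table (default: \code{path} with extension replaced by
#'   ".features.tsv").
#' @return an \code{\link{annotated_genome}}.
#' @export
read_annotated_genome <- function(path, format = c("genbank", "fasta+table"),
                                  feature_table = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "fasta+table") {
    seqs <- Biostrings::readBStringSet(path)
    if (length(seqs) != 1L) stop("expected exactly one FASTA record")
    if (is.null(feature_table)) {
      feature_table <- paste0(tools::file_path_sans_ext(path), ".features.tsv")
    }
    ft <- read.table(feature_table, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    return(annotated_genome(id = sub("\\s.*", "", names(seqs)[1L]),
                            sequence = as.character(seqs[[1L]]),
                            features = ft, source = path))
  }
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("'", path, "': not a GenBank record (no LOCUS)")
  toks <- strsplit(trimws(locus[1L]), "\\s+")[[1L]]
  id <- toks[2L]
  circular <- any(grepl("circular", locus[1L], ignore.case = TRUE))
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc) > 0L) {
    a <- strsplit(trimws(acc[1L]), "\\s+")[[1L]]
    if (length(a) >= 2L) id <- a[2L]
  }

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("'", path, "': record without sequence (no ORIGIN)")
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1L]][1L] else length(lines) + 1L
  seqlines <- lines[(ori[1L] + 1L):(endrec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (nchar(sequence) == 0L) stop("'", path, "': record without sequence")

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart) > 0L) {
    block <- lines[(fstart[1L] + 1L):(ori[1L] - 1L)]
    cur <- NULL
    for (ln in block) {
      if (grepl("^     \\S", ln)) {            # new feature at column 6
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
        key <- sub("^\\s*(\\S+)\\s+.*$", "\\1", ln)
        loc <- sub("^\\s*\\S+\\s+", "", ln)
        cur <- list(key = key, loc = loc, quals = character())
      } else if (!is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
        else cur$loc <- paste0(cur$loc, txt)   # continued location
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }

  qual_val <- function(quals, key) {
    hit <- grep(paste0("^/", key, "="), quals, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    gsub('"', "", sub(paste0("^/", key, "="), "", hit[1L]))
  }
  kind_map <- c(gene = "gene", tRNA = "tRNA", rRNA = "rRNA", CDS = "CDS",
                exon = "exon", intron = "intron", repeat_region = "IR")

  rows <- list(); cds_rows <- list()
  for (f in feats) {
    if (!f$key %in% names(kind_map)) next
    kind <- kind_map[[f$key]]
    if (kind == "IR" ) {
      rpt <- qual_val(f$quals, "rpt_type")
      if (!is.na(rpt) && !grepl("invert", rpt, ignore.case = TRUE)) next
    }
    nm <- qual_val(f$quals, "gene")
    if (is.na(nm)) nm <- qual_val(f$quals, "locus_tag")
    if (is.na(nm)) nm <- qual_val(f$quals, "product")
    if (is.na(nm)) nm <- qual_val(f$quals, "note")
    if (is.na(nm)) nm <- f$key
    iv <- parse_gb_location(f$loc)
    df <- data.frame(name = nm, kind = kind, strand = iv$strand[1L],
                     start = iv$start, end = iv$end,
                     part = seq_len(nrow(iv)), stringsAsFactors = FALSE)
    if (kind == "CDS") cds_rows[[length(cds_rows) + 1L]] <- df
    else rows[[length(rows) + 1L]] <- df
  }

  ft <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), kind = character(), strand = character(),
               start = integer(), end = integer(), part = integer(),
               stringsAsFactors = FALSE)
  # refine single-interval gene features with multi-exon CDS structure
  for (cd in cds_rows) {
    nm <- cd$name[1L]
    hit <- which(ft$name == nm & ft$kind == "gene")
    if (length(hit) == 1L && nrow(cd) > 1L &&
        min(cd$start) >= ft$start[hit] - 5L && max(cd$end) <= ft$end[hit] + 5L) {
      cd$kind <- "gene"
      ft <- rbind(ft[-hit, , drop = FALSE], cd)
    } else if (length(hit) == 0L && !nm %in% ft$name) {
      cd$kind <- "gene"
      ft <- rbind(ft, cd)
    }
  }
  # de-duplicate names of distinct features (e.g. IR gene duplicates):
  # a second feature with the same name gets suffix _2, _3, ...
  if (nrow(ft) > 0L) {
    ft <- ft[order(ft$start, ft$end), , drop = FALSE]
    key <- paste(ft$name, ft$kind)
    for (nm in unique(ft$name)) {
      idx <- which(ft$name == nm)
      if (length(idx) <= 1L) next
      # group rows into features: contiguous parts (part resets at 1)
      grp <- cumsum(ft$part[idx] == 1L)
      if (max(grp) > 1L) {
        for (gi in seq(2L, max(grp))) {
          ft$name[idx[grp == gi]] <- paste0(nm, "_", gi)
        }
      }
    }
  }
  if (format == "genbank" && nrow(ft) == 0L) {
    stop("'", path, "': GenBank record with no recognised features")
  }
  annotated_genome(id = id, sequence = sequence, features = ft,
                   circular = circular, source = path)
}

#' Write an annotated genome as a GenBank flat file
#'
#' Inverse of \code{\link{read_annotated_genome}} for records produced by
#' this package; multi-interval features are written as \code{join(...)}
#' locations, minus-strand features as \code{complement(...)}.
#'
#' @param genome an \code{annotated_genome}.
#' @param path output file.
#' @export
write_genbank <- function(genome, path) {
  len <- genome_length(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s PLN 01-JAN-2026",
                     genome$id, len,
                     if (genome$circular) "circular" else "linear"), con)
  writeLines(c("DEFINITION  synthetic plastid genome pair member.",
               sprintf("ACCESSION   %s", genome$id),
               "FEATURES             Location/Qualifiers",
               sprintf("     source          1..%d", len)), con)
  ft <- genome$features
  for (nm in unique(ft$name)) {
    rows <- ft[ft$name == nm, , drop = FALSE]
    rows <- rows[order(rows$part), , drop = FALSE]
    key <- switch(rows$kind[1L], gene = "gene", tRNA = "tRNA", rRNA = "rRNA",
                  IR = "repeat_region", exon = "exon", intron = "intron",
                  "misc_feature")
    spans <- sprintf("%d..%d", rows$start + 1L, rows$end)
    loc <- if (length(spans) > 1L) sprintf("join(%s)",
                                           paste(spans, collapse = ",")) else spans
    if (rows$strand[1L] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", key, loc), con)
    quals <- if (key == "repeat_region") {
      c("/rpt_type=inverted", sprintf('/note="%s"', nm))
    } else sprintf('/gene="%s"', nm)
    writeLines(sprintf("                     %s", quals), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write / read the plain-text feature table
#'
#' TSV with columns name, kind, strand, start, end, part (0-based half-open
#' coordinates), the annotation-free fallback interchange format.
#' @param genome an \code{annotated_genome}.
#' @param path output TSV.
#' @export
write_feature_table <- function(genome, path) {
  write.table(genome$features, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- quadripartite structure ----

#' Detect the quadripartite structure of a plastome
#'
#' Finds the maximal pair of disjoint reverse-complement repeats (the
#' inverted repeats IRa/IRb) of at least \code{min_ir_len} via seed k-mer
#' matching against the reverse complement, extended outward with a small
#' mismatch tolerance. The longer single-copy segment between the repeats is
#' the LSC, the shorter the SSC. If the record carries explicit IR
#' annotations (kind "IR"), those take precedence and detection serves as a
#' cross-check.
#'
#' @param genome an \code{annotated_genome}.
#' @param min_ir_len minimum repeat length to accept (bp).
#' @param max_mismatch_frac tolerated mismatch fraction between the two IR
#'   copies (deposited copies occasionally differ by a few bases).
#' @return object of class \code{quadripartite}: intervals \code{lsc},
#'   \code{ssc}, \code{ira}, \code{irb} (0-based half-open; \code{end} may
#'   exceed the genome length for the segment spanning the origin),
#'   \code{ir_length} (IRa) and \code{ir_length_b}, which are flagged via
#'   \code{ir_equal} when the annotated copies differ.
#' @export
detect_quadripartite <- function(genome, min_ir_len = 10000,
                                 max_mismatch_frac = 0.001) {
  s <- genome$sequence
  len <- nchar(s)
  ann <- genome$features[genome$features$kind == "IR", , drop = FALSE]
  if (nrow(ann) >= 2L) {
    ann <- ann[order(ann$start), , drop = FALSE]
    ira <- c(ann$start[1L], ann$end[1L])
    irb <- c(ann$start[2L], ann$end[2L])
    return(build_quadripartite(s, ira, irb, from_annotation = TRUE))
  }
  k <- 31L
  if (len < 2L * min_ir_len || len <= k) {
    stop_structure_not_found(min_ir_len)
  }
  rc <- revcomp(s)
  idx_r <- seq_len(len - k + 1L)
  km_r <- substring(rc, idx_r, idx_r + k - 1L)
  idx_s <- seq(1L, len - k + 1L, by = 16L)
  km_s <- substring(s, idx_s, idx_s + k - 1L)
  hit <- match(km_s, km_r)
  keep <- !is.na(hit)
  if (!any(keep)) stop_structure_not_found(min_ir_len)
  i0 <- idx_s[keep] - 1L                      # 0-based start in s
  j0 <- hit[keep] - 1L                        # 0-based start in rc
  ip <- len - j0 - k                          # partner start in s
  ok <- ip > i0                               # canonical orientation, no self hits
  i0 <- i0[ok]; ip <- ip[ok]
  if (length(i0) == 0L) stop_structure_not_found(min_ir_len)
  diag <- i0 + ip
  tab <- table(diag)
  best <- as.integer(names(tab)[which.max(tab)])
  sel <- abs(diag - best) <= 2L * k           # tolerate jitter from indel-free seeds
  if (!any(sel)) stop_structure_not_found(min_ir_len)
  a1 <- min(i0[sel]); a2 <- max(i0[sel]) + k
  cc <- best                                  # pairing: p in IRa <-> cc + k - 1 - p
  ch <- seq_chars(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  pair_ok <- function(p) {
    q <- cc + k - 1L - p
    if (p < 0L || q >= len || q <= p) return(FALSE)
    ca <- ch[p + 1L]; cb <- ch[q + 1L]
    !is.na(comp[ca]) && comp[[ca]] == cb
  }
  budget <- max(2L, ceiling(max_mismatch_frac * len / 2))
  extend <- function(p, step) {
    miss <- 0L
    repeat {
      np <- p + step
      if (pair_ok(np)) { p <- np; miss <- 0L }
      else if (miss < budget && pair_ok(np + step)) { p <- np + step; miss <- miss + 1L }
      else break
    }
    p
  }
  a1 <- extend(a1, -1L)
  a2 <- extend(a2 - 1L, 1L) + 1L
  b1 <- cc + k - a2; b2 <- cc + k - a1
  if (a2 > b1) { mid <- (a2 + b1) %/% 2L; a2 <- mid; b1 <- cc + k - mid }
  if (a2 - a1 < min_ir_len) stop_structure_not_found(min_ir_len)
  build_quadripartite(s, c(a1, a2), c(b1, b2), from_annotation = FALSE)
}

stop_structure_not_found <- function(min_ir_len) {
  stop(structure(class = c("plastscan_structure_not_found", "error", "condition"),
                 list(message = sprintf(
                   "no inverted repeat pair of length >= %d found", min_ir_len),
                   call = sys.call(-1L))))
}

build_quadripartite <- function(s, ira, irb, from_annotation) {
  len <- nchar(s)
  seg1 <- c(ira[2L], irb[1L])                 # between IRa end and IRb start
  seg2 <- c(irb[2L], ira[1L] + len)           # wraps the origin
  lens <- c(seg1[2L] - seg1[1L], seg2[2L] - seg2[1L])
  lsc <- if (lens[1L] >= lens[2L]) seg1 else seg2
  ssc <- if (lens[1L] >= lens[2L]) seg2 else seg1
  sa <- substr(s, ira[1L] + 1L, ira[2L])
  sb <- substr(s, irb[1L] + 1L, irb[2L])
  ident <- if (nchar(sa) == nchar(sb)) {
    mean(seq_chars(sa) == seq_chars(revcomp(sb)))
  } else NA_real_
  structure(list(lsc = lsc, ssc = ssc, ira = ira, irb = irb,
                 ir_length = ira[2L] - ira[1L],
                 ir_length_b = irb[2L] - irb[1L],
                 ir_equal = (ira[2L] - ira[1L]) == (irb[2L] - irb[1L]),
                 ir_identity = ident,
                 from_annotation = from_annotation),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(sprintf(paste0("<quadripartite> LSC %d bp, SSC %d bp, IR %d bp",
                     " (identity %.4f, %s)\n"),
              x$lsc[2L] - x$lsc[1L], x$ssc[2L] - x$ssc[1L], x$ir_length,
              x$ir_identity %||% NA_real_,
              if (x$from_annotation) "annotated" else "detected"))
  invisible(x)
}

# ---- noncoding region extraction ----

#' Extract introns and intergenic spacers
#'
#' Spacers are the gaps between consecutive coding-feature footprints around
#' the circle (overlapping features, e.g. matK nested in trnK, contribute
#' their union so no negative spacer can arise); introns are the gaps
#' between consecutive intervals of one multi-interval feature. The trnK
#' intron is split at the embedded matK boundaries into 5' and 3' parts when
#' \code{split_trnK}. Regions shorter than \code{min_len} (ungapped
#' reference length) are dropped. With \code{dedupe_ir}, the IRb copy of a
#' region also present in IRa is flagged via \code{copy_of} so downstream
#' statistics count it once.
#'
#' @param genome an \code{annotated_genome}.
#' @param min_len minimum region length in bp (default 100).
#' @param split_trnK split the trnK intron at matK (default TRUE).
#' @param dedupe_ir flag IRb duplicates (default TRUE).
#' @param quad optional precomputed \code{quadripartite}; when NULL,
#'   detection is attempted and IR de-duplication is skipped on failure.
#' @return data.frame of class \code{genomic_regions}: name, kind
#'   ("spacer"/"intron"), start, end (0-based half-open; end may exceed the
#'   genome length for the origin-spanning spacer), length, copy_of.
#' @export
extract_noncoding_regions <- function(genome, min_len = 100,
                                      split_trnK = TRUE, dedupe_ir = TRUE,
                                      quad = NULL) {
  ft <- genome$features
  ft <- ft[ft$kind %in% c("gene", "tRNA", "rRNA", "exon"), , drop = FALSE]
  len <- genome_length(genome)
  if (nrow(ft) == 0L) stop("no coding features to derive regions from")

  # feature footprints = full span (first exon start to last exon end)
  spans <- do.call(rbind, lapply(split(ft, ft$name), function(d) {
    data.frame(name = d$name[1L], start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]

  # merge overlapping/nested footprints into blocks, remembering the
  # left-most and right-most feature of each block for spacer naming
  blocks <- list()
  cur <- spans[1L, ]
  cur$first <- cur$name; cur$last <- cur$name; cur$last_end <- cur$end
  for (i in seq_len(nrow(spans))[-1L]) {
    r <- spans[i, ]
    if (r$start < cur$end) {
      if (r$end > cur$end) { cur$end <- r$end; cur$last <- r$name }
    } else {
      blocks[[length(blocks) + 1L]] <- cur
      cur <- r; cur$first <- r$name; cur$last <- r$name
    }
  }
  blocks[[length(blocks) + 1L]] <- cur
  bl <- do.call(rbind, lapply(blocks, function(b)
    data.frame(start = b$start, end = b$end, first = b$first, last = b$last,
               stringsAsFactors = FALSE)))

  regions <- list()
  nb <- nrow(bl)
  for (i in seq_len(nb)) {
    j <- if (i < nb) i + 1L else 1L
    gstart <- bl$end[i]
    gend <- if (i < nb) bl$start[j] else bl$start[1L] + len
    if (i == nb && !genome$circular) break
    if (gend < gstart) {
      warning("overlapping features produce a negative spacer after '",
              bl$last[i], "'; skipped")
      next
    }
    regions[[length(regions) + 1L]] <- data.frame(
      name = paste0(bl$last[i], "-", bl$first[j]), kind = "spacer",
      start = gstart, end = gend, stringsAsFactors = FALSE)
  }

  # introns: gaps between consecutive intervals of one feature
  multi <- names(which(table(genome$features$name[
    genome$features$kind %in% c("gene", "tRNA", "rRNA")]) > 1L))
  trnk_intron <- NULL
  for (nm in multi) {
    d <- genome$features[genome$features$name == nm, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    nint <- nrow(d) - 1L
    for (k in seq_len(nint)) {
      istart <- d$end[k]; iend <- d$start[k + 1L]
      if (iend <= istart) next
      num <- if (d$strand[1L] == "-") nint - k + 1L else k
      iname <- if (nint == 1L) paste(nm, "intron") else
        paste(nm, "intron", num)
      row <- data.frame(name = iname, kind = "intron", start = istart,
                        end = iend, stringsAsFactors = FALSE)
      if (split_trnK && grepl("^trnK", nm)) trnk_intron <- row
      else regions[[length(regions) + 1L]] <- row
    }
  }

  if (!is.null(trnk_intron)) {
    matk <- spans[grepl("^matK", spans$name), , drop = FALSE]
    inside <- nrow(matk) > 0L &&
      matk$start[1L] >= trnk_intron$start && matk$end[1L] <= trnk_intron$end
    if (inside) {
      nm5 <- "trnK intron 5p"; nm3 <- "trnK intron 3p"
      strand <- genome$features$strand[grepl("^trnK",
                                             genome$features$name)][1L]
      if (identical(strand, "-")) { tmp <- nm5; nm5 <- nm3; nm3 <- tmp }
      regions[[length(regions) + 1L]] <- data.frame(
        name = nm5, kind = "intron", start = trnk_intron$start,
        end = matk$start[1L], stringsAsFactors = FALSE)
      regions[[length(regions) + 1L]] <- data.frame(
        name = nm3, kind = "intron", start = matk$end[1L],
        end = trnk_intron$end, stringsAsFactors = FALSE)
    } else {
      if (split_trnK) warning("trnK present without embedded matK; split skipped")
      regions[[length(regions) + 1L]] <- trnk_intron
    }
  }

  reg <- do.call(rbind, regions)
  if (is.null(reg)) {
    reg <- data.frame(name = character(), kind = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  reg$length <- reg$end - reg$start
  reg <- reg[reg$length >= min_len, , drop = FALSE]
  reg <- reg[order(reg$start), , drop = FALSE]
  reg$copy_of <- rep(NA_character_, nrow(reg))

  if (dedupe_ir && nrow(reg) > 0L) {
    if (is.null(quad)) {
      quad <- tryCatch(detect_quadripartite(genome), error = function(e) NULL)
    }
    if (!is.null(quad)) {
      in_iv <- function(st, en, iv) st >= iv[1L] && en <= iv[2L]
      in_b <- vapply(seq_len(nrow(reg)), function(i)
        in_iv(reg$start[i], reg$end[i], quad$irb), logical(1L))
      in_a <- vapply(seq_len(nrow(reg)), function(i)
        in_iv(reg$start[i], reg$end[i], quad$ira), logical(1L))
      for (i in which(in_b)) {
        sb <- revcomp(circular_substr(genome$sequence, reg$start[i], reg$end[i]))
        for (j in which(in_a)) {
          if (reg$length[j] != reg$length[i]) next
          sa <- circular_substr(genome$sequence, reg$start[j], reg$end[j])
          if (mean(seq_chars(sa) == seq_chars(sb)) >= 0.99) {
            reg$copy_of[i] <- reg$name[j]
            break
          }
        }
      }
    }
  }
  rownames(reg) <- NULL
  class(reg) <- c("genomic_regions", "data.frame")
  reg
}

#' Sequence of a genomic region on its reference genome
#' @param genome an \code{annotated_genome}.
#' @param region one row of a \code{genomic_regions} table.
#' @return DNA string.
#' @export
region_sequence <- function(genome, region) {
  circular_substr(genome$sequence, region$start, region$end)
}

#' Write regions as BED (0-based half-open, name column = region name)
#' @param regions a \code{genomic_regions} table.
#' @param genome_id chromosome label for column 1.
#' @param path output file.
#' @export
write_regions_bed <- function(regions, genome_id, path) {
  bed <- data.frame(chrom = genome_id, start = regions$start,
                    end = regions$end,
                    name = gsub(" ", "_", regions$name))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
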