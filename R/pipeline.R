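# End-to-end orchestration: read -> (align | load) -> variants -> regions ->
# stats -> ranking -> windows -> AT profiles -> marker selection, with all
# report artifacts written to an output directory.

#' Run configuration for the pipeline
#'
#' @param genome_a,genome_b paths to annotated genome records (GenBank).
#' @param alignment optional path to a precomputed two-record gapped FASTA
#'   alignment; when NULL the built-in aligner is used.
#' @param out output directory.
#' @param min_region_len minimum intron/spacer length (bp).
#' @param window sliding-window slot size (bp).
#' @param top_n ranking depth.
#' @param seed RNG seed recorded in the run log.
#' @param ... further parameters passed through to the module functions
#'   (\code{flank}, \code{min_inv_len}, \code{size_min}, \code{size_max},
#'   \code{pad}, \code{read_len}).
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(genome_a, genome_b, alignment = NULL, out = tempdir(),
                       min_region_len = 100, window = 500, top_n = 30,
                       seed = 1, ...) {
  structure(list(genome_a = genome_a, genome_b = genome_b,
                 alignment = alignment, out = out,
                 min_region_len = min_region_len, window = window,
                 top_n = top_n, seed = seed, extra = list(...)),
            class = "run_config")
}

fmt_num <- function(x, digits = 5) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

write_ranking_tsv <- function(ranked, path) {
  out <- data.frame(rank = ranked$rank, region = ranked$name,
                    aligned_length = ranked$aligned_length,
                    pics = ranked$pics, snps = ranked$snps,
                    indels = ranked$indels,
                    p_distance = fmt_num(ranked$p_distance, 5),
                    p_distance_x1000 = fmt_num(1000 * ranked$p_distance, 2))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full comparison pipeline
#'
#' Executes every stage and writes summary.json, ranking_pdist.tsv,
#' ranking_pic.tsv, variants.tsv, windows.tsv, snp_at_profile.tsv,
#' indel_at_profile.tsv, markers.tsv and run.log into the output directory.
#' Any stage failure propagates with the stage name prefixed.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return run manifest (list): output file paths, the summary row, the two
#'   rankings and the parameters used.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  ga <- stage("read_genome_a", read_annotated_genome(cfg$genome_a))
  gb <- stage("read_genome_b", read_annotated_genome(cfg$genome_b))
  aln <- if (!is.null(cfg$alignment)) {
    stage("load_alignment", load_alignment(cfg$alignment))
  } else {
    stage("align_pair", align_pair(ga, gb))
  }
  vs <- stage("variants", call_variants(aln,
                                        flank = cfg$extra$flank %||% 20,
                                        min_inv_len = cfg$extra$min_inv_len %||% 10))
  cons <- stage("consensus", consensus(aln))
  regions <- stage("regions", extract_noncoding_regions(
    ga, min_len = cfg$min_region_len))
  stats <- stage("region_stats", region_stats_table(aln, regions))
  rank_p <- stage("ranking", rank_regions(stats, "p_distance", cfg$top_n))
  rank_pic <- stage("ranking", rank_regions(stats, "pics", cfg$top_n))
  summ <- stage("summary", whole_genome_summary(aln))
  wins <- stage("windows", sliding_windows(cons, vs, window = cfg$window))
  prof <- stage("snp_at_profile", snp_neighborhood_at(cons, vs$snps))
  iprof <- stage("indel_at_profile",
                 indel_at_profiles(vs$indels, baseline = cons$at_content))
  seqs <- setNames(
    vapply(seq_len(nrow(regions)), function(i)
      region_sequence(ga, regions[i, ]), character(1L)),
    regions$name)
  markers <- stage("markers", select_markers(
    rank_p, seqs,
    size_min = cfg$extra$size_min %||% 900,
    size_max = cfg$extra$size_max %||% 1300,
    pad = cfg$extra$pad %||% 150,
    read_len = cfg$extra$read_len %||% 1000))

  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(cfg$out, c(
    "summary.json", "ranking_pdist.tsv", "ranking_pic.tsv", "variants.tsv",
    "windows.tsv", "snp_at_profile.tsv", "indel_at_profile.tsv",
    "markers.tsv"))
  names(paths) <- c("summary", "ranking_pdist", "ranking_pic", "variants",
                    "windows", "snp_at_profile", "indel_at_profile",
                    "markers")
  jsonlite::write_json(as.list(summ), paths[["summary"]], auto_unbox = TRUE,
                       digits = NA)
  write_ranking_tsv(rank_p, paths[["ranking_pdist"]])
  write_ranking_tsv(rank_pic, paths[["ranking_pic"]])
  write_variants(vs, aln, paths[["variants"]])
  wtab <- wins; wtab$at_content <- fmt_num(wtab$at_content, 5)
  wtab$at_relative_to_genome <- fmt_num(wins$at_relative_to_genome, 5)
  write.table(wtab, paths[["windows"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  ptab <- data.frame(snp = rep(seq_len(nrow(prof$at)), ncol(prof$at)),
                     radius = rep(prof$radii, each = nrow(prof$at)),
                     at = fmt_num(as.vector(prof$at), 5),
                     truncated = as.vector(prof$truncated))
  write.table(ptab, paths[["snp_at_profile"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  itab <- iprof$summary
  for (cc in c("min", "q1", "median", "mean", "q3", "max")) {
    itab[[cc]] <- fmt_num(itab[[cc]], 5)
  }
  write.table(itab, paths[["indel_at_profile"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(markers, paths[["markers"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_path <- file.path(cfg$out, "run.log")
  writeLines(c(
    sprintf("plastscan %s", as.character(utils::packageVersion("plastscan"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("genome_a: %s (%s)", cfg$genome_a, ga$id),
    sprintf("genome_b: %s (%s)", cfg$genome_b, gb$id),
    sprintf("alignment: %s", cfg$alignment %||% "built-in aligner"),
    sprintf("seed: %d", cfg$seed),
    sprintf("min_region_len: %d  window: %d  top_n: %d",
            cfg$min_region_len, cfg$window, cfg$top_n),
    sprintf("columns: %d  snps: %d  indels: %d  inversions: %d",
            alignment_ncol(aln), nrow(vs$snps), nrow(vs$indels),
            nrow(vs$inversions))), log_path)

  list(files = c(paths, run_log = log_path), summary = summ,
       ranking_pdist = rank_p, ranking_pic = rank_pic, markers = markers,
       config = cfg)
}

# strand-agnostic spacer name normalisation: "A-B" == "B-A"
normalize_region_name <- function(x) {
  vapply(x, function(nm) {
    if (grepl("-", nm, fixed = TRUE) && !grepl(" intron", nm, fixed = TRUE)) {
      parts <- sort(strsplit(nm, "-", fixed = TRUE)[[1L]])
      paste(parts, collapse = "-")
    } else nm
  }, character(1L), USE.NAMES = FALSE)
}

#' Compare top-ranked regions across genome pairs
#'
#' Joins the top-N ranking tables of several runs by normalised region name
#' (spacer names are strand-agnostic: "A-B" and "B-A" are the same region)
#' and reports each region's occurrence count and the set present in every
#' pair.
#'
#' @param rankings list (length >= 2) of ranked tables
#'   (\code{\link{rank_regions}} output or run manifests).
#' @param top depth to compare at; when the tables are shallower the
#'   minimum available depth is used (logged via message).
#' @return list: \code{occurrence} (data.frame region / n_pairs),
#'   \code{intersection} (regions present in all pairs), \code{top_used}.
#' @export
compare_pairs <- function(rankings, top = 30) {
  if (length(rankings) < 2L) stop("compare_pairs: need at least two rankings")
  tabs <- lapply(rankings, function(r) {
    if (is.list(r) && !is.data.frame(r) && !is.null(r$ranking_pdist)) {
      r <- r$ranking_pdist
    }
    r
  })
  depth <- min(top, vapply(tabs, nrow, integer(1L)))
  if (depth < top) {
    message("compare_pairs: using top-", depth,
            " (shallowest ranking available)")
  }
  sets <- lapply(tabs, function(r)
    unique(normalize_region_name(head(r, depth)$name)))
  all_regions <- sort(unique(unlist(sets)))
  counts <- vapply(all_regions, function(nm)
    sum(vapply(sets, function(s) nm %in% s, logical(1L))), integer(1L))
  occurrence <- data.frame(region = all_regions, n_pairs = counts,
                           row.names = NULL, stringsAsFactors = FALSE)
  occurrence <- occurrence[order(-occurrence$n_pairs, occurrence$region), ]
  rownames(occurrence) <- NULL
  list(occurrence = occurrence,
       intersection = all_regions[counts == length(sets)],
       top_used = depth)
}
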