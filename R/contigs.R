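#' Selection configuration for probe target regions
#'
#' Thresholds governing which coverage contigs enter probe design and how
#' target regions are chosen within them.
#'
#' @param min_reads minimum number of supporting reads for a contig to be
#'   considered (default 5).
#' @param short_contig_cutoff contigs shorter than this (nt) receive a single
#'   signal region; longer contigs are tiled (default 70).
#' @param tiling_interval tiling window size (nt) for long contigs
#'   (default 30).
#' @param control_ratio a low-coverage control/precursor window must have mean
#'   coverage strictly below this fraction of the contig's single-base maximum
#'   (default 1/3).
#' @return a list of class `selection_config`.
#' @export
selection_config <- function(min_reads = 5L, short_contig_cutoff = 70L,
                             tiling_interval = 30L, control_ratio = 1 / 3) {
  stopifnot(min_reads >= 0, short_contig_cutoff > 0, tiling_interval > 0,
            control_ratio > 0, control_ratio < 1)
  structure(list(min_reads = as.integer(min_reads),
                 short_contig_cutoff = as.integer(short_contig_cutoff),
                 tiling_interval = as.integer(tiling_interval),
                 control_ratio = control_ratio),
            class = "selection_config")
}

MIN_OLIGO <- 18L
MAX_OLIGO <- 30L
PREF_OLIGO <- 25L

#' Read coverage contigs from BED + bedGraph + FASTA
#'
#' Assembles one coverage contig per BED interval: the interval, its sequence
#' (FASTA record matching the BED name field) and its per-base read coverage
#' extracted from the bedGraph. Minus-strand contigs are flipped to transcript
#' sense: the sequence is reverse-complemented and the coverage vector
#' reversed, so that position 1 is always the RNA 5' end. Bases not covered by
#' any bedGraph interval get coverage 0.
#'
#' Coordinates are 0-based half-open throughout (BED/bedGraph convention).
#'
#' @param bed_path BED6 file (chrom, start, end, name, score, strand); the
#'   score column is taken as the supporting read count.
#' @param bedgraph_path bedGraph file (chrom, start, end, value).
#' @param fasta_path FASTA with one record per BED name, genome-sense,
#'   length equal to the interval width.
#' @return tibble with one row per contig: `contig_id`, `chrom`, `start`,
#'   `end`, `strand`, `sequence` (transcript sense, DNA letters), `coverage`
#'   (list-column of integer vectors), `read_count`, `biotype` (parsed from a
#'   `name|biotype` BED name if present, else "unknown").
#' @export
read_contigs <- function(bed_path, bedgraph_path, fasta_path) {
  for (p in c(bed_path, bedgraph_path, fasta_path)) {
    if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
  }
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand")[1:6])
  bg <- parse_bedgraph(bedgraph_path)
  fa <- Biostrings::readDNAStringSet(fasta_path)
  fa_names <- sub("\\s.*$", "", names(fa))

  name_parts <- strsplit(bed$name, "|", fixed = TRUE)
  ids <- vapply(name_parts, `[`, character(1), 1L)
  biotypes <- vapply(name_parts, function(p) {
    if (length(p) >= 2L) p[2L] else "unknown"
  }, character(1))

  rows <- purrr::pmap(
    list(bed$chrom, bed$start, bed$end, ids, bed$score, bed$strand, biotypes),
    function(chrom, start, end, id, score, strand, biotype) {
      width <- end - start
      if (width <= 0) abort(sprintf("contig %s has non-positive width", id))
      hit <- match(id, fa_names)
      if (is.na(hit)) abort(sprintf("no FASTA record for contig %s", id))
      seq <- as.character(fa[[hit]])
      if (nchar(seq) != width) {
        abort(sprintf(
          "length mismatch for contig %s: BED width %d vs FASTA length %d",
          id, width, nchar(seq)))
      }
      cov <- numeric(width)
      sel <- bg$chrom == chrom & bg$end > start & bg$start < end
      if (any(sel)) {
        for (j in which(sel)) {
          lo <- max(bg$start[j], start) - start + 1L
          hi <- min(bg$end[j], end) - start
          cov[lo:hi] <- cov[lo:hi] + bg$value[j]
        }
      }
      if (all(cov == round(cov))) cov <- as.integer(cov)
      if (identical(strand, "-")) {
        seq <- revcomp_dna(seq)
        cov <- rev(cov)
      }
      tibble(contig_id = id, chrom = chrom, start = start, end = end,
             strand = strand, sequence = toupper(seq), coverage = list(cov),
             read_count = as.integer(score), biotype = biotype)
    })
  dplyr::bind_rows(rows)
}

parse_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad) > 0) {
    abort(sprintf("malformed bedGraph line %d in %s: expected 4 tab-separated fields",
                  idx[bad[1]], path))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(value) | end <= start)
  if (length(bad) > 0) {
    abort(sprintf("malformed bedGraph line %d in %s: bad coordinates or value",
                  idx[bad[1]], path))
  }
  data.frame(chrom = m[, 1], start = start, end = end, value = value,
             stringsAsFactors = FALSE)
}

#' Filter contigs by minimum supporting read count
#'
#' Contigs need a minimum number of supporting sequencing reads to be
#' considered for probe design; the threshold is inclusive.
#'
#' @param contigs contig tibble from [read_contigs()]
#' @param config a [selection_config()]
#' @return the retained rows, in input order.
#' @export
filter_min_reads <- function(contigs, config = selection_config()) {
  dplyr::filter(contigs, .data$read_count >= config$min_reads)
}

# tiling grid windows for a contig of length L: offsets 0, 30, 60, ...;
# the trailing partial window is dropped when shorter than 18 nt
grid_windows <- function(len, interval = 30L, min_len = MIN_OLIGO) {
  offsets <- seq.int(0L, len - 1L, by = interval)
  widths <- pmin(interval, len - offsets)
  keep <- widths >= min_len
  tibble(offset = offsets[keep], length = widths[keep])
}

#' Select signal (probe target) regions within one contig
#'
#' Short contigs (below the cutoff, default 70 nt) yield exactly one region:
#' the contiguous window of length `min(25, contig length)` with the highest
#' mean coverage (leftmost on ties). Longer contigs are tiled into windows of
#' `tiling_interval` nt anchored at the contig 5' end (a trailing partial
#' window shorter than 18 nt is dropped); every window whose mean coverage
#' exceeds the contig-wide mean is returned ("elevated" coverage), or, when no
#' window is elevated (e.g. uniform coverage), the single window with the
#' highest mean (leftmost on ties). Returned regions never overlap.
#'
#' @param contig one-row tibble as produced by [read_contigs()] (needs
#'   `contig_id` and the `coverage` list-column).
#' @param config a [selection_config()]
#' @return tibble of regions: `contig_id`, `offset` (0-based, transcript
#'   sense), `length`, `kind` ("signal"), `mean_coverage`, `coverage_ratio`.
#' @export
select_signal_regions <- function(contig, config = selection_config()) {
  cov <- contig$coverage[[1]]
  len <- length(cov)
  if (len < MIN_OLIGO) abort("contig too short for probe design")
  maxcov <- max(cov)
  ratio <- function(m) if (maxcov > 0) m / maxcov else 0
  if (len < config$short_contig_cutoff) {
    w <- min(PREF_OLIGO, len)
    means <- running_mean(cov, w)
    best <- which.max(means) # leftmost maximum
    out <- tibble(offset = best - 1L, length = w, mean_coverage = means[best])
  } else {
    wins <- grid_windows(len, config$tiling_interval)
    wins$mean_coverage <- purrr::map2_dbl(wins$offset, wins$length, function(o, w) {
      mean(cov[(o + 1L):(o + w)])
    })
    elevated <- wins$mean_coverage > mean(cov)
    out <- if (any(elevated)) wins[elevated, ] else wins[which.max(wins$mean_coverage), ]
  }
  tibble(contig_id = contig$contig_id, offset = as.integer(out$offset),
         length = as.integer(out$length), kind = "signal",
         mean_coverage = out$mean_coverage,
         coverage_ratio = ratio(out$mean_coverage))
}

#' Select the low-coverage control/precursor region of a contig
#'
#' Among the tiling grid windows, returns the window with the lowest mean
#' coverage provided that mean is strictly below `control_ratio` times the
#' contig's highest single-base coverage and the window does not overlap any
#' of the given signal regions; otherwise returns no row. Leftmost on ties.
#'
#' @inheritParams select_signal_regions
#' @param signal_regions tibble from [select_signal_regions()] for the same
#'   contig (overlap exclusion).
#' @return tibble with zero or one region row (`kind` = "control").
#' @export
select_control_region <- function(contig, signal_regions,
                                  config = selection_config()) {
  cov <- contig$coverage[[1]]
  len <- length(cov)
  empty <- tibble(contig_id = character(), offset = integer(),
                  length = integer(), kind = character(),
                  mean_coverage = double(), coverage_ratio = double())
  if (len < config$tiling_interval) return(empty)
  maxcov <- max(cov)
  wins <- grid_windows(len, config$tiling_interval)
  wins$mean_coverage <- purrr::map2_dbl(wins$offset, wins$length, function(o, w) {
    mean(cov[(o + 1L):(o + w)])
  })
  overlaps_signal <- purrr::map2_lgl(wins$offset, wins$length, function(o, w) {
    any(o < signal_regions$offset + signal_regions$length &
          signal_regions$offset < o + w)
  })
  eligible <- wins$mean_coverage < config$control_ratio * maxcov & !overlaps_signal
  if (!any(eligible)) return(empty)
  wins <- wins[eligible, ]
  best <- wins[which.min(wins$mean_coverage), ]
  tibble(contig_id = contig$contig_id, offset = as.integer(best$offset),
         length = as.integer(best$length), kind = "control",
         mean_coverage = best$mean_coverage,
         coverage_ratio = if (maxcov > 0) best$mean_coverage / maxcov else 0)
}

#' Select all probe regions for a set of contigs
#'
#' Convenience wrapper applying the minimum-read filter, signal-region
#' selection and control-region selection contig by contig.
#'
#' @param contigs contig tibble from [read_contigs()]
#' @param config a [selection_config()]
#' @param candidate_ids optional character vector of contig ids to restrict
#'   to before selection (e.g. candidates showing expression changes in an
#'   external differentiation series); `NULL` keeps all.
#' @return region tibble (columns as in [select_signal_regions()]).
#' @export
select_regions <- function(contigs, config = selection_config(),
                           candidate_ids = NULL) {
  if (!is.null(candidate_ids)) {
    contigs <- dplyr::filter(contigs, .data$contig_id %in% candidate_ids)
  }
  contigs <- filter_min_reads(contigs, config)
  purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    contig <- contigs[i, ]
    sig <- select_signal_regions(contig, config)
    ctrl <- select_control_region(contig, sig, config)
    dplyr::bind_rows(sig, ctrl)
  })
}

#' Write a probe-region table
#'
#' Tab-separated with columns contig_id, offset, length, kind, mean_coverage,
#' coverage_ratio.
#' @param regions region tibble
#' @param path output path
#' @export
write_region_table <- function(regions, path) {
  readr::write_tsv(regions, path)
  invisible(path)
}
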