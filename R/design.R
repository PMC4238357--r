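#' Scoring weights for oligonucleotide design
#'
#' Relative emphasis on the five design sub-scores. The defaults are the
#' platform's published emphasis: 24.2% cross-hybridization, 32.3% delta Tm,
#' 6.1% folding energy, 11.3% position within the target region and 16.1%
#' low-complexity. The raw weights sum to 0.900; scores are combined with the
#' weights renormalized to sum 1.
#'
#' @param crosshyb,delta_tm,folding,position,complexity weights in `[0, 1]`.
#' @return named numeric vector of class `design_weights`.
#' @export
design_weights <- function(crosshyb = 0.242, delta_tm = 0.323,
                           folding = 0.061, position = 0.113,
                           complexity = 0.161) {
  w <- c(crosshyb = crosshyb, delta_tm = delta_tm, folding = folding,
         position = position, complexity = complexity)
  stopifnot(all(w >= 0), all(w <= 1))
  structure(w, class = c("design_weights", "numeric"))
}

#' Oligonucleotide design parameters
#'
#' @param tm_target favored DNA:RNA melting temperature, degrees C
#'   (default 60).
#' @param oligo_len_pref intended oligo length, nt (default 25).
#' @param oligo_len_min,oligo_len_max allowed length window (defaults 18, 30).
#' @param mm_position 1-based position (from the probe 5' end) of the single
#'   mismatch in the MM control probe (default 13).
#' @param Na sodium concentration used for Tm, mol/L.
#' @return list of class `design_params`.
#' @export
design_params <- function(tm_target = 60, oligo_len_pref = 25L,
                          oligo_len_min = 18L, oligo_len_max = 30L,
                          mm_position = 13L, Na = 1.0) {
  stopifnot(oligo_len_min <= oligo_len_pref, oligo_len_pref <= oligo_len_max,
            mm_position <= oligo_len_min, mm_position >= 1)
  structure(list(tm_target = tm_target,
                 oligo_len_pref = as.integer(oligo_len_pref),
                 oligo_len_min = as.integer(oligo_len_min),
                 oligo_len_max = as.integer(oligo_len_max),
                 mm_position = as.integer(mm_position), Na = Na),
            class = "design_params")
}

#' Cross-hybridization background index
#'
#' Pre-concatenates background transcript sequences per excluded source so
#' the cross-hybridization sub-score can scan candidates quickly. Matching is
#' done in RNA-target space (both sides T-normalized).
#'
#' @param sequences named character vector of background transcript sequences
#'   (names are source/contig ids); may be empty.
#' @return object of class `background_index`.
#' @export
background_index <- function(sequences = character()) {
  seqs <- vapply(sequences, normalize_dna, character(1))
  structure(list(seqs = seqs), class = "background_index")
}

# longest contiguous off-target match of the oligo's RNA-sense target
# subsequence against all background sequences except its own source contig;
# matches shorter than the 12-mer seed are not reported
crosshyb_match_length <- function(target_rna, index, exclude = NULL, k = 12L) {
  seqs <- index$seqs
  if (!is.null(exclude)) seqs <- seqs[names(seqs) != exclude]
  if (length(seqs) == 0) return(0L)
  haystack <- paste(seqs, collapse = "|")
  longest_match_in(normalize_dna(target_rna), haystack, min_len = k)
}

#' Sub-scores for one candidate oligo
#'
#' Five scores in `[0, 1]`, larger is better:
#' * `delta_tm`: `exp(-|Tm - tm_target| / 5)` with the DNA:RNA
#'   nearest-neighbor Tm;
#' * `position`: `1 - |center(oligo) - center(region)| / (len(region)/2)`,
#'   clipped to `[0, 1]`;
#' * `complexity`: Shannon entropy of the oligo's dinucleotide composition
#'   divided by its maximum (log2 16);
#' * `folding`: `1 - min(1, longest self-complementary stem / 10)`;
#' * `crosshyb`: `1 - longest contiguous off-target match / oligo length`,
#'   matches found by a 12-mer seeded scan over all background sequences
#'   excluding the oligo's own source contig.
#'
#' @param target_rna RNA-sense target subsequence covered by the oligo.
#' @param oligo_offset 0-based offset of the oligo within its region.
#' @param region_length length of the enclosing target region.
#' @param params [design_params()]
#' @param background [background_index()]
#' @param exclude source contig id excluded from the background scan.
#' @return named list: the five sub-scores plus `tm`.
#' @export
oligo_sub_scores <- function(target_rna, oligo_offset, region_length,
                             params = design_params(),
                             background = background_index(),
                             exclude = NULL) {
  len <- nchar(target_rna)
  tm <- melting_temperature(probe_for_target(target_rna), Na = params$Na)
  delta_tm <- exp(-abs(tm - params$tm_target) / 5)
  oligo_center <- oligo_offset + len / 2
  region_center <- region_length / 2
  position <- 1 - abs(oligo_center - region_center) / (region_length / 2)
  position <- min(1, max(0, position))
  complexity <- dinucleotide_entropy(normalize_dna(target_rna)) / log2(16)
  stem <- max_self_stem(probe_for_target(target_rna))
  folding <- 1 - min(1, stem / 10)
  match_len <- crosshyb_match_length(target_rna, background, exclude = exclude)
  crosshyb <- 1 - match_len / len
  list(crosshyb = crosshyb, delta_tm = delta_tm, folding = folding,
       position = position, complexity = complexity, tm = tm)
}

combine_scores <- function(scores, weights) {
  w <- as.numeric(weights[c("crosshyb", "delta_tm", "folding", "position",
                            "complexity")])
  s <- as.numeric(scores[c("crosshyb", "delta_tm", "folding", "position",
                           "complexity")])
  if (sum(w) == 0) return(0)
  sum(w * s) / sum(w)
}

#' Design the perfect-match oligo for one target region
#'
#' Enumerates every sub-sequence of the region with length between
#' `oligo_len_min` and `oligo_len_max`, scores each candidate as the
#' renormalized weighted sum of the five sub-scores, and returns the maximum.
#' Ties are broken by closeness to the intended length (25 nt), then by
#' leftmost position. The PM probe sequence is the DNA reverse complement of
#' the targeted RNA subsequence, written 5'->3'.
#'
#' @param region one region row ([select_signal_regions()]).
#' @param contig the matching contig row ([read_contigs()]).
#' @param params [design_params()]
#' @param weights [design_weights()]
#' @param background [background_index()]
#' @return one-row tibble: `probe_id`, `pm_sequence`, `mm_sequence` (NA),
#'   `target_contig`, `target_offset`, `target_length`, the five sub-scores,
#'   `combined_score`, `tm`, `role`.
#' @export
design_pm <- function(region, contig, params = design_params(),
                      weights = design_weights(),
                      background = background_index()) {
  if (region$length < params$oligo_len_min) {
    abort(sprintf("region %s:%d is shorter than the minimum oligo length",
                  region$contig_id, region$offset))
  }
  region_seq <- substr(contig$sequence, region$offset + 1L,
                       region$offset + region$length)
  cands <- tidyr::expand_grid(
    len = seq.int(params$oligo_len_min, min(params$oligo_len_max, region$length)),
    off = seq.int(0L, region$length)
  )
  cands <- dplyr::filter(cands, .data$off + .data$len <= region$length)
  scored <- purrr::pmap_dfr(cands, function(len, off) {
    sub <- substr(region_seq, off + 1L, off + len)
    sc <- oligo_sub_scores(sub, off, region$length, params, background,
                           exclude = region$contig_id)
    tibble(off = off, len = len, crosshyb = sc$crosshyb,
           delta_tm = sc$delta_tm, folding = sc$folding,
           position = sc$position, complexity = sc$complexity, tm = sc$tm,
           combined_score = combine_scores(sc, weights))
  })
  best <- dplyr::arrange(scored, dplyr::desc(.data$combined_score),
                         abs(.data$len - params$oligo_len_pref), .data$off)[1, ]
  target_rna <- substr(region_seq, best$off + 1L, best$off + best$len)
  role <- if (identical(region$kind, "control")) "control_region" else "signal"
  tibble(
    probe_id = sprintf("%s_%d_%s", region$contig_id, region$offset,
                       region$kind),
    pm_sequence = probe_for_target(target_rna),
    mm_sequence = NA_character_,
    target_contig = region$contig_id,
    target_offset = as.integer(region$offset + best$off),
    target_length = as.integer(best$len),
    crosshyb = best$crosshyb, delta_tm = best$delta_tm,
    folding = best$folding, position = best$position,
    complexity = best$complexity,
    combined_score = best$combined_score, tm = best$tm, role = role
  )
}

#' Construct the single-mismatch (MM) control probe
#'
#' Returns a probe identical to the PM except at one position (1-based from
#' the probe 5' end, default 13). The substituted base (i) must actually
#' mismatch the opposing RNA base (it is never the Watson-Crick partner),
#' (ii) is never G when the opposing RNA base is U, and (iii) is never T when
#' the opposing RNA base is G, so no G-U/T-G wobble juxtaposition with the
#' target can form at the mismatch site. Among allowed bases the transversion
#' partner of the PM base (A<->C, G<->T) is preferred, falling back to the
#' alphabetically first allowed base.
#'
#' @param pm_sequence PM probe, DNA 5'->3'.
#' @param rna_target RNA target 5'->3' (same length as the probe).
#' @param params [design_params()]
#' @return MM probe sequence, DNA 5'->3'.
#' @export
design_mm <- function(pm_sequence, rna_target, params = design_params()) {
  pm_sequence <- normalize_dna(pm_sequence)
  rna <- normalize_rna(rna_target)
  n <- nchar(pm_sequence)
  pos <- params$mm_position
  if (n < pos) abort("PM probe shorter than the mismatch position")
  if (nchar(rna) != n) abort("PM probe and RNA target lengths differ")
  pm_base <- substr(pm_sequence, pos, pos)
  # probe position i pairs with target position n - i + 1 (antiparallel)
  opposing <- substr(rna, n - pos + 1L, n - pos + 1L)
  excluded <- DNA_OF_RNA[[opposing]]           # would re-form a perfect pair
  if (opposing == "U") excluded <- c(excluded, "G")  # G.U wobble
  if (opposing == "G") excluded <- c(excluded, "T")  # T.G wobble
  allowed <- setdiff(DNA_BASES, c(excluded, pm_base))
  if (length(allowed) == 0) abort("no allowed mismatch base (cannot occur)")
  transversion <- c(A = "C", C = "A", G = "T", T = "G")[[pm_base]]
  pick <- if (transversion %in% allowed) transversion else allowed[1]
  paste0(substr(pm_sequence, 1L, pos - 1L), pick,
         substr(pm_sequence, pos + 1L, n))
}

#' Design all probes for a region table
#'
#' Runs [design_pm()] for every region and attaches the MM partner to signal
#' probes; control-region probes are spotted without an MM partner.
#'
#' @param regions region tibble ([select_regions()]).
#' @param contigs contig tibble ([read_contigs()]).
#' @inheritParams design_pm
#' @return probe tibble, one row per PM probe (MM in `mm_sequence`).
#' @export
design_probes <- function(regions, contigs, params = design_params(),
                          weights = design_weights(),
                          background = background_index()) {
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    region <- regions[i, ]
    contig <- contigs[contigs$contig_id == region$contig_id, ][1, ]
    pair <- design_pm(region, contig, params, weights, background)
    if (identical(pair$role, "signal")) {
      target_rna <- normalize_rna(substr(contig$sequence,
                                         pair$target_offset + 1L,
                                         pair$target_offset + pair$target_length))
      pair$mm_sequence <- design_mm(pair$pm_sequence, target_rna, params)
    }
    pair$biotype <- contig$biotype
    pair
  })
}

# deterministic synthetic stand-ins for the U2/U6 snRNA sequences (realistic
# lengths 191/107 nt); real sequences can be passed to the control maker
synthetic_snrna <- function(which = c("U2", "U6")) {
  which <- match.arg(which)
  len <- if (which == "U2") 191L else 107L
  withr::with_seed(if (which == "U2") 2002L else 6006L, {
    random_dna(1L, len, gc = 0.5)
  })
}

#' Spike-in and snRNA control probes
#'
#' Builds the chip's internal controls: eight random spike-in 25-mers (GC
#' content 40-60%, no self-complementary stem of 6 nt or more) plus 40 probes
#' for expression analysis of the U2 and U6 snRNAs (20 each by default),
#' tiled evenly along the snRNA sequences. Control probes carry no MM
#' partner. The bundled default U2/U6 sequences are deterministic synthetic
#' stand-ins of realistic length; pass real sequences for a production chip.
#'
#' @param seed integer seed for the spike-in draw.
#' @param u2,u6 snRNA sequences (DNA letters); defaults are synthetic.
#' @param n_spike number of spike-in probes (default 8).
#' @param n_each snRNA probes per snRNA (default 20).
#' @param probe_len probe length (default 25).
#' @return probe tibble compatible with [design_probes()] output.
#' @export
make_spike_and_snrna_controls <- function(seed = 1L, u2 = synthetic_snrna("U2"),
                                          u6 = synthetic_snrna("U6"),
                                          n_spike = 8L, n_each = 20L,
                                          probe_len = 25L) {
  spikes <- withr::with_seed(seed, {
    out <- character(0)
    while (length(out) < n_spike) {
      cand <- random_dna(1L, probe_len, gc = 0.5)
      if (gc_fraction(cand) >= 0.4 && gc_fraction(cand) <= 0.6 &&
          max_self_stem(cand) < 6L) {
        out <- c(out, cand)
      }
    }
    out
  })
  tile_probes <- function(seqname, seq, n) {
    seq <- normalize_dna(seq)
    L <- nchar(seq)
    if (L < probe_len) {
      abort(sprintf("%s sequence too short to tile %d probes of %d nt",
                    seqname, n, probe_len))
    }
    if (L - probe_len + 1L < n) {
      abort(sprintf("%s sequence too short to tile %d probes of %d nt",
                    seqname, n, probe_len))
    }
    offsets <- unique(round(seq(1L, L - probe_len + 1L, length.out = n)))
    purrr::imap_dfr(offsets, function(o, i) {
      target <- substr(seq, o, o + probe_len - 1L)
      tibble(probe_id = sprintf("%s_ctrl_%02d", seqname, i),
             pm_sequence = probe_for_target(normalize_rna(target)),
             mm_sequence = NA_character_, target_contig = seqname,
             target_offset = as.integer(o - 1L),
             target_length = as.integer(probe_len),
             crosshyb = NA_real_, delta_tm = NA_real_, folding = NA_real_,
             position = NA_real_, complexity = NA_real_,
             combined_score = NA_real_,
             tm = melting_temperature(probe_for_target(normalize_rna(target))),
             role = "snRNA_control", biotype = "snRNA")
    })
  }
  spike_tbl <- purrr::imap_dfr(spikes, function(s, i) {
    tibble(probe_id = sprintf("spike_%02d", i), pm_sequence = s,
           mm_sequence = NA_character_, target_contig = NA_character_,
           target_offset = NA_integer_, target_length = as.integer(probe_len),
           crosshyb = NA_real_, delta_tm = NA_real_, folding = NA_real_,
           position = NA_real_, complexity = NA_real_,
           combined_score = NA_real_, tm = melting_temperature(s),
           role = "spike_in", biotype = "spike")
  })
  dplyr::bind_rows(spike_tbl,
                   tile_probes("U2", u2, n_each),
                   tile_probes("U6", u6, n_each))
}

#' Write probes as FASTA
#'
#' IDs follow the `<probe_id>_PM` / `<probe_id>_MM` convention.
#' @param probes probe tibble
#' @param path output FASTA path
#' @export
write_probe_fasta <- function(probes, path) {
  lines <- character(0)
  for (i in seq_len(nrow(probes))) {
    lines <- c(lines, sprintf(">%s_PM", probes$probe_id[i]),
               probes$pm_sequence[i])
    if (!is.na(probes$mm_sequence[i])) {
      lines <- c(lines, sprintf(">%s_MM", probes$probe_id[i]),
                 probes$mm_sequence[i])
    }
  }
  writeLines(lines, path)
  invisible(path)
}
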