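#' Summarise candidate sources for a chip design
#'
#' Counts candidates per source (e.g. RNA-Seq contigs vs computational
#' predictions) and the share each source contributes to the merged candidate
#' set.
#'
#' @param candidates tibble with columns `candidate_id` and `source`.
#' @return tibble: `source`, `n`, `share` (fraction), `share_pct` (rounded
#'   percent) plus a `total` attribute; also one `"total"` row.
#' @export
summarize_candidate_sources <- function(candidates) {
  total <- dplyr::n_distinct(candidates$candidate_id)
  by_source <- candidates |>
    dplyr::distinct(.data$candidate_id, .data$source) |>
    dplyr::count(.data$source, name = "n") |>
    dplyr::mutate(share = .data$n / total,
                  share_pct = round(100 * .data$n / total))
  out <- dplyr::bind_rows(by_source,
                          tibble(source = "total", n = total, share = 1,
                                 share_pct = 100))
  attr(out, "total") <- total
  out
}

#' Up/down DE counts per comparison (optionally per biotype)
#'
#' @param de DE result tibble ([analyze_experiment()]`$de`); needs `de_call`
#'   and `log2fc`, optionally `biotype`.
#' @param by optional grouping column name (e.g. "biotype").
#' @return tibble with `n_up`, `n_down`, `n_de`.
#' @export
de_counts <- function(de, by = NULL) {
  g <- if (!is.null(by) && by %in% names(de)) de |> dplyr::group_by(.data[[by]]) else de
  g |>
    dplyr::summarise(n_up = sum(.data$de_call & .data$log2fc > 0, na.rm = TRUE),
                     n_down = sum(.data$de_call & .data$log2fc < 0, na.rm = TRUE),
                     n_de = sum(.data$de_call, na.rm = TRUE),
                     .groups = "drop")
}

#' Membership overlap of DE candidates across comparisons
#'
#' Venn-style membership table: one row per candidate called DE in any
#' comparison, one logical column per comparison, plus per-pattern counts.
#'
#' @param de_tables named list of DE result tibbles.
#' @return list with `membership` (tibble) and `pattern_counts`.
#' @export
overlap_table <- function(de_tables) {
  stopifnot(!is.null(names(de_tables)), all(nzchar(names(de_tables))))
  sets <- purrr::map(de_tables, function(d) d$candidate_id[d$de_call])
  all_ids <- sort(unique(unlist(sets)))
  membership <- tibble(candidate_id = all_ids)
  for (nm in names(sets)) membership[[nm]] <- all_ids %in% sets[[nm]]
  pattern <- apply(as.matrix(membership[, -1, drop = FALSE]), 1, function(r) {
    paste(names(sets)[r], collapse = "&")
  })
  counts <- membership |>
    dplyr::mutate(pattern = pattern) |>
    dplyr::count(.data$pattern, name = "n")
  list(membership = membership, pattern_counts = counts)
}

#' Biotype-by-location frequency table
#'
#' Counts candidates per biotype and genomic-location tag, with log2-scale
#' frequencies for plotting.
#'
#' @param candidates tibble with `biotype` and `location` columns.
#' @return tibble: `biotype`, `location`, `n`, `log2_n`.
#' @export
biotype_location_table <- function(candidates) {
  candidates |>
    dplyr::count(.data$biotype, .data$location, name = "n") |>
    dplyr::mutate(log2_n = log2(.data$n))
}

#' Assemble the summary report tables for one or more comparisons
#'
#' @param de_tables named list of DE tibbles.
#' @param candidates optional candidate tibble with `biotype`/`location` for
#'   the frequency table.
#' @param dir optional output directory; tables are written as TSV.
#' @return list of tibbles: `counts` (per comparison, and per biotype where
#'   available), `overlap`, `frequencies` (when `candidates` given).
#' @export
report_summary <- function(de_tables, candidates = NULL, dir = NULL) {
  counts <- purrr::imap_dfr(de_tables, function(d, nm) {
    dplyr::mutate(de_counts(d), comparison = nm, .before = 1)
  })
  counts_biotype <- purrr::imap_dfr(de_tables, function(d, nm) {
    if (!"biotype" %in% names(d)) return(NULL)
    dplyr::mutate(de_counts(d, by = "biotype"), comparison = nm, .before = 1)
  })
  ov <- if (length(de_tables) > 1L) overlap_table(de_tables)
  freq <- if (!is.null(candidates) && all(c("biotype", "location") %in%
                                          names(candidates))) {
    biotype_location_table(candidates)
  }
  out <- list(counts = counts, counts_biotype = counts_biotype,
              overlap = ov, frequencies = freq)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(counts, file.path(dir, "de_counts.tsv"))
    if (!is.null(counts_biotype) && nrow(counts_biotype) > 0) {
      readr::write_tsv(counts_biotype, file.path(dir, "de_counts_biotype.tsv"))
    }
    if (!is.null(ov)) {
      readr::write_tsv(ov$membership, file.path(dir, "overlap_membership.tsv"))
      readr::write_tsv(ov$pattern_counts, file.path(dir, "overlap_patterns.tsv"))
    }
    if (!is.null(freq)) {
      readr::write_tsv(freq, file.path(dir, "biotype_location.tsv"))
    }
  }
  out
}

#' Operating characteristics of the pipeline on simulated truth
#'
#' Simulates a complete dye-swap experiment on a given design, runs the full
#' analysis pipeline and scores the calls against the known truth.
#'
#' @param design `array_design` whose paired probes define the candidates.
#' @param seed integer seed (drives the truth and the hybridization noise).
#' @param fraction_de fraction of candidates spiked as DE.
#' @param effect_size absolute log2 fold change of spiked candidates.
#' @param n_pairs dye-swap pairs.
#' @param ... further arguments to [truth_model()].
#' @return one-row tibble: `null_p_rate` (raw p < 0.05 among true nulls),
#'   `fdr` (false discoveries / discoveries at adjusted p < 0.05; 0 when no
#'   discovery), `sensitivity`, `mean_abs_lfc_error` (DE candidates),
#'   `n_candidates`, `n_de_true`, `n_de_called`.
#' @export
evaluate_pipeline <- function(design, seed, fraction_de = 0.10,
                              effect_size = 1, n_pairs = 3L, ...) {
  paired <- unique(design$probe_id[design$pair_role == "PM"])
  truth <- truth_model(paired, fraction_de = fraction_de,
                       effect_size = effect_size, seed = seed, ...)
  sim <- simulate_experiment(design, truth, n_pairs = n_pairs)
  res <- analyze_experiment(sim$scans, sim$sheet)
  de <- dplyr::inner_join(res$de, sim$truth, by = c(candidate_id = "candidate_id"))
  nulls <- de[!de$is_de, ]
  des <- de[de$is_de, ]
  called <- de[de$de_call, ]
  tibble(
    null_p_rate = mean(nulls$p < 0.05, na.rm = TRUE),
    fdr = if (nrow(called) > 0) mean(!called$is_de) else 0,
    sensitivity = if (nrow(des) > 0) mean(des$de_call) else NA_real_,
    mean_abs_lfc_error = mean(abs(des$log2fc - des$beta), na.rm = TRUE),
    n_candidates = nrow(de),
    n_de_true = nrow(des),
    n_de_called = nrow(called)
  )
}

#' Default simulation-scale array design
#'
#' A paired layout for `n_candidates` signal probe pairs plus the standard
#' 48 control probes, on 8 print-tip blocks sized to fit octuplicate
#' spotting. Used by the operating-characteristic studies.
#'
#' @param n_candidates number of signal probe pairs.
#' @param seed layout seed.
#' @return `array_design`.
#' @export
default_sim_design <- function(n_candidates = 2000L, seed = 100L) {
  probes <- tibble(
    probe_id = c(sprintf("cand_%04d", seq_len(n_candidates)),
                 sprintf("ctrl_%02d", 1:48)),
    mm_sequence = c(rep("x", n_candidates), rep(NA_character_, 48L)))
  rows <- ceiling(sqrt(n_candidates * 16L + 48L * 8L) / sqrt(8)) + 2L
  layout_array(probes, n_blocks = 8L, block_rows = rows,
               block_cols = rows, seed = seed)
}
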