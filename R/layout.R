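#' Lay probes out on a print-tip blocked array
#'
#' Places each probe on the spotted grid with eight-fold replication realised
#' as two spatially separated quadruplicates: four replicates go to blocks in
#' the first half of the block list and four to blocks in the second half, a
#' layout that buffers local hybridization artifacts. Each PM probe is
#' spotted immediately next to its MM partner (same block, same row, adjacent
#' columns); probes without an MM partner (control-region, spike-in and snRNA
#' probes) occupy single cells. Within a block, consecutive placements of the
#' same quadruplicate use rows two apart where capacity allows. The layout is
#' deterministic given the seed.
#'
#' @param probes probe tibble ([design_probes()] /
#'   [make_spike_and_snrna_controls()]); `mm_sequence` NA marks single spots.
#' @param n_blocks number of print-tip blocks (>= 2; split into two halves).
#' @param block_rows,block_cols grid size of each block.
#' @param seed integer seed for the randomized placement.
#' @return tibble of class `array_design` with one row per spot: `block`,
#'   `row`, `col`, `probe_id`, `replicate_index` (1-8; 1-4 first half,
#'   5-8 second), `pair_role` ("PM", "MM" or "single"); attributes `n_blocks`,
#'   `block_rows`, `block_cols`.
#' @export
layout_array <- function(probes, n_blocks, block_rows, block_cols, seed = 1L) {
  if (n_blocks < 2L) {
    abort("need at least 2 blocks to separate the two quadruplicates")
  }
  is_pair <- !is.na(probes$mm_sequence)
  n_pairs <- sum(is_pair)
  n_single <- sum(!is_pair)
  halves <- list(seq_len(n_blocks %/% 2L),
                 seq.int(n_blocks %/% 2L + 1L, n_blocks))
  pair_slots_half <- function(h) length(h) * block_rows * (block_cols %/% 2L)
  cells_half <- function(h) length(h) * block_rows * block_cols
  for (h in halves) {
    need_pair <- n_pairs * 4L
    need_cells <- n_pairs * 8L + n_single * 4L
    if (pair_slots_half(h) < need_pair || cells_half(h) < need_cells) {
      abort(sprintf(
        "array capacity exceeded: need %d cells (%d PM/MM pair slots) per half, half has %d cells (%d pair slots)",
        need_cells, need_pair, cells_half(h), pair_slots_half(h)))
    }
  }

  # per-block slot orders: pair slots are (row, left-col of a column pair),
  # rows interleaved with stride 2 so same-block repeats land far apart
  row_order <- unique(c(seq.int(1L, block_rows, by = 2L),
                        if (block_rows >= 2L) seq.int(2L, block_rows, by = 2L)))
  pair_cols <- if (block_cols >= 2L) seq.int(1L, 2L * (block_cols %/% 2L), by = 2L) else integer(0)

  make_block_slots <- function(b) {
    slots <- tidyr::expand_grid(colp = pair_cols, row = row_order)
    tibble(block = b, row = slots$row, col = slots$colp)
  }

  withr::with_seed(seed, {
    pair_probes <- probes$probe_id[is_pair]
    if (n_pairs > 1L) pair_probes <- pair_probes[sample.int(n_pairs)]
    single_probes <- probes$probe_id[!is_pair]
    if (n_single > 1L) single_probes <- single_probes[sample.int(n_single)]

    spots <- vector("list", 2L)
    for (hi in 1:2) {
      blocks <- halves[[hi]]
      if (length(blocks) > 1L) blocks <- sample(blocks)
      slot_lists <- lapply(blocks, make_block_slots)
      cursors <- rep(1L, length(blocks))
      placed <- vector("list", n_pairs * 4L + n_single * 4L)
      k <- 0L
      take_slot <- function(bi) {
        # next free pair slot in block bi, falling over to later blocks
        for (j in c(bi:length(blocks), seq_len(bi - 1L))) {
          if (cursors[j] <= nrow(slot_lists[[j]])) {
            s <- slot_lists[[j]][cursors[j], ]
            cursors[j] <<- cursors[j] + 1L
            return(s)
          }
        }
        abort("internal error: pair slots exhausted despite capacity check")
      }
      for (i in seq_along(pair_probes)) {
        for (r in 1:4) {
          bi <- ((i + r - 2L) %% length(blocks)) + 1L
          s <- take_slot(bi)
          rep_idx <- (hi - 1L) * 4L + r
          k <- k + 1L
          placed[[k]] <- tibble(block = s$block, row = s$row,
                                col = c(s$col, s$col + 1L),
                                probe_id = pair_probes[i],
                                replicate_index = rep_idx,
                                pair_role = c("PM", "MM"))
        }
      }
      # singles fill remaining pair slots cell-by-cell, then odd columns
      leftovers <- purrr::map_dfr(seq_along(blocks), function(j) {
        sl <- slot_lists[[j]]
        if (cursors[j] > nrow(sl)) return(NULL)
        rest <- sl[cursors[j]:nrow(sl), ]
        dplyr::bind_rows(rest, dplyr::mutate(rest, col = .data$col + 1L))
      })
      if (block_cols %% 2L == 1L) {
        odd <- purrr::map_dfr(blocks, function(b) {
          tibble(block = b, row = row_order, col = block_cols)
        })
        leftovers <- dplyr::bind_rows(leftovers, odd)
      }
      sidx <- 0L
      for (i in seq_along(single_probes)) {
        for (r in 1:4) {
          sidx <- sidx + 1L
          s <- leftovers[sidx, ]
          rep_idx <- (hi - 1L) * 4L + r
          k <- k + 1L
          placed[[k]] <- tibble(block = s$block, row = s$row, col = s$col,
                                probe_id = single_probes[i],
                                replicate_index = rep_idx,
                                pair_role = "single")
        }
      }
      spots[[hi]] <- dplyr::bind_rows(placed[seq_len(k)])
    }
  })
  out <- dplyr::arrange(dplyr::bind_rows(spots), .data$block, .data$row,
                        .data$col)
  structure(out, class = c("array_design", class(out)),
            n_blocks = as.integer(n_blocks),
            block_rows = as.integer(block_rows),
            block_cols = as.integer(block_cols))
}

#' Validate array-layout invariants
#'
#' Independent checker usable on any layout: no grid cell used twice; every
#' PM spot has its MM partner in the same block and row in an adjacent
#' column; every paired probe appears exactly 8 times with quadruplicates in
#' disjoint block halves; singles appear 8 times (4 + 4).
#'
#' @param design an `array_design` (or any tibble with the same columns plus
#'   `n_blocks` attribute or `n_blocks` argument).
#' @param n_blocks number of blocks if not carried as an attribute.
#' @return invisibly `TRUE`; aborts with a message describing the first
#'   violated invariant otherwise.
#' @export
validate_layout <- function(design, n_blocks = attr(design, "n_blocks")) {
  if (is.null(n_blocks)) n_blocks <- max(design$block)
  cell <- paste(design$block, design$row, design$col)
  if (anyDuplicated(cell)) {
    abort(sprintf("grid cell used twice: %s", cell[duplicated(cell)][1]))
  }
  first_half <- seq_len(n_blocks %/% 2L)
  pm <- design[design$pair_role == "PM", ]
  mm <- design[design$pair_role == "MM", ]
  if (nrow(pm) != nrow(mm)) abort("PM and MM spot counts differ")
  if (nrow(pm) > 0) {
    key <- function(d) paste(d$probe_id, d$replicate_index)
    mmi <- mm[match(key(pm), key(mm)), ]
    ok <- pm$block == mmi$block & pm$row == mmi$row &
      abs(pm$col - mmi$col) == 1L
    if (!all(ok)) {
      abort(sprintf("PM spot without adjacent MM partner: %s",
                    pm$probe_id[!ok][1]))
    }
  }
  counts <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(design), .data$probe_id, .data$pair_role),
    n = dplyr::n(),
    n_first = sum(.data$block %in% first_half),
    .groups = "drop")
  bad <- counts$n != 8L | counts$n_first != 4L
  if (any(bad)) {
    abort(sprintf("probe %s has %d spots (%d in the first block half); expected 8 (4+4)",
                  counts$probe_id[bad][1], counts$n[bad][1],
                  counts$n_first[bad][1]))
  }
  invisible(TRUE)
}

#' Write / read a layout file
#'
#' GAL-like tab-separated dialect with columns Block, Row, Column, ID, Name;
#' ID encodes probe, pair role and replicate index so that reading a written
#' layout reconstructs it exactly.
#'
#' @param design `array_design`
#' @param path file path
#' @return `write_layout` returns the path invisibly; `read_layout` returns
#'   the reconstructed `array_design`.
#' @export
write_layout <- function(design, path) {
  out <- tibble(Block = design$block, Row = design$row, Column = design$col,
                ID = sprintf("%s|%s|%d", design$probe_id, design$pair_role,
                             design$replicate_index),
                Name = design$probe_id)
  header <- sprintf("#ncarray layout n_blocks=%d block_rows=%d block_cols=%d",
                    attr(design, "n_blocks") %||% max(design$block, 0L),
                    attr(design, "block_rows") %||% max(design$row, 0L),
                    attr(design, "block_cols") %||% max(design$col, 0L))
  writeLines(c(header, paste(names(out), collapse = "\t")), path)
  if (nrow(out) > 0) {
    utils::write.table(out, path, append = TRUE, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- as.integer(stringr::str_match_all(
    header, "(n_blocks|block_rows|block_cols)=(\\d+)")[[1]][, 3])
  empty <- tibble(block = integer(), row = integer(), col = integer(),
                  probe_id = character(), replicate_index = integer(),
                  pair_role = character())
  if (length(readLines(path)) <= 2L) {
    return(structure(empty, class = c("array_design", class(empty)),
                     n_blocks = meta[1], block_rows = meta[2],
                     block_cols = meta[3]))
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                           comment.char = "", stringsAsFactors = FALSE)
  cell <- paste(tab$Block, tab$Row, tab$Column)
  if (anyDuplicated(cell)) {
    abort(sprintf("duplicate grid cell in %s: block/row/col %s", path,
                  cell[duplicated(cell)][1]))
  }
  parts <- stringr::str_split_fixed(tab$ID, stringr::fixed("|"), 3)
  out <- tibble(block = as.integer(tab$Block), row = as.integer(tab$Row),
                col = as.integer(tab$Column), probe_id = parts[, 1],
                replicate_index = as.integer(parts[, 3]),
                pair_role = parts[, 2])
  structure(out, class = c("array_design", class(out)),
            n_blocks = meta[1], block_rows = meta[2], block_cols = meta[3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
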