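#' Ground-truth generative model for two-color hybridizations
#'
#' Defines the per-candidate truth (baseline log2 expression, condition
#' effect, gene-wise dye bias) and the nuisance parameters of the spot-level
#' generative model used by [simulate_experiment()].
#'
#' Per spot, the specific signal is `S = 2^(mu_g + x_c * beta_g + e)` with
#' `x_c = 1` in the case condition and `e` a per gene x array x condition
#' Normal(0, sigma_bio^2) draw (each hybridization uses an independently
#' labeled RNA aliquot). MM spots carry `kappa * S`. The channel foregrounds
#' are
#' `F = 2^(+/- (delta_g + f_b(A)) / 2) * (S + nu) * exp(eps) + B`
#' where the sign is + for the red channel and - for the green channel,
#' `f_b(A) = c0_b + c1_b z + c2_b z^2` is a smooth per-block intensity
#' curvature (z the centered log2 abundance), `eps` is Normal(0,
#' sigma_eps^2) per spot and channel, and `B` is the local background around
#' level `b`. With all noise, curvature, `kappa` and `nu` at zero the net
#' intensity `F - B` reproduces `2^(mu + x beta)` exactly.
#'
#' @param candidate_ids character vector of candidate (probe) ids.
#' @param fraction_de fraction of candidates carrying a nonzero effect
#'   (default 0.10).
#' @param effect_size absolute log2 fold change of affected candidates
#'   (default 1); signs are drawn evenly.
#' @param mu_mean,mu_sd baseline log2 expression distribution (default 10, 1).
#' @param sigma_bio per gene x array x condition biological/labeling noise sd,
#'   log2 units (default 0.15).
#' @param sigma_dye sd of the gene-wise dye bias delta_g, log2 units
#'   (default 0.1).
#' @param sigma_eps spot-level multiplicative noise sd, natural-log units
#'   (default 0.15).
#' @param background additive local background level `b` (default 100).
#' @param kappa MM cross-hybridization fraction in `[0, 1)` (default 0.3).
#' @param nu nonspecific signal floor (default 30).
#' @param tip_coef_sd sds of the per block x array curvature coefficients
#'   (constant, linear, quadratic; default `c(0.1, 0.05, 0.02)`).
#' @param seed integer seed for the truth draw.
#' @return object of class `truth_model`: parameter list plus `$candidates`,
#'   a tibble with `candidate_id`, `mu`, `beta`, `delta`, `is_de`.
#' @export
truth_model <- function(candidate_ids, fraction_de = 0.10, effect_size = 1,
                        mu_mean = 10, mu_sd = 1, sigma_bio = 0.15,
                        sigma_dye = 0.1, sigma_eps = 0.15, background = 100,
                        kappa = 0.3, nu = 30,
                        tip_coef_sd = c(0.1, 0.05, 0.02), seed = 1L) {
  stopifnot(kappa >= 0, kappa < 1, fraction_de >= 0, fraction_de <= 1)
  n <- length(candidate_ids)
  candidates <- withr::with_seed(seed, {
    n_de <- round(fraction_de * n)
    de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
    beta <- numeric(n)
    if (n_de > 0) {
      beta[de_idx] <- effect_size * sample(c(-1, 1), n_de, replace = TRUE)
    }
    tibble(candidate_id = candidate_ids,
           mu = stats::rnorm(n, mu_mean, mu_sd),
           beta = beta,
           delta = stats::rnorm(n, 0, sigma_dye),
           is_de = seq_len(n) %in% de_idx)
  })
  structure(list(candidates = candidates, fraction_de = fraction_de,
                 effect_size = effect_size, mu_mean = mu_mean, mu_sd = mu_sd,
                 sigma_bio = sigma_bio, sigma_dye = sigma_dye,
                 sigma_eps = sigma_eps, background = background,
                 kappa = kappa, nu = nu, tip_coef_sd = tip_coef_sd,
                 seed = as.integer(seed)),
            class = "truth_model")
}

#' Simulate a dye-swap two-color microarray experiment
#'
#' Generates `2 * n_pairs` array scans: each biological replicate is
#' hybridised twice with the dye-to-condition assignment reversed (a dye-swap
#' pair). Spots follow the generative model of [truth_model()]; all draws
#' come from the seeded generator, so a given (design, truth, n_pairs) is
#' fully reproducible.
#'
#' @param design `array_design` from [layout_array()].
#' @param truth `truth_model`; its `candidate_id`s must cover the design's
#'   paired probes (single control probes get a flat nonspecific signal).
#' @param n_pairs number of dye-swap pairs (biological replicates, default 3).
#' @param conditions names of the two conditions, case first (the condition
#'   whose effect is `+beta`).
#' @return list with `scans` (long tibble: `array_id`, spot columns of the
#'   design, `F635`, `B635`, `F532`, `B532`), `sheet` (tibble: `array_id`,
#'   `channel_635`, `channel_532`, `pair_id`, `biological_replicate`) and
#'   `truth` (the candidate truth table).
#' @export
simulate_experiment <- function(design, truth, n_pairs = 3L,
                                conditions = c("case", "control")) {
  spots <- tibble::as_tibble(design)
  cand <- truth$candidates
  idx <- match(spots$probe_id, cand$candidate_id)
  mu <- cand$mu[idx]
  beta <- cand$beta[idx]
  delta <- cand$delta[idx]
  # probes absent from the truth table (spike-ins / snRNA controls):
  # constant abundance at the truth's mean baseline, no effect, no dye bias
  mu[is.na(mu)] <- truth$mu_mean
  beta[is.na(beta)] <- 0
  delta[is.na(delta)] <- 0
  is_mm <- spots$pair_role == "MM"
  n_spots <- nrow(spots)
  blocks <- sort(unique(spots$block))

  sheet <- tibble(
    array_id = sprintf("array_%02d", seq_len(2L * n_pairs)),
    channel_635 = rep(conditions, n_pairs),
    channel_532 = rep(rev(conditions), n_pairs),
    pair_id = rep(seq_len(n_pairs), each = 2L),
    biological_replicate = rep(seq_len(n_pairs), each = 2L)
  )

  scans <- withr::with_seed(truth$seed + 1L, {
    purrr::map_dfr(seq_len(2L * n_pairs), function(a) {
      bio <- matrix(stats::rnorm(2L * nrow(cand), 0, truth$sigma_bio),
                    ncol = 2L) # per gene: case, control
      tip <- matrix(stats::rnorm(3L * length(blocks), 0,
                                 rep(truth$tip_coef_sd, length(blocks))),
                    nrow = 3L)
      gene_bio_case <- bio[, 1][idx]; gene_bio_ctrl <- bio[, 2][idx]
      gene_bio_case[is.na(gene_bio_case)] <- 0
      gene_bio_ctrl[is.na(gene_bio_ctrl)] <- 0
      s_case <- 2^(mu + beta + gene_bio_case)
      s_ctrl <- 2^(mu + gene_bio_ctrl)
      mmf <- ifelse(is_mm, truth$kappa, 1)
      s_case <- s_case * mmf
      s_ctrl <- s_ctrl * mmf
      red_case <- sheet$channel_635[a] == conditions[1]
      s_red <- if (red_case) s_case else s_ctrl
      s_green <- if (red_case) s_ctrl else s_case
      z <- log2(pmax((s_red + s_green) / 2 + truth$nu, 1)) - truth$mu_mean
      bi <- match(spots$block, blocks)
      curve <- tip[1, bi] + tip[2, bi] * z + tip[3, bi] * z^2
      ratio_half <- 2^((delta + curve) / 2)
      eps_r <- exp(stats::rnorm(n_spots, 0, truth$sigma_eps))
      eps_g <- exp(stats::rnorm(n_spots, 0, truth$sigma_eps))
      b_r <- truth$background * exp(stats::rnorm(n_spots, 0, truth$sigma_eps))
      b_g <- truth$background * exp(stats::rnorm(n_spots, 0, truth$sigma_eps))
      dplyr::mutate(spots,
                    array_id = sheet$array_id[a],
                    F635 = ratio_half * (s_red + truth$nu) * eps_r + b_r,
                    B635 = b_r,
                    F532 = (s_green + truth$nu) * eps_g / ratio_half + b_g,
                    B532 = b_g)
    })
  })
  list(scans = dplyr::relocate(scans, "array_id"), sheet = sheet,
       truth = cand)
}

#' Generate synthetic probe-design inputs (BED + bedGraph + FASTA)
#'
#' Creates coverage contigs emulating short-ncRNA sequencing loci: lengths
#' log-uniform between 20 and 400 nt, a low coverage plateau across the
#' contig with one elevated peak aligned to a 30-nt grid window on longer
#' contigs (the processing-product pattern seen for e.g. snoRNA-derived
#' fragments). Biotype labels follow the platform's candidate composition
#' (snoRNA 11%, tRF 6%, miRNA 13%, unclassified 70%). Deterministic by seed.
#'
#' @param n_contigs number of contigs.
#' @param seed integer seed.
#' @param dir if non-NULL, writes `contigs.bed`, `coverage.bedGraph` and
#'   `contigs.fa` there.
#' @param min_len,max_len contig length range (default 20-400 nt).
#' @return contig tibble as from [read_contigs()], with extra columns
#'   `peak_offset` (grid offset of the planted peak, NA for short contigs)
#'   and `location` (genomic-context tag); attribute `files` gives paths when
#'   `dir` is used.
#' @export
simulate_design_inputs <- function(n_contigs, seed = 1L, dir = NULL,
                                   min_len = 20L, max_len = 400L) {
  biotypes <- c("snoRNA", "tRF", "miRNA", "unknown")
  bio_p <- c(0.11, 0.06, 0.13, 0.70)
  locations <- c("intronic", "intergenic", "exonic", "antisense")
  loc_p <- c(0.5, 0.3, 0.1, 0.1)
  contigs <- withr::with_seed(seed, {
    lens <- round(exp(stats::runif(n_contigs, log(min_len), log(max_len))))
    pos <- 1000L
    purrr::map_dfr(seq_len(n_contigs), function(i) {
      len <- lens[i]
      base <- stats::rpois(1, 8) + 1L
      cov <- stats::rpois(len, base)
      peak_offset <- NA_integer_
      if (len >= 70L) {
        wins <- grid_windows(len)
        peak_offset <- wins$offset[sample.int(nrow(wins), 1L)]
        w <- wins$length[wins$offset == peak_offset]
        amp <- stats::runif(1, 5, 20)
        cov[(peak_offset + 1L):(peak_offset + w)] <-
          stats::rpois(w, base * amp) + 1L
      }
      strand <- sample(c("+", "-"), 1L)
      chrom <- sprintf("chr%d", sample.int(19L, 1L))
      start <- pos + i * 1000L
      tibble(contig_id = sprintf("cand_%04d", i), chrom = chrom,
             start = start, end = start + len, strand = strand,
             sequence = random_dna(1L, len, gc = 0.45),
             coverage = list(as.integer(cov)),
             read_count = as.integer(round(sum(cov) / 25)),
             biotype = sample(biotypes, 1L, prob = bio_p),
             peak_offset = peak_offset,
             location = sample(locations, 1L, prob = loc_p))
    })
  })
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(bed = file.path(dir, "contigs.bed"),
                  bedgraph = file.path(dir, "coverage.bedGraph"),
                  fasta = file.path(dir, "contigs.fa"))
    bed <- sprintf("%s\t%d\t%d\t%s|%s\t%d\t%s", contigs$chrom, contigs$start,
                   contigs$end, contigs$contig_id, contigs$biotype,
                   contigs$read_count, contigs$strand)
    writeLines(bed, files$bed)
    bg <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
      cov <- contigs$coverage[[i]]
      # genome-sense coverage: transcript-sense vector flipped back for "-"
      if (contigs$strand[i] == "-") cov <- rev(cov)
      r <- rle(cov)
      ends <- cumsum(r$lengths)
      starts <- c(0L, ends[-length(ends)])
      keep <- r$values > 0
      tibble(chrom = contigs$chrom[i],
             start = contigs$start[i] + starts[keep],
             end = contigs$start[i] + ends[keep], value = r$values[keep])
    })
    readr::write_tsv(bg, files$bedgraph, col_names = FALSE)
    fa_seq <- ifelse(contigs$strand == "-",
                     vapply(contigs$sequence, revcomp_dna, character(1)),
                     contigs$sequence)
    writeLines(rbind(sprintf(">%s", contigs$contig_id), fa_seq), files$fasta)
  }
  attr(contigs, "files") <- files
  contigs
}

#' Write simulated scans as GPR-like files plus an experiment sheet
#'
#' One tab-separated file per array with columns Block, Row, Column, ID,
#' Name, "F635 Median", "B635 Median", "F532 Median", "B532 Median", plus
#' `experiment_sheet.tsv`.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory.
#' @return named list of written file paths.
#' @export
write_scans <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map(unique(sim$scans$array_id), function(a) {
    d <- sim$scans[sim$scans$array_id == a, ]
    out <- tibble(Block = d$block, Row = d$row, Column = d$col,
                  ID = sprintf("%s|%s|%d", d$probe_id, d$pair_role,
                               d$replicate_index),
                  Name = d$probe_id,
                  `F635 Median` = round(d$F635, 2),
                  `B635 Median` = round(d$B635, 2),
                  `F532 Median` = round(d$F532, 2),
                  `B532 Median` = round(d$B532, 2))
    p <- file.path(dir, paste0(a, ".gpr.tsv"))
    readr::write_tsv(out, p)
    p
  })
  sheet_path <- file.path(dir, "experiment_sheet.tsv")
  readr::write_tsv(sim$sheet, sheet_path)
  list(scans = unlist(paths), sheet = sheet_path)
}

#' Read GPR-like scan files and an experiment sheet
#'
#' Inverse of [write_scans()]: loads all `*.gpr.tsv` files of a directory (or
#' an explicit vector of paths) into the long scan tibble used by the
#' analysis pipeline.
#'
#' @param paths directory or character vector of scan files.
#' @param sheet_path experiment sheet TSV.
#' @return list with `scans` and `sheet` as in [simulate_experiment()].
#' @export
read_scans <- function(paths, sheet_path = NULL) {
  if (length(paths) == 1L && dir.exists(paths)) {
    if (is.null(sheet_path)) {
      sheet_path <- file.path(paths, "experiment_sheet.tsv")
    }
    paths <- list.files(paths, pattern = "\\.gpr\\.tsv$", full.names = TRUE)
  }
  if (length(paths) == 0) abort("no scan files found")
  scans <- purrr::map_dfr(paths, function(p) {
    if (!file.exists(p)) abort(sprintf("scan file not found: %s", p))
    d <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    parts <- stringr::str_split_fixed(d$ID, stringr::fixed("|"), 3)
    tibble(array_id = sub("\\.gpr\\.tsv$", "", basename(p)),
           block = as.integer(d$Block), row = as.integer(d$Row),
           col = as.integer(d$Column), probe_id = parts[, 1],
           replicate_index = as.integer(parts[, 3]), pair_role = parts[, 2],
           F635 = d$`F635 Median`, B635 = d$`B635 Median`,
           F532 = d$`F532 Median`, B532 = d$`B532 Median`)
  })
  sheet <- if (!is.null(sheet_path)) {
    if (!file.exists(sheet_path)) {
      abort(sprintf("experiment sheet not found: %s", sheet_path))
    }
    readr::read_tsv(sheet_path, show_col_types = FALSE, progress = FALSE)
  }
  list(scans = scans, sheet = sheet)
}
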