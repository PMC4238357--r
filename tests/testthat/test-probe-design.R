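`%+%` <- function(a, b) paste0(a, b)

# independent brute-force maximizer over all candidate oligos of a region
brute_force_pm <- function(region_seq, region_len, params, weights, background,
                           exclude) {
  best <- NULL
  for (len in params$oligo_len_min:min(params$oligo_len_max, region_len)) {
    for (off in 0:(region_len - len)) {
      sub <- substr(region_seq, off + 1, off + len)
      sc <- oligo_sub_scores(sub, off, region_len, params, background,
                             exclude = exclude)
      total <- sum(unlist(sc[c("crosshyb", "delta_tm", "folding", "position",
                               "complexity")]) *
                     as.numeric(weights)) / sum(as.numeric(weights))
      cand <- list(off = off, len = len, score = total)
      if (is.null(best) ||
            cand$score > best$score + 1e-12 ||
            (abs(cand$score - best$score) <= 1e-12 &&
               (abs(len - params$oligo_len_pref) < abs(best$len - params$oligo_len_pref) ||
                  (abs(len - params$oligo_len_pref) == abs(best$len - params$oligo_len_pref) &&
                     off < best$off)))) {
        best <- cand
      }
    }
  }
  best
}

test_that("sub-scores follow their definitions at the boundary cases", {
  # centered oligo: position exactly 1
  sc <- oligo_sub_scores("ACGUACGUACGUACGUACGUACGUAC", 2, 30)
  expect_equal(sc$position, 1)
  # homopolymer: zero dinucleotide entropy
  sc2 <- oligo_sub_scores(strrep("A", 25), 0, 30)
  expect_equal(sc2$complexity, 0)
  # oligo fully contained in a background transcript: crosshyb 0
  bg <- background_index(c(other = paste0("TTTT", strrep("ACGG", 7), "TT")))
  target <- strrep("ACGG", 6)  # 24-mer inside the background sequence
  sc3 <- oligo_sub_scores(target, 0, 30, background = bg, exclude = "self")
  expect_equal(sc3$crosshyb, 0)
  # own contig never counts as an off-target
  sc4 <- oligo_sub_scores(target, 0, 30,
                          background = background_index(c(self = target)),
                          exclude = "self")
  expect_equal(sc4$crosshyb, 1)
  # matches below the 12-mer seed are not reported
  bg5 <- background_index(c(o = strrep("ACGG", 2)))
  sc5 <- oligo_sub_scores(target, 0, 30, background = bg5, exclude = "self")
  expect_equal(sc5$crosshyb, 1)
  expect_true(all(unlist(sc[c("crosshyb", "delta_tm", "folding", "position",
                              "complexity")]) >= 0))
})

test_that("combined score is monotone in every sub-score", {
  weights <- design_weights()
  withr::with_seed(7, {
    for (i in 1:25) {
      s <- as.list(stats::runif(5))
      names(s) <- c("crosshyb", "delta_tm", "folding", "position",
                    "complexity")
      base <- ncarray:::combine_scores(s, weights)
      for (nm in names(s)) {
        s2 <- s
        s2[[nm]] <- min(1, s2[[nm]] + 0.1)
        expect_gte(ncarray:::combine_scores(s2, weights), base)
      }
    }
  })
  # paper weights sum to 0.900 exactly; renormalized combination sums to 1
  expect_equal(sum(as.numeric(weights)), 0.9)
  ones <- as.list(rep(1, 5))
  names(ones) <- names(weights)
  expect_equal(ncarray:::combine_scores(ones, weights), 1)
})

test_that("design_pm prefers the intended 25-mer under score ties and exact position weighting", {
  contig <- make_contig(rep(1, 30), sequence = strrep("ACGT", 8) %+% "AC")
  region <- tibble::tibble(contig_id = "c1", offset = 0L, length = 30L,
                           kind = "signal", mean_coverage = 1,
                           coverage_ratio = 1)
  # all weights zero: every candidate scores 0, tie-break picks a 25-mer
  none <- design_weights(0, 0, 0, 0, 0)
  pm <- design_pm(region, contig, weights = none)
  expect_equal(pm$target_length, 25L)
  expect_equal(pm$target_offset, 0L)  # leftmost among equally scored 25-mers
  # position-only weighting: the chosen oligo is exactly centered
  pos_only <- design_weights(0, 0, 0, 0.113, 0)
  pm2 <- design_pm(region, contig, weights = pos_only)
  expect_equal(pm2$position, 1)
  expect_equal(pm2$target_offset + pm2$target_length / 2, 15)
  expect_error(design_pm(dplyr::mutate(region, length = 17L), contig),
               "minimum oligo length")
})

test_that("design_pm equals the brute-force maximizer and avoids planted off-targets", {
  params <- design_params()
  weights <- design_weights()
  withr::with_seed(11, {
    for (i in 1:5) {
      seq40 <- ncarray:::random_dna(1, 40)
      bg <- background_index(c(offt = substr(seq40, 1, 20)))
      contig <- make_contig(rep(1, 40), sequence = seq40)
      region <- tibble::tibble(contig_id = "c1", offset = 0L, length = 40L,
                               kind = "signal", mean_coverage = 1,
                               coverage_ratio = 1)
      pm <- design_pm(region, contig, params, weights, bg)
      oracle <- brute_force_pm(seq40, 40L, params, weights, bg, "c1")
      expect_equal(pm$target_offset, oracle$off)
      expect_equal(pm$target_length, oracle$len)
      expect_equal(pm$combined_score, oracle$score, tolerance = 1e-12)
      # the planted off-target covers bases 1-20; a full match there would
      # zero the crosshyb score, so the winner must keep its overlap short
      expect_gt(pm$crosshyb, 0)
    }
  })
})

test_that("MM probes differ at position 13 only and never form a wobble with the target", {
  params <- design_params()
  bases_rna <- c("A", "C", "G", "U")
  for (pm_base in c("A", "C", "G", "T")) {
    for (opp in bases_rna) {
      pm <- paste0(strrep("A", 12), pm_base, strrep("A", 12))
      target <- paste0(strrep("U", 12), chartr("ACGU", "UGCA", opp),
                       strrep("U", 12))
      # place the opposing base at target position n - 13 + 1 = 13 (n = 25)
      substr(target, 13, 13) <- opp
      mm <- design_mm(pm, target, params)
      diff <- which(strsplit(pm, "")[[1]] != strsplit(mm, "")[[1]])
      expect_equal(diff, 13L)
      sub <- substr(mm, 13, 13)
      expect_false(sub == c(A = "T", C = "G", G = "C", U = "A")[[opp]])
      if (opp == "U") expect_false(sub == "G")
      if (opp == "G") expect_false(sub == "T")
    }
  }
})

test_that("MM substitution follows the fixed priority order on the worked cases", {
  # PM base A opposite U: G excluded (wobble), A excluded (re-pair);
  # transversion partner C is allowed and chosen
  pm <- paste0(strrep("C", 12), "A", strrep("C", 12))
  target_u <- paste0(strrep("G", 12), "U", strrep("G", 12))
  expect_equal(substr(design_mm(pm, target_u), 13, 13), "C")
  # PM base C opposite G: C re-pairs, T forms T.G wobble; priority picks A
  pm_c <- paste0(strrep("A", 12), "C", strrep("A", 12))
  target_g <- paste0(strrep("U", 12), "G", strrep("U", 12))
  expect_equal(substr(design_mm(pm_c, target_g), 13, 13), "A")
  expect_error(design_mm("ACGT", strrep("U", 4)), "shorter")
})

test_that("design_probes attaches MM partners to signal probes only", {
  contigs <- dplyr::bind_rows(
    make_contig(c(rep(30, 30), rep(5, 30)), id = "c1"),
    make_contig(rep(3, 25), id = "c2"))
  regions <- select_regions(contigs)
  probes <- design_probes(regions, contigs)
  expect_equal(nrow(probes), nrow(regions))
  sig <- probes[probes$role == "signal", ]
  ctrl <- probes[probes$role == "control_region", ]
  expect_true(all(!is.na(sig$mm_sequence)))
  expect_true(all(is.na(ctrl$mm_sequence)))
  for (i in seq_len(nrow(sig))) {
    d <- which(strsplit(sig$pm_sequence[i], "")[[1]] !=
                 strsplit(sig$mm_sequence[i], "")[[1]])
    expect_equal(d, 13L)
  }
  expect_true(all(nchar(probes$pm_sequence) >= 18 &
                    nchar(probes$pm_sequence) <= 30))
})

test_that("spike-in and snRNA controls: counts, constraints, determinism", {
  ctrl <- make_spike_and_snrna_controls(seed = 3)
  expect_equal(nrow(ctrl), 48L)
  expect_equal(sum(ctrl$role == "spike_in"), 8L)
  expect_equal(sum(ctrl$role == "snRNA_control"), 40L)
  expect_true(all(is.na(ctrl$mm_sequence)))
  spikes <- ctrl$pm_sequence[ctrl$role == "spike_in"]
  gc <- vapply(spikes, ncarray:::gc_fraction, numeric(1))
  expect_true(all(gc >= 0.4 & gc <= 0.6))
  expect_true(all(vapply(spikes, ncarray:::max_self_stem, integer(1)) < 6))
  expect_identical(make_spike_and_snrna_controls(seed = 3), ctrl)
  ctrl2 <- make_spike_and_snrna_controls(seed = 4)
  expect_false(identical(ctrl2$pm_sequence[1:8], spikes))
  expect_error(make_spike_and_snrna_controls(seed = 1, u6 = strrep("A", 40)),
               "too short to tile")
})

test_that("probe FASTA writer emits PM and MM records with the ID convention", {
  probes <- tibble::tibble(probe_id = c("x_0_signal", "y_0_control"),
                           pm_sequence = c(strrep("A", 20), strrep("C", 20)),
                           mm_sequence = c(strrep("G", 20), NA))
  path <- withr::local_tempfile()
  write_probe_fasta(probes, path)
  lines <- readLines(path)
  expect_equal(lines[c(1, 3, 5)],
               c(">x_0_signal_PM", ">x_0_signal_MM", ">y_0_control_PM"))
  expect_length(lines, 6L)
})
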