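# shared fixtures and independent oracles

make_contig <- function(coverage, id = "c1", sequence = NULL, strand = "+",
                        read_count = 10L, biotype = "unknown") {
  len <- length(coverage)
  if (is.null(sequence)) {
    sequence <- paste(rep(c("A", "C", "G", "T"), length.out = len),
                      collapse = "")
  }
  tibble::tibble(contig_id = id, chrom = "chr1", start = 0L, end = len,
                 strand = strand, sequence = sequence,
                 coverage = list(as.integer(coverage)),
                 read_count = as.integer(read_count), biotype = biotype)
}

# exhaustive enumerator of the written region-selection rules, independent of
# the package's implementation
oracle_signal_regions <- function(cov, cutoff = 70L, interval = 30L) {
  L <- length(cov)
  if (L < cutoff) {
    w <- min(25L, L)
    best_off <- NA_integer_
    best_mean <- -Inf
    for (o in 0:(L - w)) {
      m <- mean(cov[(o + 1):(o + w)])
      if (m > best_mean) {
        best_mean <- m
        best_off <- o
      }
    }
    return(data.frame(offset = best_off, length = w))
  }
  offs <- seq.int(0L, L - 1L, by = interval)
  lens <- pmin(interval, L - offs)
  keep <- lens >= 18L
  offs <- offs[keep]
  lens <- lens[keep]
  means <- mapply(function(o, w) mean(cov[(o + 1):(o + w)]), offs, lens)
  elevated <- means > mean(cov)
  if (any(elevated)) {
    data.frame(offset = offs[elevated], length = lens[elevated])
  } else {
    i <- which.max(means)
    data.frame(offset = offs[i], length = lens[i])
  }
}

oracle_control_region <- function(cov, signal, interval = 30L,
                                  ratio = 1 / 3) {
  L <- length(cov)
  if (L < interval) return(NULL)
  offs <- seq.int(0L, L - 1L, by = interval)
  lens <- pmin(interval, L - offs)
  keep <- lens >= 18L
  offs <- offs[keep]
  lens <- lens[keep]
  means <- mapply(function(o, w) mean(cov[(o + 1):(o + w)]), offs, lens)
  ok <- rep(TRUE, length(offs))
  for (i in seq_along(offs)) {
    if (!(means[i] < ratio * max(cov))) ok[i] <- FALSE
    if (any(offs[i] < signal$offset + signal$length &
              signal$offset < offs[i] + lens[i])) ok[i] <- FALSE
  }
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.min(means[ok])]
  data.frame(offset = offs[i], length = lens[i])
}

# noise-free truth for closed-form checks
noise_free_truth <- function(ids, fraction_de = 0.1, effect_size = 1,
                             seed = 1L, background = 100) {
  truth_model(ids, fraction_de = fraction_de, effect_size = effect_size,
              sigma_bio = 0, sigma_dye = 0, sigma_eps = 0, kappa = 0, nu = 0,
              tip_coef_sd = c(0, 0, 0), background = background, seed = seed)
}

# small layouts used across tests
small_design <- function(n_pairs = 10L, n_single = 48L, seed = 1L) {
  probes <- tibble::tibble(
    probe_id = c(sprintf("p%03d", seq_len(n_pairs)),
                 sprintf("s%03d", seq_len(n_single))),
    mm_sequence = c(rep("x", n_pairs), rep(NA_character_, n_single)))
  layout_array(probes, n_blocks = 8L, block_rows = 20L, block_cols = 20L,
               seed = seed)
}
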