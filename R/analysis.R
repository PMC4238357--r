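#' Net spot intensities
#'
#' Net intensity = foreground minus local background, per channel. Values at
#' or below zero are floored to a small epsilon (default 0.5) so subsequent
#' log2 transforms stay finite.
#'
#' @param scans long scan tibble ([simulate_experiment()] / [read_scans()]).
#' @param epsilon floor applied to non-positive net values (default 0.5).
#' @return the scans with `net635` and `net532` columns added.
#' @export
net_intensity <- function(scans, epsilon = 0.5) {
  dplyr::mutate(scans,
                net635 = ifelse(.data$F635 - .data$B635 <= 0, epsilon,
                                .data$F635 - .data$B635),
                net532 = ifelse(.data$F532 - .data$B532 <= 0, epsilon,
                                .data$F532 - .data$B532))
}

#' Per-spot M and A values
#'
#' M is the log2 ratio between the two conditions with a fixed orientation
#' (positive = higher in the case condition, resolved per array from the
#' experiment sheet), A the mean log2 net intensity of the two channels.
#'
#' @param scans scan tibble with net intensities ([net_intensity()]).
#' @param sheet experiment sheet; its first `channel_635` value defines the
#'   case condition unless `case` is given.
#' @param case name of the case condition.
#' @return tibble: spot columns plus `M`, `A`.
#' @export
compute_ma <- function(scans, sheet, case = NULL) {
  if (is.null(case)) case <- sheet$channel_635[1]
  if (any(sheet$channel_635 == sheet$channel_532)) {
    abort("experiment sheet assigns the same condition to both channels")
  }
  orient <- ifelse(sheet$channel_635 == case, 1, -1)
  names(orient) <- sheet$array_id
  dplyr::mutate(scans,
                M = unname(orient[.data$array_id]) *
                  (log2(.data$net635) - log2(.data$net532)),
                A = (log2(.data$net635) + log2(.data$net532)) / 2)
}

#' Within-array print-tip local-regression normalization
#'
#' Per array and print-tip group (block), fits a robust local linear
#' regression of M on A and replaces M by its residuals; A is unchanged.
#' Blocks with fewer than `min_spots` spots fall back to a whole-array fit
#' (reported via a message).
#'
#' @param ma tibble from [compute_ma()].
#' @param span loess span (default 0.4).
#' @param iterations robustness iterations of the lowess fit (default 4).
#' @param min_spots minimum spots per block for a block-level fit
#'   (default 20).
#' @return `ma` with normalized M.
#' @export
normalize_within <- function(ma, span = 0.4, iterations = 4L,
                             min_spots = 20L) {
  fallback <- FALSE
  out <- ma |>
    dplyr::group_by(.data$array_id) |>
    dplyr::group_modify(function(d, key) {
      small <- table(d$block)
      if (any(small < min_spots)) {
        fallback <<- TRUE
        fit <- limma::loessFit(d$M, d$A, span = span,
                               iterations = iterations)
        d$M <- d$M - fit$fitted
      } else {
        d <- d |>
          dplyr::group_by(.data$block) |>
          dplyr::group_modify(function(b, k) {
            fit <- limma::loessFit(b$M, b$A, span = span,
                                   iterations = iterations)
            b$M <- b$M - fit$fitted
            b
          }) |>
          dplyr::ungroup()
      }
      d
    }) |>
    dplyr::ungroup()
  if (fallback) {
    inform("print-tip group(s) below the spot minimum; used whole-array loess fit")
  }
  out
}

#' Between-array quantile normalization
#'
#' Quantile-normalizes the A values across arrays so that the sorted A
#' vector is identical on every array; M values are preserved (see the
#' methods vignette for the rationale and the full-channel alternative).
#'
#' @param ma tibble from [normalize_within()] (all arrays).
#' @param target `"A"` (default) quantile-normalizes A keeping M;
#'   `"channels"` quantile-normalizes the per-channel log2 net intensities
#'   and recomputes both M and A.
#' @return `ma` with normalized values.
#' @export
normalize_between <- function(ma, target = c("A", "channels")) {
  target <- match.arg(target)
  arrays <- unique(ma$array_id)
  if (length(arrays) < 2L) abort("need at least 2 arrays")
  counts <- table(ma$array_id)
  if (length(unique(counts)) != 1L) {
    abort("arrays have differing spot counts; cannot quantile normalize")
  }
  ma <- dplyr::arrange(ma, .data$array_id, .data$block, .data$row, .data$col)
  if (target == "A") {
    amat <- matrix(ma$A, ncol = length(arrays))
    ma$A <- as.vector(limma::normalizeQuantiles(amat, ties = TRUE))
  } else {
    hi <- ma$A + ma$M / 2
    lo <- ma$A - ma$M / 2
    qm <- limma::normalizeQuantiles(cbind(matrix(hi, ncol = length(arrays)),
                                          matrix(lo, ncol = length(arrays))),
                                    ties = TRUE)
    nh <- matrix(qm[, seq_along(arrays)], ncol = length(arrays))
    nl <- matrix(qm[, length(arrays) + seq_along(arrays)],
                 ncol = length(arrays))
    ma$M <- as.vector(nh - nl)
    ma$A <- as.vector((nh + nl) / 2)
  }
  ma
}

#' PM-over-MM detection filter
#'
#' A candidate is retained when its mean perfect-match net intensity exceeds
#' its mean mismatch net intensity under at least one experimental condition
#' (strict inequality). Condition-level means pool all spots, arrays and
#' channels assigned to the condition. Candidates without an MM partner
#' (control-region, spike-in, snRNA probes) are kept automatically and
#' flagged.
#'
#' @param scans scan tibble with net intensities ([net_intensity()]).
#' @param sheet experiment sheet.
#' @return tibble: `candidate_id`, `has_mm`, `passed_pm_mm_filter`, the four
#'   condition-level means.
#' @export
pm_mm_filter <- function(scans, sheet) {
  cond_of <- function(array_id, channel) {
    key <- sheet$array_id
    ifelse(channel == "635", sheet$channel_635[match(array_id, key)],
           sheet$channel_532[match(array_id, key)])
  }
  long <- dplyr::bind_rows(
    dplyr::transmute(scans, candidate_id = .data$probe_id,
                     role = .data$pair_role,
                     condition = cond_of(.data$array_id, "635"),
                     net = .data$net635),
    dplyr::transmute(scans, candidate_id = .data$probe_id,
                     role = .data$pair_role,
                     condition = cond_of(.data$array_id, "532"),
                     net = .data$net532))
  means <- long |>
    dplyr::filter(.data$role %in% c("PM", "MM")) |>
    dplyr::group_by(.data$candidate_id, .data$condition, .data$role) |>
    dplyr::summarise(net = mean(.data$net), .groups = "drop") |>
    tidyr::pivot_wider(names_from = c("role", "condition"),
                       values_from = "net")
  conditions <- unique(c(sheet$channel_635, sheet$channel_532))
  passed <- rep(FALSE, nrow(means))
  for (cc in conditions) {
    pm <- means[[paste0("PM_", cc)]]
    mm <- means[[paste0("MM_", cc)]]
    passed <- passed | (!is.na(pm) & !is.na(mm) & pm > mm)
  }
  paired <- dplyr::mutate(means, passed_pm_mm_filter = passed, has_mm = TRUE)
  singles <- tibble(candidate_id = setdiff(unique(scans$probe_id),
                                           paired$candidate_id),
                    has_mm = FALSE, passed_pm_mm_filter = TRUE)
  dplyr::bind_rows(paired, singles)
}

#' Dye-swap linear model with replicate spots
#'
#' Fits the simple dye-swap model per candidate: oriented M values (positive
#' = higher in the case condition) are first combined over a candidate's
#' replicate PM spots within each array, then the per-array values are
#' averaged across arrays to give the log2 fold-change estimate; the
#' residual variance and degrees of freedom come from the between-array
#' scatter (`d_g = n_arrays - 1`).
#'
#' Replicate-spot combination: `"average"` (default) is the plain
#' within-array mean; `"gls"` estimates a common intra-array spot
#' correlation by a compound-symmetry variance decomposition and weights
#' arrays by the implied precision `m / (1 + (m - 1) rho)` of their spot
#' means (identical to "average" when every array carries the same number of
#' spots).
#'
#' @param ma normalized, oriented M/A tibble (all arrays).
#' @param sheet experiment sheet (>= 2 arrays, orientable).
#' @param dup_method "average" or "gls".
#' @return object of class `dyeswap_fit`: `$coefficients` tibble
#'   (`candidate_id`, `log2fc`, `s2`, `df`, `n_spots_used`, `v`), `$n_arrays`,
#'   `$dup_method`, `$rho` (gls only).
#' @export
fit_dyeswap <- function(ma, sheet, dup_method = c("average", "gls")) {
  dup_method <- match.arg(dup_method)
  if (length(unique(ma$array_id)) < 2L) abort("need at least 2 arrays")
  if (any(sheet$channel_635 == sheet$channel_532)) {
    abort("experiment sheet assigns the same condition to both channels")
  }
  use <- dplyr::filter(ma, .data$pair_role %in% c("PM", "single"))
  per_array <- use |>
    dplyr::group_by(candidate_id = .data$probe_id, .data$array_id) |>
    dplyr::summarise(m = mean(.data$M), n_spots = dplyr::n(),
                     .groups = "drop")
  rho <- NULL
  if (dup_method == "gls") {
    rho <- estimate_spot_correlation(use)
    per_array <- dplyr::mutate(per_array,
                               w = .data$n_spots / (1 + (.data$n_spots - 1) * rho))
  } else {
    per_array <- dplyr::mutate(per_array, w = 1)
  }
  coefs <- per_array |>
    dplyr::group_by(.data$candidate_id) |>
    dplyr::summarise(
      log2fc = sum(.data$w * .data$m) / sum(.data$w),
      df = dplyr::n() - 1L,
      s2 = if (dplyr::n() > 1L) {
        sum(.data$w * (.data$m - sum(.data$w * .data$m) / sum(.data$w))^2) /
          (dplyr::n() - 1L)
      } else NA_real_,
      v = 1 / sum(.data$w),
      n_spots_used = sum(.data$n_spots),
      .groups = "drop")
  structure(list(coefficients = coefs,
                 n_arrays = length(unique(ma$array_id)),
                 dup_method = dup_method, rho = rho),
            class = "dyeswap_fit")
}

# compound-symmetry estimate of the common intra-array replicate-spot
# correlation, pooled over candidates with >= 2 spots per array
estimate_spot_correlation <- function(use) {
  comps <- use |>
    dplyr::group_by(.data$probe_id, .data$array_id) |>
    dplyr::summarise(m = mean(.data$M), n = dplyr::n(),
                     wss = sum((.data$M - mean(.data$M))^2),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= 2L)
  if (nrow(comps) == 0) return(0)
  msw <- sum(comps$wss) / sum(comps$n - 1L)
  between <- use |>
    dplyr::group_by(.data$probe_id, .data$array_id) |>
    dplyr::summarise(m = mean(.data$M), n = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::summarise(msb = stats::var(.data$m) * mean(.data$n),
                     .groups = "drop")
  msb <- mean(between$msb)
  m_bar <- mean(comps$n)
  rho <- (msb - msw) / (msb + (m_bar - 1) * msw)
  min(0.99, max(0, rho))
}

#' Empirical-Bayes variance moderation and moderated t-statistics
#'
#' Shrinks the per-candidate residual variances toward a common prior by
#' fitting a scaled inverse-chi-square prior with `d0` prior degrees of
#' freedom and prior value `s0^2`, estimated by moment matching on the log
#' variances (digamma/trigamma equations). The posterior variance
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` replaces `s_g^2` in the
#' t-statistic, which is referred to a t distribution on `d0 + d_g` degrees
#' of freedom; when the moment equation implies infinite `d0` every variance
#' collapses to `s0^2` and the statistic is referred to the normal
#' distribution.
#'
#' @param fit `dyeswap_fit` from [fit_dyeswap()].
#' @param d0,s0_sq optional overrides of the estimated prior (e.g. `d0 = 0`
#'   reproduces the ordinary t-test, `d0 = Inf` the z-test against `s0^2`).
#' @return the fit with `$coefficients` gaining `s2_post`, `t`, `df_total`,
#'   `p`, and elements `$d0`, `$s0_sq`.
#' @export
moderate_ebayes <- function(fit, d0 = NULL, s0_sq = NULL) {
  co <- fit$coefficients
  usable <- !is.na(co$s2) & co$df > 0
  if (sum(usable) < 10L) {
    abort("fewer than 10 candidates with positive residual df; use an exact t-test instead")
  }
  if (is.null(d0) || is.null(s0_sq)) {
    est <- fit_scaled_invchisq(co$s2[usable], co$df[usable])
    if (is.null(d0)) d0 <- est$d0
    if (is.null(s0_sq)) s0_sq <- est$s0_sq
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, nrow(co))
  } else if (d0 == 0) {
    co$s2
  } else {
    (d0 * s0_sq + co$df * co$s2) / (d0 + co$df)
  }
  tstat <- co$log2fc / sqrt(s2_post * co$v)
  df_total <- d0 + co$df
  p <- if (is.infinite(d0)) {
    2 * stats::pnorm(-abs(tstat))
  } else {
    2 * stats::pt(-abs(tstat), df_total)
  }
  fit$coefficients <- dplyr::mutate(co, s2_post = s2_post, t = tstat,
                                    df_total = df_total, p = p)
  fit$d0 <- d0
  fit$s0_sq <- s0_sq
  fit
}

# moment-matching fit of the scaled inverse-chi-square prior on observed
# sample variances s2 with df degrees of freedom, on the log scale:
#   E log s2 = log s0^2 + psi(df/2) - log(df/2) - (psi(d0/2) - log(d0/2))
#   Var log s2 = psi'(df/2) + psi'(d0/2)
fit_scaled_invchisq <- function(s2, df) {
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  n <- length(e)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # degenerate moment equation (no excess scatter in log s2): infinite
    # prior df; the prior value is the plain mean of the sample variances
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(y) = x (x > 0), on the 1/y scale for stability
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjustment and DE calls
#'
#' Step-up false-discovery-rate adjustment; candidates with adjusted p below
#' the threshold are called differentially expressed.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @param threshold adjusted-p cutoff for a DE call (default 0.05).
#' @return tibble with `p`, `p_adj`, `de_call`.
#' @export
bh_adjust <- function(p, threshold = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p_adj <- stats::p.adjust(p, method = "BH")
  tibble(p = p, p_adj = p_adj, de_call = !is.na(p_adj) & p_adj < threshold)
}

#' Run the full differential-expression pipeline
#'
#' Net intensity, PM>MM filtering (on raw net intensities), M/A computation,
#' within-array print-tip loess normalization, between-array quantile
#' normalization, dye-swap linear model, empirical-Bayes moderation, BH
#' adjustment. Candidates failing the PM>MM filter are excluded from the
#' model fit and carry NA statistics in the result.
#'
#' @param scans raw scan tibble.
#' @param sheet experiment sheet.
#' @param epsilon net-intensity floor (default 0.5).
#' @param dup_method replicate-spot combination, see [fit_dyeswap()].
#' @param quantile_target see [normalize_between()].
#' @param de_threshold adjusted-p cutoff (default 0.05).
#' @param biotypes optional tibble `candidate_id`, `biotype` to annotate the
#'   result.
#' @return list of class `ncarray_analysis`: `de` (per-candidate result
#'   tibble), `fit` (`dyeswap_fit`), `ma` (normalized M/A values), `filter`
#'   (PM/MM filter table).
#' @export
analyze_experiment <- function(scans, sheet, epsilon = 0.5,
                               dup_method = "average",
                               quantile_target = "A", de_threshold = 0.05,
                               biotypes = NULL) {
  scans <- net_intensity(scans, epsilon)
  filt <- pm_mm_filter(scans, sheet)
  ma <- compute_ma(scans, sheet)
  ma <- normalize_within(ma)
  ma <- normalize_between(ma, target = quantile_target)
  keep <- filt$candidate_id[filt$passed_pm_mm_filter]
  fit <- fit_dyeswap(dplyr::filter(ma, .data$probe_id %in% keep), sheet,
                     dup_method = dup_method)
  fit <- moderate_ebayes(fit)
  adj <- bh_adjust(fit$coefficients$p, de_threshold)
  stats_tbl <- dplyr::mutate(fit$coefficients, p_adj = adj$p_adj,
                             de_call = adj$de_call)
  de <- dplyr::left_join(filt, stats_tbl, by = "candidate_id") |>
    dplyr::transmute(.data$candidate_id, .data$log2fc, t = .data$t,
                     .data$p, .data$p_adj,
                     de_call = !is.na(.data$de_call) & .data$de_call,
                     passed_pm_mm_filter = .data$passed_pm_mm_filter,
                     has_mm = .data$has_mm,
                     n_spots_used = .data$n_spots_used)
  if (!is.null(biotypes)) {
    de <- dplyr::left_join(de, biotypes, by = "candidate_id")
  }
  structure(list(de = de, fit = fit, ma = ma, filter = filt),
            class = "ncarray_analysis")
}
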