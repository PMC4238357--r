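# minimal synthetic M/A table builder: n spots per block per array
make_ma <- function(n_arrays = 2, n_blocks = 2, n_spots = 60, seed = 1,
                    m_fun = function(a, b, A) rep(0, length(A))) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_arrays), function(a) {
      purrr::map_dfr(seq_len(n_blocks), function(b) {
        A <- stats::runif(n_spots, 6, 14)
        tibble::tibble(array_id = sprintf("array_%02d", a), block = b,
                       row = seq_len(n_spots), col = 1L,
                       probe_id = sprintf("g%d_%d", b, seq_len(n_spots)),
                       replicate_index = 1L, pair_role = "PM",
                       M = m_fun(a, b, A), A = A)
      })
    })
  })
}

test_that("net intensity subtracts local background and floors at epsilon", {
  scans <- tibble::tibble(F635 = c(1000, 100, 200), B635 = c(200, 150, 200),
                          F532 = c(500, 500, 300), B532 = c(100, 100, 300))
  out <- net_intensity(scans)
  expect_equal(out$net635, c(800, 0.5, 0.5))
  expect_equal(out$net532, c(400, 400, 0.5))
  # all-background spot gives M = 0 after the floor
  ma_row <- log2(out$net635[3]) - log2(out$net532[3])
  expect_equal(ma_row, 0)
})

test_that("print-tip loess residualizes exact linear block trends to zero", {
  ma <- make_ma(n_arrays = 2, n_blocks = 3,
                m_fun = function(a, b, A) (0.3 * b) + (0.1 * b) * A)
  out <- normalize_within(ma)
  expect_lt(max(abs(out$M)), 1e-8)
  expect_equal(sort(out$A), sort(ma$A))  # A untouched
})

test_that("block-constant dye offsets of opposite sign are removed independently", {
  ma <- make_ma(n_blocks = 2,
                m_fun = function(a, b, A) if (b == 1) rep(0.8, length(A)) else rep(-0.8, length(A)))
  out <- normalize_within(ma)
  meds <- out |>
    dplyr::group_by(.data$array_id, .data$block) |>
    dplyr::summarise(med = stats::median(.data$M), .groups = "drop")
  expect_true(all(abs(meds$med) < 1e-8))
})

test_that("small print-tip groups fall back to a whole-array fit with a message", {
  ma <- make_ma(n_blocks = 2, n_spots = 10)
  expect_message(normalize_within(ma), "whole-array")
})

test_that("quantile normalization equalizes sorted A vectors and is idempotent", {
  ma <- make_ma(n_arrays = 3, seed = 5,
                m_fun = function(a, b, A) stats::rnorm(length(A), 0, 0.1))
  ma$A <- ma$A + rep(c(0, 1.5, -0.7), each = nrow(ma) / 3)
  out <- normalize_between(ma)
  mats <- split(out$A, out$array_id)
  expect_equal(sort(mats[[1]]), sort(mats[[2]]))
  expect_equal(sort(mats[[1]]), sort(mats[[3]]))
  # reference distribution = mean of the sorted per-array vectors
  ref <- rowMeans(vapply(split(ma$A, ma$array_id), sort,
                         numeric(nrow(ma) / 3)))
  expect_equal(sort(mats[[1]]), ref)
  # M untouched, idempotent
  expect_equal(sort(out$M), sort(ma$M))
  again <- normalize_between(out)
  expect_equal(dplyr::arrange(again, .data$array_id, .data$block, .data$row),
               dplyr::arrange(out, .data$array_id, .data$block, .data$row))
  # identical multisets in different order are unchanged
  ma2 <- make_ma(n_arrays = 2, seed = 6)
  ma2$A[ma2$array_id == "array_02"] <- rev(ma2$A[ma2$array_id == "array_01"])
  out2 <- normalize_between(ma2)
  expect_equal(sort(out2$A), sort(ma2$A))
  expect_error(normalize_between(ma[-1, ]), "differing spot counts")
  expect_error(normalize_between(ma[ma$array_id == "array_01", ]),
               "at least 2")
})

test_that("PM>MM filter keeps strong signal, drops exact ties, flags MM-less candidates", {
  sheet <- tibble::tibble(array_id = c("a1", "a2"),
                          channel_635 = c("case", "control"),
                          channel_532 = c("control", "case"),
                          pair_id = 1L, biological_replicate = 1L)
  mk <- function(id, role, f6, f5) {
    tibble::tibble(array_id = rep(c("a1", "a2"), each = 1),
                   block = 1L, row = 1L, col = 1L, probe_id = id,
                   replicate_index = 1L, pair_role = role,
                   F635 = f6, B635 = 0, F532 = f5, B532 = 0)
  }
  scans <- dplyr::bind_rows(
    mk("strong", "PM", 1000, 900), mk("strong", "MM", 100, 90),
    mk("tie", "PM", 500, 500), mk("tie", "MM", 500, 500),
    mk("nomm", "single", 300, 300))
  out <- pm_mm_filter(net_intensity(scans), sheet)
  expect_true(out$passed_pm_mm_filter[out$candidate_id == "strong"])
  expect_false(out$passed_pm_mm_filter[out$candidate_id == "tie"])
  nomm <- out[out$candidate_id == "nomm", ]
  expect_true(nomm$passed_pm_mm_filter)
  expect_false(nomm$has_mm)
})

test_that("expressed candidates all pass the filter without MM cross-hybridization", {
  design <- small_design(n_pairs = 50, n_single = 0)
  ids <- unique(design$probe_id[design$pair_role == "PM"])
  truth <- truth_model(ids, kappa = 0, seed = 8)
  sim <- simulate_experiment(design, truth)
  out <- pm_mm_filter(net_intensity(sim$scans), sim$sheet)
  expect_true(all(out$passed_pm_mm_filter))
})

test_that("null probes with symmetric PM/MM noise pass at roughly 75%", {
  # in the symmetric limit (MM cross-hybridization equal to the specific
  # signal) each condition-level PM vs MM comparison is a fair coin and the
  # two conditions are independent, so pass = 1 - 0.5^2
  sheet <- tibble::tibble(array_id = c("a1", "a2"),
                          channel_635 = c("case", "control"),
                          channel_532 = c("control", "case"),
                          pair_id = 1L, biological_replicate = 1L)
  withr::with_seed(13, {
    n <- 4000L
    mk <- function(role) {
      purrr::map_dfr(c("a1", "a2"), function(a) {
        tibble::tibble(array_id = a, block = 1L, row = seq_len(n),
                       col = if (role == "PM") 1L else 2L,
                       probe_id = sprintf("g%04d", seq_len(n)),
                       replicate_index = 1L, pair_role = role,
                       F635 = 1000 * exp(stats::rnorm(n, 0, 0.2)) + 100,
                       B635 = 100,
                       F532 = 1000 * exp(stats::rnorm(n, 0, 0.2)) + 100,
                       B532 = 100)
      })
    }
    out <- pm_mm_filter(net_intensity(dplyr::bind_rows(mk("PM"), mk("MM"))),
                        sheet)
    rate <- mean(out$passed_pm_mm_filter)
    expect_gte(rate, 0.70)
    expect_lte(rate, 0.80)
  })
})

test_that("dye-swap fit recovers noise-free effects exactly with correct df bookkeeping", {
  design <- small_design(n_pairs = 30, n_single = 0)
  ids <- unique(design$probe_id[design$pair_role == "PM"])
  truth <- noise_free_truth(ids, fraction_de = 0.2, seed = 4)
  sim <- simulate_experiment(design, truth, n_pairs = 3)
  ma <- compute_ma(net_intensity(sim$scans), sim$sheet)
  fit <- fit_dyeswap(ma, sim$sheet)
  co <- dplyr::inner_join(fit$coefficients, truth$candidates,
                          by = "candidate_id")
  expect_equal(co$log2fc, co$beta, tolerance = 1e-9)
  expect_true(all(co$df == 5L))       # 2 x 3 arrays - 1
  expect_true(all(co$n_spots_used == 6L * 8L))
  # swapping the dye labels on every array leaves the estimates unchanged
  swapped_scans <- dplyr::rename(sim$scans, F635 = "F532", B635 = "B532",
                                 F532 = "F635", B532 = "B635")
  swapped_sheet <- dplyr::rename(sim$sheet, channel_635 = "channel_532",
                                 channel_532 = "channel_635")
  ma2 <- compute_ma(net_intensity(swapped_scans), swapped_sheet,
                    case = "case")
  fit2 <- fit_dyeswap(ma2, swapped_sheet)
  expect_equal(fit2$coefficients$log2fc, fit$coefficients$log2fc,
               tolerance = 1e-12)
  # unorientable sheet
  bad <- dplyr::mutate(sim$sheet, channel_532 = .data$channel_635)
  expect_error(compute_ma(net_intensity(sim$scans), bad), "same condition")
  expect_error(fit_dyeswap(ma[ma$array_id == "array_01", ], sim$sheet),
               "at least 2")
})

test_that("gls replicate handling matches averaging for balanced spot counts", {
  design <- small_design(n_pairs = 15, n_single = 0)
  ids <- unique(design$probe_id[design$pair_role == "PM"])
  sim <- simulate_experiment(design, truth_model(ids, seed = 10))
  ma <- compute_ma(net_intensity(sim$scans), sim$sheet)
  f1 <- fit_dyeswap(ma, sim$sheet, dup_method = "average")
  f2 <- fit_dyeswap(ma, sim$sheet, dup_method = "gls")
  expect_equal(f2$coefficients$log2fc, f1$coefficients$log2fc,
               tolerance = 1e-12)
  expect_true(!is.null(f2$rho) && f2$rho >= 0 && f2$rho < 1)
})

test_that("variance moderation behaves correctly in its degenerate limits", {
  fit <- structure(list(coefficients = tibble::tibble(
    candidate_id = sprintf("g%02d", 1:20),
    log2fc = seq(-1, 1, length.out = 20),
    s2 = rep(0.04, 20), df = 5L, v = 1 / 6, n_spots_used = 48L),
    n_arrays = 6L, dup_method = "average"), class = "dyeswap_fit")
  # identical variances: the log-variance moment equation degenerates,
  # d0 = Inf, every posterior variance collapses to the (bias-corrected)
  # prior and the statistic is the z against s0 -- limma agrees exactly
  out <- moderate_ebayes(fit)
  expect_true(is.infinite(out$d0))
  sq <- limma::squeezeVar(fit$coefficients$s2, df = 5)
  expect_equal(sq$df.prior, Inf)
  expect_equal(out$s0_sq, sq$var.prior, tolerance = 1e-9)
  expect_equal(out$coefficients$s2_post, sq$var.post, tolerance = 1e-9)
  expect_equal(out$coefficients$t,
               fit$coefficients$log2fc / sqrt(out$s0_sq / 6),
               tolerance = 1e-9)
  expect_equal(out$coefficients$p,
               2 * stats::pnorm(-abs(out$coefficients$t)), tolerance = 1e-9)
  # d0 = 0 recovers the ordinary t-statistic
  fit$coefficients$s2 <- seq(0.01, 0.2, length.out = 20)
  ord <- moderate_ebayes(fit, d0 = 0, s0_sq = 1)
  expect_equal(ord$coefficients$t,
               fit$coefficients$log2fc / sqrt(fit$coefficients$s2 / 6))
  expect_equal(ord$coefficients$df_total, rep(5, 20))
  expect_error(moderate_ebayes(structure(list(coefficients =
    fit$coefficients[1:5, ], n_arrays = 6L), class = "dyeswap_fit")),
    "fewer than 10")
})

test_that("prior fit matches limma::squeezeVar on scaled chi-square variances", {
  withr::with_seed(31, {
    d0 <- 8; s0 <- 0.05; d <- 5; G <- 1500
    sigma2 <- s0 * d0 / stats::rchisq(G, d0)
    s2 <- sigma2 * stats::rchisq(G, d) / d
    sq <- limma::squeezeVar(s2, df = d)
    est <- ncarray:::fit_scaled_invchisq(s2, rep(d, G))
    expect_equal(est$d0, sq$df.prior, tolerance = 1e-8)
    expect_equal(est$s0_sq, sq$var.prior, tolerance = 1e-8)
    post <- (est$d0 * est$s0_sq + d * s2) / (est$d0 + d)
    expect_equal(post, sq$var.post, tolerance = 1e-8)
    # posterior lies between prior and observed variance
    expect_true(all(post >= pmin(est$s0_sq, s2) - 1e-12 &
                      post <= pmax(est$s0_sq, s2) + 1e-12))
  })
})

test_that("BH adjustment follows the step-up rule and preserves p-ordering", {
  out <- bh_adjust(c(0.01, 0.02, 0.03))
  expect_equal(out$p_adj, rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5))$p_adj, rep(1, 5))
  expect_equal(bh_adjust(0.021)$p_adj, 0.021)
  withr::with_seed(2, {
    p <- stats::runif(200)^2
    res <- bh_adjust(p)
    expect_true(all(res$p_adj >= res$p))
    expect_equal(order(res$p_adj[order(p)]), seq_len(200))
    expect_equal(res$p_adj, stats::p.adjust(p, "BH"))
  })
})

test_that("the full pipeline recovers noise-free effects and is dye-swap symmetric", {
  design <- small_design(n_pairs = 40, n_single = 8)
  ids <- unique(design$probe_id[design$pair_role == "PM"])
  truth <- noise_free_truth(ids, fraction_de = 0.1, seed = 15)
  sim <- simulate_experiment(design, truth)
  res <- analyze_experiment(sim$scans, sim$sheet)
  de <- dplyr::inner_join(res$de, truth$candidates, by = "candidate_id")
  expect_equal(de$log2fc, de$beta, tolerance = 1e-6)
  # permuting spot order changes nothing but ordering
  perm <- sim$scans[sample(nrow(sim$scans)), ]
  res2 <- analyze_experiment(perm, sim$sheet)
  expect_equal(dplyr::arrange(res2$de, .data$candidate_id),
               dplyr::arrange(res$de, .data$candidate_id))
})
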