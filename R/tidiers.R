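#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a dye-swap model fit
#'
#' One row per candidate with the estimate, moderated statistic (when
#' [moderate_ebayes()] has been applied) and p-values.
#'
#' @param x `dyeswap_fit`
#' @param ... unused
#' @return tibble
#' @method tidy dyeswap_fit
#' @export
tidy.dyeswap_fit <- function(x, ...) {
  co <- x$coefficients
  out <- tibble(candidate_id = co$candidate_id, estimate = co$log2fc,
                std.error = sqrt(co$s2 * co$v), df = co$df)
  if ("t" %in% names(co)) {
    out$statistic <- co$t
    out$p.value <- co$p
  }
  out
}

#' Model-level summary of a dye-swap fit
#'
#' @param x `dyeswap_fit`
#' @param ... unused
#' @return one-row tibble: number of candidates and arrays, duplicate-spot
#'   method, and (after moderation) the prior df `d0` and prior variance
#'   `s0_sq`.
#' @method glance dyeswap_fit
#' @export
glance.dyeswap_fit <- function(x, ...) {
  tibble(n_candidates = nrow(x$coefficients), n_arrays = x$n_arrays,
         dup_method = x$dup_method,
         d0 = x$d0 %||% NA_real_, s0_sq = x$s0_sq %||% NA_real_)
}

#' @export
print.dyeswap_fit <- function(x, ...) {
  cat(sprintf("Dye-swap linear model fit: %d candidates, %d arrays (%s spots)\n",
              nrow(x$coefficients), x$n_arrays, x$dup_method))
  if (!is.null(x$d0)) {
    cat(sprintf("  empirical-Bayes prior: d0 = %s, s0^2 = %.4g\n",
                format(x$d0), x$s0_sq))
  }
  invisible(x)
}

#' @export
print.ncarray_analysis <- function(x, ...) {
  n_de <- sum(x$de$de_call, na.rm = TRUE)
  cat(sprintf("ncarray analysis: %d candidates, %d pass PM>MM filter, %d DE (adj. p < 0.05)\n",
              nrow(x$de), sum(x$de$passed_pm_mm_filter), n_de))
  invisible(x)
}
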