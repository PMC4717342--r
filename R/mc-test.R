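#' Empirical Monte-Carlo p-value for an observed coinfected-line count
#'
#' Places an observed count within the Monte-Carlo null distribution. Tail
#' proportions use the add-one correction standard for Monte-Carlo tests —
#' the observed value counts as one additional replicate, so
#' `P(lower) = (#\{counts <= observed\} + 1) / (n_sims + 1)` and symmetrically
#' for the upper tail — which guarantees a strictly positive p-value. The
#' two-sided p-value is the doubled smaller tail, capped at 1; this is
#' conservative for the discrete, asymmetric nulls produced here. The
#' uncorrected proportion is also reported.
#'
#' @param null A `null_dist` from [null_distribution()] (any data frame with
#'   an `n_coinfected` column works).
#' @param observed Observed number of coinfected lines, in `[0, n_lines]`.
#' @param sidedness `"two-sided"` (default), `"lower"`, or `"upper"`.
#' @return An object of class `mc_test` with the observed count, p-value,
#'   uncorrected p-value, tail proportions, and null summaries; see [tidy()]
#'   and [glance()] methods.
#' @examples
#' nd <- null_distribution(strain_params(0.96, 0.943), 40, 4, 1000, seed = 1)
#' empirical_p_value(nd, observed = 11)
#' @export
empirical_p_value <- function(null, observed,
                              sidedness = c("two-sided", "lower", "upper")) {
  stopifnot(is.data.frame(null), "n_coinfected" %in% names(null))
  sidedness <- match.arg(sidedness)
  n_lines <- attr(null, "n_lines") %||% max(null$n_coinfected)
  observed <- assert_count(observed, "observed", allow_zero = TRUE)
  if (observed > n_lines) {
    abort(sprintf("`observed` must lie in [0, %d].", n_lines),
          class = "strainseg_validation_error")
  }

  counts <- null$n_coinfected
  n_sims <- length(counts)
  lo_raw <- mean(counts <= observed)
  up_raw <- mean(counts >= observed)
  lo <- (sum(counts <= observed) + 1) / (n_sims + 1)
  up <- (sum(counts >= observed) + 1) / (n_sims + 1)

  p <- switch(sidedness,
    "two-sided" = min(1, 2 * min(lo, up)),
    "lower" = lo,
    "upper" = up
  )
  p_raw <- switch(sidedness,
    "two-sided" = min(1, 2 * min(lo_raw, up_raw)),
    "lower" = lo_raw,
    "upper" = up_raw
  )

  structure(
    list(
      observed = observed, p_value = p, p_uncorrected = p_raw,
      sidedness = sidedness, n_sims = n_sims,
      tail_lower = lo, tail_upper = up,
      null_mean = mean(counts), null_sd = sd(counts),
      n_lines = n_lines,
      n_generations = attr(null, "n_generations"),
      params = attr(null, "params"), seed = attr(null, "seed")
    ),
    class = "mc_test"
  )
}

#' @export
print.mc_test <- function(x, ...) {
  cat("<mc_test> Monte-Carlo test of the coinfected-line count\n")
  cat(sprintf("  observed: %d of %d lines | null mean %.2f (sd %.2f), %d sims\n",
              x$observed, x$n_lines, x$null_mean, x$null_sd, x$n_sims))
  cat(sprintf("  %s p = %.4g (uncorrected %.4g)\n",
              x$sidedness, x$p_value, x$p_uncorrected))
  invisible(x)
}

#' Tidy a Monte-Carlo test result
#'
#' @param x An `mc_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the observed count, p-values, tail
#'   proportions, and null summaries.
#' @export
tidy.mc_test <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, p_value = x$p_value,
    p_uncorrected = x$p_uncorrected, sidedness = x$sidedness,
    tail_lower = x$tail_lower, tail_upper = x$tail_upper,
    null_mean = x$null_mean, null_sd = x$null_sd
  )
}

#' @rdname tidy.mc_test
#' @export
glance.mc_test <- function(x, ...) {
  tibble::tibble(
    n_sims = x$n_sims, n_lines = x$n_lines,
    n_generations = x$n_generations %||% NA_integer_,
    p_value = x$p_value
  )
}
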