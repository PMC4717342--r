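#' Estimate a transmission rate with an exact confidence interval
#'
#' Point estimate `k/n` with a Clopper–Pearson (exact) confidence interval,
#' computed from the beta-quantile construction:
#' lower = `qbeta(alpha/2, k, n - k + 1)` (0 when `k = 0`),
#' upper = `qbeta(1 - alpha/2, k + 1, n - k)` (1 when `k = n`).
#'
#' @param k Number of successes (e.g. infected offspring).
#' @param n Number of trials (offspring tested); must be >= 1.
#' @param level Confidence level, default 0.95.
#' @return A one-row tibble of class `rate_estimate` with columns
#'   `successes`, `trials`, `point`, `ci_low`, `ci_high`, `level`.
#' @examples
#' estimate_rate(12, 13)  # 92% co-transfer of the coinfection
#' @export
estimate_rate <- function(k, n, level = 0.95) {
  k <- assert_count(k, "k", allow_zero = TRUE)
  n <- assert_count(n, "n")
  if (k > n) abort("`k` must not exceed `n`.", class = "strainseg_validation_error")
  assert_probability(level, "level")
  alpha <- 1 - level
  lo <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  out <- tibble::tibble(
    successes = k, trials = n, point = k / n,
    ci_low = lo, ci_high = hi, level = level
  )
  class(out) <- c("rate_estimate", class(out))
  out
}

#' Expected co-transmission under independence
#'
#' If each strain is transmitted independently with its single-infection
#' probability, a coinfected mother transmits both to a given offspring with
#' probability `p1 * p2` — the independence expectation that observed
#' co-transmission rates are tested against.
#'
#' @inheritParams transition_matrix
#' @return The product `p1 * p2`.
#' @examples
#' independence_expectation(strain_params(0.96, 0.943))  # 0.905
#' @export
independence_expectation <- function(params) {
  params <- as_strain_params(params)
  params$p1 * params$p2
}

#' Exact binomial test of co-transmission
#'
#' Two-sided exact binomial test of `k` successes in `n` trials against a
#' null probability `p0` (typically the independence expectation
#' `p1 * p2`). The two-sided p-value follows the minimum-likelihood rule:
#' the sum of `P(X = x)` over every outcome no more likely than the observed
#' one (with the customary relative tolerance of 1e-7 on the density
#' comparison, so that ties are included).
#'
#' @param k,n Observed successes and trials.
#' @param p0 Null success probability.
#' @return An object of class `cotransmission_test`; see [tidy()] method.
#' @examples
#' cotransmission_test(39, 46, independence_expectation(c(0.96, 0.943)))
#' @export
cotransmission_test <- function(k, n, p0) {
  k <- assert_count(k, "k", allow_zero = TRUE)
  n <- assert_count(n, "n")
  if (k > n) abort("`k` must not exceed `n`.", class = "strainseg_validation_error")
  assert_probability(p0, "p0")
  if (p0 == 0 && k > 0) {
    abort("`p0` = 0 contradicts k > 0.", class = "strainseg_validation_error")
  }
  if (p0 == 1 && k < n) {
    abort("`p0` = 1 contradicts k < n.", class = "strainseg_validation_error")
  }
  if (p0 %in% c(0, 1)) {
    p <- 1   # the observed outcome is the only possible one
  } else {
    d <- dbinom(0:n, n, p0)
    p <- min(1, sum(d[d <= dbinom(k, n, p0) * (1 + 1e-07)]))
  }
  structure(
    list(k = k, n = n, p0 = p0, estimate = k / n,
         p_value = p, sidedness = "two-sided"),
    class = "cotransmission_test"
  )
}

#' @export
print.cotransmission_test <- function(x, ...) {
  cat("<cotransmission_test> exact binomial test\n")
  cat(sprintf("  %d / %d = %.3f vs p0 = %.4g; two-sided P = %.4g\n",
              x$k, x$n, x$estimate, x$p0, x$p_value))
  invisible(x)
}

#' Tidy an exact binomial co-transmission test
#'
#' @param x A `cotransmission_test` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.cotransmission_test <- function(x, ...) {
  tibble::tibble(
    successes = x$k, trials = x$n, estimate = x$estimate,
    null_value = x$p0, p_value = x$p_value, sidedness = x$sidedness
  )
}

#' Protection ratio for horizontal transfer
#'
#' How much harder it is for the virus to establish horizontally in an
#' already-infected recipient than in an uninfected one: the ratio of the
#' uninfected-recipient acquisition rate to the infected-recipient rate. A
#' ratio of about 2 reproduces the roughly twofold reduction observed for
#' both strains.
#'
#' @param rate_uninfected,rate_infected Acquisition rates for uninfected and
#'   already-infected recipients, as [estimate_rate()] results or bare
#'   proportions.
#' @return The ratio of point estimates; `Inf` (with a warning) when the
#'   infected-recipient rate is zero.
#' @examples
#' protection_ratio(0.71, 0.33)  # ~2.15 for strain 1
#' protection_ratio(0.78, 0.26)  # 3.0  for strain 2
#' @export
protection_ratio <- function(rate_uninfected, rate_infected) {
  pt <- function(x, arg) {
    if (inherits(x, "rate_estimate") || (is.data.frame(x) && "point" %in% names(x))) {
      x <- x$point
    }
    assert_probability(x, arg)
    x
  }
  u <- pt(rate_uninfected, "rate_uninfected")
  i <- pt(rate_infected, "rate_infected")
  if (i == 0) {
    warn("Infected-recipient rate is zero; protection ratio is infinite.")
    return(Inf)
  }
  u / i
}
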