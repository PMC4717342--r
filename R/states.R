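#' Infection statuses
#'
#' The model tracks each individual (or isofemale line) in one of four
#' infection statuses with respect to the two symbiont strains. The canonical
#' ordering returned here indexes every state vector and transition matrix in
#' the package.
#'
#' @return Character vector of the four statuses, in canonical order:
#'   `"uninfected"`, `"strain1"`, `"strain2"`, `"coinfected"`.
#' @examples
#' infection_statuses()
#' @export
infection_statuses <- function() {
  c("uninfected", "strain1", "strain2", "coinfected")
}

assert_status <- function(status, arg = "status") {
  if (!is.character(status) || length(status) != 1L ||
      !status %in% infection_statuses()) {
    abort(sprintf(
      "`%s` must be one of %s.",
      arg, paste0('"', infection_statuses(), '"', collapse = ", ")
    ))
  }
  status
}

#' Strain transmission parameters
#'
#' Bundles the per-strain vertical transmission probabilities measured in
#' single infection. Under the independence hypothesis these two numbers fully
#' determine the transition matrix of the coinfection Markov chain.
#'
#' @param p1,p2 Vertical transmission probability of strain 1 (resp. strain 2)
#'   in single infection, in `[0, 1]`.
#' @param name1,name2 Free-text strain labels.
#' @return An object of class `strain_params`.
#' @examples
#' strain_params(0.96, 0.943)
#' @export
strain_params <- function(p1, p2, name1 = "strain1", name2 = "strain2") {
  assert_probability(p1, "p1")
  assert_probability(p2, "p2")
  structure(
    list(p1 = p1, p2 = p2, name1 = name1, name2 = name2),
    class = "strain_params"
  )
}

#' @export
print.strain_params <- function(x, ...) {
  cat("<strain_params>\n")
  cat(sprintf("  %s: p = %.4g\n", x$name1, x$p1))
  cat(sprintf("  %s: p = %.4g\n", x$name2, x$p2))
  invisible(x)
}

as_strain_params <- function(x) {
  if (inherits(x, "strain_params")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(strain_params(x[[1]], x[[2]]))
  abort("Cannot interpret `params`: supply `strain_params()` or two probabilities.")
}

#' Distribution of infection statuses at a generation
#'
#' A probability vector over the four infection statuses, tagged with the
#' generation it describes (founders are generation 0).
#'
#' @param probs Numeric vector of four probabilities summing to 1, in the
#'   canonical status order; a named vector is re-ordered by name.
#' @param generation Non-negative integer generation index.
#' @return An object of class `state_distribution`: a named probability vector
#'   with a `generation` attribute.
#' @examples
#' state_distribution(c(0, 0, 0, 1))       # all mass on coinfected founders
#' founder_distribution("coinfected")
#' @export
state_distribution <- function(probs, generation = 0L) {
  if (!is.numeric(probs) || length(probs) != 4L) {
    abort("`probs` must be a numeric vector of length 4.")
  }
  if (!is.null(names(probs))) {
    if (!setequal(names(probs), infection_statuses())) {
      abort("Named `probs` must use exactly the four canonical status names.")
    }
    probs <- probs[infection_statuses()]
  }
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12)) {
    abort("`probs` entries must lie in [0, 1].")
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    abort("`probs` must sum to 1 (within 1e-12).")
  }
  assert_count(generation, "generation", allow_zero = TRUE)
  structure(
    setNames(as.numeric(probs), infection_statuses()),
    generation = as.integer(generation),
    class = "state_distribution"
  )
}

#' @rdname state_distribution
#' @param status A single infection status; all probability mass is placed on
#'   it (generation 0).
#' @export
founder_distribution <- function(status = "coinfected") {
  assert_status(status)
  probs <- as.numeric(infection_statuses() == status)
  state_distribution(probs, generation = 0L)
}

#' @export
print.state_distribution <- function(x, ...) {
  cat(sprintf("<state_distribution> generation %d\n", attr(x, "generation")))
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Generation index of a state distribution
#'
#' @param x A `state_distribution`.
#' @return Integer generation.
#' @export
generation <- function(x) {
  stopifnot(inherits(x, "state_distribution"))
  attr(x, "generation")
}
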