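#' Transition matrix of the coinfection Markov chain
#'
#' Builds the 4x4 row-stochastic matrix of mother-to-offspring status
#' transitions under the independence hypothesis: each carried strain is
#' transmitted with its single-infection probability, irrespective of the
#' presence of the other strain. Uninfected mothers stay uninfected (the
#' chain has no horizontal transmission), and a mother cannot transmit a
#' strain she does not carry, so
#'
#' \deqn{M = \begin{pmatrix}
#'   1 & 0 & 0 & 0 \\
#'   1-P_1 & P_1 & 0 & 0 \\
#'   1-P_2 & 0 & P_2 & 0 \\
#'   (1-P_1)(1-P_2) & P_1(1-P_2) & (1-P_1)P_2 & P_1 P_2
#' \end{pmatrix}}
#'
#' with rows and columns in the canonical status order of
#' [infection_statuses()].
#'
#' @param params A [strain_params()] object (or a length-2 numeric `c(p1, p2)`).
#' @return A 4x4 matrix of class `transition_matrix`, rows = mother status,
#'   columns = offspring status.
#' @examples
#' m <- transition_matrix(strain_params(0.96, 0.943))
#' m["coinfected", "coinfected"]  # 0.96 * 0.943 = 0.905
#' @export
transition_matrix <- function(params) {
  params <- as_strain_params(params)
  p1 <- params$p1
  p2 <- params$p2
  s <- infection_statuses()
  m <- matrix(
    c(1,                   0,             0,             0,
      1 - p1,              p1,            0,             0,
      1 - p2,              0,             p2,            0,
      (1 - p1) * (1 - p2), p1 * (1 - p2), (1 - p1) * p2, p1 * p2),
    nrow = 4, byrow = TRUE,
    dimnames = list(mother = s, offspring = s)
  )
  structure(m, params = params, class = c("transition_matrix", "matrix", "array"))
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("<transition_matrix> (mother -> offspring)\n")
  m <- unclass(x)
  attr(m, "params") <- NULL
  print(round(m, digits))
  invisible(x)
}

#' Propagate a status distribution across generations
#'
#' Applies the recursion `G[n+1] = G[n] %*% M` the requested number of times:
#' the distribution of infection statuses after `n_generations` further rounds
#' of vertical transmission.
#'
#' @param g0 A [state_distribution()].
#' @param m A [transition_matrix()].
#' @param n_generations Non-negative number of transitions to apply.
#' @return A `state_distribution` at generation
#'   `generation(g0) + n_generations`.
#' @examples
#' m <- transition_matrix(strain_params(0.96, 0.943))
#' propagate(founder_distribution("coinfected"), m, 4)
#' @export
propagate <- function(g0, m, n_generations = 1L) {
  stopifnot(inherits(g0, "state_distribution"), inherits(m, "transition_matrix"))
  n_generations <- assert_count(n_generations, "n_generations", allow_zero = TRUE)
  g <- as.numeric(g0)
  for (i in seq_len(n_generations)) {
    g <- as.numeric(g %*% unclass(m))
  }
  state_distribution(g, generation = generation(g0) + n_generations)
}

#' Closed-form strain retention probability
#'
#' Marginal probability that a strain carried by a founder is still present
#' after `n` generations of vertical transmission under the independence
#' matrix: simply `p^n`, because retention each generation is an independent
#' Bernoulli event with probability `p`, unaffected by the other strain.
#'
#' @param p Single-infection vertical transmission probability.
#' @param n Non-negative number of generations.
#' @return `p^n`.
#' @examples
#' retention_closed_form(0.96, 4)  # 0.84934656
#' @export
retention_closed_form <- function(p, n) {
  assert_probability(p, "p")
  n <- assert_count(n, "n", allow_zero = TRUE)
  p^n
}

#' Write or read a transition matrix as JSON
#'
#' Serializes the matrix with status labels as keys (canonical ordering
#' preserved), so the file is self-describing.
#'
#' @param m A [transition_matrix()].
#' @param path File path.
#' @return `write_transition_json()` returns `path` invisibly;
#'   `read_transition_json()` returns a `transition_matrix`.
#' @export
write_transition_json <- function(m, path) {
  stopifnot(inherits(m, "transition_matrix"))
  params <- attr(m, "params")
  payload <- list(
    statuses = infection_statuses(),
    params = list(p1 = params$p1, p2 = params$p2,
                  name1 = params$name1, name2 = params$name2),
    rows = purrr::map(
      setNames(infection_statuses(), infection_statuses()),
      function(r) as.list(setNames(unclass(m)[r, ], infection_statuses()))
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transition_json
#' @export
read_transition_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- strain_params(payload$params$p1, payload$params$p2,
                          payload$params$name1, payload$params$name2)
  m <- transition_matrix(params)
  stored <- t(vapply(
    payload$rows[infection_statuses()],
    function(r) unlist(r)[infection_statuses()],
    numeric(4)
  ))
  if (max(abs(stored - unclass(m))) > 1e-12) {
    abort("Stored matrix entries are inconsistent with the stored parameters.")
  }
  m
}

#' Write or read a state distribution as JSON
#'
#' @param g A [state_distribution()].
#' @param path File path.
#' @return `write_state_json()` returns `path` invisibly;
#'   `read_state_json()` returns a `state_distribution`.
#' @export
write_state_json <- function(g, path) {
  stopifnot(inherits(g, "state_distribution"))
  payload <- list(
    generation = generation(g),
    probs = as.list(setNames(as.numeric(g), names(g)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state_json
#' @export
read_state_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  state_distribution(unlist(payload$probs), generation = payload$generation)
}
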