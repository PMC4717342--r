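new_report <- function(command, parameters, seed, results) {
  structure(
    list(
      command = command,
      parameters = parameters,
      seed = seed,
      package = "strainseg",
      version = as.character(packageVersion("strainseg")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      results = results
    ),
    class = "strainseg_report"
  )
}

#' @export
print.strainseg_report <- function(x, ...) {
  cat(sprintf("<strainseg_report> %s (seed %s)\n", x$command,
              if (is.null(x$seed)) "NULL" else format(x$seed)))
  utils::str(x$results, give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Write a run report as JSON
#'
#' Every stochastic result embeds the parameters and seed that reproduce it,
#' so any report can be regenerated exactly.
#'
#' @param report A `strainseg_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "strainseg_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the Monte-Carlo coinfected-line test end to end
#'
#' Builds the null distribution of coinfected-line counts under independence
#' ([null_distribution()]) and places the observed count within it
#' ([empirical_p_value()]). This is the headline analysis: with the measured
#' rates (0.96, 0.943), 40 lines and 4 generations, an observed count of 11
#' coinfected lines falls far below the null.
#'
#' @param p1,p2 Single-infection vertical transmission probabilities.
#' @param lines,generations,sims Design of the Monte-Carlo null.
#' @param observed Observed number of coinfected lines.
#' @param seed Integer seed.
#' @param null_out Optional path; when given, the null counts are written
#'   there as TSV.
#' @return A `strainseg_report` whose `results` hold the test summary and
#'   null-distribution summary.
#' @examples
#' run_null_test(0.96, 0.943, observed = 11, sims = 200, seed = 1)
#' @export
run_null_test <- function(p1, p2, lines = 40, generations = 4, sims = 1000,
                          observed, seed = NULL, null_out = NULL) {
  params <- strain_params(p1, p2)
  nd <- null_distribution(params, n_lines = lines, n_generations = generations,
                          n_sims = sims, seed = seed)
  test <- empirical_p_value(nd, observed = observed)
  if (!is.null(null_out)) {
    readr::write_tsv(tibble::as_tibble(nd), null_out)
  }
  new_report(
    command = "null_test",
    parameters = list(p1 = p1, p2 = p2, lines = lines,
                      generations = generations, sims = sims,
                      observed = observed),
    seed = seed,
    results = c(
      as.list(tidy(test)),
      list(expected_coinfected = lines * (p1 * p2)^generations)
    )
  )
}

#' Test an observed co-transmission proportion against independence
#'
#' Computes the independence expectation `p1 * p2` and runs the exact
#' binomial test of `k` coinfected offspring among `n` against it.
#'
#' @param k,n Coinfected offspring among offspring scored.
#' @param p1,p2 Single-infection vertical transmission probabilities.
#' @return A `strainseg_report`.
#' @examples
#' run_cotransmission(39, 46, 0.96, 0.943)
#' @export
run_cotransmission <- function(k, n, p1, p2) {
  params <- strain_params(p1, p2)
  expectation <- independence_expectation(params)
  test <- cotransmission_test(k, n, expectation)
  new_report(
    command = "cotransmit",
    parameters = list(k = k, n = n, p1 = p1, p2 = p2),
    seed = NULL,
    results = c(list(expected_cotransmission = expectation), as.list(tidy(test)))
  )
}

#' Generate a synthetic experiment and write it to disk
#'
#' Dispatches to the matching generator and writes its table as TSV:
#' `"vertical"` and `"horizontal"` produce the individuals format
#' ([write_individuals()]), `"segregation"` the lineage format
#' ([write_lineages()]).
#'
#' @param config A [generator_config()] or the path to a config file
#'   ([read_generator_config()]).
#' @param experiment One of `"vertical"`, `"segregation"`, `"horizontal"`.
#' @param out Output TSV path.
#' @param ... Design arguments passed to the generator (e.g. `n_mothers`,
#'   `n_lines`, `n_vials`, `seed`). Defaults: vertical — 20 mothers of 5
#'   offspring; segregation — 40 lines, 4 generations; horizontal — 4 vials
#'   of 25 offspring.
#' @return A `strainseg_report`; the generated tibble is attached as
#'   attribute `"data"`.
#' @export
run_synthesis <- function(config, experiment = c("vertical", "segregation",
                                                 "horizontal"),
                          out, ...) {
  if (is.character(config)) config <- read_generator_config(config)
  stopifnot(inherits(config, "generator_config"))
  experiment <- match.arg(experiment)
  defaults <- switch(experiment,
    vertical = list(n_mothers = 20, offspring_per_mother = 5),
    segregation = list(n_lines = 40, n_generations = 4),
    horizontal = list(n_vials = 4, offspring_per_vial = 25)
  )
  args <- utils::modifyList(defaults, list(...))
  gen <- switch(experiment,
    vertical = gen_vertical_experiment,
    segregation = gen_segregation_experiment,
    horizontal = gen_horizontal_experiment
  )
  dat <- do.call(gen, c(list(config), args))
  if (experiment == "segregation") write_lineages(dat, out)
  else write_individuals(dat, out)
  report <- new_report(
    command = paste0("synth/", experiment),
    parameters = list(
      p1 = config$params$p1, p2 = config$params$p2, gamma = config$gamma,
      rho = config$rho, h = config$h, false_negative = config$false_negative,
      vial_effect_sd = config$vial_effect_sd, out = out
    ),
    seed = attr(dat, "seed") %||% config$seed,
    results = list(n_records = nrow(dat), out = out)
  )
  attr(report, "data") <- dat
  report
}
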