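#' Synthetic-data generator configuration
#'
#' Collects every knob of the synthetic experiments in one object. With the
#' defaults (`gamma = 1`, `rho = 1` off-diagonal knobs at their null values
#' where noted) the generators collapse exactly to the independence model the
#' analysis assumes, so generated data provide a calibrated null; moving
#' `gamma` below 1 injects within-host competition for vertical transmission
#' and moving `rho` below 1 injects protection against horizontal
#' superinfection.
#'
#' @param params [strain_params()]; defaults to the measured single-infection
#'   rates (0.96, 0.943).
#' @param gamma Competition multiplier in `[0, 1]` applied to each strain's
#'   vertical transmission probability while the mother is coinfected;
#'   1 = independence.
#' @param rho Protection multiplier in `[0, 1]` on horizontal-transfer
#'   success when the recipient is already infected; 1 = no protection. The
#'   default 0.45 reproduces the observed roughly twofold reduction.
#' @param h Per-offspring probability of horizontal acquisition when the
#'   recipient is uninfected; the default 0.75 brackets the observed 71–78%.
#' @param false_negative Probability a carried strain is missed by PCR
#'   (default 0).
#' @param vial_effect_sd Standard deviation of a per-vial random effect on
#'   the logit of `h` (default 0 = off).
#' @param seed Optional integer seed used by the generators.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(params = strain_params(0.96, 0.943),
                             gamma = 1, rho = 0.45, h = 0.75,
                             false_negative = 0, vial_effect_sd = 0,
                             seed = NULL) {
  params <- as_strain_params(params)
  assert_probability(gamma, "gamma")
  assert_probability(rho, "rho")
  assert_probability(h, "h")
  assert_probability(false_negative, "false_negative")
  stopifnot(is.numeric(vial_effect_sd), vial_effect_sd >= 0)
  structure(
    list(params = params, gamma = gamma, rho = rho, h = h,
         false_negative = false_negative, vial_effect_sd = vial_effect_sd,
         seed = seed),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  p1 = %.4g, p2 = %.4g, gamma = %.3g, rho = %.3g, h = %.3g\n",
              x$params$p1, x$params$p2, x$gamma, x$rho, x$h))
  cat(sprintf("  false_negative = %.3g, vial_effect_sd = %.3g, seed = %s\n",
              x$false_negative, x$vial_effect_sd,
              if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}

#' Read a generator configuration from a file
#'
#' Accepts either JSON or plain `key=value` lines (`#` comments allowed).
#' Recognised keys: `p1`, `p2`, `name1`, `name2`, `gamma`, `rho`, `h`,
#' `false_negative`, `vial_effect_sd`, `seed`.
#'
#' @param path Path to the configuration file.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  first <- trimws(paste(txt, collapse = " "))
  vals <- if (startsWith(first, "{")) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- trimws(txt)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) abort(sprintf("Malformed config line: %s", lines[bad][1]))
    vals <- lapply(kv, function(x) {
      v <- trimws(x[2])
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) v else num
    })
    setNames(vals, trimws(vapply(kv, `[`, "", 1)))
  }
  known <- c("p1", "p2", "name1", "name2", "gamma", "rho", "h",
             "false_negative", "vial_effect_sd", "seed")
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  if (!all(c("p1", "p2") %in% names(vals))) {
    abort("Config must define keys `p1` and `p2`.")
  }
  params <- strain_params(vals$p1, vals$p2,
                          vals$name1 %||% "strain1", vals$name2 %||% "strain2")
  generator_config(
    params = params,
    gamma = vals$gamma %||% 1,
    rho = vals$rho %||% 0.45,
    h = vals$h %||% 0.75,
    false_negative = vals$false_negative %||% 0,
    vial_effect_sd = vals$vial_effect_sd %||% 0,
    seed = if (is.null(vals$seed)) NULL else as.integer(vals$seed)
  )
}

#' Generate a synthetic vertical-transmission experiment
#'
#' Emulates scoring the offspring of infected mothers by PCR: each offspring
#' inherits each maternal strain independently with that strain's
#' single-infection probability, multiplied by `gamma` when the mother is
#' coinfected; each carried strain is then missed with probability
#' `false_negative` when the bands are read.
#'
#' @param config A [generator_config()].
#' @param n_mothers Number of mothers (one vial each).
#' @param offspring_per_mother Offspring scored per mother.
#' @param mother_status Infection status of every mother.
#' @param seed Optional seed overriding `config$seed`.
#' @return An individuals tibble (`individual_id`, `line_id`, `generation`,
#'   `bands`, `status`) ready for [write_individuals()]; the generating
#'   configuration is stored as an attribute.
#' @export
gen_vertical_experiment <- function(config, n_mothers, offspring_per_mother,
                                    mother_status = "coinfected",
                                    seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n_mothers <- assert_count(n_mothers, "n_mothers")
  offspring_per_mother <- assert_count(offspring_per_mother, "offspring_per_mother")
  assert_status(mother_status, "mother_status")
  seed <- seed %||% config$seed

  mom <- presence_from_status(mother_status)
  co <- mom$s1 && mom$s2
  p1 <- config$params$p1 * (if (co) config$gamma else 1)
  p2 <- config$params$p2 * (if (co) config$gamma else 1)
  n <- n_mothers * offspring_per_mother

  drew <- with_seed_(seed, {
    s1 <- mom$s1 & (runif(n) < p1)
    s2 <- mom$s2 & (runif(n) < p2)
    o1 <- s1 & (runif(n) >= config$false_negative)
    o2 <- s2 & (runif(n) >= config$false_negative)
    list(o1 = o1, o2 = o2)
  })

  out <- tibble::tibble(
    individual_id = sprintf("ind%04d", seq_len(n)),
    line_id = rep(seq_len(n_mothers), each = offspring_per_mother),
    generation = 1L,
    bands = bands_from_presence(drew$o1, drew$o2),
    status = status_from_presence(drew$o1, drew$o2)
  )
  structure(out, config = config, mother_status = mother_status, seed = seed,
            class = class(out))
}

#' Generate a synthetic segregation experiment
#'
#' Emulates following coinfected isofemale lines for several generations of
#' strictly vertical transmission (a single female founds each next
#' generation). Delegates to [simulate_lineages()]; with `gamma = 1` the
#' generated data follow the independence null exactly, so the output can be
#' used to calibrate the Monte-Carlo test.
#'
#' @inheritParams gen_vertical_experiment
#' @param n_lines Number of isofemale lines (default 40).
#' @param n_generations Generations of vertical transmission (default 4).
#' @return A `lineage_tbl`, as from [simulate_lineages()].
#' @export
gen_segregation_experiment <- function(config, n_lines = 40, n_generations = 4,
                                       seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  simulate_lineages(
    config$params, n_lines = n_lines, n_generations = n_generations,
    founder_status = "coinfected", seed = seed %||% config$seed,
    gamma = config$gamma, false_negative = config$false_negative
  )
}

#' Generate a synthetic horizontal-transfer experiment
#'
#' Emulates superparasitism trials in which offspring of a recipient line
#' share Drosophila hosts with an infected donor line. Each recipient
#' offspring acquires the donor's strain with probability `h`, reduced by
#' the factor `rho` when the recipient line is already infected
#' (protection); a coinfected donor transmits both strains jointly in a
#' single acquisition event with the same probability, so co-transfer is not
#' rarer than single-strain transfer. A resident strain is retained with its
#' vertical transmission probability. With `vial_effect_sd > 0` a per-vial
#' normal deviate on the logit of the acquisition probability induces
#' vial-level clustering.
#'
#' @inheritParams gen_vertical_experiment
#' @param n_vials Number of replicate vials.
#' @param offspring_per_vial Recipient-line offspring scored per vial.
#' @param donor_status Infection status of the donor line (`"strain1"`,
#'   `"strain2"` or `"coinfected"`).
#' @param recipient_status Status of the recipient line (`"uninfected"`,
#'   `"strain1"` or `"strain2"`).
#' @return An individuals tibble as in [gen_vertical_experiment()], with
#'   `line_id` identifying the vial.
#' @export
gen_horizontal_experiment <- function(config, n_vials, offspring_per_vial,
                                      donor_status = "strain1",
                                      recipient_status = "uninfected",
                                      seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n_vials <- assert_count(n_vials, "n_vials")
  offspring_per_vial <- assert_count(offspring_per_vial, "offspring_per_vial")
  assert_status(donor_status, "donor_status")
  assert_status(recipient_status, "recipient_status")
  if (donor_status == "uninfected") {
    abort("`donor_status` must carry at least one strain.",
          class = "strainseg_validation_error")
  }
  seed <- seed %||% config$seed

  donor <- presence_from_status(donor_status)
  res <- presence_from_status(recipient_status)
  protected <- recipient_status != "uninfected"
  n <- n_vials * offspring_per_vial
  vial <- rep(seq_len(n_vials), each = offspring_per_vial)

  drew <- with_seed_(seed, {
    h_eff <- config$h * (if (protected) config$rho else 1)
    if (config$vial_effect_sd > 0 && h_eff > 0 && h_eff < 1) {
      lo <- stats::qlogis(h_eff) + stats::rnorm(n_vials, 0, config$vial_effect_sd)
      h_vial <- stats::plogis(lo)[vial]
    } else {
      h_vial <- rep(h_eff, n)
    }
    acquired <- runif(n) < h_vial          # one event; coinfected donors give both
    a1 <- acquired & donor$s1
    a2 <- acquired & donor$s2
    r1 <- res$s1 & (runif(n) < config$params$p1)
    r2 <- res$s2 & (runif(n) < config$params$p2)
    s1 <- a1 | r1
    s2 <- a2 | r2
    o1 <- s1 & (runif(n) >= config$false_negative)
    o2 <- s2 & (runif(n) >= config$false_negative)
    list(o1 = o1, o2 = o2)
  })

  out <- tibble::tibble(
    individual_id = sprintf("ind%04d", seq_len(n)),
    line_id = vial,
    generation = 1L,
    bands = bands_from_presence(drew$o1, drew$o2),
    status = status_from_presence(drew$o1, drew$o2)
  )
  structure(out, config = config, donor_status = donor_status,
            recipient_status = recipient_status, seed = seed,
            class = class(out))
}
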