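#' Read and write per-individual infection records
#'
#' The individuals TSV is the package's exchange format for genotyping data:
#' UTF-8, tab-separated, header required, columns `individual_id`, `line_id`,
#' `generation`, and `bands` (semicolon-separated fragment lengths in bp,
#' empty for no amplification) and/or `status` (vocabulary exactly
#' `uninfected`, `strain1`, `strain2`, `coinfected`). An optional
#' `control_ok` logical column flags records whose insect-control PCR
#' succeeded.
#'
#' @param records Data frame of individual records; a `bands` list-column is
#'   serialized as semicolon-separated integers.
#' @param path File path.
#' @return `write_individuals()` returns `path` invisibly;
#'   `read_individuals()` returns a tibble with `bands` as a list-column of
#'   integer vectors (when present).
#' @export
write_individuals <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- tibble::as_tibble(records)
  if ("bands" %in% names(out)) out$bands <- format_bands(out$bands)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_individuals
#' @export
read_individuals <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           bands = readr::col_character(),
                           .default = readr::col_guess()
                         ))
  if (!all(c("individual_id", "line_id", "generation") %in% names(out))) {
    abort("Individuals TSV must have individual_id, line_id and generation columns.")
  }
  if (!("bands" %in% names(out)) && !("status" %in% names(out))) {
    abort("Individuals TSV must have a `bands` or a `status` column.")
  }
  if ("bands" %in% names(out)) {
    out$bands <- parse_bands(tidyr::replace_na(out$bands, ""))
  }
  if ("status" %in% names(out)) {
    bad <- setdiff(unique(out$status), infection_statuses())
    if (length(bad)) {
      abort(sprintf("Unknown status value(s): %s.", paste(bad, collapse = ", ")))
    }
  }
  out
}

#' Read and write lineage tables
#'
#' The lineage TSV records one infection status per isofemale line per
#' generation (columns `line_id`, `generation`, `status`).
#'
#' @param lineages A `lineage_tbl` or any conforming data frame.
#' @param path File path.
#' @return `write_lineages()` returns `path` invisibly; `read_lineages()`
#'   returns a `lineage_tbl` tibble.
#' @export
write_lineages <- function(lineages, path) {
  stopifnot(is.data.frame(lineages),
            all(c("line_id", "generation", "status") %in% names(lineages)))
  readr::write_tsv(lineages[, c("line_id", "generation", "status")], path)
  invisible(path)
}

#' @rdname write_lineages
#' @export
read_lineages <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           line_id = readr::col_integer(),
                           generation = readr::col_integer(),
                           status = readr::col_character()
                         ))
  bad <- setdiff(unique(out$status), infection_statuses())
  if (length(bad)) {
    abort(sprintf("Unknown status value(s): %s.", paste(bad, collapse = ", ")))
  }
  structure(out, class = c("lineage_tbl", class(out)))
}
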