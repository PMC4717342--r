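#' PCR deletion-marker model
#'
#' The two strains are distinguished on a single PCR marker: the reference
#' strain amplifies the full-length fragment, while the variant strain
#' carries a deletion and amplifies a shorter one. Defaults describe the
#' LbFV marker: a 399-bp reference amplicon, a 111-bp deletion, and a
#' 205-aa protein encoded by the reference open reading frame.
#'
#' @param ref_amplicon_bp Reference amplicon length (bp).
#' @param deletion_bp Deletion length (bp); must be smaller than the amplicon.
#' @param ref_orf_aa Length of the protein encoded by the reference ORF (aa).
#' @return An object of class `marker_model`.
#' @examples
#' variant_lengths(marker_model())
#' @export
marker_model <- function(ref_amplicon_bp = 399L, deletion_bp = 111L,
                         ref_orf_aa = 205L) {
  ref_amplicon_bp <- assert_count(ref_amplicon_bp, "ref_amplicon_bp")
  deletion_bp <- assert_count(deletion_bp, "deletion_bp", allow_zero = TRUE)
  ref_orf_aa <- assert_count(ref_orf_aa, "ref_orf_aa")
  if (deletion_bp >= ref_amplicon_bp) {
    abort("`deletion_bp` must be smaller than `ref_amplicon_bp`.",
          class = "strainseg_validation_error")
  }
  structure(
    list(ref_amplicon_bp = ref_amplicon_bp, deletion_bp = deletion_bp,
         ref_orf_aa = ref_orf_aa),
    class = "marker_model"
  )
}

#' Variant amplicon and protein lengths
#'
#' Marker arithmetic for the deleted strain: the variant amplicon is the
#' reference minus the deletion; if the deletion length is a multiple of 3
#' it leaves the reading frame intact and the variant protein is shortened
#' by one residue per deleted codon, otherwise the deletion frameshifts and
#' no protein length is predicted.
#'
#' @param model A [marker_model()].
#' @return A one-row tibble with `variant_amplicon_bp`, `variant_orf_aa`
#'   (`NA` for frameshifting deletions), and `in_frame`.
#' @examples
#' variant_lengths(marker_model(399, 111, 205))  # 288 bp, 168 aa, in frame
#' @export
variant_lengths <- function(model = marker_model()) {
  stopifnot(inherits(model, "marker_model"))
  in_frame <- model$deletion_bp %% 3L == 0L
  tibble::tibble(
    variant_amplicon_bp = model$ref_amplicon_bp - model$deletion_bp,
    variant_orf_aa = if (in_frame) model$ref_orf_aa - model$deletion_bp %/% 3L
                     else NA_integer_,
    in_frame = in_frame
  )
}

#' Call an infection status from observed PCR bands
#'
#' A band within `tolerance_bp` of the reference amplicon indicates the
#' reference strain; one within tolerance of the variant amplicon indicates
#' the deleted strain; both bands together mean coinfection and no band
#' means uninfected.
#'
#' @param bands Integer vector of observed fragment lengths (bp); may be
#'   empty.
#' @param model A [marker_model()].
#' @param tolerance_bp Matching tolerance in bp (gel resolution); default 10.
#' @return A single infection status string.
#' @examples
#' call_genotype(c(399L, 288L))  # "coinfected"
#' call_genotype(integer(0))     # "uninfected"
#' @export
call_genotype <- function(bands, model = marker_model(), tolerance_bp = 10L) {
  stopifnot(inherits(model, "marker_model"))
  tolerance_bp <- assert_count(tolerance_bp, "tolerance_bp", allow_zero = TRUE)
  bands <- as.integer(bands)
  ref <- model$ref_amplicon_bp
  var <- ref - model$deletion_bp
  near_ref <- abs(bands - ref) <= tolerance_bp
  near_var <- abs(bands - var) <= tolerance_bp
  if (any(near_ref & near_var)) {
    abort(sprintf(
      "Band %d bp matches both the %d-bp and %d-bp references within %d bp.",
      bands[which(near_ref & near_var)[1]], ref, var, tolerance_bp
    ), class = "strainseg_ambiguity_error")
  }
  status_from_presence(any(near_ref), any(near_var))
}

#' Derive statuses for a table of individual records
#'
#' Applies [call_genotype()] to each record's band pattern, adding (or
#' overwriting) the `status` column. Records whose insect-control PCR failed
#' (`control_ok == FALSE`, when that column is present) are dropped, since
#' their band patterns are uninterpretable.
#'
#' @param records Data frame with a `bands` column: either a list-column of
#'   integer vectors or semicolon-separated strings (e.g. `"399;288"`).
#' @inheritParams call_genotype
#' @return The records as a tibble with a `status` column.
#' @export
genotype_records <- function(records, model = marker_model(), tolerance_bp = 10L) {
  stopifnot(is.data.frame(records), "bands" %in% names(records))
  records <- tibble::as_tibble(records)
  if ("control_ok" %in% names(records)) {
    records <- dplyr::filter(records, .data$control_ok %in% TRUE)
  }
  bands <- parse_bands(records$bands)
  records$status <- purrr::map_chr(bands, call_genotype,
                                   model = model, tolerance_bp = tolerance_bp)
  records
}

parse_bands <- function(bands) {
  if (is.list(bands)) {
    purrr::map(bands, as.integer)
  } else {
    purrr::map(as.character(bands), function(x) {
      if (is.na(x) || x == "") integer(0)
      else as.integer(strsplit(x, ";", fixed = TRUE)[[1]])
    })
  }
}

format_bands <- function(bands) {
  purrr::map_chr(parse_bands(bands), paste, collapse = ";")
}

# Bands implied by a true status after PCR dropout; inverse of call_genotype.
bands_from_presence <- function(s1, s2, model = marker_model()) {
  ref <- model$ref_amplicon_bp
  var <- ref - model$deletion_bp
  purrr::map2(s1, s2, function(a, b) c(if (a) ref, if (b) var))
}

#' Ordered presence/absence infection matrix
#'
#' Rewrites per-individual statuses as a 0/1 individuals-by-strains matrix
#' and reorders the rows for display (coinfected first, then strain-1-only,
#' strain-2-only, uninfected; ties broken by `individual_id`, stably). The
#' per-strain column sums are unchanged by the reordering.
#'
#' @param records Data frame with `individual_id` and `status` columns (run
#'   [genotype_records()] first if only bands are available).
#' @return A tibble with columns `individual_id`, `status`, `strain1`,
#'   `strain2` (0/1), in display order.
#' @export
order_infection_matrix <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("individual_id", "status") %in% names(records)))
  if (nrow(records) == 0L) abort("`records` must contain at least one row.")
  priority <- match(records$status,
                    c("coinfected", "strain1", "strain2", "uninfected"))
  if (anyNA(priority)) abort("Unknown status in `records`.")
  pres <- presence_from_status(records$status)
  out <- tibble::tibble(
    individual_id = records$individual_id,
    status = records$status,
    strain1 = as.integer(pres$s1),
    strain2 = as.integer(pres$s2)
  )
  out[order(priority, out$individual_id), ]
}

#' Write the ordered infection matrix as TSV
#'
#' @param x Result of [order_infection_matrix()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_infection_matrix <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
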