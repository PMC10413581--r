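#' Lesion volume in mm3
#'
#' Foreground voxel count times the voxel volume (product of spacings). At
#' the default 2 x 2 x 2 mm geometry each voxel contributes 8 mm3.
#'
#' @param mask a `wmh_mask`.
#' @return volume in mm3.
#' @export
lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "wmh_mask"))
  sum(mask$data) * prod(mask$spacing)
}

#' Signed over/under-segmentation ratio
#'
#' Volume-agreement score between a segmented volume `s` and the reference
#' volume `o`: `s / o` when `s <= o` (under-segmentation, in \[0, 1\]) and
#' `1 - s / o` when `s > o` (over-segmentation, negative for any `s > o`).
#' Values close to 1 mean accurate volumetry; negative values flag
#' over-prediction.
#'
#' @param s segmented volume(s), mm3, `>= 0`.
#' @param o reference volume(s), mm3, `> 0`.
#' @param digits decimals for half-away-from-zero rounding of the reported
#'   ratio; `NULL` leaves it unrounded.
#' @return numeric vector of ratios in `(-Inf, 1]`.
#' @export
signed_ratio <- function(s, o, digits = 4) {
  if (any(!is.finite(o)) || any(o <= 0))
    stop_wmh("reference volume must be positive", class = "wmh_domain_error")
  if (any(!is.finite(s)) || any(s < 0))
    stop_wmh("segmented volume must be finite and >= 0",
             class = "wmh_domain_error")
  r <- ifelse(s <= o, s / o, 1 - s / o)
  if (!is.null(digits)) r <- round_half_away(r, digits)
  r
}

#' Per-case ratio table
#'
#' Takes a long table of per-case volumes (one row per case and method) and
#' appends the signed segmentation ratio.
#'
#' @param volumes data frame with columns `case_id`, `cohort`,
#'   `original_mm3`, `method`, `segmented_mm3`.
#' @param digits rounding for the ratio column.
#' @return a tibble with a `ratio` column added.
#' @export
ratio_table <- function(volumes, digits = 4) {
  need <- c("case_id", "cohort", "original_mm3", "method", "segmented_mm3")
  miss <- setdiff(need, names(volumes))
  if (length(miss) > 0)
    stop_wmh("missing column(s): ", paste(miss, collapse = ", "),
             class = "wmh_config_error")
  out <- tibble::as_tibble(volumes)
  out$ratio <- unname(signed_ratio(unname(out$segmented_mm3),
                                   unname(out$original_mm3), digits = digits))
  class(out) <- c("wmh_ratio_table", class(out))
  out
}

#' Block means over consecutive groups of cases
#'
#' Within each cohort and method, cases (in table order) are split into
#' consecutive blocks of `block` cases and each volume column is averaged
#' per block, matching the summary rows of the reference volume tables.
#'
#' @param volumes long table as in [ratio_table()].
#' @param block cases per block; the per-cohort case count must be divisible
#'   by it.
#' @return tibble with `cohort`, `method`, `block`, `original_mm3`,
#'   `segmented_mm3` (block means).
#' @export
block_means <- function(volumes, block = 5) {
  volumes <- tibble::as_tibble(volumes)
  counts <- dplyr::count(dplyr::distinct(volumes, .data$cohort, .data$case_id),
                         .data$cohort)
  if (any(counts$n %% block != 0))
    stop_wmh("case count per cohort must be divisible by block = ", block,
             class = "wmh_partition_error")
  volumes |>
    dplyr::group_by(.data$cohort, .data$method) |>
    dplyr::mutate(block = (dplyr::row_number() - 1L) %/% block + 1L) |>
    dplyr::group_by(.data$cohort, .data$method, .data$block) |>
    dplyr::summarise(original_mm3 = mean(.data$original_mm3),
                     segmented_mm3 = mean(.data$segmented_mm3),
                     .groups = "drop")
}

#' Quantify predicted masks against reference masks
#'
#' Convenience wrapper pairing predicted and reference masks into the long
#' volume table consumed by [ratio_table()].
#'
#' @param pred named list of predicted `wmh_mask`s.
#' @param ref named list of reference `wmh_mask`s (same names).
#' @param cohort cohort label(s) recycled over cases.
#' @param method method label for the predictions.
#' @return a `wmh_ratio_table` tibble.
#' @export
quantify_masks <- function(pred, ref, cohort = "cohort", method = "ours") {
  stopifnot(length(pred) == length(ref))
  ids <- names(pred) %||% as.character(seq_along(pred))
  tbl <- tibble::tibble(
    case_id = ids,
    cohort = rep_len(cohort, length(pred)),
    original_mm3 = vapply(ref, lesion_volume, numeric(1)),
    method = method,
    segmented_mm3 = vapply(pred, lesion_volume, numeric(1)))
  ratio_table(tbl)
}

#' @export
autoplot.wmh_ratio_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$original_mm3,
                               y = .data$segmented_mm3,
                               colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$cohort), scales = "free") +
    ggplot2::labs(x = "reference WMH volume (mm3)",
                  y = "segmented WMH volume (mm3)")
}
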