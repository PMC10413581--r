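# Published reference tables from the dementia/MCI/NCI study cohort, shipped
# as plain CSV: per-case WMH volumes for three segmentation methods with the
# printed signed ratios, the per-block volume means, the per-group
# demographic/score summaries, and the printed LSD pairwise grid. These are
# inputs to the volumetry and statistics modules (e.g. for recomputing the
# printed ratio and block-mean arithmetic); they are not produced by this
# package.

ref_csv <- function(name) {
  path <- system.file("extdata", name, package = "wmhseg", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Reference cohort tables
#'
#' `wmh_reference_volumes()`: 60 cases (20 per cohort) with the reference
#' ("original") WMH volume and the volumes segmented by three methods
#' (`nnunet`, `nnunet_resnet`, `ours`), plus the ratios as printed.
#' `wmh_reference_block_means()`: the printed per-block (5 cases) volume
#' means. `wmh_reference_group_stats()`: per-group mean/SD of demographics
#' and the ten cognitive scores (groups coded 1/2/3). `wmh_reference_pairwise()`:
#' the printed LSD mean differences, standard errors and significance labels.
#'
#' @return a tibble.
#' @export
wmh_reference_volumes <- function() ref_csv("reference_volumes.csv")

#' @rdname wmh_reference_volumes
#' @export
wmh_reference_block_means <- function() ref_csv("reference_block_means.csv")

#' @rdname wmh_reference_volumes
#' @export
wmh_reference_group_stats <- function() ref_csv("reference_group_stats.csv")

#' @rdname wmh_reference_volumes
#' @export
wmh_reference_pairwise <- function() ref_csv("reference_pairwise.csv")

#' Reference volumes in long format
#'
#' Reshapes [wmh_reference_volumes()] into the long per-case/per-method
#' layout consumed by [ratio_table()] and [block_means()].
#'
#' @return tibble with `case_id`, `cohort`, `original_mm3`, `method`,
#'   `segmented_mm3`, `printed_ratio`.
#' @export
wmh_reference_volumes_long <- function() {
  wide <- wmh_reference_volumes()
  vols <- wide |>
    dplyr::select("cohort", "case", "original",
                  "nnunet", "nnunet_resnet", "ours") |>
    tidyr::pivot_longer(c("nnunet", "nnunet_resnet", "ours"),
                        names_to = "method", values_to = "segmented_mm3")
  ratios <- wide |>
    dplyr::select("cohort", "case", dplyr::starts_with("ratio_")) |>
    tidyr::pivot_longer(dplyr::starts_with("ratio_"),
                        names_to = "method", values_to = "printed_ratio",
                        names_prefix = "ratio_")
  dplyr::left_join(vols, ratios, by = c("cohort", "case", "method")) |>
    dplyr::transmute(case_id = as.character(.data$case),
                     cohort = .data$cohort,
                     original_mm3 = .data$original,
                     method = .data$method,
                     segmented_mm3 = .data$segmented_mm3,
                     printed_ratio = .data$printed_ratio)
}
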