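#' Sum of weights of the indicators present
#'
#' The raw evidence total behind the EBSA likelihood score: each indicator
#' with status `present` contributes its catalog weight; an OR-pair
#' contributes the weight of whichever variant was scored (2 threatened,
#' 1 plain, default catalog); data-deficient slots contribute nothing.
#'
#' @param data long record tibble (any number of seamounts).
#' @param catalog indicator catalog, see [ebsa_indicators()].
#' @return A tibble with columns `seamount`, `weight_sum`.
#' @export
present_weight_sum <- function(data, catalog = ebsa_indicators()) {
  check_records_frame(data)
  ind <- data[data$domain == "indicator", ]
  bad <- setdiff(ind$item, catalog$item)
  if (length(bad) > 0) abort_bad_items(bad, "indicator")
  ind |>
    dplyr::left_join(catalog[, c("item", "weight")], by = "item") |>
    dplyr::group_by(.data$seamount) |>
    dplyr::summarise(
      weight_sum = sum(.data$weight[.data$status == "present"]),
      .groups = "drop"
    )
}

# maximum achievable weight: best variant of every slot
max_weight_sum <- function(catalog = ebsa_indicators()) {
  catalog |>
    dplyr::mutate(slot = ifelse(is.na(.data$pair), .data$item, .data$pair)) |>
    dplyr::group_by(.data$slot) |>
    dplyr::summarise(w = max(.data$weight), .groups = "drop") |>
    dplyr::pull(.data$w) |>
    sum()
}

#' EBSA likelihood score
#'
#' Maps the weighted fraction of indicators present onto a 1-5 scale:
#' \deqn{S = 1 + 4 \, W / W_{max}}
#' where `W` is the present-weight sum and `Wmax` the maximum achievable
#' weight (21 for the default catalog, taking the threatened variant of each
#' OR-pair). The denominator is fixed at `Wmax` regardless of which pair
#' variant was scored or how many slots are data-deficient: the score is the
#' likelihood supported by the available evidence, and missing evidence is
#' carried separately by the uncertainty index. Scores of at most 3
#' (equivalently, `W <= 10`) are categorised `low`, above 3 `high`.
#'
#' @inheritParams present_weight_sum
#' @return A tibble with one row per seamount: `seamount`, `weight_sum`,
#'   `ebsa_score` (rounded half-up to 2 decimals), `ebsa_raw` (unrounded),
#'   `ebsa_category` (`"low"`/`"high"`, decided on the unrounded score).
#' @examples
#' case_study_seamounts() |> ebsa_score()
#' @export
ebsa_score <- function(data, catalog = ebsa_indicators()) {
  wmax <- max_weight_sum(catalog)
  present_weight_sum(data, catalog) |>
    dplyr::mutate(
      ebsa_raw = 1 + 4 * .data$weight_sum / wmax,
      ebsa_score = round_half_up(.data$ebsa_raw, 2),
      ebsa_category = ifelse(.data$ebsa_raw > 3, "high", "low")
    ) |>
    dplyr::select("seamount", "weight_sum", "ebsa_score", "ebsa_raw",
                  "ebsa_category")
}

#' EBSA component profile (radar axes)
#'
#' Per-typology presence on a 0-5 scale: for each typology, 5 times the
#' fraction of its indicator slots that are present (an OR-pair is one
#' slot whichever variant is scored). These are the yellow radar axes of
#' the per-seamount decomposition display.
#'
#' @inheritParams present_weight_sum
#' @return A long tibble with columns `seamount`, `typology`, `value`
#'   (0-5), five rows per seamount.
#' @export
ebsa_profile <- function(data, catalog = ebsa_indicators()) {
  check_records_frame(data)
  slot_info <- catalog |>
    dplyr::mutate(slot = ifelse(is.na(.data$pair), .data$item, .data$pair)) |>
    dplyr::distinct(.data$slot, .data$typology)
  slot_of <- stats::setNames(
    ifelse(is.na(catalog$pair), catalog$item, catalog$pair), catalog$item
  )
  ind <- data[data$domain == "indicator", ]
  bad <- setdiff(ind$item, catalog$item)
  if (length(bad) > 0) abort_bad_items(bad, "indicator")
  ind$slot <- slot_of[ind$item]

  present <- ind |>
    dplyr::group_by(.data$seamount, .data$slot) |>
    dplyr::summarise(present = any(.data$status == "present"), .groups = "drop")

  tidyr::expand_grid(seamount = unique(data$seamount), slot_info) |>
    dplyr::left_join(present, by = c("seamount", "slot")) |>
    dplyr::mutate(present = !is.na(.data$present) & .data$present) |>
    dplyr::group_by(.data$seamount, .data$typology) |>
    dplyr::summarise(value = 5 * mean(.data$present), .groups = "drop") |>
    dplyr::mutate(typology = factor(
      .data$typology, levels = unique(slot_info$typology)
    )) |>
    dplyr::arrange(.data$seamount, .data$typology)
}
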