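#' Data-deficiency fraction
#'
#' The proportion of a record's slots with no information at all:
#' denominator 10 for the indicator domain (an OR-pair is one slot,
#' whether scored or data-deficient) and 9 for the threat domain, with the
#' default catalogs.
#'
#' @param data long record tibble.
#' @param domain `"ebsa"` (indicator slots) or `"threat"` (activities).
#' @param indicators indicator catalog.
#' @param threats threat catalog.
#' @return A tibble `seamount`, `dd` (0-1).
#' @export
data_deficiency <- function(data, domain = c("ebsa", "threat"),
                            indicators = ebsa_indicators(),
                            threats = ebsa_threats()) {
  domain <- match.arg(domain)
  domain_slots(data, domain, indicators, threats) |>
    dplyr::group_by(.data$seamount) |>
    dplyr::summarise(dd = mean(.data$status == "DD"), .groups = "drop")
}

# one row per slot per seamount (pairs collapsed), with status and quality
domain_slots <- function(data, domain, indicators, threats) {
  check_records_frame(data)
  if (domain == "ebsa") {
    d <- data[data$domain == "indicator", ]
    slot_of <- stats::setNames(
      ifelse(is.na(indicators$pair), indicators$item, indicators$pair),
      indicators$item
    )
    bad <- setdiff(d$item, indicators$item)
    if (length(bad) > 0) abort_bad_items(bad, "indicator")
    d$slot <- unname(slot_of[d$item])
  } else {
    d <- data[data$domain == "threat", ]
    bad <- setdiff(d$item, threats$item)
    if (length(bad) > 0) abort_bad_items(bad, "threat")
    d$slot <- d$item
  }
  d[, c("seamount", "slot", "status", "quality")]
}

#' Evidence-based data-uncertainty index
#'
#' For one domain of a record, the sum of two components: the mean
#' data-quality weight over the scored (present/absent) slots — high
#' grades weigh 0, medium 0.5, low 1 — and the data-deficiency fraction.
#' The index is 0 when every slot is scored at high quality and approaches
#' its maximum of 2 for records that are entirely data-deficient (the mean
#' quality weight over an empty scored set is defined as 1, the worst
#' grade, so an all-deficient record attains exactly 2).
#'
#' @inheritParams data_deficiency
#' @return A tibble with one row per seamount: `seamount`, `domain`,
#'   `dq_mean`, `dd`, `uncertainty` (= `dq_mean + dd`, unrounded).
#' @examples
#' case_study_seamounts() |> uncertainty_index("ebsa")
#' @export
uncertainty_index <- function(data, domain = c("ebsa", "threat"),
                              indicators = ebsa_indicators(),
                              threats = ebsa_threats()) {
  domain <- match.arg(domain)
  domain_slots(data, domain, indicators, threats) |>
    dplyr::group_by(.data$seamount) |>
    dplyr::summarise(
      dq_mean = {
        w <- .quality_weight[.data$quality[.data$status %in%
                                             c("present", "absent")]]
        if (length(w) == 0) 1 else mean(w)
      },
      dd = mean(.data$status == "DD"),
      .groups = "drop"
    ) |>
    dplyr::mutate(domain = domain,
                  uncertainty = .data$dq_mean + .data$dd) |>
    dplyr::select("seamount", "domain", "dq_mean", "dd", "uncertainty")
}

#' Error bounds around a score
#'
#' The uncertainty index is drawn as a symmetric error bar: bounds are the
#' score minus and plus the index, deliberately not clipped to the 1-5
#' score range (an uncertain score near an end of the scale is allowed to
#' spill past it, signalling that the true category is unresolved).
#'
#' @param score numeric vector of scores (1-5 scale).
#' @param uncertainty numeric vector of uncertainty indices (0-2).
#' @return A tibble `lower`, `upper`.
#' @examples
#' error_bounds(3.29, 0.70)  # 2.59 to 3.99
#' @export
error_bounds <- function(score, uncertainty) {
  tibble::tibble(lower = score - uncertainty, upper = score + uncertainty)
}
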