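#' Assessment configuration
#'
#' Bundles the pieces a batch assessment needs. The defaults reproduce the
#' published framework: default catalogs, the packaged impact matrix, an
#' EBSA category boundary at 3 (scores above 3 are `high`), threat
#' boundaries at 1 (`none`) and 3 (`low`/`high`), two-decimal display
#' rounding.
#'
#' @param indicators indicator catalog, see [ebsa_indicators()].
#' @param threats threat catalog, see [ebsa_threats()].
#' @param groups ecological-group catalog, see [ebsa_groups()].
#' @param matrix impact matrix (anything [as_impact_matrix()] accepts).
#' @param digits display rounding, default 2.
#' @return A list of class `ebsa_config`.
#' @export
ebsa_config <- function(indicators = ebsa_indicators(),
                        threats = ebsa_threats(),
                        groups = ebsa_groups(),
                        matrix = default_impact_matrix(),
                        digits = 2) {
  structure(
    list(indicators = indicators, threats = threats, groups = groups,
         matrix = stop_on_invalid_matrix(matrix, threats, groups),
         digits = digits),
    class = "ebsa_config"
  )
}

#' Assess seamounts end to end
#'
#' Composes the whole framework for a batch of records: EBSA likelihood
#' score and category, threat score and category, the data-uncertainty
#' index and error bounds for both domains, and the portfolio cell.
#' Records are validated first; structural errors abort (with the
#' seamount named), warnings are relayed.
#'
#' @param data long record tibble.
#' @param config an [ebsa_config()].
#' @return A tibble of class `seamount_assessment`, one row per seamount:
#'   `seamount`, `weight_sum`, `ebsa_score`, `ebsa_raw`, `ebsa_category`,
#'   `ebsa_dq`, `ebsa_dd`, `ebsa_uncertainty`, `ebsa_lower`, `ebsa_upper`,
#'   `threat_score`, `threat_raw`, `threat_category`, `threat_dq`,
#'   `threat_dd`, `threat_uncertainty`, `threat_lower`, `threat_upper`,
#'   `portfolio`. Scores are display-rounded; `*_raw` keep full precision;
#'   bounds come from the raw values.
#' @examples
#' case_study_seamounts() |> assess_seamounts()
#' @export
assess_seamounts <- function(data, config = ebsa_config()) {
  stopifnot(inherits(config, "ebsa_config"))
  issues <- validate_records(data, config$indicators, config$threats)
  errs <- issues[issues$severity == "error", ]
  if (nrow(errs) > 0) {
    rlang::abort(
      paste0("invalid seamount record(s):\n",
             paste(sprintf("- [%s] %s", errs$seamount, errs$message),
                   collapse = "\n")),
      class = "seamountEBSA_invalid_record"
    )
  }
  for (w in unique(sprintf("[%s] %s",
                           issues$seamount[issues$severity == "warning"],
                           issues$message[issues$severity == "warning"]))) {
    rlang::warn(w)
  }

  dg <- config$digits
  e <- ebsa_score(data, config$indicators)
  t <- threat_score(data, config$matrix)
  ue <- uncertainty_index(data, "ebsa", config$indicators, config$threats)
  ut <- uncertainty_index(data, "threat", config$indicators, config$threats)

  out <- e |>
    dplyr::left_join(
      dplyr::select(ue, "seamount", ebsa_dq = "dq_mean", ebsa_dd = "dd",
                    ebsa_uncertainty_raw = "uncertainty"),
      by = "seamount") |>
    dplyr::left_join(t, by = "seamount") |>
    dplyr::left_join(
      dplyr::select(ut, "seamount", threat_dq = "dq_mean", threat_dd = "dd",
                    threat_uncertainty_raw = "uncertainty"),
      by = "seamount") |>
    dplyr::mutate(
      ebsa_uncertainty = round_half_up(.data$ebsa_uncertainty_raw, dg),
      threat_uncertainty = round_half_up(.data$threat_uncertainty_raw, dg),
      ebsa_lower = round_half_up(.data$ebsa_raw -
                                   .data$ebsa_uncertainty_raw, dg),
      ebsa_upper = round_half_up(.data$ebsa_raw +
                                   .data$ebsa_uncertainty_raw, dg),
      threat_lower = round_half_up(.data$threat_raw -
                                     .data$threat_uncertainty_raw, dg),
      threat_upper = round_half_up(.data$threat_raw +
                                     .data$threat_uncertainty_raw, dg),
      portfolio = portfolio_class(.data$ebsa_category, .data$threat_category)
    ) |>
    dplyr::select(
      "seamount", "weight_sum", "ebsa_score", "ebsa_raw", "ebsa_category",
      "ebsa_dq", "ebsa_dd", "ebsa_uncertainty", "ebsa_uncertainty_raw",
      "ebsa_lower", "ebsa_upper",
      "threat_score", "threat_raw", "threat_category",
      "threat_dq", "threat_dd", "threat_uncertainty",
      "threat_uncertainty_raw", "threat_lower", "threat_upper", "portfolio"
    )
  class(out) <- c("seamount_assessment", class(out))
  out
}

#' Portfolio scatter data
#'
#' The (threat, EBSA) coordinates with symmetric uncertainty bars and the
#' portfolio cell, one row per seamount — the data behind the portfolio
#' plot, exportable as CSV.
#'
#' @param assessment a `seamount_assessment` from [assess_seamounts()].
#' @return A tibble `seamount`, `x` (threat score), `y` (EBSA score),
#'   `xerr`, `yerr`, `cell`.
#' @export
portfolio_plot_data <- function(assessment) {
  stopifnot(inherits(assessment, "seamount_assessment"))
  tibble::tibble(
    seamount = assessment$seamount,
    x = assessment$threat_score,
    y = assessment$ebsa_score,
    xerr = assessment$threat_uncertainty,
    yerr = assessment$ebsa_uncertainty,
    cell = assessment$portfolio
  )
}

#' Radar (component decomposition) data
#'
#' The two per-seamount component profiles: the EBSA typology profile
#' (fraction of indicators present per typology, 0-5) and the threat
#' profile (maximum impact per ecological group, 1-5), as labelled
#' axis/value pairs.
#'
#' @param data long record tibble.
#' @param config an [ebsa_config()].
#' @return A long tibble `seamount`, `profile` (`"ebsa"`/`"threat"`),
#'   `axis`, `value`.
#' @export
radar_data <- function(data, config = ebsa_config()) {
  e <- ebsa_profile(data, config$indicators) |>
    dplyr::transmute(.data$seamount, profile = "ebsa",
                     axis = as.character(.data$typology),
                     value = .data$value)
  t <- group_max_impacts(data, config$matrix) |>
    dplyr::transmute(.data$seamount, profile = "threat",
                     axis = as.character(.data$group),
                     value = as.numeric(.data$max_impact))
  dplyr::bind_rows(e, t)
}

#' Case-study threat-score constraints
#'
#' The (activity set, published threat score) pairs of the eight
#' case-study seamounts plus the standalone pelagic-longline score, as
#' shipped in `extdata/case_study_constraints.json`. Feeding these to
#' [fit_impact_matrix()] reproduces the packaged default matrix.
#'
#' @return A constraints tibble (see [read_score_constraints()]).
#' @export
case_study_constraints <- function() {
  read_score_constraints(system.file(
    "extdata", "case_study_constraints.json",
    package = "seamountEBSA", mustWork = TRUE
  ))
}

#' Write an assessment to JSON
#'
#' One object per seamount with display-rounded scores under the named
#' keys and full-precision values under `raw`.
#'
#' @param assessment a `seamount_assessment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assessment_json <- function(assessment, path) {
  stopifnot(inherits(assessment, "seamount_assessment"))
  recs <- lapply(seq_len(nrow(assessment)), function(i) {
    r <- assessment[i, ]
    list(
      seamount = r$seamount,
      W = r$weight_sum,
      ebsa_score = r$ebsa_score, ebsa_category = r$ebsa_category,
      ebsa_uncertainty = list(DQ = r$ebsa_dq, DD = r$ebsa_dd,
                              U = r$ebsa_uncertainty,
                              lower = r$ebsa_lower, upper = r$ebsa_upper),
      threat_score = r$threat_score, threat_category = r$threat_category,
      threat_uncertainty = list(DQ = r$threat_dq, DD = r$threat_dd,
                                U = r$threat_uncertainty,
                                lower = r$threat_lower,
                                upper = r$threat_upper),
      portfolio = as.character(r$portfolio),
      raw = list(ebsa_score = r$ebsa_raw, threat_score = r$threat_raw,
                 ebsa_uncertainty = r$ebsa_uncertainty_raw,
                 threat_uncertainty = r$threat_uncertainty_raw)
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.seamount_assessment <- function(x, ...) {
  cat(sprintf("Seamount assessment: %d seamount(s)\n", nrow(x)))
  shown <- dplyr::select(
    tibble::as_tibble(x),
    "seamount", "ebsa_score", "ebsa_category", "ebsa_uncertainty",
    "threat_score", "threat_category", "threat_uncertainty", "portfolio"
  )
  print(shown, n = Inf)
  invisible(x)
}
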