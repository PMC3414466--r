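#' Conservation portfolio cell
#'
#' Crosses the EBSA likelihood category with the threat category into the
#' four-cell conservation portfolio. A threat category of `"none"` maps to
#' the low-threat side: the portfolio contrasts pristine versus impacted
#' sites, and no recorded activity is the pristine extreme.
#'
#' @param ebsa_category character vector, `"low"`/`"high"`.
#' @param threat_category character vector, `"none"`/`"low"`/`"high"`.
#' @return A factor with levels `lowE_lowT`, `lowE_highT`, `highE_lowT`,
#'   `highE_highT`.
#' @examples
#' portfolio_class("high", "low")   # highE_lowT
#' @export
portfolio_class <- function(ebsa_category, threat_category) {
  stopifnot(all(ebsa_category %in% c("low", "high")),
            all(threat_category %in% c("none", "low", "high")))
  t_low <- threat_category %in% c("none", "low")
  cell <- ifelse(ebsa_category == "low",
                 ifelse(t_low, "lowE_lowT", "lowE_highT"),
                 ifelse(t_low, "highE_lowT", "highE_highT"))
  factor(cell, levels = c("lowE_lowT", "lowE_highT",
                          "highE_lowT", "highE_highT"))
}

#' Simulate dummy seamounts
#'
#' Generates hypothetical seamounts with randomly assigned indicator and
#' threat configurations, the device used to probe whether the scoring
#' framework spreads plausible records over all four portfolio cells.
#' Every indicator slot is independently present with probability
#' `p_indicator`; a present OR-pair is its threatened variant with
#' probability `p_threatened` (otherwise the plain variant; an absent pair
#' is recorded under the threatened-variant id); every activity is
#' independently present with probability `p_threat`. All observations
#' are graded high quality and none are data-deficient — the dummy test
#' exercises the scores, not the uncertainty index.
#'
#' @param n number of dummy seamounts.
#' @param p_indicator per-slot presence probability (default 0.5).
#' @param p_threatened probability a present OR-pair is the threatened
#'   variant (default 0.5).
#' @param p_threat per-activity presence probability (default 0.5).
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   first so runs are reproducible.
#' @param indicators indicator catalog.
#' @param threats threat catalog.
#' @return A long record tibble (`seamount` = `"dummy_0001"`, ...)
#'   compatible with every scoring function.
#' @examples
#' simulate_seamounts(5, seed = 1) |> assess_seamounts()
#' @export
simulate_seamounts <- function(n, p_indicator = 0.5, p_threatened = 0.5,
                               p_threat = 0.5, seed = NULL,
                               indicators = ebsa_indicators(),
                               threats = ebsa_threats()) {
  stopifnot(n >= 0, p_indicator >= 0, p_indicator <= 1,
            p_threatened >= 0, p_threatened <= 1,
            p_threat >= 0, p_threat <= 1)
  if (!is.null(seed)) set.seed(seed)
  empty <- tibble::tibble(seamount = character(), domain = character(),
                          item = character(), status = character(),
                          quality = character())
  if (n == 0) return(empty)

  pairs <- unique(indicators$pair[!is.na(indicators$pair)])
  singles <- indicators$item[is.na(indicators$pair)]
  variant_of <- function(p, role) {
    indicators$item[!is.na(indicators$pair) & indicators$pair == p &
                      indicators$variant == role]
  }
  names <- sprintf("dummy_%04d", seq_len(n))

  purrr::map_dfr(names, function(nm) {
    single_present <- stats::runif(length(singles)) < p_indicator
    ind_single <- tibble::tibble(
      seamount = nm, domain = "indicator", item = singles,
      status = ifelse(single_present, "present", "absent"), quality = "H"
    )
    ind_pairs <- purrr::map_dfr(pairs, function(p) {
      if (stats::runif(1) < p_indicator) {
        role <- if (stats::runif(1) < p_threatened) "threatened" else "plain"
        tibble::tibble(seamount = nm, domain = "indicator",
                       item = variant_of(p, role), status = "present",
                       quality = "H")
      } else {
        tibble::tibble(seamount = nm, domain = "indicator",
                       item = variant_of(p, "threatened"), status = "absent",
                       quality = "H")
      }
    })
    thr_present <- stats::runif(nrow(threats)) < p_threat
    thr <- tibble::tibble(
      seamount = nm, domain = "threat", item = threats$item,
      status = ifelse(thr_present, "present", "absent"), quality = "H"
    )
    dplyr::bind_rows(ind_single, ind_pairs, thr)
  })
}

#' Exact probability of a high EBSA category
#'
#' Probability that a randomly configured seamount (the
#' [simulate_seamounts()] law) scores above the EBSA category boundary,
#' computed exactly by convolving the per-slot weight distributions —
#' equivalent to enumerating all presence patterns and pair-variant
#' choices. Used as the analytic reference for simulated portfolio
#' proportions.
#'
#' @inheritParams simulate_seamounts
#' @param indicators indicator catalog.
#' @return A single probability.
#' @examples
#' ebsa_high_probability(0.5, 0.5)
#' @export
ebsa_high_probability <- function(p_indicator = 0.5, p_threatened = 0.5,
                                  indicators = ebsa_indicators()) {
  wmax <- max_weight_sum(indicators)
  # per-slot distribution over contributed weight
  slots <- split(indicators,
                 ifelse(is.na(indicators$pair), indicators$item,
                        indicators$pair))
  dist <- c(1, numeric(wmax))  # P(W = 0..wmax), start at W = 0
  for (sl in slots) {
    contrib <- if (nrow(sl) == 1) {
      stats::setNames(c(1 - p_indicator, p_indicator), c(0, sl$weight))
    } else {
      wt <- sl$weight[sl$variant == "threatened"]
      wp <- sl$weight[sl$variant == "plain"]
      stats::setNames(
        c(1 - p_indicator, p_indicator * p_threatened,
          p_indicator * (1 - p_threatened)),
        c(0, wt, wp)
      )
    }
    new <- numeric(wmax + 1)
    for (k in seq_along(contrib)) {
      w <- as.integer(names(contrib)[k])
      if (contrib[k] > 0) {
        new[(1 + w):(wmax + 1)] <- new[(1 + w):(wmax + 1)] +
          contrib[k] * dist[1:(wmax + 1 - w)]
      }
    }
    dist <- new
  }
  # high category: S > 3  <=>  W > wmax / 2  <=>  W >= floor(wmax/2) + 1
  w_min_high <- floor(wmax / 2) + 1
  sum(dist[(w_min_high + 1):(wmax + 1)])
}

#' Portfolio cell proportions
#'
#' Fractions of records falling in each of the four portfolio cells.
#'
#' @param data long record tibble.
#' @param matrix impact matrix, default [default_impact_matrix()].
#' @param indicators indicator catalog.
#' @return A tibble `cell`, `n`, `prop` with all four cells present
#'   (zero-filled); `prop` sums to 1 for non-empty input.
#' @export
portfolio_proportions <- function(data, matrix = default_impact_matrix(),
                                  indicators = ebsa_indicators()) {
  e <- ebsa_score(data, indicators)
  t <- threat_score(data, matrix)
  cells <- portfolio_class(
    e$ebsa_category[match(t$seamount, e$seamount)], t$threat_category
  )
  counts <- table(cells)
  tibble::tibble(
    cell = factor(names(counts), levels = levels(cells)),
    n = as.integer(counts),
    prop = as.integer(counts) / max(sum(counts), 1L)
  )
}
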