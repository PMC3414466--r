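#' Default EBSA indicator catalog
#'
#' Ten indicator slots spanning the benthic, benthopelagic, pelagic,
#' historical and geological components of a seamount ecosystem. Two slots
#' are OR-pairs: air-breathing visitors and visiting large pelagics are each
#' scored either as their threatened variant (weight 2, when red-listed
#' species are involved) or as their plain variant (weight 1), never both.
#' Weights reflect how many of the seven CBD EBSA criteria an indicator
#' speaks to; the `criteria` column keeps that mapping as metadata only.
#'
#' @return A tibble with one row per indicator variant (12 rows, 10 slots)
#'   and columns `item`, `label`, `typology`, `weight`, `pair`, `variant`,
#'   `criteria`. The slot id of a row is `pair` when set, otherwise `item`.
#' @examples
#' ebsa_indicators()
#' # maximum achievable weight (threatened variant of each pair): 21
#' sum(dplyr::filter(ebsa_indicators(), is.na(variant) | variant == "threatened")$weight)
#' @export
ebsa_indicators <- function() {
  tibble::tribble(
    ~item,                          ~label,                                  ~typology,       ~weight, ~pair,                ~variant,     ~criteria,
    "vents",                        "Hydrothermal vent communities",         "benthic",       3L,      NA,                   NA,           "C1;C4;C5",
    "macrophytes",                  "Macrophytes",                           "benthic",       3L,      NA,                   NA,           "C1;C5;C6",
    "corals",                       "Cold-water coral reefs/gardens",        "benthic",       3L,      NA,                   NA,           "C3;C4;C6",
    "sponges",                      "Sponge aggregations",                   "benthic",       3L,      NA,                   NA,           "C3;C4;C6",
    "aggregating_fish",             "Aggregating deep-sea fishes",           "benthopelagic", 2L,      NA,                   NA,           "C2;C4",
    "threatened_bottom_fish",       "Threatened bottom fishes and sharks",   "benthopelagic", 1L,      NA,                   NA,           "C3",
    "threatened_air_breathing",     "Threatened air-breathing visitors",     "pelagic",       2L,      "air_breathing",      "threatened", "C2;C3",
    "air_breathing",                "Air-breathing visitors",                "pelagic",       1L,      "air_breathing",      "plain",      "C2",
    "threatened_visiting_pelagics", "Threatened visiting large pelagics",    "pelagic",       2L,      "visiting_pelagics",  "threatened", "C2;C3",
    "visiting_pelagics",            "Visiting large pelagics",               "pelagic",       1L,      "visiting_pelagics",  "plain",      "C2",
    "naturalness",                  "Naturalness (no fishing/mining)",       "historical",    1L,      NA,                   NA,           "C7",
    "depth_shallow",                "Shallow summit (above 800 m)",          "geological",    1L,      NA,                   NA,           "C5"
  )
}

#' Default human-activity (threat) catalog
#'
#' The nine activities considered relevant to seamounts: eight fishing gears
#' and seafloor mineral extraction. Climate change and pollution are outside
#' the framework.
#'
#' @return A tibble with columns `item`, `label`, `kind`.
#' @export
ebsa_threats <- function() {
  tibble::tribble(
    ~item,                ~label,                        ~kind,
    "gillnet_bottom",     "Gillnet - bottom",            "fishing",
    "hook_and_line",      "Hook and line",               "fishing",
    "longline_bottom",    "Longline - bottom",           "fishing",
    "longline_pelagic",   "Longline - pelagic",          "fishing",
    "pots_traps",         "Pots and traps",              "fishing",
    "purse_seine",        "Purse seine",                 "fishing",
    "trawl_bottom",       "Trawl - bottom",              "fishing",
    "trawl_midwater",     "Trawl - midwater",            "fishing",
    "mineral_extraction", "Seafloor mineral extraction", "mining"
  )
}

#' Ecological groups rated in the impact matrix
#'
#' The five potentially threatened components over which gear and mining
#' impacts are rated: two benthic, one benthopelagic, two pelagic.
#'
#' @return A tibble with columns `group`, `label`, `realm`.
#' @export
ebsa_groups <- function() {
  tibble::tribble(
    ~group,                   ~label,                          ~realm,
    "physical_habitat",       "Physical habitat",              "benthic",
    "corals_and_sponges",     "Habitat-forming corals/sponges","benthic",
    "groundfish",             "Groundfish",                    "benthopelagic",
    "large_pelagics",         "Large pelagic fish",            "pelagic",
    "air_breathing_visitors", "Air-breathing visitors",        "pelagic"
  )
}

# slot ids of an indicator catalog (pair collapses to one slot)
indicator_slots <- function(catalog = ebsa_indicators()) {
  unique(ifelse(is.na(catalog$pair), catalog$item, catalog$pair))
}

# parse compact "1H"/"0M"/"DD" observation codes into status + quality
parse_obs_code <- function(code) {
  if (code == "DD") {
    return(list(status = "DD", quality = NA_character_))
  }
  list(
    status = if (substr(code, 1, 1) == "1") "present" else "absent",
    quality = substr(code, 2, 2)
  )
}

build_record <- function(name, ind_items, ind_codes, thr_codes) {
  threats <- ebsa_threats()$item
  stopifnot(length(ind_items) == length(ind_codes),
            length(thr_codes) == length(threats))
  ind <- purrr::map2_dfr(ind_items, ind_codes, function(it, code) {
    o <- parse_obs_code(code)
    tibble::tibble(seamount = name, domain = "indicator", item = it,
                   status = o$status, quality = o$quality)
  })
  thr <- purrr::map2_dfr(threats, thr_codes, function(it, code) {
    o <- parse_obs_code(code)
    tibble::tibble(seamount = name, domain = "threat", item = it,
                   status = o$status, quality = o$quality)
  })
  dplyr::bind_rows(ind, thr)
}

#' Eight case-study seamount records
#'
#' Indicator and threat observations for Sedlo, Condor, Rosemary,
#' Anton Dohrn and Josephine (North Atlantic), Gorringe (Northeast
#' Atlantic) and Bowie and Cobb (Gulf of Alaska), transcribed status by
#' status and grade by grade from the published case-study tables. An
#' OR-pair appears as a single row carrying the variant that was scored;
#' a pair with no information at all is a single data-deficient row under
#' its threatened-variant id.
#'
#' @return A long tibble with columns `seamount`, `domain`
#'   (`"indicator"`/`"threat"`), `item`, `status`
#'   (`"present"`/`"absent"`/`"DD"`), `quality` (`"H"`/`"M"`/`"L"` or `NA`
#'   for data-deficient observations); 19 rows per seamount.
#' @examples
#' case_study_seamounts() |> assess_seamounts()
#' @export
case_study_seamounts <- function() {
  base_items <- c("vents", "macrophytes", "corals", "sponges",
                  "aggregating_fish", "threatened_bottom_fish")
  tail_items <- c("naturalness", "depth_shallow")
  rec <- function(name, base, air_item, air, pel_item, pel, tail, thr) {
    build_record(name,
                 c(base_items, air_item, pel_item, tail_items),
                 c(base, air, pel, tail), thr)
  }
  dplyr::bind_rows(
    rec("Sedlo",
        c("0L", "0H", "1H", "1H", "1H", "1H"),
        "threatened_air_breathing", "1M",
        "threatened_visiting_pelagics", "1L",
        c("1H", "1H"),
        c("0H", "0M", "0M", "1L", "0M", "0H", "0H", "0H", "0H")),
    rec("Condor",
        c("0M", "0M", "1H", "1H", "1M", "1M"),
        "air_breathing", "1M",
        "threatened_visiting_pelagics", "1M",
        c("0M", "1H"),
        c("0M", "1M", "1M", "1M", "0M", "0M", "0M", "0M", "0M")),
    rec("Rosemary",
        c("DD", "0H", "1L", "DD", "1H", "1H"),
        "air_breathing", "1M",
        "threatened_visiting_pelagics", "DD",
        c("0M", "1H"),
        c("1M", "0M", "1M", "1M", "1M", "0M", "1M", "1M", "DD")),
    rec("Anton Dohrn",
        c("DD", "0H", "1M", "1L", "1H", "1H"),
        "threatened_air_breathing", "1M",
        "threatened_visiting_pelagics", "DD",
        c("0L", "1H"),
        c("0M", "0M", "1M", "0M", "1M", "0M", "1M", "0M", "DD")),
    rec("Josephine",
        c("DD", "0L", "1M", "1M", "1H", "1M"),
        "threatened_air_breathing", "1M",
        "threatened_visiting_pelagics", "DD",
        c("0M", "1M"),
        c("1L", "DD", "1L", "1L", "DD", "DD", "1L", "1L", "0H")),
    rec("Gorringe",
        c("DD", "1H", "1M", "1L", "1M", "1M"),
        "threatened_air_breathing", "1H",
        "threatened_visiting_pelagics", "DD",
        c("0M", "1H"),
        c("DD", "DD", "1M", "DD", "1L", "1L", "1L", "1L", "DD")),
    rec("Bowie",
        c("0M", "1M", "0M", "0M", "1M", "1M"),
        "threatened_air_breathing", "1M",
        "threatened_visiting_pelagics", "1M",
        c("0M", "1H"),
        c("0M", "1M", "1M", "0M", "1M", "0M", "0M", "0M", "0M")),
    rec("Cobb",
        c("DD", "1M", "0M", "0M", "1M", "1M"),
        "threatened_air_breathing", "1M",
        "threatened_visiting_pelagics", "1M",
        c("0H", "1H"),
        c("1M", "DD", "1H", "DD", "1H", "DD", "0H", "1H", "DD"))
  )
}
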