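# published per-seamount results used across test files
published_results <- function() {
  tibble::tribble(
    ~seamount,     ~ebsa,  ~ebsa_cat, ~threat, ~threat_cat, ~ebsa_u, ~threat_u,
    "Sedlo",        3.86,  "high",     2.60,   "low",        0.25,    0.28,
    "Condor",       3.48,  "high",     3.60,   "high",       0.35,    0.50,
    "Rosemary",     2.52,  "low",      5.00,   "high",       0.59,    0.61,
    "Anton Dohrn",  3.29,  "high",     3.60,   "high",       0.58,    0.61,
    "Josephine",    3.29,  "high",     5.00,   "high",       0.70,    1.16,
    "Gorringe",     3.86,  "high",     4.60,   "high",       0.58,    1.34,
    "Bowie",        3.10,  "high",     2.40,   "low",        0.45,    0.50,
    "Cobb",         3.10,  "high",     2.60,   "low",        0.49,    0.54
  )
}

# build a record tibble from compact presence specifications:
# ind = named character vector item -> status code ("1H","0M","DD"),
# thr likewise over the nine activities (in catalog order if unnamed)
make_record <- function(name, ind, thr) {
  parse1 <- function(code) {
    if (code == "DD") c("DD", NA_character_)
    else c(if (substr(code, 1, 1) == "1") "present" else "absent",
           substr(code, 2, 2))
  }
  rows <- function(domain, items, codes) {
    parsed <- vapply(codes, parse1, character(2))
    tibble::tibble(seamount = name, domain = domain, item = items,
                   status = parsed[1, ], quality = parsed[2, ])
  }
  thr_items <- if (is.null(names(thr))) ebsa_threats()$item else names(thr)
  dplyr::bind_rows(rows("indicator", names(ind), unname(ind)),
                   rows("threat", thr_items, unname(thr)))
}

# a fully scored all-absent record (high quality everywhere)
all_absent_record <- function(name = "blank") {
  ind <- rep("0H", 10)
  names(ind) <- c("vents", "macrophytes", "corals", "sponges",
                  "aggregating_fish", "threatened_bottom_fish",
                  "threatened_air_breathing", "threatened_visiting_pelagics",
                  "naturalness", "depth_shallow")
  make_record(name, ind, rep("0H", 9))
}

# all slots present, threatened variants, all activities present
all_present_record <- function(name = "everything") {
  ind <- rep("1H", 10)
  names(ind) <- c("vents", "macrophytes", "corals", "sponges",
                  "aggregating_fish", "threatened_bottom_fish",
                  "threatened_air_breathing", "threatened_visiting_pelagics",
                  "naturalness", "depth_shallow")
  make_record(name, ind, rep("1H", 9))
}
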